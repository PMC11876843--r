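test_that("JASPAR parsing preserves counts and normalises names", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(">M001 foxp2",
               "A [ 10  0  3 1 0 7 ]",
               "C [  0 12  3 1 0 1 ]",
               "G [  1  0  3 9 0 2 ]",
               "T [  1  0  3 1 12 2 ]"), f)
  ms <- read_motifs(f, "jaspar")
  expect_length(ms, 1)
  m <- ms[[1]]
  expect_equal(m$tf_name, "FOXP2")
  expect_equal(motif_width(m), 6)
  expect_equal(unname(m$counts[, "A"]), c(10, 0, 3, 1, 0, 7))
  expect_equal(unname(rowSums(m$freq)), rep(1, 6), tolerance = 1e-12)
})

test_that("TRANSFAC dialect parses and matches an equivalent JASPAR record", {
  f <- withr::local_tempfile(fileext = ".transfac")
  writeLines(c("ID T0001", "NA gata3", "PO A C G T",
               "01 8 1 1 2", "02 1 9 1 1", "03 2 2 6 2", "//"), f)
  ms <- read_motifs(f, "transfac")
  m <- ms[["GATA3"]]
  expect_equal(m$motif_id, "T0001")
  expect_equal(unname(m$counts[2, ]), c(1, 9, 1, 1))
})

test_that("degenerate and malformed motif files are handled", {
  f <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(character(0), f)
  expect_warning(ms <- read_motifs(f, "jaspar"), "empty")
  expect_length(ms, 0)

  writeLines(c(">M1 A_TF", "A [ 1 2 ]", "C [ 1 2 3 ]",
               "G [ 1 2 3 ]", "T [ 1 2 3 ]"), f)
  expect_error(read_motifs(f, "jaspar"), "M1")

  writeLines(c(">M1 TF1", "A [ 0 2 ]", "C [ 0 2 ]",
               "G [ 0 2 ]", "T [ 0 2 ]"), f)
  expect_error(read_motifs(f, "jaspar"), "positive count")

  writeLines(c(">M1 TF1", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]",
               ">M1 TF2", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]"), f)
  expect_error(read_motifs(f, "jaspar"), "duplicate")
})

test_that("consensus sequence scores maximally and Ns are skipped", {
  m <- make_motif("ACGTAC", tf = "TF1")
  h <- scan_sequence(motif_consensus(m), m, min_rel_score = 0.8)
  expect_equal(nrow(h[h$strand == "+", ]), 1)
  expect_equal(h$start[h$strand == "+"], 0L)
  expect_equal(h$rel_score[h$strand == "+"], 1)

  expect_equal(nrow(scan_sequence(strrep("N", 50), m, 0)), 0)
  expect_error(scan_sequence("ACGTXGT", m, 0.8), "invalid characters")
  # motif wider than sequence: empty, not an error
  expect_equal(nrow(scan_sequence("ACG", m, 0)), 0)
})

test_that("a planted consensus is recovered and scanning matches the
           score-every-window oracle", {
  set.seed(42)
  m <- make_motif("TTGACCAT", tf = "TF2")
  s <- random_dna(200)
  substr(s, 58, 65) <- motif_consensus(m)  # 0-based start 57
  hits <- scan_sequence(s, m, 0.8, seq_id = "sq")
  expect_true(any(hits$start == 57 & hits$end == 65))
  orc <- oracle_scan(s, m, 0.8)
  expect_equal(hits$start, orc$start)
  expect_equal(hits$strand, orc$strand)
  expect_equal(hits$score, orc$score, tolerance = 1e-12)
})

test_that("scan equals the exhaustive oracle on random sequences and motifs", {
  for (seed in 1:4) {
    set.seed(seed)
    w <- sample(5:15, 1)
    m <- make_motif(random_dna(w), tf = "TFR", strong = sample(5:20, 1))
    s <- random_dna(sample(50:500, 1))
    # low threshold so many windows qualify
    hits <- scan_sequence(s, m, 0.5)
    orc <- oracle_scan(s, m, 0.5)
    expect_equal(hits$start, orc$start, info = paste("seed", seed))
    expect_equal(hits$score, orc$score, tolerance = 1e-12)
  }
})

test_that("reverse-complement scanning yields the mirror-image hit set", {
  set.seed(7)
  m <- make_motif("GATAAG", tf = "TF3")
  s <- random_dna(300)
  h1 <- scan_sequence(s, m, 0.7)
  h2 <- scan_sequence(revcomp(s), m, 0.7)
  L <- nchar(s)
  mirrored <- data.frame(start = L - h2$end, end = L - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(h1$start, mirrored$start)
  expect_equal(h1$strand, mirrored$strand)
  expect_equal(h1$score, mirrored$score, tolerance = 1e-12)
})

test_that("raising the threshold never adds hits", {
  set.seed(11)
  m <- make_motif("CCGGAT", tf = "TF4")
  s <- random_dna(400)
  lo <- scan_sequence(s, m, 0.6)
  hi <- scan_sequence(s, m, 0.85)
  key <- function(h) paste(h$start, h$strand)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("binding matrix reflects hit presence and input ordering", {
  seq_ids <- sprintf("s%d", 1:3)
  tfs <- c("FOXP2", "GATA3")
  expect_equal(sum(build_binding_matrix(hits_df(character(0), character(0),
                                                integer(0)),
                                        seq_ids, tfs)), 0)
  one <- build_binding_matrix(hits_df("s1", "FOXP2", 10), seq_ids, tfs)
  expect_equal(sum(one), 1)
  expect_equal(one["s1", "FOXP2"], 1L)
  expect_error(build_binding_matrix(hits_df("sX", "FOXP2", 1), seq_ids, tfs),
               "unknown seq_id")
})

test_that("binding matrix equals a planted truth table", {
  set.seed(3)
  seq_ids <- sprintf("sq%02d", 1:10)
  tfs <- LETTERS[1:5]
  truth <- matrix(rbinom(50, 1, 0.4), 10, 5, dimnames = list(seq_ids, tfs))
  storage.mode(truth) <- "integer"
  hits <- do.call(rbind, lapply(seq_ids, function(sid) {
    present <- tfs[truth[sid, ] == 1]
    if (!length(present)) return(NULL)
    # several redundant hits per present TF; presence is all that matters
    do.call(rbind, lapply(present, function(tf)
      hits_df(sid, tf, sample(0:100, sample(1:3, 1)))))
  }))
  expect_equal(build_binding_matrix(hits, seq_ids, tfs), truth)
})

test_that("hit files round-trip through BED and TSV writers", {
  h <- hits_df("chrA", c("FOXP2", "GATA3"), c(5, 40), width = 8,
               rel = c(0.93, 1))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(h, bed)
  lines <- readLines(bed)
  expect_length(lines, 2)
  expect_equal(strsplit(lines[1], "\t")[[1]][5], "930")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(back$rel_score, h$rel_score)
})
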