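simple_catalog <- function(chrom, start, end,
                           ids = sprintf("crm_%d", seq_along(start))) {
  data.frame(crm_id = ids, chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

gr_track <- function(chrom, start, end, name = NULL) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         name = if (is.null(name))
                           sprintf("iv_%d", seq_along(start)) else name)
}

test_that("BED parsing validates lines and skips comments", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# a comment", "track name=demo",
               "chr1\t100\t200\tpeak1", "chr2\t5\t50\tpeak2"), f)
  gr <- read_bed(f)
  expect_length(gr, 2)
  expect_equal(S4Vectors::mcols(gr)$name, c("peak1", "peak2"))
  expect_equal(GenomicRanges::start(gr), c(101L, 6L))  # 1-based internal

  writeLines(c("chr1\t100\t200", "chr1\tx\t300"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t100"), f)
  expect_error(read_bed(f), "fewer than 3")
  writeLines(c("chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 1")
})

test_that("overlap uses half-open arithmetic with a 1 bp criterion", {
  crms <- simple_catalog("chr1", 100, 200, ids = "c1")
  expect_equal(intersect_track(crms, gr_track("chr1", 199, 300))$overlap_bp, 1L)
  expect_equal(nrow(intersect_track(crms, gr_track("chr1", 200, 300))), 0)
  # chromosome-name normalisation: "1" and "chr1" intersect
  expect_equal(nrow(intersect_track(crms, gr_track("1", 150, 160))), 1)
  # alt contigs pass through verbatim and do not collide
  alt <- simple_catalog("chr1_alt", 0, 50, ids = "c2")
  expect_equal(nrow(intersect_track(alt, gr_track("chr1", 0, 50))), 0)
})

test_that("interval intersection equals the quadratic all-pairs oracle", {
  set.seed(14)
  n_crm <- 200; n_iv <- 500
  crms <- simple_catalog(sample(c("chr1", "chr2", "2"), n_crm, TRUE),
                         start <- sample(0:5000, n_crm, TRUE),
                         start + sample(20:400, n_crm, TRUE))
  ivs <- data.frame(chrom = sample(c("chr1", "2", "chr3"), n_iv, TRUE),
                    start = s2 <- sample(0:5000, n_iv, TRUE),
                    end = s2 + sample(10:300, n_iv, TRUE),
                    stringsAsFactors = FALSE)
  got <- intersect_track(crms, gr_track(ivs$chrom, ivs$start, ivs$end))
  got <- got[order(got$crm_id, got$interval_index), ]
  crms_n <- crms; crms_n$chrom <- normalize_chroms(crms_n$chrom)
  ivs_n <- ivs; ivs_n$chrom <- normalize_chroms(ivs_n$chrom)
  orc <- oracle_overlap_pairs(crms_n, ivs_n)
  expect_equal(got$crm_id, orc$crm_id)
  expect_equal(got$interval_index, orc$interval_index)
  expect_equal(got$overlap_bp, orc$overlap_bp)
  # symmetry: total overlapped bp is direction-independent
  swapped <- simple_catalog(ivs$chrom, ivs$start, ivs$end,
                            ids = sprintf("iv%04d", seq_len(n_iv)))
  back <- intersect_track(swapped,
                          gr_track(crms$chrom, crms$start, crms$end))
  expect_equal(sum(got$overlap_bp), sum(back$overlap_bp))
})

test_that("feature matrix columns mirror track coverage", {
  crms <- simple_catalog("chr1", c(0, 100, 200), c(50, 150, 250))
  full <- gr_track("chr1", 0, 300, name = "all")
  none <- GenomicRanges::GRanges()
  m <- build_feature_matrix(crms, list(everything = full, nothing = none))
  expect_equal(unname(m$matrix[, "everything"]), c(1L, 1L, 1L))
  expect_equal(unname(m$matrix[, "nothing"]), c(0L, 0L, 0L))
  expect_equal(unname(m$track_counts), c(3, 0))
  expect_error(build_feature_matrix(crms, list()), "at least one")
})

test_that("planted track memberships are recovered in the feature matrix", {
  cfg <- sim_config(seed = 6, n_crms = 40L, n_planted = 5L,
                    crms_per_contig = 20L, crm_length = 400L,
                    crm_spacer = 100L)
  cat_out <- generate_crm_catalog(cfg)
  ts <- generate_tracks_and_scores(cfg, cat_out$catalog)
  fm <- build_feature_matrix(cat_out$catalog, ts$tracks)
  for (tn in names(ts$tracks)) {
    truth <- ts$memberships$crm_id[ts$memberships$track == tn]
    expect_setequal(rownames(fm$matrix)[fm$matrix[, tn] == 1L], truth)
  }
  # column sums equal per-track counts from intersect
  expect_equal(unname(fm$track_counts),
               unname(colSums(fm$matrix)))
})

test_that("core-set rules behave under all_of and k_of modes", {
  mat <- rbind(c1 = c(h = 1L, d = 1L, t = 1L),
               c2 = c(h = 1L, d = 0L, t = 0L),
               c3 = c(h = 0L, d = 1L, t = 1L),
               c4 = c(h = 1L, d = 1L, t = 0L))
  expect_equal(core_set(mat, mode = "all_of"), "c1")
  expect_equal(core_set(mat, mode = "k_of", k = 2), c("c1", "c3", "c4"))
  expect_equal(core_set(mat, required = "h", mode = "all_of"),
               c("c1", "c2", "c4"))
  expect_error(core_set(mat, required = "zz"), "unknown")
  # monotonicity: all-tracks all_of is a subset of any-subset all_of
  expect_true(all(core_set(mat, mode = "all_of") %in%
                    core_set(mat, required = c("h", "d"), mode = "all_of")))

  # class collapsing: two histone marks union into one class indicator
  mat2 <- rbind(c1 = c(K4 = 1L, K27 = 0L, DN = 1L, TF = 0L),
                c2 = c(K4 = 0L, K27 = 0L, DN = 1L, TF = 1L))
  cls <- c(K4 = "histone", K27 = "histone", DN = "dnase", TF = "tfchip")
  expect_equal(core_set(mat2, mode = "k_of", k = 2, classes = cls),
               c("c1", "c2"))
  expect_equal(core_set(mat2, mode = "k_of", k = 3, classes = cls),
               character(0))
})

test_that("SNP overlap honours half-open boundaries", {
  crms <- simple_catalog("chr5", 100, 200, ids = "c1")
  at_start <- data.frame(rsid = "rs1", chrom = "chr5", pos = 100L)
  at_end <- data.frame(rsid = "rs2", chrom = "chr5", pos = 200L)
  expect_equal(snp_overlap(crms, at_start)$rsid, "rs1")
  expect_equal(nrow(snp_overlap(crms, at_end)), 0)

  set.seed(18)
  st <- sample(0:20000, 50)
  crms50 <- simple_catalog("chr1", st, st + sample(50:300, 50, TRUE),
                           ids = sprintf("c%02d", 1:50))
  snps <- data.frame(rsid = sprintf("rs%03d", 1:200), chrom = "chr1",
                     pos = sample(0:25000, 200), stringsAsFactors = FALSE)
  got <- snp_overlap(crms50, snps)
  exp <- do.call(rbind, lapply(seq_len(50), function(i) {
    inside <- snps$pos >= crms50$start[i] & snps$pos < crms50$end[i]
    if (!any(inside)) return(NULL)
    data.frame(crm_id = crms50$crm_id[i], rsid = snps$rsid[inside],
               stringsAsFactors = FALSE)
  }))
  key <- function(d) sort(paste(d$crm_id, d$rsid))
  expect_equal(key(got), key(exp))
})

test_that("SNP TSV reader converts 1-based positions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tposition", "rs2630772\tchr12:101"), f)
  s <- read_snps_tsv(f)
  expect_equal(s$pos, 100L)
  expect_equal(s$chrom, "chr12")
})
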