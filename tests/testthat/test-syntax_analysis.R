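TRIAD <- c("HES5", "FOXP2", "GATA3")

sites_from <- function(tfs, starts, width = 10L, seq_id = "e1") {
  hits_df(seq_id, tfs, starts, width = width)
}

test_that("ordered_sites sorts stably and collapses positional ties", {
  expect_equal(nrow(ordered_sites(hits_df(character(0), character(0),
                                          integer(0)))), 0)
  h <- rbind(hits_df("e1", "GATA3", 50), hits_df("e1", "FOXP2", 50))
  os <- ordered_sites(h)
  expect_equal(os$tf_name, c("FOXP2", "GATA3"))  # lexicographic at ties

  # same TF, same start, different scores: best rel_score survives
  dup <- rbind(hits_df("e1", "HES5", 10, rel = 0.85),
               hits_df("e1", "HES5", 10, rel = 0.95))
  expect_equal(ordered_sites(dup)$rel_score, 0.95)

  set.seed(21)
  sh <- hits_df("e1", sample(TRIAD, 12, TRUE), sample(0:500, 12))
  os <- ordered_sites(sh)
  expect_equal(os$start, sort(sh$start))
})

test_that("adjacency requires exactly the triad with no intervening motif", {
  s1 <- sites_from(c("HES5", "FOXP2", "GATA3"), c(0, 30, 60))
  occ <- find_adjacent_triads(s1, TRIAD)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$center_tf, "FOXP2")
  expect_equal(occ$order, "HES5-FOXP2-GATA3")
  expect_equal(occ$left_gap, 20)   # 30 - (0 + 10)
  expect_equal(occ$right_gap, 20)

  s2 <- sites_from(c("HES5", "SOX2", "FOXP2", "GATA3"), c(0, 15, 30, 60))
  expect_equal(nrow(find_adjacent_triads(s2, TRIAD)), 0)
  # but ignoring SOX2 restores adjacency among the analysis set
  expect_equal(nrow(find_adjacent_triads(s2, TRIAD, tf_set = TRIAD)), 1)
})

test_that("triad detection equals the brute-force adjacency oracle", {
  tf_pool <- c(TRIAD, "SOX2", "PAX6")
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(4:14, 1)
    h <- hits_df("e1", sample(tf_pool, n, TRUE),
                 sample(seq(0, 2000, by = 15), n))
    occ <- find_adjacent_triads(h, TRIAD)
    orc <- oracle_triads(ordered_sites(h), TRIAD)
    expect_equal(nrow(occ), length(orc), info = paste("seed", seed))
    if (length(orc)) {
      orc_df <- do.call(rbind, orc)
      expect_equal(occ$left_start, orc_df$left_start)
      expect_equal(occ$center_tf, orc_df$center_tf)
    }
  }
})

test_that("each sequence contributes one arrangement (leftmost occurrence)", {
  h <- rbind(
    sites_from(c("HES5", "FOXP2", "GATA3"), c(0, 30, 60), seq_id = "a"),
    sites_from(c("GATA3", "HES5", "FOXP2"), c(300, 340, 380), seq_id = "a"),
    sites_from(c("HES5", "GATA3", "FOXP2"), c(0, 40, 80), seq_id = "b"))
  occ <- find_adjacent_triads(h, TRIAD)
  arr <- count_arrangements(occ, TRIAD)
  expect_equal(arr$n_sequences, 2)
  expect_equal(unname(arr$counts[c("FOXP2", "GATA3")]), c(1L, 1L))
  expect_equal(unname(arr$counts["HES5"]), 0L)  # second occurrence on 'a' ignored
  expect_equal(sum(arr$counts), arr$n_sequences)
})

test_that("arrangement frequencies follow the counts", {
  occ <- do.call(rbind, lapply(seq_len(16), function(i) {
    ctr <- rep(c("FOXP2", "HES5", "GATA3"), c(10, 4, 2))[i]
    ord <- switch(ctr, FOXP2 = c("HES5", "FOXP2", "GATA3"),
                  HES5 = c("GATA3", "HES5", "FOXP2"),
                  GATA3 = c("HES5", "GATA3", "FOXP2"))
    sites_from(ord, c(0, 50, 100), seq_id = sprintf("hs%02d", i))
  }))
  arr <- count_arrangements(find_adjacent_triads(occ, TRIAD), TRIAD)
  expect_equal(arr$n_sequences, 16)
  expect_equal(unname(arr$counts[c("FOXP2", "HES5", "GATA3")]),
               c(10L, 4L, 2L))
  expect_equal(unname(arr$frequencies[c("FOXP2", "HES5", "GATA3")]),
               c(0.625, 0.25, 0.125))
})

test_that("Fisher arrangement test matches hypergeometric enumeration", {
  expect_error(fisher_arrangement_test(1, 1, 0), "positive")
  expect_equal(fisher_arrangement_test(5, 5, 12), 1.0)
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:30, 1)
    a <- sample(0:n, 1); b <- sample(0:n, 1)
    expect_equal(fisher_arrangement_test(a, b, n), oracle_fisher(a, b, n),
                 tolerance = 1e-12, info = sprintf("(%d,%d,%d)", a, b, n))
  }
})

test_that("spacing summaries report per-pair mean, sd and extremes", {
  one <- find_adjacent_triads(
    sites_from(c("HES5", "FOXP2", "GATA3"), c(0, 45, 115)), TRIAD)
  sp <- spacing_stats(one)
  expect_equal(sort(sp$pair), c("FOXP2-GATA3", "FOXP2-HES5"))
  expect_equal(sp$mean_bp, sp$min_bp)
  expect_equal(sp$mean_bp, sp$max_bp)
  expect_equal(sp$sd_bp, c(0, 0))

  # gaps uniform(50, 250): mean near 150
  set.seed(31)
  n <- 200
  g1 <- floor(runif(n, 50, 251)); g2 <- floor(runif(n, 50, 251))
  w <- 10L
  occ <- do.call(rbind, lapply(seq_len(n), function(i)
    sites_from(c("HES5", "FOXP2", "GATA3"),
               c(0, w + g1[i], 2 * w + g1[i] + g2[i]),
               seq_id = sprintf("sq%03d", i))))
  sp <- spacing_stats(find_adjacent_triads(occ, TRIAD))
  mu <- mean(c(g1, g2)); se <- sd(c(g1, g2)) / sqrt(2 * n)
  expect_equal(sum(sp$n), 2 * n)
  pooled <- sum(sp$mean_bp * sp$n) / sum(sp$n)
  expect_equal(pooled, mu, tolerance = 1e-12)   # same data, exact
  expect_lt(abs(pooled - 150), 3 * 58 / sqrt(2 * n) + 5)

  # min/max carry their originating sequence ids
  hes <- sp[sp$pair == "FOXP2-HES5", ]
  expect_equal(hes$min_bp, min(g1))
  expect_equal(hes$min_seq_id, sprintf("sq%03d", which.min(g1)))
})

test_that("population sd uses the n denominator", {
  occ <- find_adjacent_triads(rbind(
    sites_from(c("HES5", "FOXP2", "GATA3"), c(0, 20, 60), seq_id = "a"),
    sites_from(c("HES5", "FOXP2", "GATA3"), c(0, 40, 120), seq_id = "b")),
    TRIAD)
  samp <- spacing_stats(occ, "sample")
  pop <- spacing_stats(occ, "population")
  expect_equal(pop$sd_bp, samp$sd_bp * sqrt(1 / 2), tolerance = 1e-12)
})

test_that("long spacing tables summarise like occurrence tables", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tpair\tgap", "hs240\tFOXP2-GATA3\t35",
               "hs957\tFOXP2-GATA3\t504", "hs123\tFOXP2-HES5\t43"), f)
  long <- read_spacing_table(f)
  sm <- summarize_spacing(long)
  fg <- sm[sm$pair == "FOXP2-GATA3", ]
  expect_equal(fg$n, 2)
  expect_equal(fg$mean_bp, (35 + 504) / 2)
  expect_equal(fg$min_seq_id, "hs240")
  expect_equal(fg$max_seq_id, "hs957")
})
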