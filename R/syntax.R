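# Ordered-triad syntax detection: adjacency, arrangement counts, Fisher
# arrangement tests and inter-site spacing statistics.

#' Order the motif hits of one sequence
#'
#' Stable sort by (start, end, tf_name), retaining only TFs in `tf_set` when
#' given. Hits of one TF that tie at the same start position are collapsed to
#' the single highest-scoring hit, so each genomic site is represented once.
#'
#' @param hits Hit data.frame for a single sequence.
#' @param tf_set Optional character vector of TF names to retain.
#' @return Sorted hit data.frame.
#' @export
ordered_sites <- function(hits, tf_set = NULL) {
  if (nrow(hits) && length(unique(hits$seq_id)) > 1L)
    stop("ordered_sites() expects hits from a single sequence")
  if (!is.null(tf_set)) hits <- hits[hits$tf_name %in% tf_set, , drop = FALSE]
  if (!nrow(hits)) { rownames(hits) <- NULL; return(hits) }
  # collapse (tf, start) ties to the best-scoring hit
  keykey <- paste(hits$tf_name, hits$start)
  hits <- hits[order(keykey, -hits$rel_score), , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$tf_name, hits$start)), , drop = FALSE]
  hits <- hits[order(hits$start, hits$end, hits$tf_name), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find adjacent ordered triads on sorted site lists
#'
#' Slides a window of three consecutive sites along each sequence's ordered
#' site list (ordered over the full analysis TF set, so "adjacent" means no
#' intervening site of any analysed TF) and reports every window whose TF
#' names are exactly the triad, one of each. Gaps are edge-to-edge:
#' `center$start - left$end` and `right$start - center$end` (floored at zero
#' for overlapping site calls).
#'
#' @param hits Hit data.frame (one or many sequences); each sequence's hits
#'   are passed through [ordered_sites()] internally.
#' @param triad Character vector of exactly 3 distinct TF names.
#' @param tf_set TF names defining "no intervening motif"; defaults to all
#'   TFs present in `hits`.
#' @return Data.frame of occurrences: `seq_id`, `order` (e.g.
#'   "HES5-FOXP2-GATA3"), `center_tf`, left/center/right TF, start and end
#'   columns, `left_gap`, `right_gap`, `span`.
#' @export
find_adjacent_triads <- function(hits, triad, tf_set = NULL) {
  if (length(triad) != 3L || anyDuplicated(triad))
    stop("triad must name exactly 3 distinct TFs")
  triad <- toupper(triad)
  if (is.null(tf_set)) tf_set <- unique(hits$tf_name)
  out <- list()
  for (sid in unique(hits$seq_id)) {
    sites <- ordered_sites(hits[hits$seq_id == sid, , drop = FALSE], tf_set)
    n <- nrow(sites)
    if (n < 3L) next
    for (k in seq_len(n - 2L)) {
      win <- sites[k:(k + 2L), ]
      if (setequal(win$tf_name, triad)) {
        out[[length(out) + 1L]] <- data.frame(
          seq_id = sid,
          order = paste(win$tf_name, collapse = "-"),
          center_tf = win$tf_name[2],
          left_tf = win$tf_name[1], right_tf = win$tf_name[3],
          left_start = win$start[1], left_end = win$end[1],
          center_start = win$start[2], center_end = win$end[2],
          right_start = win$start[3], right_end = win$end[3],
          left_gap = max(0L, win$start[2] - win$end[1]),
          right_gap = max(0L, win$start[3] - win$end[2]),
          span = win$end[3] - win$start[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(seq_id = character(0), order = character(0),
                      center_tf = character(0), left_tf = character(0),
                      right_tf = character(0), left_start = integer(0),
                      left_end = integer(0), center_start = integer(0),
                      center_end = integer(0), right_start = integer(0),
                      right_end = integer(0), left_gap = integer(0),
                      right_gap = integer(0), span = integer(0),
                      stringsAsFactors = FALSE))
  occ <- do.call(rbind, out)
  occ <- occ[order(occ$seq_id, occ$left_start), , drop = FALSE]
  rownames(occ) <- NULL
  occ
}

#' Count center-TF arrangements across sequences
#'
#' Each sequence with at least one adjacent triad contributes exactly one
#' arrangement: its leftmost occurrence (counting follows sequences, not
#' occurrences). Relative frequencies are reported per center TF.
#'
#' @param occurrences Data.frame from [find_adjacent_triads()].
#' @param triad The 3 TF names (fixes the category order of the output).
#' @return List with `n_sequences`, `counts` (named integer per center TF)
#'   and `frequencies` (counts / n_sequences; percentages via `* 100`).
#' @export
count_arrangements <- function(occurrences, triad) {
  triad <- toupper(triad)
  counts <- setNames(integer(length(triad)), triad)
  if (nrow(occurrences)) {
    first <- occurrences[order(occurrences$seq_id, occurrences$left_start), ]
    first <- first[!duplicated(first$seq_id), ]
    tab <- table(factor(first$center_tf, levels = triad))
    counts[names(tab)] <- as.integer(tab)
  }
  n <- sum(counts)
  list(n_sequences = n, counts = counts,
       frequencies = if (n > 0) counts / n else counts * NA_real_)
}

#' Fisher's exact test comparing two arrangement proportions
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[a, n-a], [b, n-b]]` comparing the number of sequences showing one
#' arrangement (`count_a` of `n`) against another (`count_b` of `n`). The
#' two-sided p-value follows the minimum-likelihood rule: the sum of all
#' hypergeometric outcomes no more probable than the observed table.
#'
#' @param count_a,count_b Sequence counts for the two arrangements.
#' @param n Total number of sequences carrying the triad.
#' @return Two-sided p-value.
#' @export
fisher_arrangement_test <- function(count_a, count_b, n) {
  if (n <= 0) stop("n must be positive")
  if (count_a < 0 || count_b < 0 || count_a > n || count_b > n)
    stop("counts must lie in [0, n]")
  tab <- matrix(c(count_a, n - count_a, count_b, n - count_b),
                nrow = 2, byrow = TRUE)
  stats::fisher.test(tab)$p.value
}

#' Spacing statistics between adjacent triad sites
#'
#' Pools the edge-to-edge gaps of each occurrence into per-TF-pair summaries.
#' A pair label is the two TF names in alphabetical order joined by "-"
#' (e.g. both HES5-FOXP2-GATA3 and GATA3-FOXP2-HES5 orders contribute their
#' FOXP2/GATA3 gap to the "FOXP2-GATA3" pair).
#'
#' @param occurrences Data.frame from [find_adjacent_triads()].
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return Data.frame with one row per pair: `pair`, `n`, `mean_bp`, `sd_bp`,
#'   `min_bp`, `min_seq_id`, `max_bp`, `max_seq_id`.
#' @export
spacing_stats <- function(occurrences, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (!nrow(occurrences))
    return(data.frame(pair = character(0), n = integer(0),
                      mean_bp = numeric(0), sd_bp = numeric(0),
                      min_bp = numeric(0), min_seq_id = character(0),
                      max_bp = numeric(0), max_seq_id = character(0),
                      stringsAsFactors = FALSE))
  pair_label <- function(a, b)
    vapply(seq_along(a), function(i)
      paste(sort(c(a[i], b[i])), collapse = "-"), character(1))
  long <- rbind(
    data.frame(pair = pair_label(occurrences$left_tf, occurrences$center_tf),
               gap = occurrences$left_gap, seq_id = occurrences$seq_id,
               stringsAsFactors = FALSE),
    data.frame(pair = pair_label(occurrences$center_tf, occurrences$right_tf),
               gap = occurrences$right_gap, seq_id = occurrences$seq_id,
               stringsAsFactors = FALSE))
  out <- lapply(split(long, long$pair), function(g) {
    m <- mean(g$gap)
    s <- if (nrow(g) > 1) stats::sd(g$gap) else 0
    if (sd_type == "population")
      s <- sqrt(mean((g$gap - m)^2))
    i_min <- which.min(g$gap); i_max <- which.max(g$gap)
    data.frame(pair = g$pair[1], n = nrow(g), mean_bp = m, sd_bp = s,
               min_bp = g$gap[i_min], min_seq_id = g$seq_id[i_min],
               max_bp = g$gap[i_max], max_seq_id = g$seq_id[i_max],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a spacing table (TSV of per-occurrence gaps)
#'
#' Reads a supplementary-style distance table with columns `seq_id`, `pair`,
#' `gap` (base pairs) for direct use with summary statistics.
#' @param path TSV path.
#' @export
read_spacing_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("seq_id", "pair", "gap")
  if (!all(need %in% names(df)))
    stop("spacing table must have columns: ", paste(need, collapse = ", "))
  df$gap <- as.numeric(df$gap)
  df
}

#' Summarise a long spacing table
#'
#' Same summary as [spacing_stats()] but starting from an already-long table
#' of (seq_id, pair, gap) rows, e.g. from [read_spacing_table()].
#' @param long Data.frame with columns `seq_id`, `pair`, `gap`.
#' @inheritParams spacing_stats
#' @export
summarize_spacing <- function(long, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  out <- lapply(split(long, long$pair), function(g) {
    m <- mean(g$gap)
    s <- if (nrow(g) > 1) stats::sd(g$gap) else 0
    if (sd_type == "population") s <- sqrt(mean((g$gap - m)^2))
    i_min <- which.min(g$gap); i_max <- which.max(g$gap)
    data.frame(pair = g$pair[1], n = nrow(g), mean_bp = m, sd_bp = s,
               min_bp = g$gap[i_min], min_seq_id = g$seq_id[i_min],
               max_bp = g$gap[i_max], max_seq_id = g$seq_id[i_max],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
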