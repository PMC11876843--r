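# Conservation-depth classification of CRMs from per-base phastCons-style
# scores (probabilities of negative selection in [0, 1]).

CONS_CATEGORIES <- c("primate", "mammalian", "birds", "amphibian_teleost")

#' Read a per-base conservation track (fixed-step wiggle)
#'
#' @param path Wiggle file (fixedStep dialect).
#' @return A [GenomicRanges::GRanges] with a `score` metadata column.
#' @export
read_wig_track <- function(path) {
  rtracklayer::import(path, format = "wig")
}

#' Read a per-interval mean-conservation TSV
#'
#' Columns: `crm_id`, `chrom`, `start`, `end` (0-based half-open),
#' `mean_score`.
#' @param path TSV path.
#' @export
read_conservation_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("crm_id", "chrom", "start", "end", "mean_score")
  if (!all(need %in% names(df)))
    stop("conservation TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' Mean conservation score over an interval
#'
#' Arithmetic mean of the track scores over the bases of `[start, end)` that
#' the track covers. Uncovered bases are excluded from both numerator and
#' denominator (no zero-filling); an interval with zero covered bases yields
#' `mean = NA` with `n_covered = 0`, never 0.0.
#'
#' @param chrom,start,end Interval (0-based half-open).
#' @param track GRanges with a numeric `score` column (per-base or spans).
#' @return List with `mean` and `n_covered`.
#' @export
mean_score <- function(chrom, start, end, track) {
  if (end <= start) stop("interval must satisfy start < end")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  # disjoint seqlevels legitimately mean zero coverage, not a user error
  ov <- suppressWarnings(GenomicRanges::findOverlaps(q, track))
  if (!length(ov)) return(list(mean = NA_real_, n_covered = 0L))
  tr <- track[S4Vectors::subjectHits(ov)]
  inter <- GenomicRanges::pintersect(tr, rep(q, length(tr)))
  wts <- GenomicRanges::width(inter)
  sc <- S4Vectors::mcols(tr)$score
  if (any(sc < 0 | sc > 1)) stop("conservation scores must lie in [0, 1]")
  list(mean = sum(sc * wts) / sum(wts), n_covered = sum(wts))
}

#' Classify a mean conservation score into a clade-depth category
#'
#' Thresholds: `< 0.2` primate-specific; `[0.2, 0.5]` mammalian;
#' `(0.5, 0.6]` birds; `> 0.6` amphibians/teleost fish. The four-bin scheme
#' is primary; set `bins = 3` to collapse birds and amphibian_teleost into a
#' single `non_mammalian` category (scores `> 0.5`).
#'
#' @param x Numeric vector of mean scores in \[0, 1\].
#' @param bins 4 (default) or 3.
#' @return Factor of categories.
#' @export
classify_conservation <- function(x, bins = 4) {
  if (any(!is.na(x) & (x < 0 | x > 1)))
    stop("conservation scores must lie in [0, 1]")
  cat4 <- ifelse(is.na(x), NA_character_,
          ifelse(x < 0.2, "primate",
          ifelse(x <= 0.5, "mammalian",
          ifelse(x <= 0.6, "birds", "amphibian_teleost"))))
  if (bins == 4) return(factor(cat4, levels = CONS_CATEGORIES))
  if (bins == 3) {
    cat3 <- ifelse(cat4 %in% c("birds", "amphibian_teleost"),
                   "non_mammalian", cat4)
    return(factor(cat3, levels = c("primate", "mammalian", "non_mammalian")))
  }
  stop("bins must be 3 or 4")
}

#' Per-CRM conservation records for a catalog
#'
#' @param catalog CRM catalog data.frame.
#' @param track Either a per-base GRanges track (see [read_wig_track()]) or a
#'   per-interval mean TSV data.frame (see [read_conservation_tsv()]), matched
#'   on `crm_id`.
#' @return Data.frame `crm_id`, `mean_score`, `n_bases_covered`, `category`.
#' @export
conservation_records <- function(catalog, track) {
  if (is.data.frame(track)) {
    i <- match(catalog$crm_id, track$crm_id)
    if (anyNA(i))
      stop("mean-conservation table lacks CRMs: ",
           paste(utils::head(catalog$crm_id[is.na(i)], 5), collapse = ", "))
    means <- track$mean_score[i]
    ncov <- catalog$end - catalog$start
  } else {
    res <- lapply(seq_len(nrow(catalog)), function(r)
      mean_score(catalog$chrom[r], catalog$start[r], catalog$end[r], track))
    means <- vapply(res, function(z) z$mean, numeric(1))
    ncov <- vapply(res, function(z) as.integer(z$n_covered), integer(1))
  }
  data.frame(crm_id = catalog$crm_id, mean_score = means,
             n_bases_covered = ncov,
             category = classify_conservation(means),
             stringsAsFactors = FALSE)
}

#' Summarise conservation categories over a catalog
#'
#' @param records Data.frame from [conservation_records()] (or any data.frame
#'   with a `category` column).
#' @return Data.frame of per-category `count` and `fraction` (computed, never
#'   copied from any printed percentage).
#' @export
summarize_conservation <- function(records) {
  if (!nrow(records)) stop("no conservation records supplied")
  cat <- factor(records$category, levels = CONS_CATEGORIES)
  n_na <- sum(is.na(cat))
  if (n_na) warning(n_na, " record(s) without coverage excluded from summary")
  cat <- cat[!is.na(cat)]
  counts <- table(cat)
  data.frame(category = names(counts), count = as.integer(counts),
             fraction = as.numeric(counts) / length(cat),
             stringsAsFactors = FALSE)
}
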