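# PWM scanning of nucleotide sequences.
#
# Coordinates are 0-based half-open internally (BED interchange); strand "-"
# hits are reported in forward-strand coordinates.

#' Scan one sequence with one motif
#'
#' Every window of motif width is scored as the sum of per-position
#' log2(frequency/background) terms (frequencies regularised by the motif's
#' pseudocount). A window is reported as a hit when its relative score
#' `(score - min_possible) / (max_possible - min_possible)` reaches
#' `min_rel_score`. Windows containing N are skipped. When `both_strands` is
#' set, the reverse strand is scored by scanning with the reverse-complemented
#' PWM, and hits are reported in forward-strand coordinates with strand "-".
#'
#' @param seq A nucleotide string over A, C, G, T, N (case-insensitive), or a
#'   [Biostrings::DNAString].
#' @param motif A `motif` object.
#' @param min_rel_score Relative score threshold in \[0, 1\]. Default 0.8.
#' @param both_strands Scan both strands (default TRUE).
#' @param seq_id Sequence identifier carried into the hit table.
#' @return A data.frame of hits with columns `seq_id`, `tf_name`, `start`
#'   (0-based), `end` (exclusive), `strand`, `score` (log2-odds bits),
#'   `rel_score`, sorted by `start` then strand. A motif wider than the
#'   sequence yields zero hits.
#' @export
scan_sequence <- function(seq, motif, min_rel_score = 0.8,
                          both_strands = TRUE, seq_id = "seq") {
  if (min_rel_score < 0 || min_rel_score > 1)
    stop("min_rel_score must be in [0, 1]")
  s <- toupper(as.character(seq))
  chars <- strsplit(s, "")[[1]]
  bad <- setdiff(unique(chars), c(BASES, "N"))
  if (length(bad))
    stop("sequence '", seq_id, "' contains invalid characters: ",
         paste(bad, collapse = ", "))
  w <- motif_width(motif)
  L <- length(chars)
  if (w > L) return(empty_hits())
  idx <- match(chars, BASES)  # NA at N positions

  # iorder fixes the accumulation order: motif-position order on both
  # strands, so forward and reverse scores of complementary windows are
  # bit-identical
  score_strand <- function(pwm, iorder) {
    n <- L - w + 1L
    sc <- numeric(n)
    for (i in iorder) {
      col <- idx[i:(i + n - 1L)]
      sc <- sc + pwm[cbind(i, col)]  # NA propagates through N windows
    }
    sc
  }
  rel <- function(sc, pwm) {
    lo <- sum(apply(pwm, 1, min)); hi <- sum(apply(pwm, 1, max))
    if (hi - lo < .Machine$double.eps) return(rep(1, length(sc)))
    (sc - lo) / (hi - lo)
  }

  res <- list()
  sc_f <- score_strand(motif$pwm, seq_len(w))
  rel_f <- rel(sc_f, motif$pwm)
  keep <- !is.na(rel_f) & rel_f >= min_rel_score
  if (any(keep)) {
    p <- which(keep)
    res[["+"]] <- data.frame(seq_id = seq_id, tf_name = motif$tf_name,
                             start = p - 1L, end = p - 1L + w, strand = "+",
                             score = sc_f[p], rel_score = rel_f[p],
                             stringsAsFactors = FALSE)
  }
  if (both_strands) {
    pwm_rc <- motif$pwm[w:1, 4:1, drop = FALSE]
    dimnames(pwm_rc) <- list(NULL, BASES)
    sc_r <- score_strand(pwm_rc, rev(seq_len(w)))
    rel_r <- rel(sc_r, pwm_rc)
    keep <- !is.na(rel_r) & rel_r >= min_rel_score
    if (any(keep)) {
      p <- which(keep)
      res[["-"]] <- data.frame(seq_id = seq_id, tf_name = motif$tf_name,
                               start = p - 1L, end = p - 1L + w, strand = "-",
                               score = sc_r[p], rel_score = rel_r[p],
                               stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_hits())
  hits <- do.call(rbind, res)
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(seq_id = character(0), tf_name = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             score = numeric(0), rel_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Scan a set of sequences with a motif collection
#'
#' @param seqs Named character vector of sequences or a
#'   [Biostrings::DNAStringSet].
#' @param motifs List of `motif` objects (e.g. from [read_motifs()]).
#' @inheritParams scan_sequence
#' @return Combined hit data.frame (see [scan_sequence()]).
#' @export
scan_sequences <- function(seqs, motifs, min_rel_score = 0.8,
                           both_strands = TRUE) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named")
  out <- vector("list", length(seqs) * length(motifs))
  k <- 0L
  for (sid in names(seqs)) {
    for (m in motifs) {
      k <- k + 1L
      out[[k]] <- scan_sequence(seqs[[sid]], m, min_rel_score,
                                both_strands, seq_id = sid)
    }
  }
  hits <- do.call(rbind, out)
  if (is.null(hits)) hits <- empty_hits()
  rownames(hits) <- NULL
  hits
}

#' Build the binary sequence-by-TF binding matrix
#'
#' Cell (i, j) is 1 iff at least one hit of TF j exists on sequence i.
#' Row/column order follows the supplied identifier lists, so sequences with
#' zero hits still appear as all-zero rows.
#'
#' @param hits Hit data.frame from [scan_sequences()].
#' @param seq_ids Ordered character vector of sequence identifiers.
#' @param tf_names Ordered character vector of TF names.
#' @return Integer 0/1 matrix with `seq_ids` rows and `tf_names` columns.
#' @export
build_binding_matrix <- function(hits, seq_ids, tf_names) {
  if (anyDuplicated(seq_ids) || anyDuplicated(tf_names))
    stop("seq_ids and tf_names must be unique")
  mat <- matrix(0L, nrow = length(seq_ids), ncol = length(tf_names),
                dimnames = list(seq_ids, tf_names))
  if (nrow(hits)) {
    unknown_s <- setdiff(unique(hits$seq_id), seq_ids)
    if (length(unknown_s))
      stop("hits reference unknown seq_id: ", paste(unknown_s, collapse = ", "))
    unknown_t <- setdiff(unique(hits$tf_name), tf_names)
    if (length(unknown_t))
      stop("hits reference unknown tf_name: ", paste(unknown_t, collapse = ", "))
    mat[cbind(match(hits$seq_id, seq_ids), match(hits$tf_name, tf_names))] <- 1L
  }
  mat
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path (multi-record, wrapped lines, case-insensitive).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
  setNames(toupper(as.character(ss)), names(ss))
}

#' Write sequences to FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write motif hits as BED6
#'
#' The BED score column is `round(rel_score * 1000)`; full log-odds scores are
#' preserved only in the TSV representation ([write_hits_tsv()]).
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$seq_id, hits$start, hits$end, hits$tf_name,
                    as.integer(round(hits$rel_score * 1000)), hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write motif hits as TSV (full scores)
#' @param hits Hit data.frame.
#' @param path Output path.
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a binding matrix as TSV
#'
#' Rows are sequences, columns are TFs, cells 0/1; the first column holds the
#' sequence identifier.
#' @param mat Binary matrix from [build_binding_matrix()].
#' @param path File path.
#' @export
write_binding_matrix <- function(mat, path) {
  df <- data.frame(seq_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_binding_matrix
#' @export
read_binding_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!all(mat %in% c(0, 1)))
    stop("binding matrix must be binary 0/1: ", path)
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  colnames(mat) <- toupper(colnames(mat))
  mat
}
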