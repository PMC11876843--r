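#' @importFrom stats rbinom runif sd setNames
#' @importFrom utils read.table write.table head
NULL

BASES <- c("A", "C", "G", "T")

#' Construct a motif object
#'
#' A motif is a position count matrix for one transcription factor, together
#' with the pseudocount and background base composition used to turn counts
#' into a position weight matrix (PWM) of log2-odds scores.
#'
#' @param tf_name Transcription factor label (normalised to upper case).
#' @param motif_id Source identifier (e.g. a JASPAR accession); must be unique
#'   within a motif collection.
#' @param counts Numeric matrix of nonnegative base counts, positions in rows
#'   and columns named A, C, G, T.
#' @param pseudocount Nonnegative scalar added to each position's counts,
#'   split across bases in proportion to `background`. Default 0.8, a common
#'   PWM regularisation.
#' @param background Probability vector over A, C, G, T; must sum to 1.
#'   Default uniform.
#' @return An object of class `motif` with elements `tf_name`, `motif_id`,
#'   `counts`, `pseudocount`, `background`, and derived `freq` (per-position
#'   base frequencies, rows summing to 1) and `pwm` (log2(freq/background)).
#' @export
new_motif <- function(tf_name, motif_id, counts, pseudocount = 0.8,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("motif '", motif_id, "': counts must have 4 columns (A,C,G,T), got ",
         ncol(counts))
  if (is.null(colnames(counts))) colnames(counts) <- BASES
  counts <- counts[, BASES, drop = FALSE]
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("motif '", motif_id, "': counts must be finite and nonnegative")
  if (any(rowSums(counts) <= 0))
    stop("motif '", motif_id, "': every position must have at least one positive count")
  if (length(background) != 4L) stop("background must have length 4")
  if (is.null(names(background))) names(background) <- BASES
  background <- background[BASES]
  if (abs(sum(background) - 1) > 1e-9)
    stop("background must sum to 1 (got ", sum(background), ")")
  if (any(background <= 0)) stop("background probabilities must be positive")
  if (length(pseudocount) != 1L || pseudocount < 0)
    stop("pseudocount must be a single nonnegative number")

  freq <- sweep(counts, 2, background * pseudocount, "+") /
    (rowSums(counts) + pseudocount)
  pwm <- log2(sweep(freq, 2, background, "/"))
  structure(
    list(tf_name = toupper(tf_name), motif_id = motif_id, counts = counts,
         pseudocount = pseudocount, background = background,
         freq = freq, pwm = pwm),
    class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s (%s), width %d\n", x$tf_name, x$motif_id,
              motif_width(x)))
  cat("consensus:", motif_consensus(x), "\n")
  invisible(x)
}

#' Motif width (number of positions)
#' @param motif A `motif` object.
#' @export
motif_width <- function(motif) nrow(motif$counts)

#' Consensus sequence of a motif (highest-count base per position)
#' @param motif A `motif` object.
#' @export
motif_consensus <- function(motif) {
  paste(BASES[apply(motif$counts, 1, which.max)], collapse = "")
}

#' Read a motif collection from a JASPAR- or TRANSFAC-style file
#'
#' The JASPAR dialect is `>ID NAME` headers followed by four labelled rows
#' `A [ n n ... ]` (brackets optional). The minimal TRANSFAC dialect is
#' records with `ID`/`AC` (identifier) and `NA` (factor name) lines, a
#' `PO A C G T` column header, numbered count rows `01 .. NN`, and a `//`
#' terminator.
#'
#' @param path Path to the motif file.
#' @param format Either `"jaspar"` or `"transfac"`.
#' @inheritParams new_motif
#' @return A named list of `motif` objects (names are TF names). TF names are
#'   normalised to upper case; counts are preserved exactly.
#' @export
read_motifs <- function(path, format = c("jaspar", "transfac"),
                        pseudocount = 0.8,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    warning("motif file '", path, "' is empty; returning an empty collection")
    return(list())
  }
  motifs <- switch(format,
    jaspar = parse_jaspar(lines, pseudocount, background),
    transfac = parse_transfac(lines, pseudocount, background))
  ids <- vapply(motifs, function(m) m$motif_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate motif_id in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(motifs) <- vapply(motifs, function(m) m$tf_name, character(1))
  motifs
}

parse_jaspar <- function(lines, pseudocount, background) {
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no JASPAR '>' headers found")
  bounds <- c(headers, length(lines) + 1L)
  lapply(seq_along(headers), function(k) {
    hdr <- sub("^>\\s*", "", lines[headers[k]])
    toks <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) >= 2) toks[2] else toks[1]
    block <- lines[(headers[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(block) != 4L)
      stop("JASPAR record '", motif_id, "': expected 4 count rows, got ",
           length(block))
    rows <- lapply(block, function(ln) {
      ln2 <- gsub("[][]", " ", ln)
      toks <- strsplit(trimws(ln2), "\\s+")[[1]]
      base <- toupper(toks[1])
      vals <- suppressWarnings(as.numeric(toks[-1]))
      if (!base %in% BASES || anyNA(vals))
        stop("JASPAR record '", motif_id, "': malformed count row: ", ln)
      list(base = base, vals = vals)
    })
    lens <- vapply(rows, function(r) length(r$vals), integer(1))
    if (length(unique(lens)) != 1L)
      stop("JASPAR record '", motif_id,
           "': count rows have differing widths (", paste(lens, collapse = ","), ")")
    counts <- matrix(0, nrow = lens[1], ncol = 4, dimnames = list(NULL, BASES))
    for (r in rows) counts[, r$base] <- r$vals
    new_motif(tf_name, motif_id, counts, pseudocount, background)
  })
}

parse_transfac <- function(lines, pseudocount, background) {
  # accumulate record blocks up to each "//" terminator
  out <- list()
  cur <- character(0)
  for (ln in lines) {
    if (grepl("^//", ln)) {
      if (length(cur)) out[[length(out) + 1L]] <- cur
      cur <- character(0)
    } else cur <- c(cur, ln)
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  lapply(out, function(block) {
    idln <- grep("^(ID|AC)\\s+", block, value = TRUE)
    motif_id <- if (length(idln)) strsplit(idln[1], "\\s+")[[1]][2] else "TRANSFAC_motif"
    naln <- grep("^NA\\s+", block, value = TRUE)
    tf_name <- if (length(naln)) strsplit(naln[1], "\\s+")[[1]][2] else motif_id
    po <- grep("^P[O0]\\b", block)
    if (length(po) != 1L)
      stop("TRANSFAC record '", motif_id, "': missing PO header")
    col_order <- toupper(strsplit(trimws(sub("^P[O0]", "", block[po])), "\\s+")[[1]])
    if (!setequal(col_order, BASES))
      stop("TRANSFAC record '", motif_id, "': PO header must name A C G T")
    rowlines <- block[grepl("^\\d+\\s", block)]
    if (length(rowlines) == 0L)
      stop("TRANSFAC record '", motif_id, "': no count rows")
    counts <- t(vapply(rowlines, function(ln) {
      toks <- strsplit(trimws(ln), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks[2:5]))
      if (anyNA(vals))
        stop("TRANSFAC record '", motif_id, "': malformed count row: ", ln)
      vals
    }, numeric(4)))
    colnames(counts) <- col_order
    rownames(counts) <- NULL
    new_motif(tf_name, motif_id, counts[, BASES, drop = FALSE],
              pseudocount, background)
  })
}

#' Write motifs in JASPAR format
#' @param motifs A list of `motif` objects.
#' @param path Output file path.
#' @export
write_motifs_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", m$motif_id, m$tf_name), con)
    for (b in BASES) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(m$counts[, b], trim = TRUE), collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
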