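# Genome-wide search of a CRM catalog for an ordered TF triad pattern.

#' Read a CRM catalog from BED4
#'
#' @param path BED4 file (chrom, start, end, crm_id; tab-separated, comment
#'   and `track` lines ignored).
#' @return Data.frame with columns `crm_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and a `sequence` column of NAs to be filled by
#'   [extract_sequences()].
#' @export
read_crm_catalog <- function(path) {
  gr <- read_bed(path)
  ids <- S4Vectors::mcols(gr)$name
  if (is.null(ids)) stop("CRM catalog must be BED4 (needs a crm_id column): ", path)
  if (anyDuplicated(ids)) stop("duplicate crm_id in catalog: ", path)
  data.frame(crm_id = ids,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             sequence = NA_character_,
             stringsAsFactors = FALSE)
}

#' Attach sequences to a CRM catalog from a genome FASTA
#'
#' Sequences are the half-open slices `[start, end)` of the named contig,
#' upper-cased.
#'
#' @param catalog CRM catalog data.frame (see [read_crm_catalog()]).
#' @param genome Path to a genome FASTA, a named character vector of contigs,
#'   or a [Biostrings::DNAStringSet].
#' @return The catalog with its `sequence` column filled.
#' @export
extract_sequences <- function(catalog, genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome)
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(toupper(as.character(genome)), names(genome))
  missing_chr <- setdiff(unique(catalog$chrom), names(genome))
  if (length(missing_chr))
    stop("contigs not found in genome: ", paste(missing_chr, collapse = ", "))
  lens <- nchar(genome)[catalog$chrom]
  bad <- which(catalog$end > lens | catalog$start < 0)
  if (length(bad))
    stop("interval beyond contig end for CRM: ",
         paste(catalog$crm_id[bad], collapse = ", "))
  catalog$sequence <- toupper(substring(genome[catalog$chrom],
                                        catalog$start + 1L, catalog$end))
  catalog
}

#' Define an ordered triad query
#'
#' @param left_tf,center_tf,right_tf Three distinct TF names; the pattern
#'   requires a `center_tf` site strictly between a `left_tf` and a
#'   `right_tf` site.
#' @param require_adjacency When TRUE, the three sites must be consecutive
#'   among all sites of the three TFs on the CRM (no intervening triad-TF
#'   site). Default FALSE: the genome-wide pattern demands order, not
#'   adjacency.
#' @param max_gap Optional bound (bp) on each edge-to-edge inter-site gap.
#' @param allow_mirror Accept the mirrored order right-center-left as the
#'   same pattern (a segment read on the other strand reverses apparent
#'   order). Default TRUE.
#' @return An object of class `triad_query`.
#' @export
triad_query <- function(left_tf, center_tf, right_tf,
                        require_adjacency = FALSE, max_gap = NULL,
                        allow_mirror = TRUE) {
  tfs <- toupper(c(left_tf, center_tf, right_tf))
  if (anyDuplicated(tfs)) stop("triad query requires 3 distinct TF names")
  if (!is.null(max_gap) && max_gap <= 0) stop("max_gap must be positive")
  structure(list(left_tf = tfs[1], center_tf = tfs[2], right_tf = tfs[3],
                 require_adjacency = require_adjacency, max_gap = max_gap,
                 allow_mirror = allow_mirror),
            class = "triad_query")
}

#' Scan a CRM catalog for an ordered triad
#'
#' Each CRM is scanned with the three query motifs; a CRM matches when some
#' `center_tf` hit starts strictly between a `left_tf` hit and a `right_tf`
#' hit (mirror orientation also accepted when `allow_mirror`). Adjacency and
#' `max_gap` constraints are applied when set. A matched CRM is listed once
#' with its best (smallest-span) match; output is sorted by `crm_id` and so
#' independent of catalog input order.
#'
#' @param catalog CRM catalog with sequences (see [extract_sequences()]).
#' @param motifs Named list of `motif` objects containing the three query
#'   TFs.
#' @param query A [triad_query()].
#' @param min_rel_score Relative PWM score threshold (see [scan_sequence()]).
#' @param both_strands Scan both strands. Default TRUE.
#' @return Data.frame with one row per matched CRM: `crm_id`, `orientation`,
#'   site coordinates (CRM-relative, 0-based), gaps and `span`.
#' @export
scan_catalog <- function(catalog, motifs, query, min_rel_score = 0.8,
                         both_strands = TRUE) {
  if (!inherits(query, "triad_query")) stop("query must be a triad_query")
  tfs <- c(query$left_tf, query$center_tf, query$right_tf)
  have <- toupper(names(motifs))
  if (!all(tfs %in% have))
    stop("motif set lacks required TFs: ",
         paste(setdiff(tfs, have), collapse = ", "))
  no_seq <- which(is.na(catalog$sequence))
  if (length(no_seq))
    stop("CRM without sequence (supply a genome FASTA via extract_sequences): ",
         paste(utils::head(catalog$crm_id[no_seq], 5), collapse = ", "))
  motifs3 <- motifs[match(tfs, have)]

  orientations <- list(c(query$left_tf, query$center_tf, query$right_tf))
  if (query$allow_mirror)
    orientations <- c(orientations,
                      list(c(query$right_tf, query$center_tf, query$left_tf)))

  rows <- list()
  for (r in seq_len(nrow(catalog))) {
    hits <- do.call(rbind, lapply(motifs3, function(m)
      scan_sequence(catalog$sequence[r], m, min_rel_score, both_strands,
                    seq_id = catalog$crm_id[r])))
    if (is.null(hits) || !nrow(hits)) next
    sites <- ordered_sites(hits, tfs)
    best <- NULL
    for (ori in orientations) {
      li <- which(sites$tf_name == ori[1])
      ci <- which(sites$tf_name == ori[2])
      ri <- which(sites$tf_name == ori[3])
      for (c0 in ci) for (l0 in li[li < c0]) for (r0 in ri[ri > c0]) {
        if (sites$start[l0] >= sites$start[c0] ||
            sites$start[c0] >= sites$start[r0]) next
        if (query$require_adjacency && (c0 - l0 != 1L || r0 - c0 != 1L)) next
        g1 <- sites$start[c0] - sites$end[l0]
        g2 <- sites$start[r0] - sites$end[c0]
        if (!is.null(query$max_gap) &&
            (g1 > query$max_gap || g2 > query$max_gap)) next
        span <- sites$end[r0] - sites$start[l0]
        if (is.null(best) || span < best$span) {
          best <- data.frame(
            crm_id = catalog$crm_id[r],
            orientation = paste(ori, collapse = "-"),
            left_tf = ori[1], center_tf = ori[2], right_tf = ori[3],
            left_start = sites$start[l0], left_end = sites$end[l0],
            center_start = sites$start[c0], center_end = sites$end[c0],
            right_start = sites$start[r0], right_end = sites$end[r0],
            left_gap = max(0L, g1), right_gap = max(0L, g2), span = span,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- best
  }
  if (!length(rows))
    return(data.frame(crm_id = character(0), orientation = character(0),
                      left_tf = character(0), center_tf = character(0),
                      right_tf = character(0), left_start = integer(0),
                      left_end = integer(0), center_start = integer(0),
                      center_end = integer(0), right_start = integer(0),
                      right_end = integer(0), left_gap = integer(0),
                      right_gap = integer(0), span = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$crm_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write matched CRMs as BED4
#' @param catalog Catalog data.frame.
#' @param matches Output of [scan_catalog()].
#' @param path Output path.
#' @export
write_matched_bed <- function(catalog, matches, path) {
  sub <- catalog[match(matches$crm_id, catalog$crm_id), , drop = FALSE]
  write.table(data.frame(sub$chrom, sub$start, sub$end, sub$crm_id),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
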