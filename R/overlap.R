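# Intersection of CRMs with epigenomic interval tracks, per-CRM feature
# matrix and core-set shortlisting. Half-open interval arithmetic throughout;
# the overlap criterion is >= 1 bp.

#' Read BED3/BED4/BED6 as GRanges
#'
#' Tab-separated; comment (`#`) and `track`/`browser` lines ignored. A
#' malformed line raises a parse error naming its line number.
#'
#' @param path BED path.
#' @param track_name Optional label stored as metadata.
#' @return GRanges (1-based internally; `name`, `score`, `strand` kept when
#'   present).
#' @export
read_bed <- function(path, track_name = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lnum <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges()
    attr(gr, "track_name") <- track_name
    return(gr)
  }
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", lnum[which(nf < 3)[1]], " in ", path,
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop("malformed BED line ", lnum[bad[1]], " in ", path,
         ": invalid coordinates")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (all(nf >= 4))
    S4Vectors::mcols(gr)$name <- vapply(fields, `[`, character(1), 4)
  if (all(nf >= 6)) {
    strand_col <- vapply(fields, `[`, character(1), 6)
    if (all(strand_col %in% c("+", "-", ".")))
      GenomicRanges::strand(gr) <- sub("\\.", "*", strand_col)
  }
  attr(gr, "track_name") <- track_name
  gr
}

#' Normalise chromosome names
#'
#' Maps plain numeric/X/Y names to "chr"-prefixed form (`1` -> `chr1`) so
#' catalogs and tracks with differing conventions intersect; mitochondrial
#' and alternative contigs pass through verbatim.
#'
#' @param x Character vector of chromosome names.
#' @export
normalize_chroms <- function(x) {
  plain <- grepl("^([0-9]+|X|Y)$", x)
  x[plain] <- paste0("chr", x[plain])
  x
}

catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(normalize_chroms(catalog$chrom),
                         IRanges::IRanges(catalog$start + 1L, catalog$end),
                         crm_id = catalog$crm_id)
}

normalize_track <- function(track) {
  GenomicRanges::GRanges(
    normalize_chroms(as.character(GenomicRanges::seqnames(track))),
    IRanges::IRanges(GenomicRanges::start(track), GenomicRanges::end(track)),
    name = if (!is.null(S4Vectors::mcols(track)$name))
      S4Vectors::mcols(track)$name else NA_character_)
}

#' Intersect a CRM catalog with an interval track
#'
#' Reports every (CRM, interval) pair sharing at least one base under
#' half-open arithmetic, with the overlap length in bp.
#'
#' @param catalog CRM catalog data.frame (`crm_id`, `chrom`, `start`, `end`).
#' @param track GRanges of track intervals (e.g. from [read_bed()]).
#' @return Data.frame `crm_id`, `interval_index`, `interval_id`,
#'   `overlap_bp`.
#' @export
intersect_track <- function(catalog, track) {
  crms <- catalog_granges(catalog)
  trk <- normalize_track(track)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(crms, trk, minoverlap = 1L))
  if (!length(ov))
    return(data.frame(crm_id = character(0), interval_index = integer(0),
                      interval_id = character(0), overlap_bp = integer(0),
                      stringsAsFactors = FALSE))
  q <- crms[S4Vectors::queryHits(ov)]
  s <- trk[S4Vectors::subjectHits(ov)]
  inter <- GenomicRanges::pintersect(q, s)
  data.frame(crm_id = S4Vectors::mcols(q)$crm_id,
             interval_index = S4Vectors::subjectHits(ov),
             interval_id = S4Vectors::mcols(s)$name,
             overlap_bp = GenomicRanges::width(inter),
             stringsAsFactors = FALSE)
}

#' Build the per-CRM binary feature matrix over several tracks
#'
#' @param catalog CRM catalog data.frame.
#' @param tracks Named list of GRanges tracks.
#' @return List with `matrix` (CRMs x tracks, 0/1; a cell is 1 iff >= 1 bp
#'   overlap), `details` (all overlap pairs from [intersect_track()] with a
#'   `track` column) and `track_counts` (CRMs overlapped per track).
#' @export
build_feature_matrix <- function(catalog, tracks) {
  if (!length(tracks)) stop("at least one track is required")
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be named")
  mat <- matrix(0L, nrow = nrow(catalog), ncol = length(tracks),
                dimnames = list(catalog$crm_id, names(tracks)))
  det <- list()
  for (tn in names(tracks)) {
    d <- intersect_track(catalog, tracks[[tn]])
    if (nrow(d)) {
      mat[unique(d$crm_id), tn] <- 1L
      d$track <- tn
      det[[tn]] <- d
    }
  }
  details <- if (length(det)) do.call(rbind, det) else
    data.frame(crm_id = character(0), interval_index = integer(0),
               interval_id = character(0), overlap_bp = integer(0),
               track = character(0), stringsAsFactors = FALSE)
  rownames(details) <- NULL
  list(matrix = mat, details = details, track_counts = colSums(mat))
}

#' Shortlist a core CRM set from the feature matrix
#'
#' With `classes` given (a named vector mapping track name to feature class,
#' e.g. three histone marks to "histone"), tracks of one class are unioned
#' into a class indicator before the membership rule is applied. Modes:
#' `"k_of"` keeps CRMs positive for at least `k` required features (default
#' k = 3, mirroring shortlisting on at least three distinct cis-regulatory
#' feature classes); `"all_of"` keeps CRMs positive for every required
#' feature.
#'
#' @param feature_matrix Binary matrix from [build_feature_matrix()]
#'   (`$matrix`).
#' @param required Feature (or class) names the rule applies to; default all.
#' @param mode `"k_of"` or `"all_of"`.
#' @param k Minimum feature count for `"k_of"`.
#' @param classes Optional named character vector: `classes[track] = class`.
#' @return Sorted character vector of core `crm_id`s.
#' @export
core_set <- function(feature_matrix, required = NULL,
                     mode = c("k_of", "all_of"), k = 3L, classes = NULL) {
  mode <- match.arg(mode)
  mat <- feature_matrix
  if (!is.null(classes)) {
    unknown <- setdiff(names(classes), colnames(mat))
    if (length(unknown))
      stop("unknown track name in classes: ", paste(unknown, collapse = ", "))
    cls <- unique(classes[colnames(mat)])
    cls <- cls[!is.na(cls)]
    cmat <- sapply(cls, function(cl) {
      cols <- colnames(mat)[!is.na(classes[colnames(mat)]) &
                              classes[colnames(mat)] == cl]
      as.integer(rowSums(mat[, cols, drop = FALSE]) > 0)
    })
    rownames(cmat) <- rownames(mat)
    mat <- cmat
  }
  if (is.null(required)) required <- colnames(mat)
  unknown <- setdiff(required, colnames(mat))
  if (length(unknown))
    stop("unknown track/class name: ", paste(unknown, collapse = ", "))
  sub <- mat[, required, drop = FALSE]
  keep <- if (mode == "all_of") rowSums(sub) == length(required)
          else rowSums(sub) >= k
  sort(rownames(mat)[keep])
}

#' Overlap CRMs with point SNPs
#'
#' SNPs are treated as 1 bp half-open intervals; a SNP at a CRM's start
#' coordinate hits, a SNP at its end coordinate does not.
#'
#' @param catalog CRM catalog data.frame.
#' @param snps Data.frame with columns `rsid`, `chrom`, `pos` (0-based).
#' @return Data.frame of (crm_id, rsid) pairs.
#' @export
snp_overlap <- function(catalog, snps) {
  if (!nrow(snps))
    return(data.frame(crm_id = character(0), rsid = character(0),
                      stringsAsFactors = FALSE))
  trk <- GenomicRanges::GRanges(normalize_chroms(snps$chrom),
                                IRanges::IRanges(snps$pos + 1L, snps$pos + 1L),
                                name = snps$rsid)
  d <- intersect_track(catalog, trk)
  data.frame(crm_id = d$crm_id, rsid = d$interval_id,
             stringsAsFactors = FALSE)
}

#' Read SNPs from a two-column TSV (rsid, chrom:pos)
#'
#' `pos` in the `chrom:pos` form is 1-based (dbSNP style) and converted to
#' the package's 0-based convention.
#' @param path TSV path with columns `rsid` and `position` (`chrom:pos`).
#' @export
read_snps_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("rsid", "position") %in% names(df)))
    stop("SNP TSV must have columns rsid, position (chrom:pos)")
  parts <- strsplit(df$position, ":")
  data.frame(rsid = df$rsid,
             chrom = vapply(parts, `[`, character(1), 1),
             pos = as.integer(vapply(parts, `[`, character(1), 2)) - 1L,
             stringsAsFactors = FALSE)
}
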