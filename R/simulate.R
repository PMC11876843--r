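# Synthetic-data generators: every pipeline input with known ground truth.
# One RNG stream per generator stage, derived arithmetically from the master
# seed, so enlarging one stage never perturbs another.

stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 9973 + 1) %% 2147483647)
}

#' Load the package's bundled synthetic motif set
#'
#' Ten synthetic high-information count matrices (widths 13-14) carrying
#' forebrain-TF names (HES5, FOXP2, GATA3 and seven other canonical forebrain
#' regulators). The matrices are synthetic constructions for simulation and
#' testing, not JASPAR or TRANSFAC records.
#' @inheritParams new_motif
#' @return Named list of `motif` objects.
#' @export
example_motifs <- function(pseudocount = 0.8,
                           background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  read_motifs(system.file("extdata", "synthetic_motifs.jaspar",
                          package = "motifgrammar"),
              format = "jaspar", pseudocount = pseudocount,
              background = background)
}

#' Simulation configuration
#'
#' Defaults define the study conditions the generators emulate: a positive
#' enhancer set in which the HES5/FOXP2/GATA3 triad co-occurs adjacently in
#' 28% of sequences with center split 62.5/25/12.5 (FOXP2/HES5/GATA3) and
#' uniform(35, 504) bp inter-site gaps; pure-background negative controls; a
#' 500-CRM catalog with 120 CRMs carrying the ordered triad; track coverage
#' fractions and a conservation category mixture matching the genome-wide
#' catalog proportions (2051/414/21/128 of 2614).
#'
#' @param seed Master seed (integer).
#' @param n_positive,n_negative Sequence counts.
#' @param seq_length Enhancer length (bp).
#' @param background Base probabilities (A, C, G, T).
#' @param motifs Named motif list; default [example_motifs()].
#' @param triad Canonical order (left, center, right) of the planted triad.
#' @param p_triad Probability a positive sequence carries the adjacent triad.
#' @param center_probs Named probabilities of each TF being central.
#' @param gap_min,gap_max Uniform bounds (bp) for inter-site gaps.
#' @param marginal Per-TF marginal presence probability for independent
#'   (non-triad) planted sites; scalar or named vector.
#' @param n_crms,n_planted Catalog size and planted ordered-triad count.
#' @param crm_length,crm_spacer CRM length and inter-CRM spacer (bp).
#' @param crms_per_contig CRMs per synthetic contig.
#' @param track_coverage Named fractions of CRMs each epigenomic track covers.
#' @param conservation_weights Named category mixture weights (sum to 1).
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_positive = 160L, n_negative = 100L,
                       seq_length = 2000L,
                       background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       motifs = NULL,
                       triad = c("HES5", "FOXP2", "GATA3"),
                       p_triad = 0.28,
                       center_probs = c(FOXP2 = 0.625, HES5 = 0.25, GATA3 = 0.125),
                       gap_min = 35L, gap_max = 504L,
                       marginal = 0.35,
                       n_crms = 500L, n_planted = 120L,
                       crm_length = 1200L, crm_spacer = 500L,
                       crms_per_contig = 100L,
                       track_coverage = c(H3K4me1 = 583, H3K4me2 = 583,
                                          H3K27ac = 583, DNase_HS = 2487,
                                          GATA3_ChIP = 2332,
                                          FOXP2_ChIP = 170) / 2614,
                       conservation_weights = c(primate = 2051, mammalian = 414,
                                                birds = 21,
                                                amphibian_teleost = 128) / 2614) {
  if (is.null(motifs)) motifs <- example_motifs()
  names(motifs) <- toupper(names(motifs))
  triad <- toupper(triad)
  if (!all(triad %in% names(motifs)))
    stop("triad TFs missing from motif set: ",
         paste(setdiff(triad, names(motifs)), collapse = ", "))
  if (p_triad < 0 || p_triad > 1) stop("p_triad must be in [0, 1]")
  if (abs(sum(center_probs) - 1) > 1e-9)
    stop("center_probs must sum to 1")
  if (!setequal(names(center_probs), triad))
    stop("center_probs must be named by the triad TFs")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  if (abs(sum(conservation_weights) - 1) > 1e-9)
    stop("conservation_weights must sum to 1")
  if (any(track_coverage < 0 | track_coverage > 1))
    stop("track_coverage fractions must be in [0, 1]")
  if (any(marginal < 0 | marginal > 1))
    stop("marginal probabilities must be in [0, 1]")
  if (length(marginal) == 1L)
    marginal <- setNames(rep(marginal, length(motifs)), names(motifs))
  if (!all(names(motifs) %in% names(marginal)))
    stop("marginal must cover every motif TF")
  if (n_planted > n_crms) stop("n_planted cannot exceed n_crms")
  if (gap_min < 0 || gap_max < gap_min) stop("need 0 <= gap_min <= gap_max")
  structure(list(seed = as.integer(seed), n_positive = as.integer(n_positive),
                 n_negative = as.integer(n_negative),
                 seq_length = as.integer(seq_length),
                 background = background[BASES], motifs = motifs,
                 triad = triad, p_triad = p_triad,
                 center_probs = center_probs,
                 gap_min = as.integer(gap_min), gap_max = as.integer(gap_max),
                 marginal = marginal, n_crms = as.integer(n_crms),
                 n_planted = as.integer(n_planted),
                 crm_length = as.integer(crm_length),
                 crm_spacer = as.integer(crm_spacer),
                 crms_per_contig = as.integer(crms_per_contig),
                 track_coverage = track_coverage,
                 conservation_weights = conservation_weights),
            class = "sim_config")
}

random_seq <- function(L, background) {
  paste(sample(BASES, L, replace = TRUE, prob = background), collapse = "")
}

plant_site <- function(seq, start0, site) {
  substr(seq, start0 + 1L, start0 + nchar(site)) <- site
  seq
}

# orientation (left, center, right) for a given center TF, relative to the
# canonical triad order c(left, center, right)
center_orientation <- function(center, triad) {
  flanks <- setdiff(triad, center)
  if (center == triad[2]) return(triad)
  if (center == triad[1]) return(c(triad[3], center, triad[2]))
  c(triad[1], center, triad[2])
}

#' Generate positive enhancer sequences with planted motif structure
#'
#' Each sequence is i.i.d. background DNA. With probability `p_triad` an
#' adjacent ordered triad is planted: the center TF is sampled from
#' `center_probs`, gaps from uniform(`gap_min`, `gap_max`), and the three
#' motif consensus strings are placed at a uniformly chosen offset. All TFs
#' additionally receive independent marginal consensus sites planted outside
#' the triad span, so planted adjacency is never broken.
#'
#' @param config A [sim_config()].
#' @return List with `sequences` (named character), `truth_sites`
#'   (seq_id, tf_name, start, strand, role), `truth_triads` (per-sequence
#'   planted arrangement with gaps) and `config`.
#' @export
generate_enhancers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 1L))
  L <- config$seq_length
  seq_ids <- sprintf("pos_%03d", seq_len(config$n_positive))
  seqs <- setNames(character(config$n_positive), seq_ids)
  sites <- list(); triads <- list()
  widths <- vapply(config$motifs, motif_width, integer(1))
  consensi <- vapply(config$motifs, motif_consensus, character(1))
  for (i in seq_len(config$n_positive)) {
    sid <- seq_ids[i]
    s <- random_seq(L, config$background)
    span <- NULL
    if (runif(1) < config$p_triad) {
      center <- sample(names(config$center_probs), 1,
                       prob = config$center_probs)
      ord <- center_orientation(center, config$triad)
      gaps <- floor(runif(2, config$gap_min, config$gap_max + 1))
      w3 <- widths[ord]
      total <- sum(w3) + sum(gaps)
      if (total > L)
        stop("planted content (", total, " bp) exceeds seq_length (", L,
             " bp); increase seq_length")
      start0 <- sample.int(L - total + 1L, 1L) - 1L
      pos <- start0
      for (k in 1:3) {
        s <- plant_site(s, pos, consensi[[ord[k]]])
        sites[[length(sites) + 1L]] <- data.frame(
          seq_id = sid, tf_name = ord[k], start = pos, strand = "+",
          role = "triad", stringsAsFactors = FALSE)
        pos <- pos + w3[k] + if (k < 3) gaps[k] else 0L
      }
      span <- c(start0, start0 + total)
      triads[[length(triads) + 1L]] <- data.frame(
        seq_id = sid, order = paste(ord, collapse = "-"), center_tf = center,
        start = start0, end = start0 + total,
        left_gap = gaps[1], right_gap = gaps[2], stringsAsFactors = FALSE)
    }
    for (tf in names(config$motifs)) {
      if (runif(1) >= config$marginal[[tf]]) next
      w <- widths[[tf]]
      allowed <- 0:(L - w)
      if (!is.null(span))
        allowed <- allowed[allowed + w <= span[1] | allowed >= span[2]]
      if (!length(allowed)) next
      p0 <- allowed[sample.int(length(allowed), 1L)]
      s <- plant_site(s, p0, consensi[[tf]])
      sites[[length(sites) + 1L]] <- data.frame(
        seq_id = sid, tf_name = tf, start = p0, strand = "+",
        role = "marginal", stringsAsFactors = FALSE)
    }
    seqs[[sid]] <- s
  }
  list(sequences = seqs,
       truth_sites = if (length(sites)) do.call(rbind, sites) else
         data.frame(seq_id = character(0), tf_name = character(0),
                    start = integer(0), strand = character(0),
                    role = character(0), stringsAsFactors = FALSE),
       truth_triads = if (length(triads)) do.call(rbind, triads) else
         data.frame(seq_id = character(0), order = character(0),
                    center_tf = character(0), start = integer(0),
                    end = integer(0), left_gap = integer(0),
                    right_gap = integer(0), stringsAsFactors = FALSE),
       config = config)
}

#' Generate negative-control sequences (pure background)
#'
#' Non-coding, non-conserved stand-ins: i.i.d. background DNA with no planted
#' structure; any motif match arises by chance.
#'
#' @param config A [sim_config()].
#' @return Named character vector of sequences.
#' @export
generate_negative_controls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 2L))
  ids <- sprintf("neg_%03d", seq_len(config$n_negative))
  setNames(vapply(ids, function(.) random_seq(config$seq_length,
                                              config$background),
                  character(1)), ids)
}

#' Generate a synthetic CRM catalog with planted ordered triads
#'
#' Builds synthetic genome contigs carrying non-overlapping CRMs separated by
#' background spacers. A sampled subset of CRMs receives the ordered triad
#' (canonical order, consensus sites, uniform gaps); the rest are pure
#' background.
#'
#' @param config A [sim_config()].
#' @return List with `catalog` (data.frame with sequences), `genome` (named
#'   character contigs), `planted_ids` and `config`.
#' @export
generate_crm_catalog <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 3L))
  n <- config$n_crms
  per <- config$crms_per_contig
  n_contig <- ceiling(n / per)
  widths <- vapply(config$motifs[config$triad], motif_width, integer(1))
  consensi <- vapply(config$motifs[config$triad], motif_consensus, character(1))
  w_sum <- sum(widths)
  gap_cap <- min(config$gap_max,
                 floor((config$crm_length - w_sum) / 2) - 1L)
  if (gap_cap < config$gap_min)
    stop("crm_length too small to fit the planted triad with gap_min")

  crm_rows <- list(); contigs <- setNames(character(n_contig),
                                          paste0("chr", seq_len(n_contig)))
  idx <- 0L
  for (ct in seq_len(n_contig)) {
    chrom <- names(contigs)[ct]
    parts <- character(0)
    pos <- 0L
    k_here <- min(per, n - (ct - 1L) * per)
    for (j in seq_len(k_here)) {
      idx <- idx + 1L
      parts <- c(parts, random_seq(config$crm_spacer, config$background))
      pos <- pos + config$crm_spacer
      crm_seq <- random_seq(config$crm_length, config$background)
      crm_rows[[idx]] <- data.frame(
        crm_id = sprintf("%s_crm_%d", chrom, j), chrom = chrom,
        start = pos, end = pos + config$crm_length,
        sequence = crm_seq, stringsAsFactors = FALSE)
      parts <- c(parts, crm_seq)
      pos <- pos + config$crm_length
    }
    parts <- c(parts, random_seq(config$crm_spacer, config$background))
    contigs[[chrom]] <- paste(parts, collapse = "")
  }
  catalog <- do.call(rbind, crm_rows)
  planted <- sort(sample(catalog$crm_id, config$n_planted))
  for (cid in planted) {
    r <- which(catalog$crm_id == cid)
    gaps <- floor(runif(2, config$gap_min, gap_cap + 1))
    total <- w_sum + sum(gaps)
    start0 <- sample.int(config$crm_length - total + 1L, 1L) - 1L
    s <- catalog$sequence[r]
    pos <- start0
    for (k in 1:3) {
      s <- plant_site(s, pos, consensi[[k]])
      pos <- pos + widths[k] + if (k < 3) gaps[k] else 0L
    }
    catalog$sequence[r] <- s
    # keep the contig consistent with the planted CRM
    chrom <- catalog$chrom[r]
    contigs[[chrom]] <- plant_site(contigs[[chrom]],
                                   catalog$start[r] + start0,
                                   substr(s, start0 + 1L, start0 + total))
  }
  list(catalog = catalog, genome = contigs, planted_ids = planted,
       config = config)
}

CONS_BOUNDS <- list(primate = c(0.02, 0.18), mammalian = c(0.21, 0.49),
                    birds = c(0.505, 0.595), amphibian_teleost = c(0.61, 0.95))

#' Generate epigenomic tracks and conservation scores for a CRM catalog
#'
#' Each track covers its configured fraction of CRMs (sampled without
#' replacement) with one interval strictly inside every covered CRM. Each
#' CRM's conservation category is drawn from the configured mixture and its
#' mean score from a within-category uniform distribution that respects the
#' category bounds, so classification recovers the planted category exactly.
#'
#' @param config A [sim_config()].
#' @param catalog CRM catalog data.frame (see [generate_crm_catalog()]).
#' @return List with `tracks` (named list of GRanges), `memberships`
#'   (track, crm_id truth), `scores` (crm_id, chrom, start, end, mean_score,
#'   category truth) and `config`.
#' @export
generate_tracks_and_scores <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, 4L))
  n <- nrow(catalog)
  tracks <- list(); memberships <- list()
  for (tn in names(config$track_coverage)) {
    frac <- config$track_coverage[[tn]]
    if (frac > 1) stop("track coverage fraction > 1 for ", tn)
    k <- round(frac * n)
    chosen <- if (k > 0) sort(sample(catalog$crm_id, k)) else character(0)
    rows <- catalog[match(chosen, catalog$crm_id), , drop = FALSE]
    off <- pmax(1L, floor((rows$end - rows$start) * 0.1))
    tracks[[tn]] <- GenomicRanges::GRanges(
      rows$chrom,
      IRanges::IRanges(rows$start + off + 1L, rows$end - off),
      name = paste0(tn, "_", seq_len(nrow(rows))))
    memberships[[tn]] <- data.frame(track = rep(tn, length(chosen)),
                                    crm_id = chosen,
                                    stringsAsFactors = FALSE)
  }
  cats <- sample(names(config$conservation_weights), n, replace = TRUE,
                 prob = config$conservation_weights)
  target <- vapply(cats, function(cc) {
    b <- CONS_BOUNDS[[cc]]
    runif(1, b[1], b[2])
  }, numeric(1))
  scores <- data.frame(crm_id = catalog$crm_id, chrom = catalog$chrom,
                       start = catalog$start, end = catalog$end,
                       mean_score = unname(target), category = cats,
                       stringsAsFactors = FALSE)
  list(tracks = tracks,
       memberships = do.call(rbind, memberships),
       scores = scores, config = config)
}

#' Write a per-base fixed-step conservation wiggle from per-CRM means
#'
#' Per-base values are the CRM's target mean plus mean-centred bounded noise,
#' so the interval's arithmetic mean equals the target exactly and every
#' value stays in \[0, 1\].
#'
#' @param scores Data.frame from [generate_tracks_and_scores()] (`$scores`).
#' @param path Output wiggle path.
#' @param noise Noise amplitude control in \[0, 1\); 0 writes constant values.
#' @param seed Seed for the noise stream.
#' @export
write_conservation_wig <- function(scores, path, noise = 0.5, seed = 1L) {
  set.seed(seed)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(scores))) {
    len <- scores$end[r] - scores$start[r]
    mu <- scores$mean_score[r]
    a <- noise * 0.4 * min(0.1, mu, 1 - mu)
    vals <- rep(mu, len)
    if (a > 0 && len > 1) {
      eps <- runif(len, -a, a)
      vals <- mu + (eps - mean(eps))
    }
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                       scores$chrom[r], scores$start[r] + 1L), con)
    writeLines(sprintf("%.6f", vals), con)
  }
  invisible(path)
}

#' Write per-CRM mean conservation as TSV
#' @param scores Data.frame with crm_id, chrom, start, end, mean_score.
#' @param path Output path.
#' @export
write_conservation_tsv <- function(scores, path) {
  write.table(scores[, c("crm_id", "chrom", "start", "end", "mean_score")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a GRanges track as BED4
#' @param track GRanges with a `name` column.
#' @param path Output path.
#' @export
write_track_bed <- function(track, path) {
  nm <- S4Vectors::mcols(track)$name
  if (is.null(nm)) nm <- paste0("iv_", seq_along(track))
  write.table(data.frame(as.character(GenomicRanges::seqnames(track)),
                         GenomicRanges::start(track) - 1L,
                         GenomicRanges::end(track), nm),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
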