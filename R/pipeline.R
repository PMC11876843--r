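# End-to-end orchestration: discovery (scan -> matrix -> mine -> contrast ->
# syntax) and genome-wide shortlisting (catalog scan -> conservation ->
# epigenomic overlap -> core set). Outputs are pure functions of
# (inputs, parameters); run manifests record content digests to prove it.

write_manifest <- function(out_dir, params) {
  files <- sort(setdiff(list.files(out_dir, full.names = TRUE,
                                   recursive = TRUE),
                        file.path(out_dir, "manifest.tsv")))
  man <- data.frame(file = basename(files),
                    md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
  write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  attr(man, "params") <- params
  man
}

#' Run the motif-grammar discovery pipeline
#'
#' Scans positive and negative sequence sets, builds binding matrices, mines
#' association rules in both, contrasts them, selects the minimal regulatory
#' code (>= `min_items` TFs, highest support then confidence), and runs the
#' adjacency/arrangement/spacing syntax analysis of the chosen triad on the
#' positive set. A negative set producing no rule with >= `min_items` TFs is
#' recorded as `minimal_code = NULL` with a note, not an error.
#'
#' @param positive,negative Named character vectors of sequences (or FASTA
#'   paths).
#' @param motifs Named list of `motif` objects.
#' @param triad 3 TF names whose syntax is analysed; default the top rule's
#'   TF set when it has exactly 3 members, else must be supplied.
#' @param min_rel_score PWM relative-score threshold.
#' @param min_support,min_confidence Mining thresholds.
#' @param min_items Minimum TFs in the minimal-code rule.
#' @param out_dir Optional directory for TSV reports plus a digest manifest.
#' @return List with hit tables, binding matrices, rule tables, contrast
#'   table, `minimal_code`, triad occurrences, arrangement counts, Fisher
#'   p-values, spacing summary and (when `out_dir` is given) the manifest.
#' @export
run_discovery <- function(positive, negative, motifs,
                          triad = NULL, min_rel_score = 0.8,
                          min_support = 0.1, min_confidence = 0.6,
                          min_items = 3L, out_dir = NULL) {
  if (is.character(positive) && length(positive) == 1L && file.exists(positive))
    positive <- read_fasta(positive)
  if (is.character(negative) && length(negative) == 1L && file.exists(negative))
    negative <- read_fasta(negative)
  names(motifs) <- toupper(names(motifs))
  tf_names <- names(motifs)

  pos_hits <- scan_sequences(positive, motifs, min_rel_score)
  neg_hits <- scan_sequences(negative, motifs, min_rel_score)
  pos_mat <- build_binding_matrix(pos_hits, names(positive), tf_names)
  neg_mat <- build_binding_matrix(neg_hits, names(negative), tf_names)

  pos_items <- frequent_itemsets(pos_mat, min_support)
  neg_items <- frequent_itemsets(neg_mat, min_support)
  pos_rules <- derive_rules(pos_items, pos_mat, min_confidence)
  neg_rules <- derive_rules(neg_items, neg_mat, min_confidence)
  contrast <- contrast_controls(pos_rules, neg_rules)

  minimal_code <- tryCatch(select_minimal_code(pos_rules, min_items),
                           error = function(e) NULL)
  note <- if (is.null(minimal_code))
    sprintf("no minimal code: no positive-set rule with >= %d TFs", min_items)
  else NA_character_

  if (is.null(triad)) {
    if (!is.null(minimal_code)) {
      tfs <- unique(c(strsplit(minimal_code$antecedent, ",")[[1]],
                      strsplit(minimal_code$consequent, ",")[[1]]))
      if (length(tfs) == 3L) triad <- tfs
    }
  }
  syntax <- NULL
  if (!is.null(triad)) {
    occ <- find_adjacent_triads(pos_hits, triad, tf_set = tf_names)
    arr <- count_arrangements(occ, triad)
    fisher <- NULL
    if (arr$n_sequences > 0) {
      top <- names(which.max(arr$counts))
      others <- setdiff(names(arr$counts), top)
      fisher <- data.frame(
        center_a = top, center_b = others,
        count_a = arr$counts[[top]],
        count_b = as.integer(arr$counts[others]),
        n = arr$n_sequences,
        p_value = vapply(others, function(o)
          fisher_arrangement_test(arr$counts[[top]], arr$counts[[o]],
                                  arr$n_sequences), numeric(1)),
        stringsAsFactors = FALSE)
      rownames(fisher) <- NULL
    }
    syntax <- list(triad = toupper(triad), occurrences = occ,
                   arrangements = arr, fisher = fisher,
                   spacing = spacing_stats(occ))
  }

  res <- list(pos_hits = pos_hits, neg_hits = neg_hits,
              pos_matrix = pos_mat, neg_matrix = neg_mat,
              pos_rules = pos_rules, neg_rules = neg_rules,
              contrast = contrast, minimal_code = minimal_code, note = note,
              syntax = syntax,
              params = list(min_rel_score = min_rel_score,
                            min_support = min_support,
                            min_confidence = min_confidence,
                            min_items = min_items))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hits_tsv(pos_hits, file.path(out_dir, "pos_hits.tsv"))
    write_hits_tsv(neg_hits, file.path(out_dir, "neg_hits.tsv"))
    write_binding_matrix(pos_mat, file.path(out_dir, "pos_matrix.tsv"))
    write_binding_matrix(neg_mat, file.path(out_dir, "neg_matrix.tsv"))
    write_rules_tsv(pos_rules, file.path(out_dir, "pos_rules.tsv"))
    write_rules_tsv(neg_rules, file.path(out_dir, "neg_rules.tsv"))
    write_rules_tsv(contrast, file.path(out_dir, "contrast.tsv"))
    if (!is.null(syntax)) {
      write_rules_tsv(syntax$occurrences, file.path(out_dir, "triads.tsv"))
      write_rules_tsv(syntax$spacing, file.path(out_dir, "spacing.tsv"))
    }
    res$manifest <- write_manifest(out_dir, res$params)
  }
  res
}

#' Run the genome-wide shortlisting pipeline
#'
#' Scans a CRM catalog for the ordered triad, classifies matched CRMs by
#' conservation depth, intersects them with epigenomic tracks and shortlists
#' the core set.
#'
#' @param catalog CRM catalog data.frame; sequences are extracted from
#'   `genome` when absent.
#' @param motifs Named motif list.
#' @param query A [triad_query()].
#' @param genome Optional genome (FASTA path or named contigs) for
#'   [extract_sequences()].
#' @param conservation Optional conservation source: per-base GRanges track
#'   or per-CRM mean data.frame (see [conservation_records()]).
#' @param tracks Optional named list of GRanges epigenomic tracks; an empty
#'   list skips the feature matrix with a warning.
#' @param track_classes Optional named vector mapping track names to feature
#'   classes for [core_set()].
#' @param core_mode,core_k Core-set membership rule (see [core_set()]).
#' @param snps Optional SNP data.frame (`rsid`, `chrom`, `pos`).
#' @param min_rel_score PWM relative-score threshold.
#' @param out_dir Optional directory for reports plus a digest manifest.
#' @return List with `matches`, `matched_catalog`, `conservation` (records +
#'   summary), `features`, `core`, `snp_hits`, parameters and (when
#'   `out_dir` is given) the manifest.
#' @export
run_shortlist <- function(catalog, motifs, query, genome = NULL,
                          conservation = NULL, tracks = NULL,
                          track_classes = NULL,
                          core_mode = c("k_of", "all_of"), core_k = 3L,
                          snps = NULL, min_rel_score = 0.8, out_dir = NULL) {
  core_mode <- match.arg(core_mode)
  if (anyNA(catalog$sequence)) {
    if (is.null(genome))
      stop("CRM without sequence and no genome provided: ",
           paste(utils::head(catalog$crm_id[is.na(catalog$sequence)], 5),
                 collapse = ", "))
    catalog <- extract_sequences(catalog, genome)
  }
  matches <- scan_catalog(catalog, motifs, query, min_rel_score)
  matched <- catalog[match(matches$crm_id, catalog$crm_id), , drop = FALSE]

  cons <- NULL
  if (!is.null(conservation)) {
    recs <- conservation_records(matched, conservation)
    cons <- list(records = recs, summary = summarize_conservation(recs))
  }
  features <- NULL; core <- NULL
  if (is.null(tracks) || !length(tracks)) {
    warning("no epigenomic tracks supplied; feature matrix skipped")
  } else {
    features <- build_feature_matrix(matched, tracks)
    core <- core_set(features$matrix, mode = core_mode, k = core_k,
                     classes = track_classes)
  }
  snp_hits <- if (!is.null(snps)) snp_overlap(matched, snps) else NULL

  res <- list(matches = matches, matched_catalog = matched,
              conservation = cons, features = features, core = core,
              snp_hits = snp_hits,
              params = list(query = unclass(query),
                            min_rel_score = min_rel_score,
                            core_mode = core_mode, core_k = core_k))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_matched_bed(catalog, matches, file.path(out_dir, "matched.bed"))
    write_rules_tsv(matches, file.path(out_dir, "matches.tsv"))
    if (!is.null(cons))
      write_rules_tsv(cons$records, file.path(out_dir, "conservation.tsv"))
    if (!is.null(features)) {
      write_binding_matrix(features$matrix,
                           file.path(out_dir, "feature_matrix.tsv"))
      writeLines(core, file.path(out_dir, "core_set.txt"))
    }
    res$manifest <- write_manifest(out_dir, res$params)
  }
  res
}
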