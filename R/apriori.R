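# Market-basket association mining over the binary binding matrix.
# Transactions are sequences; items are TF names; presence only (no
# multiplicity weighting). Item counts here are small (<= 23 TFs), so a
# level-wise Apriori with exact support counting on the matrix is used.

itemset_support <- function(mat, items) {
  sum(rowSums(mat[, items, drop = FALSE]) == length(items)) / nrow(mat)
}

#' Mine frequent TF itemsets (Apriori)
#'
#' Level-wise Apriori over the binary binding matrix: candidates of size k are
#' joined from frequent (k-1)-itemsets sharing a (k-2)-prefix and pruned by
#' downward closure; supports are exact transaction fractions.
#'
#' @param mat Binary sequence-by-TF matrix (see [build_binding_matrix()]).
#' @param min_support Minimum support threshold in (0, 1\]. Default 0.1.
#' @return An object of class `itemset_table`: a data.frame with columns
#'   `items` (list column of sorted TF name vectors), `label`
#'   (comma-joined), `size`, `support` and `count`, plus attributes
#'   `min_support` and `n_transactions`.
#' @export
frequent_itemsets <- function(mat, min_support = 0.1) {
  if (is.null(dim(mat)) || nrow(mat) == 0L || ncol(mat) == 0L)
    stop("binding matrix is empty")
  if (min_support <= 0 || min_support > 1)
    stop("min_support must be in (0, 1]")
  if (!all(mat %in% c(0L, 1L))) stop("binding matrix must be binary 0/1")
  items <- sort(colnames(mat))
  mat <- mat[, items, drop = FALSE]
  n <- nrow(mat)

  found <- list()
  sup1 <- colSums(mat) / n
  level <- lapply(items[sup1 >= min_support], identity)
  for (it in level)
    found[[length(found) + 1L]] <- list(items = it, support = sup1[[it]])

  while (length(level) > 1L) {
    cands <- list()
    for (i in seq_len(length(level) - 1L)) {
      for (j in (i + 1L):length(level)) {
        a <- level[[i]]; b <- level[[j]]
        k <- length(a)
        if (k == 1L || identical(a[1:(k - 1L)], b[1:(k - 1L)])) {
          cand <- sort(union(a, b))
          if (length(cand) == k + 1L) cands[[length(cands) + 1L]] <- cand
        }
      }
    }
    if (!length(cands)) break
    cands <- unique(cands)
    # downward-closure prune: all k-subsets must be frequent
    freq_labels <- vapply(level, paste, character(1), collapse = ",")
    cands <- Filter(function(cand) {
      subs <- vapply(seq_along(cand), function(d)
        paste(cand[-d], collapse = ","), character(1))
      all(subs %in% freq_labels)
    }, cands)
    level <- list()
    for (cand in cands) {
      s <- itemset_support(mat, cand)
      if (s >= min_support) {
        level[[length(level) + 1L]] <- cand
        found[[length(found) + 1L]] <- list(items = cand, support = s)
      }
    }
  }

  tab <- data.frame(
    label = vapply(found, function(f) paste(f$items, collapse = ","), character(1)),
    size = vapply(found, function(f) length(f$items), integer(1)),
    support = vapply(found, function(f) f$support, numeric(1)),
    stringsAsFactors = FALSE)
  tab$count <- as.integer(round(tab$support * n))
  tab$items <- I(lapply(found, function(f) f$items))
  tab <- tab[order(tab$size, tab$label), c("items", "label", "size", "support", "count")]
  rownames(tab) <- NULL
  attr(tab, "min_support") <- min_support
  attr(tab, "n_transactions") <- n
  class(tab) <- c("itemset_table", "data.frame")
  tab
}

all_proper_splits <- function(items) {
  k <- length(items)
  out <- list()
  for (mask in 1:(2^k - 2L)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(k - 1L))))
    out[[length(out) + 1L]] <- list(antecedent = items[sel],
                                    consequent = items[!sel])
  }
  out
}

#' Derive association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every nonempty proper-subset
#' split A -> B, the rule is emitted when
#' `confidence = support(A∪B)/support(A) >= min_confidence`, with
#' `lift = confidence / support(B)`. Raw transaction counts are carried along
#' so the support denominator is always auditable.
#'
#' @param itemsets An `itemset_table` from [frequent_itemsets()].
#' @param mat The same binding matrix the itemsets were mined from.
#' @param min_confidence Minimum confidence threshold. Default 0.6.
#' @return Data.frame with columns `antecedent`, `consequent` (comma-joined
#'   TF names), `support`, `confidence`, `lift`, `n_items`, `count` (joint
#'   transaction count) and `n_transactions`; sorted by support desc,
#'   confidence desc, lift desc, then rule label.
#' @export
derive_rules <- function(itemsets, mat, min_confidence = 0.6) {
  if (!inherits(itemsets, "itemset_table"))
    stop("itemsets must come from frequent_itemsets()")
  n <- attr(itemsets, "n_transactions")
  if (n != nrow(mat))
    stop("itemsets were mined from a matrix with ", n,
         " transactions, but 'mat' has ", nrow(mat))
  sup <- setNames(itemsets$support, itemsets$label)
  rows <- list()
  for (r in which(itemsets$size >= 2L)) {
    its <- itemsets$items[[r]]
    s_all <- itemsets$support[r]
    for (split in all_proper_splits(its)) {
      a <- sort(split$antecedent); b <- sort(split$consequent)
      s_a <- sup[[paste(a, collapse = ",")]]  # present by downward closure
      conf <- s_all / s_a
      if (conf >= min_confidence) {
        s_b <- sup[[paste(b, collapse = ",")]]
        rows[[length(rows) + 1L]] <- data.frame(
          antecedent = paste(a, collapse = ","),
          consequent = paste(b, collapse = ","),
          support = s_all, confidence = conf, lift = conf / s_b,
          n_items = length(its),
          count = as.integer(round(s_all * n)), n_transactions = n,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(antecedent = character(0), consequent = character(0),
                      support = numeric(0), confidence = numeric(0),
                      lift = numeric(0), n_items = integer(0),
                      count = integer(0), n_transactions = integer(0)))
  rules <- do.call(rbind, rows)
  lab <- paste(rules$antecedent, "=>", rules$consequent)
  rules <- rules[order(-rules$support, -rules$confidence, -rules$lift, lab), ]
  rownames(rules) <- NULL
  rules
}

#' Select the minimal tissue-specific regulatory code
#'
#' Returns the rule involving at least `min_items` distinct TFs with the
#' highest support, ties broken by confidence (then lift, then rule label).
#'
#' @param rules Rule data.frame from [derive_rules()].
#' @param min_items Minimum number of distinct TFs in the rule. Default 3.
#' @return A one-row data.frame (the selected rule).
#' @export
select_minimal_code <- function(rules, min_items = 3L) {
  if (!nrow(rules)) stop("no rules supplied")
  cand <- rules[rules$n_items >= min_items, , drop = FALSE]
  if (!nrow(cand))
    stop("no minimal code: no association rule involves at least ",
         min_items, " distinct TFs")
  lab <- paste(cand$antecedent, "=>", cand$consequent)
  cand <- cand[order(-cand$support, -cand$confidence, -cand$lift, lab), ]
  cand[1, , drop = FALSE]
}

#' Contrast rule sets between positive and negative datasets
#'
#' Annotates every rule seen in either dataset with presence flags and metric
#' deltas, flagging rules exclusive to the positive set.
#'
#' @param pos_rules,neg_rules Rule data.frames from [derive_rules()], mined
#'   with identical thresholds.
#' @return Data.frame keyed by (antecedent, consequent) with per-dataset
#'   support/confidence/lift, deltas (positive minus negative, NA when absent
#'   on one side), and logical `in_positive`, `in_negative`,
#'   `exclusive_to_positive` columns.
#' @export
contrast_controls <- function(pos_rules, neg_rules) {
  key <- function(r) paste(r$antecedent, "=>", r$consequent)
  pos <- pos_rules; neg <- neg_rules
  pos$rule <- if (nrow(pos)) key(pos) else character(0)
  neg$rule <- if (nrow(neg)) key(neg) else character(0)
  cols <- c("rule", "antecedent", "consequent", "support", "confidence",
            "lift", "n_items")
  m <- merge(pos[, intersect(cols, names(pos)), drop = FALSE],
             neg[, intersect(cols, names(neg)), drop = FALSE],
             by = "rule", all = TRUE, suffixes = c("_pos", "_neg"))
  m$antecedent <- ifelse(is.na(m$antecedent_pos), m$antecedent_neg, m$antecedent_pos)
  m$consequent <- ifelse(is.na(m$consequent_pos), m$consequent_neg, m$consequent_pos)
  m$n_items <- ifelse(is.na(m$n_items_pos), m$n_items_neg, m$n_items_pos)
  m$in_positive <- !is.na(m$support_pos)
  m$in_negative <- !is.na(m$support_neg)
  m$exclusive_to_positive <- m$in_positive & !m$in_negative
  m$d_support <- m$support_pos - m$support_neg
  m$d_confidence <- m$confidence_pos - m$confidence_neg
  m$d_lift <- m$lift_pos - m$lift_neg
  out <- m[, c("rule", "antecedent", "consequent", "n_items",
               "support_pos", "confidence_pos", "lift_pos",
               "support_neg", "confidence_neg", "lift_neg",
               "d_support", "d_confidence", "d_lift",
               "in_positive", "in_negative", "exclusive_to_positive")]
  out <- out[order(out$rule), ]
  rownames(out) <- NULL
  out
}

#' Write association rules as TSV
#' @param rules Rule data.frame.
#' @param path Output path.
#' @export
write_rules_tsv <- function(rules, path) {
  write.table(rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
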