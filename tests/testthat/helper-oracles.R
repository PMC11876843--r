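# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle recomputes its quantity from first principles and never
# calls the implementation path it checks.

BASES4 <- c("A", "C", "G", "T")

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_dna <- function(L, prob = rep(0.25, 4)) {
  paste(sample(BASES4, L, replace = TRUE, prob = prob), collapse = "")
}

# Score every window of both strands by direct per-position summation using
# frequencies recomputed from raw counts.
oracle_scan <- function(seq, motif, min_rel_score, both_strands = TRUE) {
  counts <- motif$counts
  bg <- motif$background
  freq <- sweep(counts, 2, bg * motif$pseudocount, "+") /
    (rowSums(counts) + motif$pseudocount)
  score_win <- function(win) {
    chs <- strsplit(win, "")[[1]]
    if (any(!chs %in% BASES4)) return(NA_real_)
    sc <- 0
    for (i in seq_along(chs))  # plain double accumulation, position by position
      sc <- sc + log2(freq[i, chs[i]] / bg[chs[i]])
    sc
  }
  pwm <- log2(sweep(freq, 2, bg, "/"))
  smin <- sum(apply(pwm, 1, min)); smax <- sum(apply(pwm, 1, max))
  w <- nrow(counts); L <- nchar(seq)
  out <- list()
  for (p in seq_len(max(0L, L - w + 1L))) {
    win <- substr(seq, p, p + w - 1L)
    for (strand in if (both_strands) c("+", "-") else "+") {
      sc <- score_win(if (strand == "+") win else revcomp(win))
      if (is.na(sc)) next
      rel <- (sc - smin) / (smax - smin)
      if (rel >= min_rel_score)
        out[[length(out) + 1L]] <- data.frame(
          start = p - 1L, end = p - 1L + w, strand = strand,
          score = sc, rel_score = rel, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# Exhaustive itemset enumeration over all 2^k - 1 nonempty subsets.
oracle_itemsets <- function(mat, min_support) {
  items <- sort(colnames(mat))
  k <- length(items)
  out <- list()
  for (mask in 1:(2^k - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(k - 1L))))
    sub <- items[sel]
    s <- sum(rowSums(mat[, sub, drop = FALSE]) == length(sub)) / nrow(mat)
    if (s >= min_support)
      out[[length(out) + 1L]] <- data.frame(
        label = paste(sub, collapse = ","), size = length(sub), support = s,
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$size, res$label), ]
  rownames(res) <- NULL
  res
}

# Exhaustive rule enumeration with direct counting.
oracle_rules <- function(mat, min_support, min_confidence) {
  items <- sort(colnames(mat))
  k <- length(items)
  supp <- function(sub)
    sum(rowSums(mat[, sub, drop = FALSE]) == length(sub)) / nrow(mat)
  out <- list()
  for (mask in 1:(2^k - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(k - 1L))))
    full <- items[sel]
    if (length(full) < 2L) next
    s_all <- supp(full)
    if (s_all < min_support) next
    kk <- length(full)
    for (amask in 1:(2^kk - 2L)) {
      asel <- as.logical(bitwAnd(amask, 2^(0:(kk - 1L))))
      a <- full[asel]; b <- full[!asel]
      conf <- s_all / supp(a)
      if (conf >= min_confidence)
        out[[length(out) + 1L]] <- data.frame(
          antecedent = paste(sort(a), collapse = ","),
          consequent = paste(sort(b), collapse = ","),
          support = s_all, confidence = conf, lift = conf / supp(b),
          stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$antecedent, res$consequent), , drop = FALSE]
}

# Two-sided Fisher p by direct hypergeometric enumeration with choose().
oracle_fisher <- function(a, b, n) {
  m <- a + b
  lo <- max(0L, m - n); hi <- min(n, m)
  prob <- function(x) choose(n, x) * choose(n, m - x) / choose(2 * n, m)
  p_obs <- prob(a)
  xs <- lo:hi
  sum(vapply(xs, prob, numeric(1))[vapply(xs, prob, numeric(1)) <=
                                     p_obs * (1 + 1e-7)])
}

# Quadratic all-pairs interval overlap oracle (half-open coordinates).
oracle_overlap_pairs <- function(crms, ivs) {
  out <- list()
  for (i in seq_len(nrow(crms))) for (j in seq_len(nrow(ivs))) {
    if (crms$chrom[i] != ivs$chrom[j]) next
    ov <- min(crms$end[i], ivs$end[j]) - max(crms$start[i], ivs$start[j])
    if (ov >= 1)
      out[[length(out) + 1L]] <- data.frame(
        crm_id = crms$crm_id[i], interval_index = j, overlap_bp = ov,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(crm_id = character(0), interval_index = integer(0),
                      overlap_bp = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$crm_id, res$interval_index), , drop = FALSE]
}

# Adjacency oracle: an occurrence is any in-order triple of sites carrying
# the three triad TFs (one each) such that no other site of the analysis set
# starts strictly between the two flanks. On site lists with distinct start
# positions this is equivalent to the consecutive-window rule but derived
# from the adjacency definition rather than from window sliding.
oracle_triads <- function(sites, triad) {
  n <- nrow(sites)
  out <- list()
  if (n < 3L) return(out)
  for (i in 1:(n - 2L)) for (j in (i + 1L):(n - 1L)) for (k in (j + 1L):n) {
    tfs <- sites$tf_name[c(i, j, k)]
    if (!setequal(tfs, triad)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    if (any(sites$start[others] > sites$start[i] &
              sites$start[others] < sites$start[k])) next
    out[[length(out) + 1L]] <- data.frame(
      left_tf = tfs[1], center_tf = tfs[2], right_tf = tfs[3],
      left_start = sites$start[i], center_start = sites$start[j],
      right_start = sites$start[k], stringsAsFactors = FALSE)
  }
  out
}

# small deterministic binary matrix fixture
random_binary_matrix <- function(n, k, p = 0.4, seed = 1) {
  set.seed(seed)
  mat <- matrix(rbinom(n * k, 1L, p), nrow = n,
                dimnames = list(sprintf("s%02d", 1:n), LETTERS[1:k]))
  storage.mode(mat) <- "integer"
  mat
}

# tiny motif fixture: strongly biased counts with the given consensus
make_motif <- function(consensus, tf = "TFX", id = paste0("M_", tf),
                       strong = 12, weak = 1) {
  chs <- strsplit(consensus, "")[[1]]
  counts <- t(vapply(chs, function(b)
    ifelse(BASES4 == b, strong, weak), numeric(4)))
  colnames(counts) <- BASES4
  new_motif(tf, id, counts)
}

hits_df <- function(seq_id, tf, start, width = 5L, rel = 1, strand = "+") {
  n <- max(length(seq_id), length(start))
  if (n == 0L)
    return(data.frame(seq_id = character(0), tf_name = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      rel_score = numeric(0), stringsAsFactors = FALSE))
  data.frame(seq_id = seq_id, tf_name = tf, start = as.integer(start),
             end = as.integer(start + width), strand = strand,
             score = rel * 10, rel_score = rel, stringsAsFactors = FALSE)
}
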