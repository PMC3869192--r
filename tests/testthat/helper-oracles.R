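# Independent brute-force oracles. These are deliberately naive (explicit
# loops, no shared code with the package internals) so they can vouch for
# the vectorized implementations.

# TF-iDF, entry by entry, straight from the defining formula.
oracle_tfidf <- function(m, base = exp(1)) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m), dimnames = dimnames(m))
  for (i in seq_len(ncol(m))) {
    m_i <- 0
    for (j in seq_len(n)) if (m[j, i] > 0) m_i <- m_i + 1
    for (j in seq_len(n)) {
      tot <- sum(m[j, ])
      if (tot > 0 && m_i > 0) {
        out[j, i] <- (m[j, i] / tot) * log(n / m_i, base = base)
      }
    }
  }
  out
}

# Plug-in mutual information from an explicit contingency table, in bits.
oracle_mi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  mi <- 0
  for (x in ua) {
    for (y in ub) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0) {
        mi <- mi + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
      }
    }
  }
  mi
}

# Mann-Whitney AUC by O(n^2) pairwise comparison, half credit for ties.
oracle_auc <- function(scores, labels, positive = "old") {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) total <- total + 1
      else if (scores[i] == scores[j]) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive best next feature under the mRMR difference criterion, given an
# already-discretized matrix `d`, class vector `y`, and selected index set.
oracle_mrmr_step <- function(d, y, selected) {
  cand <- setdiff(seq_len(ncol(d)), selected)
  best <- NULL
  best_obj <- -Inf
  for (i in cand) {
    rel <- oracle_mi(d[, i], y)
    red <- 0
    for (j in selected) red <- red + oracle_mi(d[, i], d[, j])
    obj <- if (length(selected)) rel - red / length(selected) else rel
    name_i <- colnames(d)[i]
    if (obj > best_obj + 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && !is.null(best) && name_i < colnames(d)[best])) {
      best <- i
      best_obj <- obj
    }
  }
  list(index = best, objective = best_obj)
}

random_count_matrix <- function(n, p, max_count = 20, sparsity = 0.5) {
  m <- matrix(rbinom(n * p, 1, 1 - sparsity) * sample.int(max_count, n * p, replace = TRUE),
              n, p, dimnames = list(paste0("S", seq_len(n)), sprintf("F%03d", seq_len(p))))
  # guard against all-zero rows, which TF is undefined for
  for (j in which(rowSums(m) == 0)) m[j, sample.int(p, 1)] <- 1
  m
}
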