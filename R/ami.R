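#' Adjusted mutual information between two partitions
#'
#' `AMI = (MI - E[MI]) / (mean(H_a, H_b) - E[MI])`, where the expected mutual
#' information is taken under the fixed-marginals permutation model and
#' computed exactly as a hypergeometric sum over every feasible contingency
#' cell count (no sampling, no approximation). Identical non-degenerate
#' partitions score 1; a constant partition against anything scores 0; when
#' the denominator is 0 the value is defined as 0.
#'
#' @param labels_a,labels_b Equal-length label vectors (any atomic type).
#' @return Numeric scalar, at most 1.
#' @examples
#' ami(c(1, 1, 2, 2), c("a", "a", "b", "b")) # 1
#' @export
ami <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort(sprintf("length mismatch: %d vs %d",
                  length(labels_a), length(labels_b)))
  }
  n <- length(labels_a)
  if (n < 2) abort("need n >= 2")
  tab <- table(as.character(labels_a), as.character(labels_b))
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- mutual_information(tab)
  h_a <- partition_entropy(a, n)
  h_b <- partition_entropy(b, n)
  emi <- expected_mi(a, b, n)
  denom <- (h_a + h_b) / 2 - emi
  if (abs(denom) < 1e-12) return(0)
  (mi - emi) / denom
}

partition_entropy <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- tab[i, j]
      if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
    }
  }
  unname(mi)
}

# Exact E[MI] under the fixed-marginals permutation (hypergeometric) model.
# For each contingency cell (i, j), sum over all feasible counts nij from
# max(1, a_i + b_j - n) to min(a_i, b_j); the probability of each count is a
# ratio of factorials evaluated in log space.
expected_mi <- function(a, b, n) {
  emi <- 0
  lf <- lgamma(seq_len(n + 1))  # lf[m + 1] = log(m!)
  lfac <- function(m) lf[m + 1]
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lfac(ai) + lfac(bj) + lfac(n - ai) + lfac(n - bj) -
        lfac(n) - lfac(nij) - lfac(ai - nij) - lfac(bj - nij) -
        lfac(n - ai - bj + nij)
      term <- (nij / n) * log(n * nij / (ai * bj))
      emi <- emi + sum(term * exp(log_p))
    }
  }
  unname(emi)
}
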