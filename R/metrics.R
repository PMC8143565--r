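#' Newman-Girvan modularity of a partition
#'
#' Computes Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) delta(C_i, C_j), the
#' standard quality function comparing the density of within-community edges
#' against a degree-preserving random null model. Internally the equivalent
#' per-community form sum_c (l_c/m - (d_c/2m)^2) is used, with l_c the number
#' of edges inside community c and d_c the total degree of its members.
#'
#' @param net an `mni_network` with at least one edge.
#' @param part a partition: membership vector named by node id (any label
#'   type), or unnamed in node order.
#' @return modularity Q, a number in \[-0.5, 1).
#' @examples
#' fx <- load_fixture("karate")
#' modularity_q(fx$network, fx$truth)
#' @export
modularity_q <- function(net, part) {
  stopifnot(inherits(net, "mni_network"))
  if (net$m < 1) stop("modularity is undefined for a network with no edges")
  memb <- align_partition(net, part)
  m <- net$m
  d_c <- tapply(net$deg, memb, sum)
  cu <- memb[net$edges[, 1]]
  cv <- memb[net$edges[, 2]]
  internal <- cu == cv
  l_c <- tapply(internal, cu, sum) # only within-community edges contribute
  l_by_comm <- rep(0, length(d_c))
  names(l_by_comm) <- names(d_c)
  l_by_comm[names(l_c)] <- l_c
  sum(l_by_comm / m - (d_c / (2 * m))^2)
}

#' Contingency table between two partitions
#'
#' Cross-tabulates community memberships: entry N_ij is the number of nodes
#' placed in community i by `a` and community j by `b`. Rows/columns are
#' ordered by sorted label. The table underlies NMI and AMI.
#'
#' @param a,b partitions as named membership vectors over the identical node
#'   set.
#' @return object of class `mni_contingency`: list with `counts` (matrix),
#'   `row_sums`, `col_sums`, `n`, `c_a`, `c_b`.
#' @export
contingency <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b)) stop("unnamed partitions must have equal length")
    names(a) <- names(b) <- seq_along(a)
  }
  only_a <- setdiff(names(a), names(b))
  only_b <- setdiff(names(b), names(a))
  if (length(only_a) || length(only_b)) {
    stop("partitions cover different node sets; only in first: {",
         paste(utils::head(only_a, 5), collapse = ","), "}, only in second: {",
         paste(utils::head(only_b, 5), collapse = ","), "}")
  }
  b <- b[names(a)]
  counts <- table(factor(a), factor(b))
  counts <- unclass(matrix(as.integer(counts), nrow(counts), ncol(counts),
                           dimnames = dimnames(counts)))
  structure(
    list(counts = counts,
         row_sums = rowSums(counts), col_sums = colSums(counts),
         n = length(a), c_a = nrow(counts), c_b = ncol(counts)),
    class = "mni_contingency"
  )
}

#' @export
print.mni_contingency <- function(x, ...) {
  cat(sprintf("<mni_contingency> %d x %d communities, %d nodes\n",
              x$c_a, x$c_b, x$n))
  print(x$counts)
  invisible(x)
}

# Mutual information (nats) and marginal entropies from a contingency table.
mi_entropies <- function(ct) {
  N <- ct$n
  nij <- ct$counts
  ai <- ct$row_sums
  bj <- ct$col_sums
  pos <- nij > 0
  outer_ab <- outer(ai, bj)
  mi <- sum((nij[pos] / N) * log(N * nij[pos] / outer_ab[pos]))
  h <- function(x) { p <- x[x > 0] / N; -sum(p * log(p)) }
  list(mi = mi, h_a = h(ai), h_b = h(bj))
}

#' Normalized mutual information between two partitions
#'
#' NMI(A, B) = -2 * sum_ij N_ij log(N_ij N / (N_i N_j)) /
#' (sum_i N_i log(N_i/N) + sum_j N_j log(N_j/N)): mutual information
#' normalized by the sum of the marginal entropies (the log base cancels).
#' 1 means the partitions agree exactly (up to label renaming), 0 that they
#' are independent. If both partitions are a single community the marginal
#' entropies vanish; the partitions are then identical and NMI is defined
#' as 1.
#'
#' @inheritParams contingency
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  ct <- contingency(a, b)
  me <- mi_entropies(ct)
  denom <- me$h_a + me$h_b
  if (denom <= .Machine$double.eps) {
    return(if (same_partition(a, b)) 1 else 0)
  }
  val <- 2 * me$mi / denom
  min(max(val, 0), 1)
}

#' Adjusted mutual information between two partitions
#'
#' AMI corrects mutual information for chance agreement:
#' AMI = (MI - E\[MI\]) / (mean(H(A), H(B)) - E\[MI\]), where E\[MI\] is the
#' expected mutual information under the hypergeometric model of random
#' partitions with the observed community sizes. Random partitions score
#' 0 in expectation; identical partitions score 1. The arithmetic mean of
#' the entropies is used for normalization.
#'
#' @inheritParams contingency
#' @return AMI in \[-1, 1\].
#' @export
ami <- function(a, b) {
  ct <- contingency(a, b)
  me <- mi_entropies(ct)
  if (me$h_a <= .Machine$double.eps && me$h_b <= .Machine$double.eps) {
    return(if (same_partition(a, b)) 1 else 0)
  }
  emi_val <- expected_mi(ct)
  denom <- (me$h_a + me$h_b) / 2 - emi_val
  if (abs(denom) < 1e-12) {
    return(if (same_partition(a, b)) 1 else 0)
  }
  (me$mi - emi_val) / denom
}

# Expected mutual information (nats) under the hypergeometric null model
# of partitions with fixed community sizes (Vinh, Epps & Bailey 2010).
expected_mi <- function(ct) {
  N <- ct$n
  ai <- ct$row_sums
  bj <- ct$col_sums
  emi <- 0
  lgN <- lgamma(N + 1)
  for (i in seq_along(ai)) {
    a <- ai[[i]]
    for (j in seq_along(bj)) {
      b <- bj[[j]]
      lo <- max(1, a + b - N)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / N) * log(N * nij / (a * b))
      logp <- lgamma(a + 1) + lgamma(b + 1) +
        lgamma(N - a + 1) + lgamma(N - b + 1) -
        lgN - lgamma(nij + 1) - lgamma(a - nij + 1) -
        lgamma(b - nij + 1) - lgamma(N - a - b + nij + 1)
      emi <- emi + sum(term * exp(logp))
    }
  }
  emi
}

#' Number of communities in a partition
#'
#' @param part membership vector (any label type); must be non-empty.
#' @return integer count of distinct labels in use.
#' @export
community_count <- function(part) {
  if (length(part) == 0) stop("empty partition")
  length(unique(part))
}

#' Information entropy of a sequence of metric values
#'
#' The stability statistic for repeated runs of a stochastic algorithm:
#' values are rounded to `precision` decimals, the empirical distribution
#' over distinct rounded values is formed, and its Shannon entropy in bits
#' is returned. A perfectly stable algorithm yields identical values in
#' every run and therefore entropy 0; 100 all-distinct values yield
#' log2(100) ~ 6.64 bits.
#'
#' @param values numeric vector (one metric value per run); non-empty.
#' @param precision decimal places used to bin values before counting
#'   (default 3, the precision the metrics are customarily reported at).
#' @return entropy in bits.
#' @examples
#' sequence_entropy(rep(0.372, 100)) # 0
#' sequence_entropy(c(1, 1, 2, 2))   # 1 bit
#' @export
sequence_entropy <- function(values, precision = 3) {
  if (length(values) == 0) stop("empty value sequence")
  if (precision < 0) stop("precision must be >= 0")
  p <- table(round(values, precision)) / length(values)
  -sum(p * log2(p))
}
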