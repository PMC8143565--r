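# Independent oracles and small random-case generators used across tests.
# These deliberately re-derive quantities by direct definition (dense
# matrices, full double sums, exhaustive enumeration) rather than calling
# the package's incremental code paths.

# Modularity by the literal pairwise double sum over all ordered node pairs:
# (1/2m) * sum_ij [A_ij - k_i k_j / 2m] delta(C_i, C_j).
oracle_modularity <- function(net, memb) {
  n <- net$n
  m <- net$m
  A <- matrix(0, n, n)
  A[net$edges] <- 1
  A[net$edges[, c(2, 1), drop = FALSE]] <- 1
  k <- rowSums(A)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) total <- total + A[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  total / (2 * m)
}

# Erdos-Renyi style random simple graph with at least one edge.
random_graph <- function(n, p = 0.5) {
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) {
      return(network_from_edges(pairs[keep, 1], pairs[keep, 2],
                                ids = as.character(seq_len(n))))
    }
  }
}

random_partition <- function(n, k) {
  p <- sample.int(k, n, replace = TRUE)
  # dense labels in first-appearance order, matching the package's internal
  # community indexing so labels can double as community indices
  p <- match(p, unique(p))
  names(p) <- as.character(seq_len(n))
  p
}

# All set partitions of 1..n (Bell-number enumeration, for tiny n).
set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- set_partitions(n - 1)
  out <- list()
  for (p in smaller) {
    for (b in seq_len(max(p) + 1)) {
      out[[length(out) + 1]] <- c(p, b)
    }
  }
  out
}

# Two triangles joined by one bridge edge (3-4); m = 7.
bridged_triangles <- function() {
  e <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4))
  network_from_edges(e[, 1], e[, 2])
}

karate <- function() load_fixture("karate")
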