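#' Stochastic label propagation (classical LPA)
#'
#' The classical asynchronous label propagation algorithm: every node starts
#' with a unique label; each sweep visits all nodes in a fresh uniformly
#' random order and each node adopts the label held by the maximum number of
#' its neighbors, breaking ties uniformly at random. Updates are
#' asynchronous: within a sweep, already-updated neighbors contribute their
#' new label and not-yet-updated neighbors their previous one. The algorithm
#' stops when every node's label is among the most frequent labels of its
#' neighbors (the standard convergence criterion, which is robust to random
#' tie re-flips), or after `max_sweeps` sweeps. Isolated nodes keep their own
#' label.
#'
#' All randomness (visit order and tie-breaks) is drawn from one RNG stream
#' seeded with `seed`, so results are bit-for-bit reproducible per seed; the
#' caller's RNG state is left untouched.
#'
#' @param net an `mni_network`.
#' @param seed integer seed for the run's RNG stream.
#' @param max_sweeps hard cap on sweeps (default 100); hitting it is flagged,
#'   not an error.
#' @return list with `membership` (integer labels named by node id,
#'   relabeled to consecutive integers), `sweeps` (sweeps used) and
#'   `converged` (logical; `FALSE` when the cap was hit).
#' @examples
#' fx <- load_fixture("two_triangles")
#' run_lpa(fx$network, seed = 1)$membership
#' @export
run_lpa <- function(net, seed = 1, max_sweeps = 100) {
  stopifnot(inherits(net, "mni_network"))
  if (net$n < 1) stop("empty network")
  if (max_sweeps < 1) stop("max_sweeps must be >= 1")
  n <- net$n
  adj <- net$adj
  labels <- seq_len(n)

  with_rng(seed, {
    converged <- FALSE
    sweeps <- 0L
    while (sweeps < max_sweeps && !converged) {
      sweeps <- sweeps + 1L
      for (x in sample.int(n)) {
        nb <- adj[[x]]
        if (length(nb) == 0) next
        nl <- labels[nb]
        ul <- unique(nl)
        cnt <- tabulate(match(nl, ul))
        best <- ul[cnt == max(cnt)]
        labels[x] <- if (length(best) == 1) best
                     else best[sample.int(length(best), 1)]
      }
      # converged when each node's label is among its neighbors' modal labels
      converged <- TRUE
      for (x in seq_len(n)) {
        nb <- adj[[x]]
        if (length(nb) == 0) next
        nl <- labels[nb]
        ul <- unique(nl)
        cnt <- tabulate(match(nl, ul))
        if (!(labels[x] %in% ul[cnt == max(cnt)])) { converged <- FALSE; break }
      }
    }
  })
  if (!converged) warning("label propagation hit the sweep cap (", max_sweeps,
                          ") before converging")
  memb <- relabel(labels)
  names(memb) <- net$ids
  list(membership = memb, sweeps = sweeps, converged = converged)
}

#' Repeated-run stability experiment
#'
#' Runs a community-detection algorithm `runs` times on the same network and
#' collects per-run metric sequences: modularity `Q`, community count `CN`,
#' and (when a ground-truth partition is supplied) `NMI` and `AMI`. The
#' sequences feed [sequence_entropy()]: a deterministic algorithm produces
#' constant sequences with entropy 0, while stochastic label propagation
#' produces fluctuating ones. Run r of a stochastic algorithm uses seed
#' `base_seed + r - 1`.
#'
#' @param net an `mni_network`.
#' @param algorithm `"lpa"` (stochastic baseline) or `"lpa-mni"`
#'   (deterministic; seeds are irrelevant but runs are still executed).
#' @param runs number of repetitions (>= 1).
#' @param truth optional ground-truth partition for NMI/AMI columns.
#' @param base_seed first seed of the consecutive seed block.
#' @param max_sweeps per-run sweep cap.
#' @return data.frame with columns `run`, `seed`, `Q`, `CN` and, if `truth`
#'   is given, `NMI`, `AMI`.
#' @export
stability_run <- function(net, algorithm = c("lpa", "lpa-mni"), runs = 100,
                          truth = NULL, base_seed = 1, max_sweeps = 100) {
  algorithm <- match.arg(algorithm)
  if (runs < 1) stop("runs must be >= 1")
  seeds <- base_seed + seq_len(runs) - 1
  res <- lapply(seeds, function(s) {
    memb <- switch(algorithm,
      "lpa" = run_lpa(net, seed = s, max_sweeps = max_sweeps)$membership,
      "lpa-mni" = run_lpa_mni(net, max_sweeps = max_sweeps)$membership)
    row <- data.frame(seed = s,
                      Q = modularity_q(net, memb),
                      CN = community_count(memb))
    if (!is.null(truth)) {
      row$NMI <- nmi(memb, truth)
      row$AMI <- ami(memb, truth)
    }
    row
  })
  out <- do.call(rbind, res)
  out <- cbind(run = seq_len(runs), out)
  rownames(out) <- NULL
  out
}
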