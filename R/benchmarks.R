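# Synthetic benchmark graphs with planted community structure.

#' Generate a Girvan-Newman planted-partition benchmark
#'
#' The classical benchmark: 128 nodes in four planted communities of 32,
#' with every node expecting 16 links split between its own community and
#' the rest. `external_fraction` f sets the split: the expected external
#' degree is z_out = 16 f and the expected internal degree z_in = 16 (1-f),
#' realised as a stochastic block model with within-block edge probability
#' z_in/31 and between-block probability z_out/96. At f = 0 the four blocks
#' are disconnected; as f grows the planted structure fades.
#'
#' @param external_fraction fraction of a node's expected links that leave
#'   its planted community, in \[0, 1\].
#' @param seed integer seed; generation is reproducible per seed.
#' @param n_communities,community_size,expected_degree block structure
#'   (defaults 4 x 32, expected degree 16, the canonical setting).
#' @return list with `network` (an `mni_network`), `truth` (named
#'   membership) and `stats` (realised mean degree and mixing).
#' @examples
#' b <- generate_gn(0.1, seed = 1)
#' b$network$n; community_count(b$truth)
#' @export
generate_gn <- function(external_fraction, seed = 1, n_communities = 4,
                        community_size = 32, expected_degree = 16) {
  f <- external_fraction
  if (f < 0 || f > 1) stop("external_fraction must be in [0, 1]")
  n <- n_communities * community_size
  z_out <- f * expected_degree
  z_in <- (1 - f) * expected_degree
  p_in <- z_in / (community_size - 1)
  p_out <- z_out / (n - community_size)
  if (p_in > 1 || p_out > 1) stop("edge probability exceeds 1; reduce degree")
  pm <- matrix(p_out, n_communities, n_communities)
  diag(pm) <- p_in
  g <- with_rng(seed,
                igraph::sample_sbm(n, pref.matrix = pm,
                                   block.sizes = rep(community_size,
                                                     n_communities)))
  net <- from_igraph(g)
  truth <- rep(seq_len(n_communities), each = community_size)
  names(truth) <- net$ids
  list(network = net, truth = truth,
       stats = realized_stats(net, truth))
}

# Realised mean degree and mixing of a benchmark instance: edge-level
# mixing (fraction of edges crossing communities) and node-averaged mixing
# (mean over non-isolated nodes of external degree / degree).
realized_stats <- function(net, truth) {
  memb <- align_partition(net, truth)
  cross <- memb[net$edges[, 1]] != memb[net$edges[, 2]]
  ext_deg <- integer(net$n)
  for (e in which(cross)) {
    u <- net$edges[e, 1]; v <- net$edges[e, 2]
    ext_deg[u] <- ext_deg[u] + 1L
    ext_deg[v] <- ext_deg[v] + 1L
  }
  nz <- net$deg > 0
  list(mean_degree = 2 * net$m / net$n,
       mixing_edges = if (net$m) mean(cross) else NA_real_,
       mixing_nodes = if (any(nz)) mean(ext_deg[nz] / net$deg[nz]) else NA_real_)
}

#' Generate an LFR-style benchmark network
#'
#' Builds a synthetic network with planted communities whose node degrees
#' and community sizes follow truncated power laws, as in the LFR benchmark
#' family. Degrees are drawn from an exponent-`tau1` power law truncated at
#' `k_max` with the lower cutoff calibrated so the mean is `k_mean`;
#' community sizes from an exponent-`tau2` power law on
#' \[`c_min`, `c_max`\] summing to `n`. Each node gets an internal degree of
#' (1 - `mu`) of its degree (stochastically rounded so the expectation is
#' exact), is assigned to a community large enough to host it, and stubs are
#' wired by a configuration model with rewiring to remove self-loops,
#' duplicate edges and (for external stubs) within-community pairs;
#' irreparable stub pairs are dropped, so realised degrees can fall slightly
#' short of the drawn ones.
#'
#' @param n number of nodes.
#' @param k_mean,k_max mean and maximum degree.
#' @param tau1,tau2 power-law exponents for degrees and community sizes.
#' @param c_min,c_max community size bounds.
#' @param mu mixing parameter in \[0, 1\]: expected fraction of a node's
#'   links that leave its community.
#' @param seed integer seed.
#' @return list with `network`, `truth` and `stats` as in [generate_gn()].
#' @examples
#' b <- generate_lfr(200, k_mean = 8, k_max = 20, c_min = 10, c_max = 50,
#'                   mu = 0.1, seed = 1)
#' b$stats$mixing_nodes
#' @export
generate_lfr <- function(n, k_mean = 15, k_max = 50, tau1 = 2, tau2 = 1,
                         c_min = 10, c_max = 50, mu = 0.1, seed = 1) {
  if (!(c_min <= c_max && c_max <= n)) stop("need c_min <= c_max <= n")
  if (!(k_mean <= k_max && k_max < n)) stop("need k_mean <= k_max < n")
  if (mu < 0 || mu > 1) stop("mu must be in [0, 1]")
  if ((1 - mu) * k_max >= c_max) {
    stop("infeasible parameters: (1 - mu) * k_max = ", (1 - mu) * k_max,
         " >= c_max = ", c_max,
         "; the largest community cannot host the max-degree node")
  }
  with_rng(seed, {
    deg <- sample_powerlaw_degrees(n, k_mean, k_max, tau1)
    sizes <- sample_community_sizes(n, tau2, c_min, c_max)
    d_int <- stochastic_round((1 - mu) * deg)
    d_int <- pmin(d_int, deg)
    asg <- assign_communities(d_int, sizes)
    memb <- asg$membership
    d_int <- asg$d_int

    edges <- matrix(integer(0), 0, 2)
    # internal wiring: realize each community's internal degree sequence as
    # a simple graph, then randomize by degree-preserving rewiring
    for (c in seq_along(sizes)) {
      members <- which(memb == c)
      di <- d_int[members]
      # trim to a graphical sequence (surplus stubs become external)
      repeat {
        if (sum(di) %% 2 == 1) di[which.max(di)] <- di[which.max(di)] - 1L
        if (sum(di) == 0 || igraph::is_graphical(di)) break
        di[which.max(di)] <- di[which.max(di)] - 1L
      }
      d_int[members] <- di
      if (sum(di) == 0) next
      gc_ <- igraph::realize_degseq(di)
      ne <- igraph::ecount(gc_)
      if (ne > 1) {
        gc_ <- igraph::rewire(gc_, igraph::keeping_degseq(niter = 10 * ne))
      }
      el <- igraph::as_edgelist(gc_, names = FALSE)
      edges <- rbind(edges, cbind(members[el[, 1]], members[el[, 2]]))
    }
    # external wiring across communities
    d_ext <- deg - d_int
    if (sum(d_ext) %% 2 == 1) {
      j <- which.max(d_ext)
      d_ext[j] <- d_ext[j] - 1L
    }
    edges <- rbind(edges,
                   match_stubs(rep(seq_len(n), d_ext), forbid_group = memb,
                               existing = edges))

    net <- suppressWarnings(
      network_from_edges(edges[, 1], edges[, 2], ids = as.character(seq_len(n))))
    truth <- memb
    names(truth) <- net$ids
    list(network = net, truth = truth, stats = realized_stats(net, truth))
  })
}

# Integer degrees from a truncated continuous power law, lower cutoff
# calibrated by bisection so the rounded-sample mean hits k_mean.
sample_powerlaw_degrees <- function(n, k_mean, k_max, tau) {
  u_grid <- (seq_len(4096) - 0.5) / 4096
  inv <- function(u, a, b) {
    if (abs(tau - 1) < 1e-9) a * (b / a)^u
    else (a^(1 - tau) - u * (a^(1 - tau) - b^(1 - tau)))^(1 / (1 - tau))
  }
  mean_at <- function(a) mean(pmin(pmax(round(inv(u_grid, a, k_max)), 1), k_max))
  lo <- 1; hi <- k_max
  if (mean_at(lo) > k_mean) {
    a <- lo # even the widest cutoff overshoots; accept the closest mean
  } else {
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (mean_at(mid) < k_mean) lo <- mid else hi <- mid
    }
    a <- (lo + hi) / 2
  }
  d <- pmin(pmax(round(inv(stats::runif(n), a, k_max)), 1), k_max)
  as.integer(d)
}

# Community sizes from a discrete power law on [c_min, c_max] summing to n.
sample_community_sizes <- function(n, tau, c_min, c_max) {
  support <- c_min:c_max
  w <- support^(-tau)
  for (attempt in 1:1000) {
    sizes <- integer(0)
    while (sum(sizes) < n) {
      sizes <- c(sizes, sample(support, 1, prob = w))
    }
    excess <- sum(sizes) - n
    if (excess == 0) return(sizes)
    last <- sizes[length(sizes)] - excess
    head_sizes <- sizes[-length(sizes)]
    if (last >= c_min) return(c(head_sizes, last))
    # fold the short remainder into earlier communities, respecting c_max
    need <- n - sum(head_sizes)
    room <- c_max - head_sizes
    if (sum(room) >= need && length(head_sizes) > 0) {
      ord <- order(room, decreasing = TRUE)
      for (i in ord) {
        add <- min(room[i], need)
        head_sizes[i] <- head_sizes[i] + add
        need <- need - add
        if (need == 0) break
      }
      if (need == 0) return(head_sizes)
    }
  }
  stop("could not partition ", n, " nodes into community sizes in [",
       c_min, ", ", c_max, "]")
}

# floor(x) + Bernoulli(frac(x)): integer rounding with exact expectation.
stochastic_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + (stats::runif(length(x)) < (x - fl)))
}

# Assign nodes to communities so each node's internal degree fits
# (d_int <= size - 1), filling by remaining capacity. Nodes whose internal
# degree fits no open community get it trimmed to what the roomiest open
# community can host (the surplus becomes external stubs).
assign_communities <- function(d_int, sizes) {
  n <- length(d_int)
  slots <- sizes
  memb <- integer(n)
  for (i in order(d_int, decreasing = TRUE)) {
    ok <- which(slots > 0 & sizes - 1 >= d_int[i])
    if (length(ok) == 0) {
      ok <- which(slots > 0)
      if (length(ok) == 0) stop("community capacity exhausted")
      c <- ok[which.max(sizes[ok])]
      d_int[i] <- sizes[c] - 1L
    } else {
      c <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = slots[ok] / sum(slots[ok]))
    }
    memb[i] <- c
    slots[c] <- slots[c] - 1L
  }
  list(membership = memb, d_int = d_int)
}

# Configuration-model stub matching with repair: pairs stubs uniformly,
# then swaps endpoints to remove self-loops, duplicate edges and (when
# forbid_group is given) within-group pairs; irreparable pairs are dropped.
match_stubs <- function(owners, forbid_group = NULL, existing = NULL) {
  if (length(owners) < 2) return(matrix(integer(0), 0, 2))
  owners <- sample(owners)
  if (length(owners) %% 2 == 1) owners <- owners[-length(owners)]
  half <- length(owners) / 2
  a <- owners[seq_len(half)]
  b <- owners[half + seq_len(half)]
  nmax <- max(owners) + 1
  ekey <- function(u, v) pmin(u, v) * nmax + pmax(u, v)
  seen_prior <- if (!is.null(existing) && nrow(existing) > 0) {
    ekey(existing[, 1], existing[, 2])
  } else numeric(0)
  bad <- function(u, v, keys) {
    u == v |
      (if (!is.null(forbid_group)) forbid_group[u] == forbid_group[v] else FALSE) |
      keys %in% seen_prior | duplicated(keys)
  }
  for (it in seq_len(200)) {
    keys <- ekey(a, b)
    isbad <- bad(a, b, keys)
    if (!any(isbad)) break
    # swap each bad pair's second endpoint with a random partner pair
    idx <- which(isbad)
    partner <- sample.int(half, length(idx), replace = TRUE)
    tmp <- b[idx]
    b[idx] <- b[partner]
    b[partner] <- tmp
  }
  keys <- ekey(a, b)
  isbad <- bad(a, b, keys)
  if (any(isbad)) {
    warning("dropping ", sum(isbad), " irreparable stub pair(s)")
    a <- a[!isbad]; b <- b[!isbad]
  }
  cbind(a, b, deparse.level = 0)
}

#' Benchmark sweep over mixing values
#'
#' For each mixing value and replicate, generates a benchmark instance,
#' runs each requested algorithm and scores its partition against the
#' planted truth. The stochastic LPA baseline is run once per replicate
#' with a derived seed (averaging across replicates plays the role of
#' averaging across repeated runs). Generation failures flag the affected
#' rows but do not abort the sweep.
#'
#' @param type `"gn"` (sweeps the external fraction) or `"lfr"` (sweeps
#'   the mixing parameter mu).
#' @param mixing numeric vector of mixing values (non-empty).
#' @param algorithms character subset of `c("lpa-mni", "lpa")`.
#' @param replicates instances per mixing value.
#' @param seed base seed; all instance and run seeds derive from it.
#' @param lfr list of [generate_lfr()] parameters (used when
#'   `type = "lfr"`).
#' @return data.frame with one row per (mixing, replicate, algorithm):
#'   columns `type`, `mixing`, `replicate`, `algorithm`, `cn`, `nmi`,
#'   `ami`, `ok`, `note`.
#' @export
sweep_benchmark <- function(type = c("gn", "lfr"), mixing,
                            algorithms = c("lpa-mni", "lpa"),
                            replicates = 5, seed = 1,
                            lfr = list(n = 1000, k_mean = 15, k_max = 50,
                                       tau1 = 2, tau2 = 1,
                                       c_min = 10, c_max = 50)) {
  type <- match.arg(type)
  if (length(mixing) == 0) stop("empty mixing grid")
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  rows <- list()
  for (gi in seq_along(mixing)) {
    for (rep_i in seq_len(replicates)) {
      gseed <- derive_seed(seed, gi, rep_i)
      inst <- tryCatch({
        if (type == "gn") generate_gn(mixing[gi], seed = gseed)
        else do.call(generate_lfr,
                     c(lfr, list(mu = mixing[gi], seed = gseed)))
      }, error = function(e) e)
      for (alg in algorithms) {
        row <- data.frame(type = type, mixing = mixing[gi],
                          replicate = rep_i, algorithm = alg,
                          cn = NA_integer_, nmi = NA_real_, ami = NA_real_,
                          ok = FALSE, note = "")
        if (inherits(inst, "error")) {
          row$note <- conditionMessage(inst)
        } else {
          memb <- if (alg == "lpa-mni") {
            run_lpa_mni(inst$network)$membership
          } else {
            suppressWarnings(
              run_lpa(inst$network,
                      seed = derive_seed(seed, gi, rep_i, 7))$membership)
          }
          row$cn <- community_count(memb)
          row$nmi <- nmi(memb, inst$truth)
          row$ami <- ami(memb, inst$truth)
          row$ok <- TRUE
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
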