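# Bundled example networks with known community structure.

karate_truth_members1 <- c(1, 2, 3, 4, 5, 6, 7, 8, 11, 12, 13, 14, 17, 18, 20, 22)

#' Load a bundled example network
#'
#' Three small networks with known community structure ship with the package:
#' \describe{
#'   \item{`"karate"`}{the Zachary karate club (34 nodes, 78 edges) with the
#'     historical two-faction split as ground truth: faction 1 is nodes
#'     1,2,3,4,5,6,7,8,11,12,13,14,17,18,20,22, faction 2 the remaining 18.}
#'   \item{`"fig2_sample"`}{an 8-node graph of two 4-cliques (nodes 1-4 and
#'     5-8) joined by the single bridge edge 4-5; ground truth is the two
#'     cliques. A single bridge makes stochastic label propagation collapse
#'     to one community on some seeds, the failure mode deterministic
#'     propagation avoids.}
#'   \item{`"two_triangles"`}{two disjoint triangles; ground truth is the
#'     connected components.}
#' }
#'
#' @param name one of `"karate"`, `"fig2_sample"`, `"two_triangles"`.
#' @return list with `network` (an `mni_network`) and `truth` (named integer
#'   membership vector).
#' @examples
#' fx <- load_fixture("two_triangles")
#' fx$network$m
#' @export
load_fixture <- function(name = c("karate", "fig2_sample", "two_triangles")) {
  known <- c("karate", "fig2_sample", "two_triangles")
  if (!is.character(name) || length(name) != 1 || !(name %in% known)) {
    stop("unknown fixture ", sQuote(name[1]),
         "; available: ", paste(known, collapse = ", "))
  }
  switch(name,
    karate = {
      path <- system.file("extdata", "karate.edgelist", package = "lpamni",
                          mustWork = TRUE)
      net <- read_edge_list(path)
      truth <- ifelse(as.integer(net$ids) %in% karate_truth_members1, 1L, 2L)
      names(truth) <- net$ids
      list(network = net, truth = truth)
    },
    fig2_sample = {
      # two 4-cliques bridged by a single edge 4-5
      cl <- function(v) t(utils::combn(v, 2))
      e <- rbind(cl(1:4), cl(5:8), c(4, 5))
      net <- network_from_edges(e[, 1], e[, 2])
      truth <- rep(1:2, each = 4L)
      names(truth) <- net$ids
      list(network = net, truth = truth)
    },
    two_triangles = {
      e <- rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))
      net <- network_from_edges(e[, 1], e[, 2])
      truth <- rep(1:2, each = 3L)
      names(truth) <- net$ids
      list(network = net, truth = truth)
    })
}
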