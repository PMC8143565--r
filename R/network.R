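#' Construct a simple undirected network from an edge list
#'
#' Builds the package's network container from two parallel vectors of node
#' identifiers. Self-loops and duplicate edges are dropped (with a warning, or
#' an error when `strict = TRUE`): the community-detection model assumes a
#' simple, undirected, unweighted graph. Node identifiers are arbitrary
#' strings; they are mapped to dense 1-based internal indices in first-seen
#' order and all outputs report the original identifiers.
#'
#' @param from,to character (or coercible) vectors of equal length giving the
#'   endpoints of each edge.
#' @param ids optional character vector of node identifiers; lets isolated
#'   nodes (appearing in no edge) be part of the network. Defaults to the
#'   identifiers seen in `from`/`to`.
#' @param strict logical; if `TRUE`, self-loops or duplicate edges raise an
#'   error instead of being dropped.
#' @return an object of class `mni_network`: a list with elements `ids`
#'   (original identifiers), `adj` (adjacency list of internal indices),
#'   `deg` (integer degrees), `n` (node count) and `m` (edge count).
#' @examples
#' net <- network_from_edges(c("a", "b"), c("b", "c"))
#' net$n; net$m
#' @export
network_from_edges <- function(from, to, ids = NULL, strict = FALSE) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("'from' and 'to' must have equal length")
  if (is.null(ids)) {
    ids <- unique(as.vector(rbind(from, to)))
  } else {
    ids <- as.character(ids)
    missing <- setdiff(unique(c(from, to)), ids)
    if (length(missing) > 0) {
      stop("edge endpoints not in 'ids': ", paste(missing, collapse = ", "))
    }
  }
  n <- length(ids)
  if (n < 1) stop("a network needs at least one node")
  u <- match(from, ids)
  v <- match(to, ids)

  loops <- u == v
  if (any(loops)) {
    if (strict) stop(sum(loops), " self-loop(s) present and strict = TRUE")
    warning("dropping ", sum(loops), " self-loop(s)")
    u <- u[!loops]; v <- v[!loops]
  }
  lo <- pmin(u, v); hi <- pmax(u, v)
  key <- (lo - 1) * n + hi
  dup <- duplicated(key)
  if (any(dup)) {
    if (strict) stop(sum(dup), " duplicate edge(s) present and strict = TRUE")
    warning("dropping ", sum(dup), " duplicate edge(s)")
    lo <- lo[!dup]; hi <- hi[!dup]
  }

  adj <- vector("list", n)
  both_from <- c(lo, hi)
  both_to <- c(hi, lo)
  ord <- order(both_from, both_to)
  split_idx <- split(both_to[ord], factor(both_from[ord], levels = seq_len(n)))
  adj <- lapply(split_idx, as.integer)
  names(adj) <- NULL
  deg <- lengths(adj)

  structure(
    list(ids = ids, adj = adj, deg = as.integer(deg),
         n = n, m = length(lo),
         edges = cbind(lo, hi, deparse.level = 0)),
    class = "mni_network"
  )
}

#' @export
print.mni_network <- function(x, ...) {
  cat(sprintf("<mni_network> %d nodes, %d edges, max degree %d\n",
              x$n, x$m, if (x$n) max(x$deg) else 0L))
  invisible(x)
}

#' Read a whitespace-separated edge list
#'
#' One edge per line, two (or more; extras ignored) whitespace-separated
#' tokens. Lines starting with `#` and blank lines are skipped. Self-loops and
#' duplicate edges are dropped with a warning (see [network_from_edges()]).
#'
#' @param path path to the edge-list file.
#' @param strict passed on to [network_from_edges()].
#' @return an `mni_network`.
#' @export
read_edge_list <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no edges in file: ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad) > 0) {
    stop("malformed edge on line ", lineno[bad[1]], " of ", path,
         ": ", sQuote(lines[bad[1]]))
  }
  network_from_edges(vapply(toks, `[`, "", 1L),
                     vapply(toks, `[`, "", 2L),
                     strict = strict)
}

#' Write a network as a whitespace-separated edge list
#'
#' @param net an `mni_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "mni_network"))
  writeLines(paste(net$ids[net$edges[, 1]], net$ids[net$edges[, 2]]), path)
  invisible(path)
}

#' Read a network from a GML file
#'
#' Supports the usual `graph [ node [ id N ] ... edge [ source A target B ] ]`
#' subset via igraph's GML reader. A `directed` flag is ignored with a warning
#' (edges are treated as undirected); self-loops and duplicate edges are
#' dropped as in [read_edge_list()].
#'
#' @inheritParams read_edge_list
#' @return an `mni_network`.
#' @export
read_gml <- function(path, strict = FALSE) {
  g <- igraph::read_graph(path, format = "gml")
  if (igraph::is_directed(g)) {
    warning("GML file declares a directed graph; treating edges as undirected")
    g <- igraph::as_undirected(g, mode = "each")
  }
  from_igraph(g, strict = strict)
}

#' Convert an igraph object to an `mni_network`
#'
#' Vertex identifiers are taken from the `id` attribute if present (the GML
#' convention), else from vertex names, else from 1-based position.
#'
#' @param g an `igraph` graph.
#' @param strict passed on to [network_from_edges()].
#' @return an `mni_network`.
#' @export
from_igraph <- function(g, strict = FALSE) {
  va <- igraph::vertex_attr_names(g)
  ids <- if ("id" %in% va) {
    as.character(igraph::vertex_attr(g, "id"))
  } else if ("name" %in% va) {
    as.character(igraph::vertex_attr(g, "name"))
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  network_from_edges(ids[el[, 1]], ids[el[, 2]], ids = ids, strict = strict)
}

#' Convert an `mni_network` to an igraph object
#'
#' @param net an `mni_network`.
#' @return an undirected `igraph` graph with vertex attribute `name` set to
#'   the original node identifiers.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "mni_network"))
  g <- igraph::make_empty_graph(net$n, directed = FALSE)
  g <- igraph::add_edges(g, t(net$edges))
  igraph::set_vertex_attr(g, "name", value = net$ids)
}

#' Degree-centrality node importance ranking
#'
#' Node importance is the normalized degree centrality DC(i) = k_i / (n - 1):
#' the degree divided by the maximum degree a node could have. The ranking
#' orders nodes by descending importance; equal scores are broken by ascending
#' internal index (first-seen order of the node identifier), so the order is a
#' deterministic function of the network.
#'
#' @param net an `mni_network`.
#' @return an object of class `importance_ranking`: list with `scores`
#'   (numeric in \[0, 1\], named by node id) and `order` (integer permutation
#'   of internal indices, most important first).
#' @examples
#' net <- load_fixture("karate")$network
#' head(degree_centrality(net)$scores[degree_centrality(net)$order])
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "mni_network"))
  scores <- if (net$n >= 2) net$deg / (net$n - 1) else rep(0, net$n)
  names(scores) <- net$ids
  ord <- order(-scores, seq_len(net$n))
  structure(list(scores = scores, order = as.integer(ord)),
            class = "importance_ranking")
}

#' @export
print.importance_ranking <- function(x, ...) {
  cat(sprintf("<importance_ranking> %d nodes; top: %s (DC = %.4f)\n",
              length(x$scores), names(x$scores)[x$order[1]],
              x$scores[x$order[1]]))
  invisible(x)
}
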