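# Internal helpers shared across modules.

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so stochastic runs never disturb the
# session RNG stream.
with_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Coerce a partition to an integer membership vector aligned with net$ids.
# Accepts a named vector in any order (names matched to node ids) or an
# unnamed vector in node order. Labels may be any atomic type; they are
# mapped to consecutive integers.
align_partition <- function(net, part) {
  stopifnot(inherits(net, "mni_network"))
  if (is.null(part)) stop("partition is NULL")
  if (!is.null(names(part))) {
    idx <- match(net$ids, names(part))
    if (anyNA(idx)) {
      stop("partition is missing node(s): ",
           paste(utils::head(net$ids[is.na(idx)], 5), collapse = ", "))
    }
    part <- part[idx]
  } else if (length(part) != net$n) {
    stop("unnamed partition must have length n = ", net$n)
  }
  lab <- match(part, unique(part))
  names(lab) <- net$ids
  lab
}

# Dense integer relabeling of any label vector (names preserved).
relabel <- function(part) {
  out <- match(part, unique(part))
  names(out) <- names(part)
  out
}

# Are two partitions identical up to label renaming?
same_partition <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) return(FALSE)
    b <- b[names(a)]
  }
  if (length(a) != length(b)) return(FALSE)
  all(match(a, unique(a)) == match(b, unique(b)))
}

# Deterministic small seed derived from a base seed and stream indices,
# kept within the 32-bit integer range.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k)) %% 2147483647
  as.integer(s)
}
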