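# Seed plumbing: every stochastic stage draws from a named substream derived
# from one root seed, so whole-pipeline runs are replayable piecewise.

#' Derive a reproducible substream seed
#'
#' Maps a root seed and a stage name to a deterministic 31-bit integer, so
#' each pipeline stage gets its own independent, replayable random stream.
#'
#' @param seed integer root seed.
#' @param name character stage label (e.g. "permute", "founders").
#' @return an integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(substream_seed(seed, name))
  }
  force(expr)
}

# union-find over 1..n, used for family components
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1]); b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
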