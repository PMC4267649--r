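# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

# Cross-set squared-distance helper: rows of `a` (n x 3) vs rows of `b` (m x 3).
# Returns the n x m matrix of Euclidean distances.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# let data.table's [ dispatch work inside this package
.datatable.aware <- TRUE
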