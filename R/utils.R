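# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Keeps every sampler deterministic without
# clobbering the session RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Deterministic 32-bit sub-seed derived from a base seed and an index.
derive_seed <- function(seed, index, salt = 0L) {
  x <- (as.double(seed) * 48271 + as.double(index) * 16807 +
          as.double(salt) * 69621) %% 2147483629
  as.integer(x) + 1L
}

# Squared Euclidean distances between rows of a (n x 3) and rows of b (m x 3).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ptppi <- function(class, message, ...) {
  stop(structure(class = c(class, "ptppi_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
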