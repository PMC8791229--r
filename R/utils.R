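# Internal helpers: seeding, rounding, validation.

# Deterministic 32-bit substream seed from a master seed and up to two
# indices. Arithmetic stays below 2^53 so the modulo is exact in doubles.
substream_seed <- function(seed, i = 0L, j = 0L) {
  as.integer((as.numeric(seed) %% 2147483629 * 69069 +
                as.numeric(i) * 100003 + as.numeric(j) * 1009) %% 2147483629)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# round half away from zero (platform-independent edge counts)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == floor(x) && x >= 0

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_adjacency <- function(adj, arg = "adjacency") {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stopf("%s must be a square matrix", arg)
  if (any(is.na(adj)) || !all(adj %in% c(0, 1)))
    stopf("%s must be binary (0/1) with no missing values", arg)
  if (any(diag(adj) != 0))
    stopf("%s must have a zero diagonal", arg)
  if (!isTRUE(all.equal(adj, t(adj), tolerance = 0)))
    stopf("%s must be symmetric", arg)
  storage.mode(adj) <- "integer"
  adj
}
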