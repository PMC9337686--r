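# Internal helpers: seeded RNG streams and small numeric utilities.
#
# Every stochastic operation draws from its own stream derived from
# (seed, tag) so that, e.g., scene sampling and render noise are
# decoupled: changing the noise model never changes the sampled scene.

# deterministic 31-bit hash of a character tag
.tagHash <- function(tag) {
  codes <- utf8ToInt(tag)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

.deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) %% 2147483647 + .tagHash(tag)) %% 2147483647)
}

# evaluate expr under a derived seed, restoring the caller's RNG state
.withSeed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(.deriveSeed(seed, tag))
  expr
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

.isBinary <- function(x) all(x == 0 | x == 1)

# squared distance map (um^2) from each pixel center to a 0-based point
.distUmSq <- function(nrow, ncol, center, pixelSizeUm) {
  rows <- (seq_len(nrow) - 1) - center[1L]
  cols <- (seq_len(ncol) - 1) - center[2L]
  (outer(rows^2, cols^2, "+")) * pixelSizeUm^2
}
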