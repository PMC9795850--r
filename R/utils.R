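## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Deterministic child seed; keeps results within 32-bit integer range.
derivedSeed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 7919
  as.integer(s %% 2147483629 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Smooth random surface in [-1, 1]-ish: coarse Gaussian grid, bilinearly
## upsampled. Used to give canopy blobs irregular outlines.
smoothNoise <- function(nr, nc, coarse = 4L) {
  g <- matrix(rnorm(coarse * coarse), coarse, coarse)
  ri <- seq(1, coarse, length.out = nr)
  ci <- seq(1, coarse, length.out = nc)
  r0 <- pmin(floor(ri), coarse - 1L); rf <- ri - r0
  c0 <- pmin(floor(ci), coarse - 1L); cf <- ci - c0
  out <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    cj <- c0[j]; fj <- cf[j]
    col <- g[r0, cj] * (1 - rf) + g[r0 + 1L, cj] * rf
    col2 <- g[r0, cj + 1L] * (1 - rf) + g[r0 + 1L, cj + 1L] * rf
    out[, j] <- col * (1 - fj) + col2 * fj
  }
  out
}
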