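## Internal helpers: zeitgeber-time arithmetic, seeded substreams, window logic.

#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats approx aov cor cutree dist hclust median qt quantile rnorm
#'   rpois runif sd t.test TukeyHSD cor.test rbinom setNames
#' @importFrom utils read.delim write.table head tail
NULL

## Wrap hours onto [0, 24).
ztWrap <- function(zt) zt %% 24

## Circular Gaussian bump on the 24-h cycle (three-image wrap is exact to
## double precision for the sigma values used here).
ztBump <- function(zt, center, sigma) {
  d <- ztWrap(zt - center)
  d <- pmin(d, 24 - d)
  exp(-(d^2) / (2 * sigma^2))
}

## TRUE for zt inside the half-open window [start, end); windows may wrap
## midnight (start > end).
ztInWindow <- function(zt, window) {
  zt <- ztWrap(zt)
  if (window[2] >= window[1]) {
    zt >= window[1] & zt < window[2]
  } else {
    zt >= window[1] | zt < window[2]
  }
}

## Deterministic substream seeds: one master seed plus a non-negative counter.
## Multipliers are primes chosen so distinct (seed, counter) pairs in normal
## use do not collide; everything stays below 2^31 - 1.
deriveSeed <- function(master_seed, counter) {
  s <- (as.double(master_seed) %% 2147483647) * 48271 + as.double(counter) * 104729
  as.integer(s %% 2147483629) + 1L
}

## Evaluate expr under a derived substream without disturbing the caller's RNG.
withSubstream <- function(master_seed, counter, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(deriveSeed(master_seed, counter))
  expr
}

## Standard error of the mean; NA for n < 2 (degenerate n is reported as
## missing, never as 0).
semOf <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
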