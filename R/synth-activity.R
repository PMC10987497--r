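## Locomotion generator: a two-state (wake/sleep) Markov chain at 10-s
## epochs whose stationary wake probability follows the diurnal profile
## w(zt), with Poisson movement counts while awake and structural zeros
## while asleep. The chain uses entry/exit probabilities
##   P(wake -> sleep) = r * (1 - w(zt)),  P(sleep -> wake) = r * w(zt)
## so its stationary distribution at frozen zt is exactly w(zt); r sets the
## bout time scale.

epochsPerDay <- function(config) as.integer(round(24 * 3600 / config@epoch_s))

epochZT <- function(config) {
  n <- epochsPerDay(config)
  (seq_len(n) - 1) * config@epoch_s / 3600
}

## Large condition-specific stride keeps per-fly substreams disjoint across
## conditions and stable when flies are appended.
conditionOffset <- function(condition) sum(utf8ToInt(condition)) * 131071

## One fly-day of counts; RNG must already be seeded by the caller.
simFlyDayCounts <- function(config, condition) {
  zt <- epochZT(config)
  lam <- conditionRate(config, condition, zt)
  w <- conditionWakeProb(config, condition, zt)
  r <- config@switch_rate
  p_ws <- r * (1 - w)
  p_sw <- r * w
  n <- length(zt)
  u <- stats::runif(n)
  wake <- logical(n)
  wake[1] <- u[1] < w[1]
  for (t in 2:n)
    wake[t] <- if (wake[t - 1]) u[t] >= p_ws[t] else u[t] < p_sw[t]
  counts <- integer(n)
  if (any(wake)) counts[wake] <- stats::rpois(sum(wake), lam[wake])
  counts
}

#' Generate synthetic locomotion records
#'
#' One \linkS4class{ActivityRecord} per fly per day under the requested
#' temperature condition. Per-epoch movement counts are Poisson draws at the
#' diurnal rate while the fly's wake/sleep chain is in the wake state, and
#' structurally zero while asleep. Each (fly, day) uses its own seed
#' substream derived from the master seed by counter, so the same fly is
#' bit-identical regardless of cohort size.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param condition a temperature-condition label present in
#'   \code{config@temp_effects} (unknown labels fail naming the valid ones).
#' @return list of \linkS4class{ActivityRecord}, flies varying fastest over
#'   days.
#' @examples
#' recs <- genActivity(synthConfig(1, n_flies = 2), "24C")
#' @export
genActivity <- function(config, condition) {
  conditionEffect(config, condition)   # validates the label
  off <- conditionOffset(condition)
  out <- vector("list", config@n_flies * config@n_days)
  k <- 0
  for (i in seq_len(config@n_flies)) {
    for (d in seq_len(config@n_days)) {
      counts <- withSubstream(config@master_seed, off + (i - 1) * 1000 + d,
                              simFlyDayCounts(config, condition))
      k <- k + 1
      out[[k]] <- activityRecord(
        counts, fly_id = sprintf("fly%03d", i), condition = "synthetic",
        temp_condition = condition, day_index = d,
        lights_on = config@lights_on, lights_off = config@lights_off,
        epoch_s = config@epoch_s)
    }
  }
  out
}

## Fast vectorized-across-flies simulator used by the Monte-Carlo oracles:
## returns a bins x n matrix of binned counts (and optionally the epoch-level
## counts). RNG must already be seeded by the caller.
simCohortBinned <- function(config, condition, n, bin_min = 30,
                            keep_epochs = FALSE) {
  zt <- epochZT(config)
  lam <- conditionRate(config, condition, zt)
  w <- conditionWakeProb(config, condition, zt)
  r <- config@switch_rate
  p_ws <- r * (1 - w)
  p_sw <- r * w
  n_ep <- length(zt)
  bin_of <- floor(zt / (bin_min / 60)) + 1
  n_bins <- max(bin_of)
  binned <- matrix(0L, n_bins, n)
  epochs <- if (keep_epochs) matrix(0L, n_ep, n) else NULL
  wake <- stats::runif(n) < w[1]
  for (t in seq_len(n_ep)) {
    if (t > 1) {
      u <- stats::runif(n)
      wake <- ifelse(wake, u >= p_ws[t], u < p_sw[t])
    }
    if (any(wake)) {
      c_t <- integer(n)
      c_t[wake] <- stats::rpois(sum(wake), lam[t])
      binned[bin_of[t], ] <- binned[bin_of[t], ] + c_t
      if (keep_epochs) epochs[t, ] <- c_t
    }
  }
  if (keep_epochs) list(binned = binned, epochs = epochs) else list(binned = binned)
}

#' Expected binned activity in a ZT window
#'
#' The large-sample expectation of per-30-min-bin movement counts under a
#' condition: the independent oracle the behavioral-index recovery tests
#' compare against. By default it is computed deterministically, integrating
#' lambda(zt) * P(wake at zt) where the wake marginal comes from forward
#' iteration of the two-state chain; \code{method = "simulation"} instead
#' averages a simulated cohort.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param condition temperature-condition label.
#' @param window ZT interval, half-open \code{[start, end)} hours.
#' @param bin_min bin width (min), must divide 24 h.
#' @param method "analytic" (deterministic integration) or "simulation".
#' @param n_sim flies for the simulation method.
#' @return list with \code{bin_centers}, \code{expected} (counts per bin),
#'   \code{window_mean} (mean over the window's bins) and \code{method}.
#' @export
expectedWindowMean <- function(config, condition, window = c(0, 24),
                               bin_min = 30,
                               method = c("analytic", "simulation"),
                               n_sim = 1e5) {
  method <- match.arg(method)
  zt <- epochZT(config)
  bin_h <- bin_min / 60
  stopIfNot(abs(24 / bin_h - round(24 / bin_h)) < 1e-9,
            "bin width must divide 24 h")
  bin_of <- floor(zt / bin_h) + 1
  centers <- (seq_len(max(bin_of)) - 0.5) * bin_h
  if (method == "analytic") {
    lam <- conditionRate(config, condition, zt)
    w <- conditionWakeProb(config, condition, zt)
    r <- config@switch_rate
    p_ws <- r * (1 - w)
    p_sw <- r * w
    p <- numeric(length(zt))
    p[1] <- w[1]
    for (t in 2:length(zt))
      p[t] <- p[t - 1] * (1 - p_ws[t]) + (1 - p[t - 1]) * p_sw[t]
    expected <- as.numeric(tapply(lam * p, bin_of, sum))
  } else {
    sim <- withSubstream(config@master_seed,
                         conditionOffset(condition) + 900000L,
                         simCohortBinned(config, condition, n_sim, bin_min))
    expected <- rowMeans(sim$binned)
  }
  keep <- ztInWindow(centers, window)
  list(bin_centers = centers[keep], expected = expected[keep],
       window_mean = mean(expected[keep]), method = method)
}

#' Expected sleep minutes per bin in a ZT window (Monte-Carlo oracle)
#'
#' No closed form exists for scored sleep (bout structure and Poisson zeros
#' during quiet wakefulness both matter), so the expectation is estimated by
#' simulating a large cohort and scoring it; the method is reported in the
#' return value.
#'
#' @inheritParams expectedWindowMean
#' @param n_sim simulated flies.
#' @param min_bout_min minimum immobility-bout length scored as sleep (min).
#' @return list with \code{window_mean} (expected sleep minutes per
#'   \code{bin_min} bin in the window), \code{n} and \code{method}.
#' @export
expectedSleepWindowMean <- function(config, condition, window,
                                    bin_min = 30, n_sim = 2000,
                                    min_bout_min = 5) {
  chunk <- 500L
  done <- 0L
  total <- 0
  zt <- epochZT(config)
  bin_h <- bin_min / 60
  bin_of <- floor(zt / bin_h) + 1
  centers <- (seq_len(max(bin_of)) - 0.5) * bin_h
  keep_bins <- which(ztInWindow(centers, window))
  min_bout_epochs <- as.integer(round(min_bout_min * 60 / config@epoch_s))
  ci <- 0L
  while (done < n_sim) {
    m <- min(chunk, n_sim - done)
    ci <- ci + 1L
    sim <- withSubstream(config@master_seed,
                         conditionOffset(condition) + 950000L + ci,
                         simCohortBinned(config, condition, m, bin_min,
                                         keep_epochs = TRUE))
    for (j in seq_len(m)) {
      asleep <- sleepFromCounts(sim$epochs[, j], min_bout_epochs, 0L)
      mins <- tapply(asleep, bin_of, sum) * config@epoch_s / 60
      total <- total + mean(mins[keep_bins])
    }
    done <- done + m
  }
  list(window_mean = total / n_sim, n = n_sim, method = "simulation")
}
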