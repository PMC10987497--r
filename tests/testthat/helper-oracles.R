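# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's implementation routes (rle, tapply/rowsum aggregation)
# so agreement is informative.

# Explicit state-machine scan for sleep bouts: walks the epoch vector once,
# tracking the current inactivity run.
bruteForceSleepScan <- function(counts, min_bout_epochs = 30L,
                                inactive_threshold = 0L) {
  n <- length(counts)
  sleep <- logical(n)
  starts <- integer(0)
  lens <- integer(0)
  run_start <- 0L
  for (i in seq_len(n)) {
    if (counts[i] <= inactive_threshold) {
      if (run_start == 0L) run_start <- i
    } else {
      if (run_start > 0L) {
        len <- i - run_start
        if (len >= min_bout_epochs) {
          starts <- c(starts, run_start)
          lens <- c(lens, len)
          sleep[run_start:(i - 1L)] <- TRUE
        }
        run_start <- 0L
      }
    }
  }
  if (run_start > 0L) {
    len <- n - run_start + 1L
    if (len >= min_bout_epochs) {
      starts <- c(starts, run_start)
      lens <- c(lens, len)
      sleep[run_start:n] <- TRUE
    }
  }
  list(sleep = sleep,
       bouts = data.frame(start_epoch = starts, length_epochs = lens))
}
bruteForceSleepScan <- compiler::cmpfun(bruteForceSleepScan)

# Nested-loop partner aggregation over raw connection rows.
bruteForceRank <- function(con, source_type, direction, min_weight = 1) {
  totals <- list()
  bodies <- list()
  for (i in seq_len(nrow(con))) {
    row <- con[i, ]
    if (direction == "downstream" && row$type_pre == source_type) {
      p <- row$type_post; b <- row$bodyId_post
    } else if (direction == "upstream" && row$type_post == source_type) {
      p <- row$type_pre; b <- row$bodyId_pre
    } else next
    totals[[p]] <- (if (is.null(totals[[p]])) 0 else totals[[p]]) + row$weight
    bodies[[p]] <- union(if (is.null(bodies[[p]])) c() else bodies[[p]], b)
  }
  if (!length(totals))
    return(data.frame(partner_type = character(0), total_weight = numeric(0),
                      n_partner_bodies = integer(0)))
  df <- data.frame(partner_type = names(totals),
                   total_weight = unlist(totals),
                   n_partner_bodies = vapply(bodies[names(totals)],
                                             length, 0L),
                   stringsAsFactors = FALSE)
  df <- df[df$total_weight >= min_weight, , drop = FALSE]
  df <- df[order(-df$total_weight, df$partner_type), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Naive double-loop binning of one activity record.
bruteForceBin <- function(counts, epoch_s = 10, bin_min = 30) {
  per_bin <- bin_min * 60 / epoch_s
  n_bins <- length(counts) / per_bin
  out <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    s <- 0
    for (e in seq_len(per_bin)) s <- s + counts[(b - 1) * per_bin + e]
    out[b] <- s
  }
  out
}
bruteForceBin <- compiler::cmpfun(bruteForceBin)

# Minimal configs reused across tests.
quietConfig <- function(seed = 1, ...) {
  synthConfig(master_seed = seed,
              activity = list(lambda_b = 0, a_m = 0, a_e = 0),
              wake_prob = function(zt) rep(1, length(zt)), ...)
}

flatAwakeConfig <- function(seed = 1, lambda = 1, ...) {
  synthConfig(master_seed = seed,
              activity = list(lambda_b = lambda, a_m = 0, a_e = 0),
              wake_prob = function(zt) rep(1, length(zt)), ...)
}

coolingProtocol <- function(baseline = 24, target = 18, onset = 60,
                            ramp = 80, span = 300) {
  temperatureProtocol(baseline, data.frame(onset_s = onset,
                                           target_c = target,
                                           ramp_s = ramp), span)
}

# Build an ActivityRecord whose 30-min-bin sums are exactly `per_bin_counts`
# by placing that many 1-count epochs at the start of each bin.
recordWithBins <- function(per_bin_counts, ...) {
  counts <- integer(8640)
  for (b in seq_along(per_bin_counts)) {
    k <- per_bin_counts[b]
    if (k > 0) counts[(b - 1) * 180 + seq_len(k)] <- 1L
  }
  activityRecord(counts, ...)
}
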