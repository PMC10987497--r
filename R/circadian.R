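## Reconstruction of the 24-h diurnal calcium curve from four 6-h-shifted
## recording groups, ratiometric normalization, double-plot export, and
## estimation of the circadian gating of temperature responses.

#' Ratiometric normalization (GCaMP / tdTomato)
#'
#' Pointwise division of the calcium-sensitive by the calcium-insensitive
#' channel. Any drift multiplying both channels equally (bleaching, focus,
#' laser power) cancels exactly.
#'
#' @param gcamp,tdtom numeric series of equal length; tdTomato must be
#'   positive everywhere (a non-positive sample fails naming its position).
#' @return the ratio series.
#' @export
ratiometricNormalize <- function(gcamp, tdtom) {
  stopIfNot(length(gcamp) == length(tdtom),
            "channels must have equal length")
  bad <- which(tdtom <= 0)
  if (length(bad))
    stop(sprintf("non-positive tdTomato sample at position %d", bad[1]),
         call. = FALSE)
  gcamp / tdtom
}

#' Stitch phase-shifted groups into a 24-h circadian curve
#'
#' Each sample's zeitgeber time is (local_time + shift) mod 24; samples
#' fall into half-open 30-min bins [left, left + 0.5) labeled by their
#' centers, with the ZT 23.5-24 bin closing the circle. Flies are the
#' statistical unit: within-fly means per bin are taken first, then mean,
#' SEM and n across flies, pooling flies of different groups where their
#' windows meet (never averaging group averages). Empty bins stay NA, not
#' interpolated.
#'
#' @param groups list of \linkS4class{DiurnalGroup} with distinct shifts;
#'   each fly needs >= 2 samples.
#' @param bin_h bin width in hours (default 0.5).
#' @return a \linkS4class{CircadianCurve}.
#' @export
stitchGroups <- function(groups, bin_h = 0.5) {
  shifts <- vapply(groups, function(g) g@shift_h, 0)
  stopIfNot(!anyDuplicated(shifts), "group shifts must be distinct")
  rows <- do.call(rbind, lapply(groups, function(g) {
    d <- g@data
    counts <- table(d$fly_id)
    stopIfNot(all(counts >= 2), "each fly needs >= 2 samples")
    data.frame(fly_id = d$fly_id,
               zt = ztWrap(d$local_time_h + g@shift_h),
               ratio = ratiometricNormalize(d$gcamp, d$tdtom))
  }))
  centers <- seq(bin_h / 2, 24 - bin_h / 2, by = bin_h)
  rows$bin <- floor(rows$zt / bin_h) + 1
  # within-fly mean per bin first, so SEM is over flies
  key <- paste(rows$fly_id, rows$bin, sep = "\r")
  fly_bin <- tapply(rows$ratio, key, mean)
  bin_idx <- as.integer(sub(".*\r", "", names(fly_bin)))
  mean_v <- rep(NA_real_, length(centers))
  sem_v <- rep(NA_real_, length(centers))
  n_v <- integer(length(centers))
  for (b in unique(bin_idx)) {
    v <- fly_bin[bin_idx == b]
    mean_v[b] <- mean(v)
    sem_v[b] <- semOf(v)
    n_v[b] <- length(v)
  }
  new("CircadianCurve", bin_centers = centers, mean = mean_v, sem = sem_v,
      n = n_v)
}

#' Double-plot a circadian curve
#'
#' Returns the curve concatenated with a second copy offset by +24 h (the
#' standard way to visualize patterns crossing the day boundary). Pure
#' duplication: nothing is recomputed.
#'
#' @param curve a \linkS4class{CircadianCurve}.
#' @return data.frame(time_h, mean, sem, n) of length 2x the curve.
#' @seealso \code{\link{undouble}}
#' @export
doublePlot <- function(curve) {
  data.frame(time_h = c(curve@bin_centers, curve@bin_centers + 24),
             mean = rep(curve@mean, 2), sem = rep(curve@sem, 2),
             n = rep(curve@n, 2))
}

#' Invert a double plot back to the 24-h curve
#'
#' @param doubled data.frame from \code{\link{doublePlot}}.
#' @return the original \linkS4class{CircadianCurve}.
#' @export
undouble <- function(doubled) {
  h <- nrow(doubled) / 2
  stopIfNot(h == floor(h), "doubled table must have even length")
  first <- doubled[seq_len(h), ]
  second <- doubled[h + seq_len(h), ]
  stopIfNot(all(abs(second$time_h - 24 - first$time_h) < 1e-9) &&
              identical(unname(first$mean), unname(second$mean)),
            "not a double-plotted curve")
  new("CircadianCurve", bin_centers = first$time_h, mean = first$mean,
      sem = first$sem, n = as.integer(first$n))
}

#' Estimate the circadian gating profile of temperature responses
#'
#' Groups step responses into ZT windows and estimates the per-window gain
#' as the mean absolute response (|post - pre| on the ratiometric scale,
#' which is independent of the diurnal baseline), with a seeded percentile
#' bootstrap CI, and reports each window's ratio to a reference window.
#'
#' @param responses list of \linkS4class{TemperatureResponse} or a
#'   data.frame from \code{\link{responseTable}}.
#' @param windows named list of ZT windows (numeric(2), half-open). Default
#'   follows the recording scheme: ZT0-2, ZT6-8, ZT10-14, ZT17-19.
#' @param reference name of the reference window (default "ZT6-8", the
#'   weak-response daytime window).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @return a \linkS4class{GatingProfile}.
#' @export
estimateGating <- function(responses,
                           windows = list("ZT0-2" = c(0, 2),
                                          "ZT6-8" = c(6, 8),
                                          "ZT10-14" = c(10, 14),
                                          "ZT17-19" = c(17, 19)),
                           reference = "ZT6-8", n_boot = 1000, seed = 1) {
  df <- if (is.data.frame(responses)) responses else responseTable(responses)
  df$resp <- abs(df$post_mean - df$pre_mean)
  per_window <- lapply(windows, function(w) df$resp[ztInWindow(df$zt, w)])
  n <- vapply(per_window, length, 0L)
  stopIfNot(reference %in% names(windows) && n[[reference]] > 0,
            "reference window is empty")
  stopIfNot(sum(n >= 2) >= 2, "need >= 2 windows with >= 2 responses each")
  gain <- vapply(per_window, function(v) if (length(v)) mean(v) else NA_real_, 0)
  ci <- withSubstream(seed, 0L, vapply(per_window, function(v) {
    if (length(v) < 2) return(c(NA_real_, NA_real_))
    bm <- vapply(seq_len(n_boot), function(i)
      mean(sample(v, length(v), replace = TRUE)), 0)
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }, numeric(2)))
  new("GatingProfile", windows = windows, gain = gain,
      ci_lo = ci[1, ], ci_hi = ci[2, ], ratio = gain / gain[[reference]],
      reference = reference, n = n)
}
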