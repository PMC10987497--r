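## Fluorescence-trace quantification: dF/F0, step-response fold change and
## responder classification, saturation summaries, correlation/clustering,
## and the simultaneous-locomotion comparison.

#' Baseline-normalized fluorescence change (dF/F0)
#'
#' dF/F0 = (F_t - F0)/F0 x 100 (percent). By default F0 is the mean of the
#' samples in the pre-stimulus baseline window, which is robust to shot
#' noise; \code{f0_method = "literal"} reproduces the strict
#' fluorescence-at-time-zero definition (the first sample inside the
#' window). The result is exactly invariant to multiplying the whole trace
#' by a positive constant; additive offsets are deliberately NOT invariant
#' (F0 absorbs them into the denominator).
#'
#' @param trace a \linkS4class{FluorescenceTrace}.
#' @param baseline_window numeric(2), seconds, half-open \code{[start, end)};
#'   must contain at least one sample.
#' @param f0_method "mean" (default) or "literal".
#' @return a \linkS4class{DeltaFTrace}.
#' @examples
#' tr <- fluorescenceTrace(0:10, c(rep(100, 5), rep(150, 6)))
#' computeDff(tr, c(0, 5))
#' @export
computeDff <- function(trace, baseline_window = c(0, 30),
                       f0_method = c("mean", "literal")) {
  f0_method <- match.arg(f0_method)
  sel <- trace@times >= baseline_window[1] & trace@times < baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples", call. = FALSE)
  f0 <- if (f0_method == "mean") mean(trace@values[sel])
        else trace@values[which(sel)[1]]
  if (f0 <= 0)
    stop("non-physical baseline: F0 <= 0 in the baseline window", call. = FALSE)
  new("DeltaFTrace", roi_id = trace@roi_id, times = trace@times,
      dff = (trace@values - f0) / f0 * 100, f0 = f0,
      baseline_window = as.numeric(baseline_window))
}

#' Maximum (or signed-extremum) dF/F0 in a response window
#'
#' \code{signed = FALSE} returns the maximum dF/F0 in the window
#' (dFmax/F0); \code{signed = TRUE} returns the signed extremum -- the
#' sample of largest absolute dF/F0 with its sign preserved -- the variant
#' used when quantifying inhibition.
#'
#' @param dff a \linkS4class{DeltaFTrace}.
#' @param response_window numeric(2), seconds, half-open.
#' @param signed use the signed-extremum variant.
#' @return dF/F0 in percent.
#' @export
computeMaxDff <- function(dff, response_window, signed = FALSE) {
  sel <- dff@times >= response_window[1] & dff@times < response_window[2]
  if (!any(sel)) stop("response window contains no samples", call. = FALSE)
  v <- dff@dff[sel]
  if (signed) v[which.max(abs(v))] else max(v)
}

#' Quantify the response to one temperature step
#'
#' Window means of the fluorescence before the step onset and after the
#' ramp completes; the relative fold change is post/pre. When a tdTomato
#' partner trace is supplied the means are taken on the ratiometric
#' (GCaMP/tdTomato) values, making the fold change invariant to common
#' multiplicative drift. A ROI is classified activated when post - pre
#' exceeds \code{k_sd} pre-window SDs, inhibited when it falls below
#' \code{-k_sd} SDs, else nonresponsive.
#'
#' @param trace GCaMP \linkS4class{FluorescenceTrace}.
#' @param protocol \linkS4class{TemperatureProtocol}.
#' @param step_index which step (1-based).
#' @param pre_s length of the pre window ending at the step onset (s).
#' @param post_s length of the post window starting when the ramp
#'   completes (s).
#' @param post_delay_s extra delay between ramp completion and the post
#'   window (s); useful to let a slow sensor settle. Negative values that
#'   make the windows overlap are rejected.
#' @param tdtom optional tdTomato partner trace on the same time grid.
#' @param k_sd responder threshold in pre-window SDs (default 2).
#' @return a \linkS4class{TemperatureResponse}.
#' @export
quantifyStepResponse <- function(trace, protocol, step_index = 1,
                                 pre_s = 30, post_s = 30, post_delay_s = 0,
                                 tdtom = NULL, k_sd = 2) {
  s <- protocol@steps
  if (step_index < 1 || step_index > nrow(s))
    stop(sprintf("step_index %d not in protocol (%d steps)", step_index,
                 nrow(s)), call. = FALSE)
  onset <- s$onset_s[step_index]
  ramp_end <- onset + s$ramp_s[step_index]
  pre_win <- c(onset - pre_s, onset)
  post_win <- c(ramp_end + post_delay_s, ramp_end + post_delay_s + post_s)
  if (pre_win[2] > post_win[1])
    stop("pre and post windows overlap", call. = FALSE)
  vals <- trace@values
  if (!is.null(tdtom)) {
    stopIfNot(length(tdtom@values) == length(vals) &&
                all(abs(tdtom@times - trace@times) < 1e-9),
              "tdTomato partner must share the GCaMP time grid")
    stopIfNot(all(tdtom@values > 0), "tdTomato values must be positive")
    vals <- vals / tdtom@values
  }
  pre_sel <- trace@times >= pre_win[1] & trace@times < pre_win[2]
  post_sel <- trace@times >= post_win[1] & trace@times < post_win[2]
  stopIfNot(any(pre_sel) && any(post_sel),
            "pre/post windows must contain samples")
  pre_mean <- mean(vals[pre_sel])
  post_mean <- mean(vals[post_sel])
  baseline_sd <- stats::sd(vals[pre_sel])
  if (is.na(baseline_sd)) baseline_sd <- 0
  delta <- post_mean - pre_mean
  cls <- if (delta > k_sd * baseline_sd) "activated"
         else if (delta < -k_sd * baseline_sd) "inhibited"
         else "nonresponsive"
  # dF/F0 on the same (possibly ratiometric) values with the pre window as
  # baseline
  dff <- (vals - pre_mean) / pre_mean * 100
  post_dff <- dff[post_sel]
  delta_t_c <- s$target_c[step_index] - protocol@baseline_c
  new("TemperatureResponse", roi_id = trace@roi_id,
      neuron_class = trace@neuron_class, zt = trace@zt,
      delta_t_c = delta_t_c, pre_mean = pre_mean, post_mean = post_mean,
      fold_change = post_mean / pre_mean, max_dff = max(post_dff),
      extremum_dff = post_dff[which.max(abs(post_dff))],
      response_class = cls, baseline_sd = baseline_sd)
}

#' Collect TemperatureResponse objects into a data.frame
#'
#' @param responses list of \linkS4class{TemperatureResponse}.
#' @return data.frame, one row per response.
#' @export
responseTable <- function(responses) {
  do.call(rbind, lapply(responses, function(r) data.frame(
    roi_id = r@roi_id, neuron_class = r@neuron_class, zt = r@zt,
    delta_t_c = r@delta_t_c, pre_mean = r@pre_mean, post_mean = r@post_mean,
    fold_change = r@fold_change, max_dff = r@max_dff,
    extremum_dff = r@extremum_dff, response_class = r@response_class,
    baseline_sd = r@baseline_sd, stringsAsFactors = FALSE)))
}

#' Summarize step responses across temperature amplitudes
#'
#' Groups responses by step amplitude (cooling and heating handled
#' separately), reports mean response (post - pre) with SEM per |dT|, flags
#' amplitude pairs whose means differ by less than \code{tol_frac} of the
#' dynamic range (saturation), estimates the saturation amplitude as the
#' smallest |dT| from which all larger amplitudes stay within tolerance of
#' the plateau, and tests the monotone trend with a Spearman rank
#' correlation on the per-ROI responses.
#'
#' @param responses list of \linkS4class{TemperatureResponse} (or a
#'   data.frame from \code{\link{responseTable}}) spanning >= 2 distinct
#'   amplitudes.
#' @param tol_frac saturation tolerance as a fraction of the dynamic range
#'   (default 0.05).
#' @return list with one element per sign present (\code{cooling},
#'   \code{heating}): a \code{table} (|dT|, n, mean, sem, saturated flag),
#'   \code{sat_dt} the estimated saturation amplitude, and
#'   \code{trend} the Spearman test.
#' @export
saturationSummary <- function(responses, tol_frac = 0.05) {
  df <- if (is.data.frame(responses)) responses else responseTable(responses)
  if (length(unique(df$delta_t_c)) < 2)
    stop("need responses at >= 2 distinct step amplitudes", call. = FALSE)
  df$response <- df$post_mean - df$pre_mean
  out <- list()
  for (sgn in c(-1, 1)) {
    sub <- df[sign(df$delta_t_c) == sgn, , drop = FALSE]
    if (nrow(sub) == 0) next
    sub$abs_dt <- abs(sub$delta_t_c)
    amps <- sort(unique(sub$abs_dt))
    mean_r <- sapply(amps, function(a) mean(sub$response[sub$abs_dt == a]))
    sem_r <- sapply(amps, function(a) semOf(sub$response[sub$abs_dt == a]))
    n_r <- sapply(amps, function(a) sum(sub$abs_dt == a))
    rng <- max(abs(mean_r))
    tol <- tol_frac * rng
    sat_flag <- c(FALSE, abs(diff(mean_r)) < tol)
    plateau <- mean_r[length(mean_r)]
    within <- abs(mean_r - plateau) <= tol
    sat_dt <- NA_real_
    for (i in seq_along(amps)) {
      if (all(within[i:length(amps)])) { sat_dt <- amps[i]; break }
    }
    trend <- if (length(amps) >= 3 && nrow(sub) >= 4)
      suppressWarnings(stats::cor.test(sub$abs_dt, abs(sub$response),
                                       method = "spearman")) else NULL
    out[[if (sgn < 0) "cooling" else "heating"]] <- list(
      table = data.frame(abs_dt = amps, n = n_r, mean = mean_r, sem = sem_r,
                         saturated = sat_flag),
      sat_dt = sat_dt, trend = trend)
  }
  out
}

#' Correlate and hierarchically cluster dF/F0 traces
#'
#' Resamples every trace onto a common grid (linear interpolation at the
#' coarsest native rate over the shared time range, no extrapolation),
#' computes pairwise Pearson correlations, and clusters on distance 1 - r
#' with average linkage. Zero-variance traces get NA correlations and are
#' excluded from clustering with a warning. Identical input yields an
#' identical leaf order.
#'
#' @param dff_set named list of \linkS4class{DeltaFTrace}.
#' @param k number of cluster labels to cut (default 2).
#' @return list: \code{correlation} matrix, \code{leaf_order},
#'   \code{labels} (cluster assignment), \code{grid} (common times),
#'   \code{excluded} (zero-variance trace names), and \code{zmatrix}
#'   (per-trace z-scored resampled values, heatmap-ready).
#' @export
correlateAndCluster <- function(dff_set, k = 2) {
  stopIfNot(length(dff_set) >= 2, "need at least 2 traces")
  nm <- names(dff_set)
  if (is.null(nm)) nm <- vapply(dff_set, function(d) d@roi_id, "")
  t0 <- max(vapply(dff_set, function(d) min(d@times), 0))
  t1 <- min(vapply(dff_set, function(d) max(d@times), 0))
  stopIfNot(t1 > t0, "traces share no time range")
  dt <- max(vapply(dff_set, function(d) stats::median(diff(d@times)), 0))
  grid <- seq(t0, t1, by = dt)
  m <- vapply(dff_set, function(d)
    stats::approx(d@times, d@dff, xout = grid)$y, numeric(length(grid)))
  colnames(m) <- nm
  vars <- apply(m, 2, stats::sd)
  excluded <- nm[vars == 0]
  if (length(excluded))
    warning("zero-variance traces excluded from clustering: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  r <- suppressWarnings(stats::cor(m))
  keep <- vars > 0
  labels <- setNames(rep(NA_integer_, length(nm)), nm)
  leaf_order <- character(0)
  if (sum(keep) >= 2) {
    hc <- stats::hclust(stats::as.dist(1 - r[keep, keep, drop = FALSE]),
                        method = "average")
    leaf_order <- colnames(m)[keep][hc$order]
    labels[keep] <- stats::cutree(hc, k = min(k, sum(keep)))
  }
  zm <- scale(m)
  list(correlation = r, leaf_order = leaf_order, labels = labels,
       grid = grid, excluded = excluded, zmatrix = zm)
}

#' Locomotion change around a temperature event
#'
#' Per-fly mean ball-rotation speed in windows before and after the event,
#' with a two-sided paired t test across flies (means only when n < 2).
#'
#' @param speeds data.frame(fly_id, time_s, speed); speed as produced by
#'   ball tracking (tracking itself is out of scope).
#' @param event_s event time (s).
#' @param pre_s,post_s window lengths (s); pre ends at the event, post
#'   starts at it.
#' @return list: \code{per_fly} data.frame(fly_id, pre_mean, post_mean,
#'   diff), \code{mean_diff}, \code{p_value} (NA when n < 2).
#' @export
locomotionChange <- function(speeds, event_s, pre_s = 60, post_s = 60) {
  stopIfNot(all(c("fly_id", "time_s", "speed") %in% names(speeds)),
            "speeds needs columns fly_id, time_s, speed")
  flies <- unique(speeds$fly_id)
  per <- do.call(rbind, lapply(flies, function(f) {
    s <- speeds[speeds$fly_id == f, ]
    pre <- s$speed[s$time_s >= event_s - pre_s & s$time_s < event_s]
    post <- s$speed[s$time_s >= event_s & s$time_s < event_s + post_s]
    stopIfNot(length(pre) > 0 && length(post) > 0,
              sprintf("fly %s: windows outside series", f))
    data.frame(fly_id = f, pre_mean = mean(pre), post_mean = mean(post),
               diff = mean(post) - mean(pre), stringsAsFactors = FALSE)
  }))
  p <- NA_real_
  if (nrow(per) >= 2) {
    if (stats::sd(per$diff) == 0) {
      p <- if (all(per$diff == 0)) 1 else 0
    } else {
      p <- stats::t.test(per$post_mean, per$pre_mean, paired = TRUE)$p.value
    }
  }
  list(per_fly = per, mean_diff = mean(per$diff), p_value = p)
}
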