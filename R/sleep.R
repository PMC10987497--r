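## Sleep scoring and activity binning. Sleep follows the field-standard
## rule: any run of behavioral immobility (zero movement counts by default)
## lasting at least 5 min is a sleep bout; every epoch inside a bout is
## asleep. Activity is summed per fly into 30-min bins.

## Run-length scoring on a raw count vector; returns the per-epoch sleep
## state. Shared by scoreSleep and the simulation oracle.
sleepFromCounts <- function(counts, min_bout_epochs, inactive_threshold = 0L) {
  inactive <- counts <= inactive_threshold
  r <- rle(inactive)
  asleep <- r$values & r$lengths >= min_bout_epochs
  inverse.rle(list(lengths = r$lengths, values = asleep))
}

#' Score sleep from an activity record
#'
#' Runs of inactivity (count <= \code{inactive_threshold}, default 0)
#' lasting at least \code{min_bout_min} minutes (default 5, i.e. 30
#' consecutive 10-s epochs) are sleep bouts.
#'
#' @param record an \linkS4class{ActivityRecord}.
#' @param min_bout_min minimum immobility duration scored as sleep (min).
#' @param inactive_threshold counts at or below this are "inactive".
#' @return a \linkS4class{SleepSeries}.
#' @examples
#' rec <- activityRecord(rep(0L, 8640))
#' sum(sleepState(scoreSleep(rec))) / 6   # 1440 sleep minutes
#' @export
scoreSleep <- function(record, min_bout_min = 5, inactive_threshold = 0L) {
  min_bout_epochs <- as.integer(round(min_bout_min * 60 / record@epoch_s))
  asleep <- sleepFromCounts(record@counts, min_bout_epochs,
                            inactive_threshold)
  r <- rle(asleep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  bouts <- data.frame(start_epoch = starts[keep],
                      length_epochs = r$lengths[keep])
  if (!nrow(bouts)) bouts <- data.frame(start_epoch = integer(0),
                                        length_epochs = integer(0))
  new("SleepSeries", sleep = asleep, bouts = bouts,
      epoch_s = record@epoch_s, min_bout_epochs = min_bout_epochs)
}

#' Sleep minutes per bin
#'
#' @param series a \linkS4class{SleepSeries}.
#' @param bin_min bin width in minutes (must divide 24 h).
#' @return numeric vector of sleep minutes per bin (named by ZT bin center).
#' @export
sleepMinutesPerBin <- function(series, bin_min = 30) {
  n <- length(series@sleep)
  per_bin <- as.integer(round(bin_min * 60 / series@epoch_s))
  stopIfNot(n %% per_bin == 0, "bin width must divide the day")
  bins <- rep(seq_len(n / per_bin), each = per_bin)
  mins <- as.numeric(tapply(series@sleep, bins, sum)) * series@epoch_s / 60
  names(mins) <- (seq_along(mins) - 0.5) * bin_min / 60
  mins
}

## Per-fly binned activity matrix (bins x fly-days); used by the profile and
## the indices.
activityBinMatrix <- function(records, bin_min = 30) {
  stopIfNot(length(records) >= 1, "need at least one record")
  epoch_s <- records[[1]]@epoch_s
  per_bin <- bin_min * 60 / epoch_s
  stopIfNot(abs(per_bin - round(per_bin)) < 1e-9 &&
              (24 * 60) %% bin_min == 0,
            "bin width must divide 24 h into whole epochs")
  per_bin <- as.integer(round(per_bin))
  n_bins <- as.integer(24 * 60 / bin_min)
  m <- vapply(records, function(r) {
    as.numeric(rowsum(as.numeric(r@counts),
                      rep(seq_len(n_bins), each = per_bin)))
  }, numeric(n_bins))
  colnames(m) <- vapply(records, function(r) r@fly_id, "")
  rownames(m) <- (seq_len(n_bins) - 0.5) * bin_min / 60
  m
}

#' Bin activity and summarize across flies
#'
#' Counts are summed within each fly's bins; mean and SEM are across flies
#' (SEM is NA for a single fly).
#'
#' @param records list of \linkS4class{ActivityRecord}.
#' @param bin_min bin width in minutes; must divide 24 h.
#' @return an \linkS4class{ActivityProfile}.
#' @export
binActivity <- function(records, bin_min = 30) {
  m <- activityBinMatrix(records, bin_min)
  new("ActivityProfile",
      bin_centers = as.numeric(rownames(m)),
      mean = rowMeans(m),
      sem = apply(m, 1, semOf),
      n = ncol(m))
}

#' Locate the evening activity peak
#'
#' Within the search window, the peak is the bin of maximal mean activity
#' (ties broken toward the earlier bin); onset and offset are the first and
#' last bins whose activity rises at least 50 percent of (peak - window
#' baseline) above the baseline, where the baseline is the window minimum.
#' A flat profile returns all three as NA.
#'
#' @param profile an \linkS4class{ActivityProfile}.
#' @param search_window ZT window to search, half-open (default ZT6-14).
#' @param rise_frac fraction of the peak-over-baseline rise defining
#'   onset/offset (default 0.5).
#' @return list(onset_zt, peak_zt, offset_zt).
#' @export
epeakTiming <- function(profile, search_window = c(6, 14), rise_frac = 0.5) {
  sel <- ztInWindow(profile@bin_centers, search_window)
  v <- profile@mean[sel]
  ctr <- profile@bin_centers[sel]
  base <- min(v)
  pk <- max(v)
  if (pk - base <= 0)
    return(list(onset_zt = NA_real_, peak_zt = NA_real_,
                offset_zt = NA_real_))
  peak_i <- which.max(v)            # earliest bin on ties
  thr <- base + rise_frac * (pk - base)
  above <- which(v >= thr)
  list(onset_zt = ctr[min(above)], peak_zt = ctr[peak_i],
       offset_zt = ctr[max(above)])
}
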