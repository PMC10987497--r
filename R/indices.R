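## The four temperature-response behavioral indices. Each index is computed
## per fly as (window mean under condition A - window mean under condition
## B) / window mean under condition B, where the window mean is the mean of
## the fly's 30-min-binned activity (or sleep minutes) over a half-open ZT
## window, days within a condition averaged first; the group summary is the
## mean +/- SEM of the per-fly values. Flies with a zero denominator are
## excluded with a warning. Sign conventions follow the published formulas
## exactly, including the cold evening-sleep variant whose positive
## direction is sleep GAIN (noted in the result metadata).

windowMeanPerFly <- function(records, window, measure = c("activity", "sleep"),
                             bin_min = 30, min_bout_min = 5,
                             inactive_threshold = 0L) {
  measure <- match.arg(measure)
  per_rec <- vapply(records, function(r) {
    if (measure == "activity") {
      m <- activityBinMatrix(list(r), bin_min)
      mean(m[ztInWindow(as.numeric(rownames(m)), window), 1])
    } else {
      mins <- sleepMinutesPerBin(scoreSleep(r, min_bout_min,
                                            inactive_threshold), bin_min)
      mean(mins[ztInWindow(as.numeric(names(mins)), window)])
    }
  }, 0)
  ids <- vapply(records, function(r) r@fly_id, "")
  vals <- tapply(per_rec, ids, mean)
  setNames(as.numeric(vals), names(vals))
}

## Per-fly (A - B) / D where D is the window mean under cond_a ("a") or
## cond_b ("b"); all four published indices are instances of this.
conditionIndex <- function(records, cond_a, cond_b, window, measure,
                           index_name, den = c("b", "a"), note = "", ...) {
  den <- match.arg(den)
  temp <- vapply(records, function(r) r@temp_condition, "")
  recs_a <- records[temp == cond_a]
  recs_b <- records[temp == cond_b]
  stopIfNot(length(recs_a) > 0 && length(recs_b) > 0,
            sprintf("%s: need records at both %s and %s", index_name,
                    cond_a, cond_b))
  a <- windowMeanPerFly(recs_a, window, measure, ...)
  b <- windowMeanPerFly(recs_b, window, measure, ...)
  flies <- intersect(names(a), names(b))
  stopIfNot(length(flies) > 0, "no flies present under both conditions")
  a <- a[flies]; b <- b[flies]
  d <- if (den == "b") b else a
  ok <- d > 0
  if (any(!ok))
    warning(sprintf("%s: excluding %d fly/flies with zero denominator-window mean",
                    index_name, sum(!ok)), call. = FALSE)
  stopIfNot(any(ok), sprintf("%s: all flies excluded (zero denominators)",
                             index_name))
  vals <- (a[ok] - b[ok]) / d[ok]
  new("IndexResult", index_name = index_name,
      per_fly = data.frame(fly_id = names(vals), value = as.numeric(vals),
                           stringsAsFactors = FALSE),
      mean = mean(vals), sem = semOf(vals), window = as.numeric(window),
      conditions = c(cond_a, cond_b),
      excluded = names(d)[!ok], note = note)
}

#' Evening-peak advance index (cooling)
#'
#' Per fly: (mean ZT6-12 movement at 18C - mean ZT6-12 movement at 24C) /
#' mean ZT6-12 movement at 24C. Larger values mean the evening activity
#' bout starts earlier in the cold.
#'
#' @param records list of \linkS4class{ActivityRecord} containing both
#'   temperature conditions (matched by fly_id).
#' @param cold,control temperature-condition labels.
#' @param ... passed to the window-mean machinery (\code{bin_min}, sleep
#'   scoring parameters).
#' @return an \linkS4class{IndexResult}.
#' @export
epeakAdvanceIndex <- function(records, cold = "18C", control = "24C", ...) {
  conditionIndex(records, cold, control, c(6, 12), "activity",
                 "epeak_advance", ...)
}

#' Evening-peak offset delay index (heating)
#'
#' Per fly: (mean ZT12-18 movement at 30C - mean ZT12-18 movement at 22C) /
#' mean ZT12-18 movement at 22C. Larger values mean evening locomotion
#' finishes later in the heat.
#'
#' @inheritParams epeakAdvanceIndex
#' @param hot,control temperature-condition labels.
#' @return an \linkS4class{IndexResult}.
#' @export
epeakOffsetDelayIndex <- function(records, hot = "30C", control = "22C", ...) {
  conditionIndex(records, hot, control, c(12, 18), "activity",
                 "epeak_offset_delay", ...)
}

#' Night-time sleep reduction index (heating)
#'
#' Per fly: (mean ZT12-24 sleep at 22C - mean ZT12-24 sleep at 30C) / mean
#' ZT12-24 sleep at 22C, sleep in minutes per 30-min bin from
#' \code{\link{scoreSleep}}. Larger values mean more heat-induced night
#' wakefulness.
#'
#' @inheritParams epeakOffsetDelayIndex
#' @return an \linkS4class{IndexResult}.
#' @export
nightSleepReductionIndex <- function(records, hot = "30C", control = "22C",
                                     ...) {
  # (sleep at 22C - sleep at 30C) / sleep at 22C
  conditionIndex(records, control, hot, c(12, 24), "sleep",
                 "night_sleep_reduction", den = "a",
                 note = "positive = sleep lost in the heat", ...)
}

#' Evening sleep reduction index (cold or hot variant)
#'
#' Cold variant: (mean ZT6-12 sleep at 18C - at 24C) / at 24C -- as
#' published, the positive direction of this variant is sleep GAIN in the
#' cold. Hot variant: (mean ZT12-18 sleep at 30C - at 22C) / at 22C.
#'
#' @inheritParams epeakAdvanceIndex
#' @param variant "cold" or "hot".
#' @param cold,hot,control_cold,control_hot temperature-condition labels.
#' @return an \linkS4class{IndexResult}.
#' @export
epeakSleepReductionIndex <- function(records, variant = c("cold", "hot"),
                                     cold = "18C", control_cold = "24C",
                                     hot = "30C", control_hot = "22C", ...) {
  variant <- match.arg(variant)
  if (variant == "cold")
    conditionIndex(records, cold, control_cold, c(6, 12), "sleep",
                   "epeak_sleep_reduction_cold",
                   note = "sign as published: positive = evening sleep gain at 18C",
                   ...)
  else
    conditionIndex(records, hot, control_hot, c(12, 18), "sleep",
                   "epeak_sleep_reduction_hot", ...)
}

#' Index results as a one-row summary data.frame
#'
#' @param result an \linkS4class{IndexResult}.
#' @return data.frame(index, mean, sem, n, window_start, window_end,
#'   numerator, denominator, n_excluded, note).
#' @export
indexSummary <- function(result) {
  data.frame(index = result@index_name, mean = result@mean,
             sem = result@sem, n = nrow(result@per_fly),
             window_start = result@window[1], window_end = result@window[2],
             numerator = result@conditions[1],
             denominator = result@conditions[2],
             n_excluded = length(result@excluded),
             note = if (length(result@note)) result@note else "",
             stringsAsFactors = FALSE)
}
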