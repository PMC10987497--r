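## Central S4 containers. Validity methods enforce the structural invariants
## the downstream quantification relies on; accessors are defined in
## accessors.R and show methods in show-methods.R.

#' TemperatureProtocol: a Peltier-style temperature stimulus
#'
#' Describes the thermal stimulus delivered to a tethered fly: a holding
#' baseline plus one or more ramped steps. Each step ramps linearly from the
#' current temperature to its target over \code{ramp_s} seconds (the rig
#' reaches a commanded step in roughly 80 s) and then holds until the next
#' step or the end of the recording.
#'
#' @slot baseline_c holding temperature in degrees Celsius.
#' @slot steps data.frame with columns \code{onset_s}, \code{target_c},
#'   \code{ramp_s}; onsets strictly increasing, ramps positive, all steps
#'   inside the recording span.
#' @slot span_s total recording span in seconds.
#' @export
setClass("TemperatureProtocol",
  representation(baseline_c = "numeric", steps = "data.frame",
                 span_s = "numeric"),
  validity = function(object) {
    s <- object@steps
    need <- c("onset_s", "target_c", "ramp_s")
    if (!all(need %in% names(s)))
      return(sprintf("steps must have columns %s", paste(need, collapse = ", ")))
    if (nrow(s)) {
      if (any(diff(s$onset_s) <= 0)) return("step onsets must be strictly increasing")
      if (any(s$ramp_s <= 0)) return("ramp_s must be > 0")
      if (any(s$onset_s < 0) || any(s$onset_s + s$ramp_s > object@span_s))
        return("steps must lie within the recording span")
    }
    if (length(object@span_s) != 1 || object@span_s <= 0)
      return("span_s must be a single positive number")
    TRUE
  })

#' Construct a TemperatureProtocol
#'
#' @param baseline_c baseline temperature (degrees C).
#' @param steps data.frame(onset_s, target_c, ramp_s).
#' @param span_s recording span (s).
#' @return a \linkS4class{TemperatureProtocol}.
#' @examples
#' coolingStep <- temperatureProtocol(24, data.frame(
#'   onset_s = 60, target_c = 18, ramp_s = 80), span_s = 300)
#' @export
temperatureProtocol <- function(baseline_c, steps, span_s) {
  new("TemperatureProtocol", baseline_c = as.numeric(baseline_c),
      steps = as.data.frame(steps), span_s = as.numeric(span_s))
}

#' FluorescenceTrace: one ROI/channel time series
#'
#' A single region-of-interest fluorescence time series in arbitrary units,
#' from either the calcium-sensitive (GCaMP) or the calcium-insensitive
#' (tdTomato) channel, recorded at a known zeitgeber time.
#'
#' @slot roi_id character identifier.
#' @slot neuron_class neuron-class label (e.g. "DN1a", "LNd", "DN3"); purely
#'   metadata in this package.
#' @slot channel "GCaMP" or "tdTomato".
#' @slot zt zeitgeber hour of the recording, in [0, 24).
#' @slot times sampling times (s), strictly increasing, length >= 2.
#' @slot values fluorescence (a.u.), finite and non-negative.
#' @export
setClass("FluorescenceTrace",
  representation(roi_id = "character", neuron_class = "character",
                 channel = "character", zt = "numeric",
                 times = "numeric", values = "numeric"),
  validity = function(object) {
    if (!object@channel %in% c("GCaMP", "tdTomato"))
      return("channel must be 'GCaMP' or 'tdTomato'")
    if (length(object@times) < 2) return("need at least 2 samples")
    if (length(object@times) != length(object@values))
      return("times and values must have equal length")
    if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
    if (any(!is.finite(object@values))) return("values must be finite")
    if (any(object@values < 0)) return("values must be non-negative")
    TRUE
  })

#' Construct a FluorescenceTrace
#'
#' @param roi_id,neuron_class,channel,zt,times,values see
#'   \linkS4class{FluorescenceTrace}.
#' @return a \linkS4class{FluorescenceTrace}.
#' @export
fluorescenceTrace <- function(times, values, roi_id = "roi1",
                              neuron_class = "DN1a", channel = "GCaMP",
                              zt = 0) {
  new("FluorescenceTrace", roi_id = as.character(roi_id),
      neuron_class = as.character(neuron_class), channel = channel,
      zt = ztWrap(as.numeric(zt)), times = as.numeric(times),
      values = as.numeric(values))
}

#' DeltaFTrace: baseline-normalized fluorescence change
#'
#' Holds dF/F0 in percent together with the baseline F0 and the window it
#' was estimated from, so the normalization is reproducible from the object
#' alone.
#'
#' @slot roi_id identifier of the source trace.
#' @slot times sampling times (s).
#' @slot dff (F_t - F0)/F0 x 100, in percent.
#' @slot f0 baseline fluorescence (a.u.), positive.
#' @slot baseline_window numeric(2), the [start, end) window F0 came from.
#' @export
setClass("DeltaFTrace",
  representation(roi_id = "character", times = "numeric", dff = "numeric",
                 f0 = "numeric", baseline_window = "numeric"),
  validity = function(object) {
    if (length(object@times) != length(object@dff))
      return("times and dff must have equal length")
    if (object@f0 <= 0) return("f0 must be positive")
    if (length(object@baseline_window) != 2) return("baseline_window must be numeric(2)")
    TRUE
  })

#' TemperatureResponse: quantified response to one temperature step
#'
#' @slot roi_id,neuron_class,zt provenance of the trace.
#' @slot delta_t_c step amplitude, target minus baseline (degrees C).
#' @slot pre_mean,post_mean window means of the (ratiometric, if available)
#'   fluorescence before the step onset and after the ramp completes.
#' @slot fold_change post_mean / pre_mean.
#' @slot max_dff maximum dF/F0 (percent) in the post window.
#' @slot extremum_dff signed extremum of dF/F0 in the post window (largest
#'   absolute value, sign preserved) -- the variant used for inhibition.
#' @slot response_class "activated", "inhibited" or "nonresponsive".
#' @slot baseline_sd SD of the pre-window samples (a.u.).
#' @export
setClass("TemperatureResponse",
  representation(roi_id = "character", neuron_class = "character",
                 zt = "numeric", delta_t_c = "numeric",
                 pre_mean = "numeric", post_mean = "numeric",
                 fold_change = "numeric", max_dff = "numeric",
                 extremum_dff = "numeric", response_class = "character",
                 baseline_sd = "numeric"),
  validity = function(object) {
    if (!object@response_class %in% c("activated", "inhibited", "nonresponsive"))
      return("response_class must be activated/inhibited/nonresponsive")
    if (is.finite(object@pre_mean) && is.finite(object@post_mean) &&
        abs(object@fold_change - object@post_mean / object@pre_mean) >
          1e-8 * max(1, abs(object@fold_change)))
      return("fold_change must equal post_mean/pre_mean")
    TRUE
  })

#' ActivityRecord: one fly-day of 10-s-epoch movement counts
#'
#' @slot fly_id fly identifier.
#' @slot condition genotype/treatment label (metadata).
#' @slot temp_condition temperature condition label (e.g. "24C", "18C").
#' @slot day_index recording day, 1-based.
#' @slot counts integer movement counts per epoch, non-negative; one full
#'   day (8640 epochs at 10 s).
#' @slot lights_on,lights_off ZT hours of the light schedule.
#' @slot epoch_s epoch length in seconds (10).
#' @export
setClass("ActivityRecord",
  representation(fly_id = "character", condition = "character",
                 temp_condition = "character", day_index = "integer",
                 counts = "integer", lights_on = "numeric",
                 lights_off = "numeric", epoch_s = "numeric"),
  validity = function(object) {
    if (any(is.na(object@counts))) return("counts must not contain NA")
    if (any(object@counts < 0)) return("counts must be non-negative")
    n_expected <- 24 * 3600 / object@epoch_s
    if (length(object@counts) != n_expected)
      return(sprintf("counts must cover one day (%d epochs)", n_expected))
    TRUE
  })

#' Construct an ActivityRecord
#'
#' @param counts integer vector of per-epoch movement counts (one day).
#' @param fly_id,condition,temp_condition,day_index metadata.
#' @param lights_on,lights_off light schedule (ZT h).
#' @param epoch_s epoch length (s).
#' @return an \linkS4class{ActivityRecord}.
#' @export
activityRecord <- function(counts, fly_id = "fly1", condition = "control",
                           temp_condition = "24C", day_index = 1L,
                           lights_on = 0, lights_off = 12, epoch_s = 10) {
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("counts must be integers", call. = FALSE)
  new("ActivityRecord", fly_id = as.character(fly_id),
      condition = as.character(condition),
      temp_condition = as.character(temp_condition),
      day_index = as.integer(day_index), counts = as.integer(round(counts)),
      lights_on = lights_on, lights_off = lights_off, epoch_s = epoch_s)
}

#' SleepSeries: scored sleep for one fly-day
#'
#' Sleep is scored as runs of behavioral immobility lasting at least the
#' minimum bout length (field convention: 5 min). \code{sleep} marks every
#' epoch inside a bout; \code{bouts} lists (start_epoch, length_epochs) with
#' 1-based starts.
#'
#' @slot sleep logical per epoch.
#' @slot bouts data.frame(start_epoch, length_epochs), sorted, non-overlapping.
#' @slot epoch_s epoch length (s).
#' @slot min_bout_epochs minimum bout length used for scoring.
#' @export
setClass("SleepSeries",
  representation(sleep = "logical", bouts = "data.frame", epoch_s = "numeric",
                 min_bout_epochs = "integer"),
  validity = function(object) {
    b <- object@bouts
    if (!all(c("start_epoch", "length_epochs") %in% names(b)))
      return("bouts needs columns start_epoch, length_epochs")
    if (nrow(b)) {
      if (any(b$length_epochs < object@min_bout_epochs))
        return("every bout must reach the minimum bout length")
      ends <- b$start_epoch + b$length_epochs - 1
      if (any(diff(b$start_epoch) <= 0)) return("bouts must be sorted")
      if (nrow(b) > 1 && any(b$start_epoch[-1] <= ends[-nrow(b)]))
        return("bouts must not overlap")
    }
    inside <- rep(FALSE, length(object@sleep))
    for (i in seq_len(nrow(b)))
      inside[seq(b$start_epoch[i], length.out = b$length_epochs[i])] <- TRUE
    if (!identical(inside, object@sleep))
      return("sleep must be TRUE exactly inside bouts")
    TRUE
  })

#' ActivityProfile: group mean activity in 30-min bins
#'
#' @slot bin_centers ZT hours at the bin centers (48 bins/day).
#' @slot mean,sem mean and SEM of per-fly binned activity (counts/bin).
#' @slot n number of flies.
#' @export
setClass("ActivityProfile",
  representation(bin_centers = "numeric", mean = "numeric", sem = "numeric",
                 n = "integer"),
  validity = function(object) {
    if (length(object@mean) != length(object@bin_centers) ||
        length(object@sem) != length(object@bin_centers))
      return("bin_centers, mean, sem must align")
    TRUE
  })

#' IndexResult: a temperature-response behavioral index
#'
#' Per-fly values of one of the four indices plus the group summary. The
#' per-fly value is only defined when the denominator-window mean is
#' positive; excluded flies are listed.
#'
#' @slot index_name one of epeak_advance, epeak_offset_delay,
#'   night_sleep_reduction, epeak_sleep_reduction_cold,
#'   epeak_sleep_reduction_hot.
#' @slot per_fly data.frame(fly_id, value).
#' @slot mean,sem group mean and SEM.
#' @slot window ZT window used, numeric(2).
#' @slot conditions character(2): numerator and denominator temperature labels.
#' @slot excluded fly ids dropped for a zero denominator.
#' @slot note sign-convention note carried into output metadata.
#' @export
setClass("IndexResult",
  representation(index_name = "character", per_fly = "data.frame",
                 mean = "numeric", sem = "numeric", window = "numeric",
                 conditions = "character", excluded = "character",
                 note = "character"))

#' DiurnalGroup: one phase-shifted long-term recording group
#'
#' Flies entrained with a fixed shift of the light schedule and imaged every
#' 30 min over 6 h of their local time; both channel sums per time point.
#'
#' @slot shift_h entrainment shift in hours (0, 6, 12 or 18).
#' @slot data data.frame(fly_id, local_time_h, gcamp, tdtom); both channels
#'   positive.
#' @export
setClass("DiurnalGroup",
  representation(shift_h = "numeric", data = "data.frame"),
  validity = function(object) {
    need <- c("fly_id", "local_time_h", "gcamp", "tdtom")
    if (!all(need %in% names(object@data)))
      return(sprintf("data needs columns %s", paste(need, collapse = ", ")))
    if (nrow(object@data) &&
        (any(object@data$gcamp <= 0) || any(object@data$tdtom <= 0)))
      return("both channels must be positive")
    TRUE
  })

#' CircadianCurve: the stitched 24-h diurnal calcium curve
#'
#' @slot bin_centers ZT h at 30-min spacing covering [0, 24).
#' @slot mean,sem ratiometric mean and SEM per bin (NA where no data).
#' @slot n flies contributing per bin.
#' @export
setClass("CircadianCurve",
  representation(bin_centers = "numeric", mean = "numeric", sem = "numeric",
                 n = "integer"),
  validity = function(object) {
    k <- length(object@bin_centers)
    if (length(object@mean) != k || length(object@sem) != k ||
        length(object@n) != k)
      return("slots must align")
    if (any(object@n < 1 & !is.na(object@mean)))
      return("mean must be NA where n = 0")
    TRUE
  })

#' GatingProfile: circadian gating of temperature responses
#'
#' Per-ZT-window mean absolute response with bootstrap CI, plus the ratio of
#' each window to a reference window.
#'
#' @slot windows named list of numeric(2) ZT windows.
#' @slot gain,ci_lo,ci_hi per-window mean |response| and percentile CI.
#' @slot ratio gain relative to the reference window.
#' @slot reference name of the reference window.
#' @slot n responses per window.
#' @export
setClass("GatingProfile",
  representation(windows = "list", gain = "numeric", ci_lo = "numeric",
                 ci_hi = "numeric", ratio = "numeric", reference = "character",
                 n = "integer"),
  validity = function(object) {
    if (any(object@gain < 0, na.rm = TRUE)) return("gains must be >= 0")
    TRUE
  })

#' SynapseTable: typed synaptic connections (neuPrint export dialect)
#'
#' @slot connections data.frame(bodyId_pre, type_pre, bodyId_post, type_post,
#'   weight); duplicate body pairs already summed; weights positive integers.
#' @export
setClass("SynapseTable",
  representation(connections = "data.frame"),
  validity = function(object) {
    need <- c("bodyId_pre", "type_pre", "bodyId_post", "type_post", "weight")
    if (!all(need %in% names(object@connections)))
      return(sprintf("connections needs columns %s", paste(need, collapse = ", ")))
    w <- object@connections$weight
    if (length(w) && (any(w < 1) || any(abs(w - round(w)) > 1e-9)))
      return("weights must be integers >= 1")
    TRUE
  })

#' PartnerRanking: aggregated, thresholded synaptic partners of a cell type
#'
#' @slot source_type the focal cell type.
#' @slot direction "downstream" (partners postsynaptic to the source) or
#'   "upstream".
#' @slot entries data.frame(partner_type, total_weight, n_partner_bodies),
#'   sorted by descending weight, ties broken lexicographically.
#' @slot min_weight threshold used; partners below it were dropped.
#' @slot dropped_weight summed weight of dropped partners (conservation:
#'   retained + dropped = total source-incident weight).
#' @export
setClass("PartnerRanking",
  representation(source_type = "character", direction = "character",
                 entries = "data.frame", min_weight = "numeric",
                 dropped_weight = "numeric"),
  validity = function(object) {
    if (!object@direction %in% c("downstream", "upstream"))
      return("direction must be downstream or upstream")
    e <- object@entries
    if (nrow(e) > 1) {
      o <- order(-e$total_weight, e$partner_type)
      if (!identical(o, seq_len(nrow(e))))
        return("entries must be sorted by descending weight, ties lexicographic")
    }
    TRUE
  })

#' SankeyData: node/link structure for Sankey renderers
#'
#' @slot nodes character labels.
#' @slot links data.frame(source, target, value); 0-based indices into
#'   nodes, values positive.
#' @export
setClass("SankeyData",
  representation(nodes = "character", links = "data.frame"),
  validity = function(object) {
    l <- object@links
    if (!all(c("source", "target", "value") %in% names(l)))
      return("links needs columns source, target, value")
    if (nrow(l)) {
      if (any(l$value <= 0)) return("link values must be > 0")
      idx <- c(l$source, l$target)
      if (any(idx < 0) || any(idx >= length(object@nodes)))
        return("link indices out of range")
    }
    TRUE
  })
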