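## Accessor generics so user code never touches slots directly.

#' Sampling times of a trace
#' @param x a \linkS4class{FluorescenceTrace} or \linkS4class{DeltaFTrace}.
#' @return numeric vector of seconds.
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname traceTimes
#' @export
setMethod("traceTimes", "FluorescenceTrace", function(x) x@times)
#' @rdname traceTimes
#' @export
setMethod("traceTimes", "DeltaFTrace", function(x) x@times)

#' Fluorescence values of a trace
#' @param x a \linkS4class{FluorescenceTrace}.
#' @return numeric vector (a.u.).
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname traceValues
#' @export
setMethod("traceValues", "FluorescenceTrace", function(x) x@values)

#' dF/F0 values (percent)
#' @param x a \linkS4class{DeltaFTrace}.
#' @return numeric vector of percent changes.
#' @export
setGeneric("dffValues", function(x) standardGeneric("dffValues"))
#' @rdname dffValues
#' @export
setMethod("dffValues", "DeltaFTrace", function(x) x@dff)

#' Baseline fluorescence F0
#' @param x a \linkS4class{DeltaFTrace}.
#' @return F0 (a.u.).
#' @export
setGeneric("f0", function(x) standardGeneric("f0"))
#' @rdname f0
#' @export
setMethod("f0", "DeltaFTrace", function(x) x@f0)

#' Per-epoch sleep state
#' @param x a \linkS4class{SleepSeries}.
#' @return logical vector, TRUE while asleep.
#' @export
setGeneric("sleepState", function(x) standardGeneric("sleepState"))
#' @rdname sleepState
#' @export
setMethod("sleepState", "SleepSeries", function(x) x@sleep)

#' Sleep bouts
#' @param x a \linkS4class{SleepSeries}.
#' @return data.frame(start_epoch, length_epochs).
#' @export
setGeneric("sleepBouts", function(x) standardGeneric("sleepBouts"))
#' @rdname sleepBouts
#' @export
setMethod("sleepBouts", "SleepSeries", function(x) x@bouts)

#' Movement counts of an activity record
#' @param x an \linkS4class{ActivityRecord}.
#' @return integer vector of per-epoch counts.
#' @export
setGeneric("activityCounts", function(x) standardGeneric("activityCounts"))
#' @rdname activityCounts
#' @export
setMethod("activityCounts", "ActivityRecord", function(x) x@counts)

#' Bin centers (ZT hours)
#' @param x an \linkS4class{ActivityProfile} or \linkS4class{CircadianCurve}.
#' @return numeric vector of ZT hours.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))
#' @rdname binCenters
#' @export
setMethod("binCenters", "ActivityProfile", function(x) x@bin_centers)
#' @rdname binCenters
#' @export
setMethod("binCenters", "CircadianCurve", function(x) x@bin_centers)

#' Per-bin means
#' @param x an \linkS4class{ActivityProfile} or \linkS4class{CircadianCurve}.
#' @return numeric vector (activity counts/bin or ratio units).
#' @export
setGeneric("binMeans", function(x) standardGeneric("binMeans"))
#' @rdname binMeans
#' @export
setMethod("binMeans", "ActivityProfile", function(x) x@mean)
#' @rdname binMeans
#' @export
setMethod("binMeans", "CircadianCurve", function(x) x@mean)

#' Per-bin SEMs
#' @param x an \linkS4class{ActivityProfile} or \linkS4class{CircadianCurve}.
#' @return numeric vector.
#' @export
setGeneric("binSems", function(x) standardGeneric("binSems"))
#' @rdname binSems
#' @export
setMethod("binSems", "ActivityProfile", function(x) x@sem)
#' @rdname binSems
#' @export
setMethod("binSems", "CircadianCurve", function(x) x@sem)

#' Per-fly index values
#' @param x an \linkS4class{IndexResult}.
#' @return data.frame(fly_id, value).
#' @export
setGeneric("perFly", function(x) standardGeneric("perFly"))
#' @rdname perFly
#' @export
setMethod("perFly", "IndexResult", function(x) x@per_fly)

#' Group summary of an index
#' @param x an \linkS4class{IndexResult}.
#' @return named numeric c(mean, sem).
#' @export
setGeneric("indexMean", function(x) standardGeneric("indexMean"))
#' @rdname indexMean
#' @export
setMethod("indexMean", "IndexResult", function(x)
  c(mean = x@mean, sem = x@sem))

#' Ranked partner entries
#' @param x a \linkS4class{PartnerRanking}.
#' @return data.frame(partner_type, total_weight, n_partner_bodies).
#' @export
setGeneric("rankingEntries", function(x) standardGeneric("rankingEntries"))
#' @rdname rankingEntries
#' @export
setMethod("rankingEntries", "PartnerRanking", function(x) x@entries)

#' Connection rows of a synapse table
#' @param x a \linkS4class{SynapseTable}.
#' @return data.frame of typed connections.
#' @export
setGeneric("connections", function(x) standardGeneric("connections"))
#' @rdname connections
#' @export
setMethod("connections", "SynapseTable", function(x) x@connections)

#' Gating gains per ZT window
#' @param x a \linkS4class{GatingProfile}.
#' @return data.frame(window, gain, ci_lo, ci_hi, ratio, n).
#' @export
setGeneric("gatingTable", function(x) standardGeneric("gatingTable"))
#' @rdname gatingTable
#' @export
setMethod("gatingTable", "GatingProfile", function(x)
  data.frame(window = names(x@windows), gain = x@gain, ci_lo = x@ci_lo,
             ci_hi = x@ci_hi, ratio = x@ratio, n = x@n, row.names = NULL))
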