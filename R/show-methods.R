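## Compact show methods.

#' @importFrom methods show
setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: seed", object@master_seed, "|", object@n_flies,
      "flies x", object@n_days, "day(s) |",
      length(object@temp_effects), "conditions:",
      paste(names(object@temp_effects), collapse = ", "), "\n")
  cat("  calcium: sat", object@calcium$dt_sat_cool, "/",
      object@calcium$dt_sat_heat, "degC, tau",
      object@calcium$tau_sensor_s, "s",
      if (object@ablate_dn1a) "(DN1a ablated)" else "", "\n")
})

setMethod("show", "TemperatureProtocol", function(object) {
  cat("TemperatureProtocol:", object@baseline_c, "degC baseline,",
      nrow(object@steps), "step(s) over", object@span_s, "s\n")
  if (nrow(object@steps)) print(object@steps)
})

setMethod("show", "FluorescenceTrace", function(object) {
  cat(sprintf("FluorescenceTrace %s [%s, %s] ZT %.1f: %d samples, %.1f-%.1f s\n",
              object@roi_id, object@neuron_class, object@channel, object@zt,
              length(object@times), min(object@times), max(object@times)))
})

setMethod("show", "DeltaFTrace", function(object) {
  cat(sprintf("DeltaFTrace %s: F0 = %.3g, dF/F0 range [%.1f, %.1f]%%\n",
              object@roi_id, object@f0, min(object@dff), max(object@dff)))
})

setMethod("show", "TemperatureResponse", function(object) {
  cat(sprintf("TemperatureResponse %s (%s, ZT %.1f, dT %+.1f degC): fold %.3f, %s\n",
              object@roi_id, object@neuron_class, object@zt,
              object@delta_t_c, object@fold_change, object@response_class))
})

setMethod("show", "ActivityRecord", function(object) {
  cat(sprintf("ActivityRecord %s day %d [%s]: %d counts over %d epochs\n",
              object@fly_id, object@day_index, object@temp_condition,
              sum(object@counts), length(object@counts)))
})

setMethod("show", "SleepSeries", function(object) {
  cat(sprintf("SleepSeries: %d bouts, %.0f sleep min of %.0f\n",
              nrow(object@bouts), sum(object@sleep) * object@epoch_s / 60,
              length(object@sleep) * object@epoch_s / 60))
})

setMethod("show", "ActivityProfile", function(object) {
  cat(sprintf("ActivityProfile: %d bins, n = %d flies\n",
              length(object@bin_centers), object@n))
})

setMethod("show", "IndexResult", function(object) {
  cat(sprintf("IndexResult %s [%s vs %s, ZT %g-%g]: %.4f +/- %.4f (n = %d)\n",
              object@index_name, object@conditions[1], object@conditions[2],
              object@window[1], object@window[2], object@mean, object@sem,
              nrow(object@per_fly)))
  if (length(object@note) && nzchar(object@note))
    cat(" note:", object@note, "\n")
})

setMethod("show", "DiurnalGroup", function(object) {
  cat(sprintf("DiurnalGroup shift %g h: %d flies, %d samples\n",
              object@shift_h, length(unique(object@data$fly_id)),
              nrow(object@data)))
})

setMethod("show", "CircadianCurve", function(object) {
  cat(sprintf("CircadianCurve: %d bins, n %d-%d per bin\n",
              length(object@bin_centers), min(object@n), max(object@n)))
})

setMethod("show", "GatingProfile", function(object) {
  cat("GatingProfile (reference", object@reference, ")\n")
  print(gatingTable(object))
})

setMethod("show", "SynapseTable", function(object) {
  cat(sprintf("SynapseTable: %d connections, total weight %d\n",
              nrow(object@connections), sum(object@connections$weight)))
})

setMethod("show", "PartnerRanking", function(object) {
  cat(sprintf("PartnerRanking: %s of %s (min weight %g, dropped %g)\n",
              object@direction, object@source_type, object@min_weight,
              object@dropped_weight))
  print(utils::head(object@entries, 10))
})

setMethod("show", "SankeyData", function(object) {
  cat(sprintf("SankeyData: %d nodes, %d links, total flow %g\n",
              length(object@nodes), nrow(object@links),
              sum(object@links$value)))
})
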