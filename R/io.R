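## Delimited-text-first I/O. All tables are tab-separated with explicit
## headers; ZT is always hours as floats, epochs are 0-based in files
## (1-based inside R), intervals half-open. Floats round-trip at full
## double precision (15 significant digits).

writeTSV <- function(df, path) {
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read activity records (long table)
#'
#' Columns: fly_id, condition, temp_condition, day, epoch_index (0-based),
#' count.
#'
#' @param records list of \linkS4class{ActivityRecord}.
#' @param path file path.
#' @return \code{readActivityTable} returns the list of records.
#' @export
writeActivityTable <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r) data.frame(
    fly_id = r@fly_id, condition = r@condition,
    temp_condition = r@temp_condition, day = r@day_index,
    epoch_index = seq_along(r@counts) - 1L, count = r@counts,
    stringsAsFactors = FALSE)))
  writeTSV(df, path)
  invisible(path)
}

#' @rdname writeActivityTable
#' @export
readActivityTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(df$fly_id, df$temp_condition, df$day, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    sub <- sub[order(sub$epoch_index), ]
    activityRecord(sub$count, fly_id = sub$fly_id[1],
                   condition = sub$condition[1],
                   temp_condition = sub$temp_condition[1],
                   day_index = sub$day[1])
  })
}

#' Write / read fluorescence traces (long table)
#'
#' Columns: roi_id, neuron_class, channel, zt, time_s, value.
#'
#' @param traces list of \linkS4class{FluorescenceTrace} (trace pairs from
#'   \code{\link{genTwoChannelTraces}} are flattened).
#' @param path file path.
#' @return \code{readTraceTable} returns a list of
#'   \linkS4class{FluorescenceTrace}.
#' @export
writeTraceTable <- function(traces, path) {
  flat <- list()
  for (tr in traces) {
    if (is(tr, "FluorescenceTrace")) flat <- c(flat, list(tr))
    else flat <- c(flat, unname(tr))
  }
  df <- do.call(rbind, lapply(flat, function(tr) data.frame(
    roi_id = tr@roi_id, neuron_class = tr@neuron_class,
    channel = tr@channel, zt = tr@zt, time_s = tr@times, value = tr@values,
    stringsAsFactors = FALSE)))
  writeTSV(df, path)
  invisible(path)
}

#' @rdname writeTraceTable
#' @export
readTraceTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  key <- paste(df$roi_id, df$channel, sep = "\r")
  lapply(unique(key), function(k) {
    sub <- df[key == k, ]
    sub <- sub[order(sub$time_s), ]
    fluorescenceTrace(sub$time_s, sub$value, roi_id = sub$roi_id[1],
                      neuron_class = sub$neuron_class[1],
                      channel = sub$channel[1], zt = sub$zt[1])
  })
}

#' Write / read diurnal recording groups (long table)
#'
#' Columns: group_shift_h, fly_id, local_time_h, gcamp, tdtom.
#'
#' @param groups list of \linkS4class{DiurnalGroup}.
#' @param path file path.
#' @return \code{readDiurnalGroups} returns the list of groups.
#' @export
writeDiurnalGroups <- function(groups, path) {
  df <- do.call(rbind, lapply(groups, function(g)
    cbind(group_shift_h = g@shift_h, g@data)))
  writeTSV(df, path)
  invisible(path)
}

#' @rdname writeDiurnalGroups
#' @export
readDiurnalGroups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(sort(unique(df$group_shift_h)), function(sh) {
    new("DiurnalGroup", shift_h = sh,
        data = df[df$group_shift_h == sh,
                  c("fly_id", "local_time_h", "gcamp", "tdtom")])
  })
}

#' Write a circadian curve (table + JSON metadata)
#'
#' @param curve a \linkS4class{CircadianCurve}.
#' @param path TSV output path; per-bin n goes to \code{paste0(path,
#'   ".meta.json")}.
#' @return the curve (for \code{readCurve}) or the path, invisibly.
#' @export
writeCurve <- function(curve, path) {
  writeTSV(data.frame(bin_center_zt = curve@bin_centers, mean = curve@mean,
                      sem = curve@sem, n = curve@n), path)
  jsonlite::write_json(list(n_per_bin = curve@n,
                            bin_h = curve@bin_centers[2] - curve@bin_centers[1]),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCurve
#' @export
readCurve <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("CircadianCurve", bin_centers = df$bin_center_zt,
      mean = ifelse(is.na(df$mean), NA_real_, df$mean),
      sem = df$sem, n = as.integer(df$n))
}

#' Read a temperature protocol from YAML or JSON
#'
#' Expected fields: \code{baseline_c}, \code{span_s}, \code{steps} (list of
#' \code{onset_s}, \code{target_c}, \code{ramp_s}).
#'
#' @param path file; dispatch on extension (.yaml/.yml vs .json).
#' @return a \linkS4class{TemperatureProtocol}.
#' @export
readProtocol <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  steps <- obj$steps
  if (is.list(steps) && !is.data.frame(steps))
    steps <- do.call(rbind, lapply(steps, as.data.frame))
  temperatureProtocol(obj$baseline_c, steps, obj$span_s)
}

#' Write a partner ranking (TSV + JSON)
#'
#' @param ranking a \linkS4class{PartnerRanking}.
#' @param path TSV path; a JSON summary (source, direction, threshold,
#'   dropped weight) is written to \code{paste0(path, ".meta.json")}.
#' @export
writeRanking <- function(ranking, path) {
  writeTSV(ranking@entries, path)
  jsonlite::write_json(list(source_type = ranking@source_type,
                            direction = ranking@direction,
                            min_weight = ranking@min_weight,
                            dropped_weight = ranking@dropped_weight),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a run manifest
#'
#' Records every parameter needed to reproduce a run bit-for-bit: the master
#' seed, the package version, and all analysis parameters supplied.
#' Deliberately contains no timestamps, so identical runs produce identical
#' manifests.
#'
#' @param path output JSON path.
#' @param seed master seed of the run.
#' @param params named list of analysis parameters.
#' @export
writeManifest <- function(path, seed, params = list()) {
  jsonlite::write_json(
    list(package = "ThermoClock",
         version = as.character(utils::packageVersion("ThermoClock")),
         master_seed = seed, parameters = params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
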