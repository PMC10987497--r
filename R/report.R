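## End-to-end synthetic demonstration run and the subcommand dispatcher.

#' Run the full synthetic pipeline end to end
#'
#' Generates a synthetic cohort, scores sleep, computes the four
#' temperature-response indices, builds activity profiles, quantifies
#' temperature-step calcium responses across amplitudes (saturation
#' summary) and ZT windows (gating profile), stitches the 24-h diurnal
#' curve from four phase-shifted groups, ranks connectome partners, and
#' writes every table plus a run manifest to \code{out_dir}. Fully
#' deterministic given \code{seed}: running twice produces byte-identical
#' files.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param n_flies flies per condition.
#' @param n_per_group flies per diurnal group.
#' @return invisibly, a list with the computed summaries.
#' @export
runReport <- function(out_dir, seed = 1, n_flies = 16, n_per_group = 6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  cfg <- synthConfig(master_seed = seed, n_flies = n_flies,
                     calcium = list(noise_sd = 2, ratio_noise_sd = 0.05))

  ## behavior: records under all four temperature conditions
  records <- c(genActivity(cfg, "24C"), genActivity(cfg, "18C"),
               genActivity(cfg, "22C"), genActivity(cfg, "30C"))
  writeActivityTable(records, p("activity.tsv"))
  idx <- list(epeakAdvanceIndex(records),
              epeakOffsetDelayIndex(records),
              nightSleepReductionIndex(records),
              epeakSleepReductionIndex(records, "cold"),
              epeakSleepReductionIndex(records, "hot"))
  idx_df <- do.call(rbind, lapply(idx, indexSummary))
  writeTSV(idx_df, p("indices.tsv"))
  temp <- vapply(records, function(r) r@temp_condition, "")
  prof <- binActivity(records[temp == "24C"])
  writeTSV(data.frame(bin_center_zt = binCenters(prof), mean = binMeans(prof),
                      sem = binSems(prof)), p("profile_24C.tsv"))

  ## calcium: step responses across amplitudes at a fixed evening window
  protoFor <- function(base, target) temperatureProtocol(
    base, data.frame(onset_s = 60, target_c = target, ramp_s = 80), 300)
  resp <- list()
  for (dt in c(-10, -8, -6, -4, -2)) {
    pairs <- genTwoChannelTraces(cfg, protoFor(24, 24 + dt), zt = 12,
                                 n = 8)
    resp <- c(resp, lapply(pairs, function(pr)
      quantifyStepResponse(pr$gcamp, protoFor(24, 24 + dt), pre_s = 40,
                           post_s = 120, tdtom = pr$tdtom)))
  }
  for (dt in c(2, 4, 6, 8, 10)) {
    pairs <- genTwoChannelTraces(cfg, protoFor(22, 22 + dt), zt = 12,
                                 n = 8)
    resp <- c(resp, lapply(pairs, function(pr)
      quantifyStepResponse(pr$gcamp, protoFor(22, 22 + dt), pre_s = 40,
                           post_s = 120, tdtom = pr$tdtom)))
  }
  writeTSV(responseTable(resp), p("responses.tsv"))
  sat <- saturationSummary(resp)

  ## gating: cooling responses at four ZT windows
  gresp <- list()
  for (zt in c(1, 7, 12, 18)) {
    pairs <- genTwoChannelTraces(cfg, protoFor(24, 18), zt = zt, n = 8)
    gresp <- c(gresp, lapply(pairs, function(pr)
      quantifyStepResponse(pr$gcamp, protoFor(24, 18), pre_s = 40,
                           post_s = 120, tdtom = pr$tdtom)))
  }
  gating <- estimateGating(gresp, seed = seed)
  writeTSV(gatingTable(gating), p("gating.tsv"))

  ## diurnal curve from four phase-shifted groups
  groups <- genDiurnalGroups(cfg, n_per_group = n_per_group)
  writeDiurnalGroups(groups, p("diurnal_groups.tsv"))
  curve <- stitchGroups(groups)
  writeCurve(curve, p("circadian_curve.tsv"))
  writeTSV(doublePlot(curve), p("circadian_curve_double.tsv"))

  ## connectome ranking
  planted <- data.frame(
    type_pre = "DN1a",
    type_post = c("DN3", "LNd", "5th s-LNv", "KC(a'b')", "SMP232"),
    weight = c(120L, 60L, 40L, 25L, 90L))
  stab <- genSynapseTable(cfg, planted)
  ranking <- rankPartners(stab, "DN1a", "downstream")
  writeRanking(ranking, p("ranking.tsv"))
  sankeyJSON(toSankey(ranking), p("sankey.json"))

  writeManifest(p("manifest.json"), seed,
                params = list(n_flies = n_flies, n_per_group = n_per_group,
                              conditions = names(cfg@temp_effects)))
  invisible(list(indices = idx_df, saturation = sat, gating = gating,
                 curve = curve, ranking = ranking))
}

usageText <- function() {
  paste(
    "usage: thermoclock <subcommand> [options]",
    "subcommands:",
    "  simulate   --seed S --out DIR [--n-flies N]   write synthetic activity/traces/groups",
    "  sleep      --in activity.tsv --out sleep.tsv  score sleep per fly-day",
    "  indices    --in activity.tsv --out idx.tsv    the four temperature indices",
    "  dff        --in traces.tsv --out dff.tsv      dF/F0 per GCaMP trace",
    "  respond    --in traces.tsv --protocol P --out resp.tsv  step responses",
    "  cluster    --in traces.tsv --out prefix       correlation + clustering",
    "  stitch     --in groups.tsv --out curve.tsv    24-h diurnal curve",
    "  connectome --in synapses.(csv|tsv) --source TYPE --out prefix  ranking + Sankey",
    "  report     --seed S --out DIR                 full end-to-end demo",
    "global flags: --seed S (default 1)", sep = "\n")
}

argValue <- function(args, flag, default = NULL) {
  i <- which(args == flag)
  if (!length(i)) return(default)
  if (i[1] == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i[1] + 1]
}

#' Command-line entry point
#'
#' Thin dispatcher over the package functions; see
#' \code{inst/scripts/thermoclock} for the Rscript wrapper. Returns a shell
#' exit status (0 ok, 2 usage error, 1 runtime failure).
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status.
#' @export
cliMain <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usageText(), "\n")
    return(if (length(args)) 0L else 2L)
  }
  sub <- args[1]
  rest <- args[-1]
  seed <- as.integer(argValue(rest, "--seed", "1"))
  status <- tryCatch({
    switch(sub,
      simulate = {
        out <- argValue(rest, "--out")
        stopIfNot(!is.null(out), "simulate needs --out DIR")
        n <- as.integer(argValue(rest, "--n-flies", "8"))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        cfg <- synthConfig(master_seed = seed, n_flies = n)
        recs <- c(genActivity(cfg, "24C"), genActivity(cfg, "18C"),
                  genActivity(cfg, "22C"), genActivity(cfg, "30C"))
        writeActivityTable(recs, file.path(out, "activity.tsv"))
        writeDiurnalGroups(genDiurnalGroups(cfg),
                           file.path(out, "diurnal_groups.tsv"))
        proto <- temperatureProtocol(24, data.frame(
          onset_s = 60, target_c = 18, ramp_s = 80), 300)
        writeTraceTable(genTwoChannelTraces(cfg, proto, zt = 12, n = 4),
                        file.path(out, "traces.tsv"))
        writeManifest(file.path(out, "manifest.json"), seed,
                      list(n_flies = n))
        0L
      },
      sleep = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        stopIfNot(!is.null(input) && !is.null(out),
                  "sleep needs --in and --out")
        recs <- readActivityTable(input)
        df <- do.call(rbind, lapply(recs, function(r) {
          ss <- scoreSleep(r)
          data.frame(fly_id = r@fly_id, temp_condition = r@temp_condition,
                     day = r@day_index, n_bouts = nrow(sleepBouts(ss)),
                     sleep_min = sum(sleepState(ss)) * r@epoch_s / 60)
        }))
        writeTSV(df, out)
        0L
      },
      indices = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        stopIfNot(!is.null(input) && !is.null(out),
                  "indices needs --in and --out")
        recs <- readActivityTable(input)
        idx <- list(epeakAdvanceIndex(recs), epeakOffsetDelayIndex(recs),
                    nightSleepReductionIndex(recs),
                    epeakSleepReductionIndex(recs, "cold"),
                    epeakSleepReductionIndex(recs, "hot"))
        writeTSV(do.call(rbind, lapply(idx, indexSummary)), out)
        0L
      },
      dff = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        stopIfNot(!is.null(input) && !is.null(out), "dff needs --in and --out")
        traces <- readTraceTable(input)
        gc <- Filter(function(tr) tr@channel == "GCaMP", traces)
        df <- do.call(rbind, lapply(gc, function(tr) {
          d <- computeDff(tr, c(min(tr@times), min(tr@times) + 30))
          data.frame(roi_id = tr@roi_id, time_s = d@times, dff = d@dff)
        }))
        writeTSV(df, out)
        0L
      },
      respond = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        proto_path <- argValue(rest, "--protocol")
        stopIfNot(!is.null(input) && !is.null(out) && !is.null(proto_path),
                  "respond needs --in, --protocol and --out")
        proto <- readProtocol(proto_path)
        traces <- readTraceTable(input)
        gc <- Filter(function(tr) tr@channel == "GCaMP", traces)
        td <- Filter(function(tr) tr@channel == "tdTomato", traces)
        td_by <- setNames(td, vapply(td, function(tr) tr@roi_id, ""))
        resp <- lapply(gc, function(tr)
          quantifyStepResponse(tr, proto, tdtom = td_by[[tr@roi_id]]))
        writeTSV(responseTable(resp), out)
        0L
      },
      cluster = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        stopIfNot(!is.null(input) && !is.null(out),
                  "cluster needs --in and --out prefix")
        traces <- readTraceTable(input)
        gc <- Filter(function(tr) tr@channel == "GCaMP", traces)
        dffs <- lapply(gc, function(tr)
          computeDff(tr, c(min(tr@times), min(tr@times) + 30)))
        names(dffs) <- vapply(gc, function(tr) tr@roi_id, "")
        cl <- correlateAndCluster(dffs)
        writeTSV(as.data.frame(cl$correlation), paste0(out, "_cor.tsv"))
        writeTSV(data.frame(roi_id = names(cl$labels), cluster = cl$labels),
                 paste0(out, "_labels.tsv"))
        0L
      },
      stitch = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        stopIfNot(!is.null(input) && !is.null(out),
                  "stitch needs --in and --out")
        writeCurve(stitchGroups(readDiurnalGroups(input)), out)
        0L
      },
      connectome = {
        input <- argValue(rest, "--in"); out <- argValue(rest, "--out")
        src <- argValue(rest, "--source")
        stopIfNot(!is.null(input) && !is.null(out) && !is.null(src),
                  "connectome needs --in, --source and --out prefix")
        tab <- loadSynapseTable(input)
        dirn <- argValue(rest, "--direction", "downstream")
        minw <- as.numeric(argValue(rest, "--min-weight", "1"))
        r <- rankPartners(tab, src, dirn, minw)
        writeRanking(r, paste0(out, "_ranking.tsv"))
        sankeyJSON(toSankey(r), paste0(out, "_sankey.json"))
        0L
      },
      report = {
        out <- argValue(rest, "--out")
        stopIfNot(!is.null(out), "report needs --out DIR")
        runReport(out, seed = seed)
        0L
      },
      {
        cat(usageText(), "\n")
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
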