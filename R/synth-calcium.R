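## Two-channel calcium-trace generator. Latent neuronal activity is
##   a(t) = b(zt) + s_class * g(zt) * R(dT(t)) [+ coupling from DN1a]
## where R is the signed, saturating step response
##   R(dT) = sign(dT) * min(|dT| / dT_sat, 1)
## with separate saturation limits for cooling and heating. The latent
## signal is low-pass filtered with the sensor time constant (exact
## exponential update of a first-order ODE), then rendered as
##   GCaMP:    F = F0g * (1 + kappa * a_f) * bleach(t) + noise
##   tdTomato: F = F0t * bleach(t) + noise.

#' Temperature trajectory of a protocol
#'
#' Piecewise-linear temperature over time: each step ramps from the current
#' temperature to its target over its ramp duration, then holds.
#'
#' @param protocol a \linkS4class{TemperatureProtocol}.
#' @param times evaluation times (s).
#' @return temperature (degrees C) at each time.
#' @export
protocolTemperature <- function(protocol, times) {
  temp <- rep(protocol@baseline_c, length(times))
  current <- protocol@baseline_c
  s <- protocol@steps
  for (i in seq_len(nrow(s))) {
    on <- s$onset_s[i]; tgt <- s$target_c[i]; ramp <- s$ramp_s[i]
    frac <- pmin(pmax((times - on) / ramp, 0), 1)
    temp <- ifelse(times < on, temp, current + frac * (tgt - current))
    current <- tgt
  }
  temp
}

#' Saturating step-response function R(dT)
#'
#' Signed and clamped: linear in the step amplitude up to the saturation
#' limit, then exactly 1 in magnitude. Cooling saturates at
#' \code{dt_sat_cool} degrees below baseline, heating at
#' \code{dt_sat_heat} above.
#'
#' @param delta_t temperature change relative to baseline (degC).
#' @param dt_sat_cool,dt_sat_heat saturation limits (degC, positive).
#' @return response in [-1, 1].
#' @export
stepResponseFun <- function(delta_t, dt_sat_cool = 6, dt_sat_heat = 8) {
  ifelse(delta_t >= 0, pmin(delta_t / dt_sat_heat, 1),
         -pmin(-delta_t / dt_sat_cool, 1))
}

## Exact first-order low-pass (single-pole sensor model).
lowPass <- function(x, times, tau) {
  y <- x
  for (i in 2:length(x)) {
    alpha <- 1 - exp(-(times[i] - times[i - 1]) / tau)
    y[i] <- y[i - 1] + alpha * (x[i] - y[i - 1])
  }
  y
}

## Latent activity of one neuron class under a protocol at fixed zt.
latentActivity <- function(config, protocol, zt, neuron_class, times) {
  cc <- config@calcium
  dT <- protocolTemperature(protocol, times) - protocol@baseline_c
  r <- stepResponseFun(dT, cc$dt_sat_cool, cc$dt_sat_heat)
  gain <- if (neuron_class %in% names(cc$gain)) cc$gain[[neuron_class]] else 1
  a <- cc$baseline_fun(zt) + gain * cc$gating_fun(zt) * r
  if (neuron_class %in% names(cc$coupling)) {
    w <- cc$coupling[[neuron_class]]
    if (config@ablate_dn1a) w <- w * cc$residual_coupling
    drive_dn1a <- cc$gain[["DN1a"]] * cc$gating_fun(zt) * r
    a <- a + w * drive_dn1a
  }
  a
}

#' Generate two-channel (GCaMP + tdTomato) fluorescence trace pairs
#'
#' Simulates ROI-level trace pairs for a temperature-step protocol at a
#' fixed zeitgeber time. Each trace gets its own seed substream.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param protocol a \linkS4class{TemperatureProtocol}; steps must lie
#'   within the recording span.
#' @param zt zeitgeber hour of the recording.
#' @param neuron_classes classes to simulate (recycled over \code{n}).
#' @param n trace pairs per class.
#' @param dt_s sampling interval (s).
#' @return list of \code{list(gcamp =, tdtom =)} pairs of
#'   \linkS4class{FluorescenceTrace}.
#' @export
genTwoChannelTraces <- function(config, protocol, zt,
                                neuron_classes = "DN1a", n = 8, dt_s = 1) {
  cc <- config@calcium
  stopIfNot(cc$tau_sensor_s > 0, "tau_sensor_s must be positive")
  stopIfNot(cc$f0_gcamp > 0 && cc$f0_tdtom > 0, "F0 must be positive")
  times <- seq(0, protocol@span_s, by = dt_s)
  bleach <- if (is.finite(cc$bleach_tau_s)) exp(-times / cc$bleach_tau_s) else rep(1, length(times))
  out <- list()
  idx <- 0
  for (cls in neuron_classes) {
    a_f <- lowPass(latentActivity(config, protocol, zt, cls, times),
                   times, cc$tau_sensor_s)
    for (j in seq_len(n)) {
      idx <- idx + 1
      counter <- 500000L + sum(utf8ToInt(cls)) * 1009L +
        as.integer(round(zt * 10)) * 97L + j
      tr <- withSubstream(config@master_seed, counter, {
        g_noise <- if (cc$noise_sd > 0) stats::rnorm(length(times), 0, cc$noise_sd) else 0
        t_noise <- if (cc$noise_sd > 0) stats::rnorm(length(times), 0, cc$noise_sd) else 0
        g_vals <- pmax(cc$f0_gcamp * (1 + cc$kappa * a_f) * bleach + g_noise, 0)
        t_vals <- pmax(cc$f0_tdtom * bleach + t_noise, 0)
        roi <- sprintf("%s_zt%04.1f_%02d", cls, zt, j)
        list(gcamp = fluorescenceTrace(times, g_vals, roi_id = roi,
                                       neuron_class = cls, channel = "GCaMP",
                                       zt = zt),
             tdtom = fluorescenceTrace(times, t_vals, roi_id = roi,
                                       neuron_class = cls,
                                       channel = "tdTomato", zt = zt))
      })
      out[[idx]] <- tr
    }
  }
  out
}

#' Generate the four phase-shifted long-term recording groups
#'
#' Emulates the long-term protocol used to assemble a 24-h diurnal calcium
#' curve: four cohorts entrained with light-schedule shifts of 0, 6, 12 and
#' 18 h, each fly imaged every 30 min over 6 h of its local time (13
#' samples). The ratiometric value at each sample equals the diurnal
#' baseline b(zt) plus noise; both raw channel sums are returned, sharing a
#' common bleaching drift so the ratio cancels it exactly.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param n_per_group flies per group.
#' @return list of four \linkS4class{DiurnalGroup} (shifts 0, 6, 12, 18).
#' @export
genDiurnalGroups <- function(config, n_per_group = 6) {
  cc <- config@calcium
  shifts <- c(0, 6, 12, 18)
  local_t <- seq(0, 6, by = 0.5)
  lapply(shifts, function(sh) {
    rows <- list()
    for (i in seq_len(n_per_group)) {
      rows[[i]] <- withSubstream(config@master_seed,
                                 700000L + sh * 4000L + i, {
        zt <- ztWrap(local_t + sh)
        ratio <- cc$baseline_fun(zt) +
          if (cc$ratio_noise_sd > 0)
            stats::rnorm(length(zt), 0, cc$ratio_noise_sd) else 0
        drift <- if (is.finite(cc$bleach_tau_s))
          exp(-(local_t * 3600) / cc$bleach_tau_s) else rep(1, length(local_t))
        tdtom <- cc$f0_tdtom * drift
        data.frame(fly_id = sprintf("g%02d_fly%02d", sh, i),
                   local_time_h = local_t,
                   gcamp = pmax(ratio, 1e-6) * tdtom, tdtom = tdtom)
      })
    }
    new("DiurnalGroup", shift_h = sh, data = do.call(rbind, rows))
  })
}
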