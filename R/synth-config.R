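## Synthetic-data configuration. The defaults ARE the emulated study
## conditions: a bimodal diurnal activity pattern whose evening peak shifts
## with temperature, night sleep that shrinks in the heat, a diurnal calcium
## baseline rising through the day and falling at night, circadian-gated
## saturating temperature-step responses (clamping 6 degC below baseline for
## cooling, 8 degC above for heating), and inhibitory DN1a -> LNd / DN1a ->
## DN3 coupling.

#' SynthConfig: parameters of the synthetic-data generator
#'
#' All planted parameters downstream recovery tests rely on live here. Use
#' \code{\link{synthConfig}} to build one; validity checks the invariants
#' (wake probability in [0,1], gating non-negative, positive peak widths).
#'
#' @slot master_seed integer master seed; per-fly / per-trace substreams are
#'   derived from it by counter, so adding flies never reshuffles earlier
#'   ones.
#' @slot n_flies,n_days cohort size and days per condition.
#' @slot lights_on,lights_off ZT hours of the light schedule.
#' @slot epoch_s locomotion epoch length (s), default 10.
#' @slot activity list: \code{lambda_b} baseline Poisson rate (counts/epoch),
#'   morning peak (\code{t_m}, \code{sigma_m}, \code{a_m}) and evening peak
#'   (\code{t_e}, \code{sigma_e}, \code{a_e}) as circular Gaussian bumps.
#' @slot wake_prob function(zt) -> stationary wake probability in [0,1].
#' @slot switch_rate per-epoch rate scale of the two-state wake/sleep chain.
#' @slot siesta_window,night_window ZT windows the condition deltas act on.
#' @slot temp_effects named list per temperature condition, each with
#'   \code{t_e_shift_h}, \code{night_wake_delta}, \code{siesta_delta},
#'   \code{rate_mult}.
#' @slot calcium list of calcium-trace parameters: \code{baseline_fun} b(zt)
#'   (ratiometric units), \code{gating_fun} g(zt) >= 0, \code{gain} named
#'   per neuron class, \code{coupling} named negative weights for
#'   DN1a-driven inhibition of LNd and DN3, saturation limits
#'   \code{dt_sat_cool} (6) and \code{dt_sat_heat} (8) in degC,
#'   \code{tau_sensor_s} sensor time constant, \code{kappa} fractional
#'   fluorescence gain per unit latent activity, \code{f0_gcamp},
#'   \code{f0_tdtom} resting intensities, \code{bleach_tau_s},
#'   \code{noise_sd} (a.u. per sample), \code{ratio_noise_sd} (ratio units,
#'   long-term sampling), \code{residual_coupling} fraction of coupling that
#'   survives DN1a ablation.
#' @slot ablate_dn1a logical; if TRUE the DN1a->target coupling is reduced
#'   to its residual fraction.
#' @export
setClass("SynthConfig",
  representation(master_seed = "integer", n_flies = "integer",
                 n_days = "integer", lights_on = "numeric",
                 lights_off = "numeric", epoch_s = "numeric",
                 activity = "list", wake_prob = "function",
                 switch_rate = "numeric", siesta_window = "numeric",
                 night_window = "numeric", temp_effects = "list",
                 calcium = "list", ablate_dn1a = "logical"),
  validity = function(object) {
    zt <- seq(0, 24, by = 0.05)
    w <- object@wake_prob(zt)
    if (any(w < 0 | w > 1)) return("wake_prob must map into [0, 1]")
    g <- object@calcium$gating_fun(zt)
    if (any(g < 0)) return("gating_fun must be >= 0")
    a <- object@activity
    if (a$sigma_m <= 0 || a$sigma_e <= 0) return("peak widths must be > 0")
    if (object@n_flies < 1) return("n_flies must be >= 1")
    if (object@switch_rate <= 0 || object@switch_rate > 1)
      return("switch_rate must be in (0, 1]")
    if (object@calcium$tau_sensor_s <= 0) return("tau_sensor_s must be > 0")
    if (object@calcium$f0_gcamp <= 0 || object@calcium$f0_tdtom <= 0)
      return("resting intensities must be > 0")
    for (eff in object@temp_effects) {
      if (!all(c("t_e_shift_h", "night_wake_delta", "siesta_delta",
                 "rate_mult") %in% names(eff)))
        return("each temp_effects entry needs t_e_shift_h, night_wake_delta, siesta_delta, rate_mult")
    }
    TRUE
  })

#' One temperature-condition effect
#'
#' @param t_e_shift_h shift of the evening activity peak (h; negative =
#'   advanced).
#' @param night_wake_delta added to the wake probability in the night window.
#' @param siesta_delta added to the wake probability in the siesta window.
#' @param rate_mult multiplier on the movement rate.
#' @return a named list usable inside \code{temp_effects}.
#' @export
tempEffect <- function(t_e_shift_h = 0, night_wake_delta = 0,
                       siesta_delta = 0, rate_mult = 1) {
  list(t_e_shift_h = t_e_shift_h, night_wake_delta = night_wake_delta,
       siesta_delta = siesta_delta, rate_mult = rate_mult)
}

## Default diurnal wake-probability profile: alert after lights-on, midday
## siesta, a second alert phase around the evening peak, consolidated night
## sleep.
defaultWakeProb <- function(zt) {
  zt <- ztWrap(zt)
  ifelse(zt < 4, 0.80, ifelse(zt < 8, 0.45, ifelse(zt < 12, 0.85, 0.25)))
}

## Diurnal calcium baseline (ratiometric units): rises through the day,
## peaks late-day, falls at night.
defaultBaselineFun <- function(zt) 1 + 0.4 * cos(2 * pi * (ztWrap(zt) - 10) / 24)

## Circadian gating of temperature-step responses: strong in the evening
## (ZT10-14) and around midnight (ZT17-19), weak otherwise (4:1).
defaultGatingFun <- function(zt) {
  zt <- ztWrap(zt)
  ifelse((zt >= 10 & zt < 14) | (zt >= 17 & zt < 19), 4, 1)
}

#' Build a synthetic-data configuration
#'
#' Returns a \linkS4class{SynthConfig} holding the emulated study
#' conditions. Defaults: 12:12 LD; baseline movement rate 0.1 counts/epoch
#' with morning (ZT1) and evening (ZT11) activity peaks; the cold condition
#' ("18C") advances the evening peak by 1 h, multiplies the movement rate by
#' 1.30 and raises siesta-window wakefulness; the hot condition ("30C")
#' delays the evening peak by 1 h, multiplies the rate by 1.50 and raises
#' night wakefulness by 0.30. Calcium: step responses saturate 6 degC below
#' baseline (cooling) and 8 degC above (heating); gating is 4x stronger in
#' ZT10-14 and ZT17-19 than elsewhere; coupling DN1a->LNd = -0.6 and
#' DN1a->DN3 = -0.8.
#'
#' @param master_seed integer master seed.
#' @param n_flies,n_days cohort size, days per condition.
#' @param ... any slot-level override (same names as the slots /
#'   sub-lists; \code{activity}, \code{calcium} and \code{temp_effects}
#'   entries are merged into the defaults).
#' @return a validated \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(master_seed = 1, n_flies = 4)
#' @export
synthConfig <- function(master_seed = 1L, n_flies = 8L, n_days = 1L, ...) {
  defaults <- list(
    lights_on = 0, lights_off = 12, epoch_s = 10,
    activity = list(lambda_b = 0.1, t_m = 1, sigma_m = 1.0, a_m = 1.2,
                    t_e = 11, sigma_e = 1.5, a_e = 1.5),
    wake_prob = defaultWakeProb,
    switch_rate = 0.05,
    siesta_window = c(4, 8), night_window = c(12, 24),
    temp_effects = list(
      "24C" = tempEffect(),
      "22C" = tempEffect(),
      "18C" = tempEffect(t_e_shift_h = -1, siesta_delta = 0.15,
                         rate_mult = 1.30),
      "30C" = tempEffect(t_e_shift_h = 1, night_wake_delta = 0.30,
                         rate_mult = 1.50)),
    calcium = list(baseline_fun = defaultBaselineFun,
                   gating_fun = defaultGatingFun,
                   gain = c(DN1a = 0.08, LNd = 0, DN3 = 0),
                   coupling = c(LNd = -0.6, DN3 = -0.8),
                   dt_sat_cool = 6, dt_sat_heat = 8,
                   tau_sensor_s = 15, kappa = 0.8,
                   f0_gcamp = 100, f0_tdtom = 50,
                   bleach_tau_s = Inf, noise_sd = 0,
                   ratio_noise_sd = 0, residual_coupling = 0),
    ablate_dn1a = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown synthConfig fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  for (nm in names(over)) {
    if (nm %in% c("activity", "calcium") && is.list(over[[nm]])) {
      defaults[[nm]][names(over[[nm]])] <- over[[nm]]
    } else if (nm == "temp_effects") {
      defaults$temp_effects[names(over$temp_effects)] <- over$temp_effects
    } else defaults[[nm]] <- over[[nm]]
  }
  new("SynthConfig", master_seed = as.integer(master_seed),
      n_flies = as.integer(n_flies), n_days = as.integer(n_days),
      lights_on = defaults$lights_on, lights_off = defaults$lights_off,
      epoch_s = defaults$epoch_s, activity = defaults$activity,
      wake_prob = defaults$wake_prob, switch_rate = defaults$switch_rate,
      siesta_window = defaults$siesta_window,
      night_window = defaults$night_window,
      temp_effects = defaults$temp_effects, calcium = defaults$calcium,
      ablate_dn1a = defaults$ablate_dn1a)
}

## Condition lookup with an explicit failure naming valid labels.
conditionEffect <- function(config, condition) {
  eff <- config@temp_effects[[condition]]
  if (is.null(eff))
    stop(sprintf("unknown condition '%s'; valid conditions: %s", condition,
                 paste(names(config@temp_effects), collapse = ", ")),
         call. = FALSE)
  eff
}

## Movement rate lambda(zt) under a condition (counts per epoch while awake).
conditionRate <- function(config, condition, zt) {
  a <- config@activity
  eff <- conditionEffect(config, condition)
  (a$lambda_b +
     a$a_m * ztBump(zt, a$t_m, a$sigma_m) +
     a$a_e * ztBump(zt, ztWrap(a$t_e + eff$t_e_shift_h), a$sigma_e)) *
    eff$rate_mult
}

## Stationary wake probability w(zt) under a condition, clamped to [0, 1].
conditionWakeProb <- function(config, condition, zt) {
  eff <- conditionEffect(config, condition)
  w <- config@wake_prob(zt)
  w <- w + eff$night_wake_delta * ztInWindow(zt, config@night_window)
  w <- w + eff$siesta_delta * ztInWindow(zt, config@siesta_window)
  pmin(pmax(w, 0), 1)
}
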