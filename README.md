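# ThermoClock

Quantitative analysis of temperature encoding in the *Drosophila*
circadian circuit, for chronobiologists working with camera-based
sleep/locomotion monitors, two-photon GCaMP imaging under Peltier
temperature control, and connectome exports.

Flies shift their behavior with ambient temperature: cooling advances the
evening activity peak, heating delays its offset and erodes night sleep.
These behavioral shifts are driven by temperature-sensitive clock neurons
(DN1a) whose calcium responses saturate a few degrees from baseline, are
gated by circadian time, and propagate through inhibitory synapses onto
downstream clock neurons (LNd, DN3). ThermoClock implements the complete
quantification chain for this biology:

* **Sleep & behavior** — SCAMP-convention sleep scoring (≥5 min immobility
  at 10-s epochs), 30-min activity binning, evening-peak timing, and the
  four published temperature-response indices, e.g. the evening-peak
  advance index

  `E = (mean ZT6–12 movement at 18 °C − at 24 °C) / at 24 °C`

  computed per fly with group mean ± SEM, one-way ANOVA + Tukey HSD, and a
  compact letter display.
* **Calcium quantification** — ΔF/F₀ = (Fₜ − F₀)/F₀ × 100 % and
  ΔFmax/F₀, temperature-step fold change post/pre with responder
  classification (±2 baseline SDs), saturation summaries across step
  amplitudes, ratiometric (GCaMP/tdTomato) normalization, circadian gating
  profiles with bootstrap CIs, trace correlation/clustering, and paired
  pre/post locomotion comparison.
* **Diurnal curve** — reconstruction of the 24-h DN1a calcium curve by
  stitching four recording groups entrained with 6-h light-schedule
  shifts, each sampled every 30 min over 6 h, with double-plot export.
* **Connectome** — neuPrint-style synapse tables aggregated by cell type,
  thresholded partner rankings, and Sankey node/link JSON.
* **Synthetic data** — a seeded generator planting every parameter above
  (evening-peak shifts, wake-probability changes, saturation limits 6/8 °C,
  4:1 circadian gating, inhibitory DN1a→LNd/DN3 coupling), so the whole
  pipeline is testable with no external data.

## Worked example

```r
library(ThermoClock)

cfg  <- synthConfig(master_seed = 7, n_flies = 8)    # planted study conditions
recs <- c(genActivity(cfg, "24C"), genActivity(cfg, "18C"))

epeakAdvanceIndex(recs)
#> IndexResult epeak_advance [18C vs 24C, ZT 6-12]: 0.5927 +/- 0.0532 (n = 8)
```

The cohort's evening-peak advance index is 0.59 ± 0.05: cooling to 18 °C
raised ZT6–12 locomotion by ~59 % over the 24 °C day. The generator's
deterministic oracle gives the expectation for this configuration:

```r
ew <- function(cond) expectedWindowMean(cfg, cond, c(6, 12))$window_mean
(ew("18C") - ew("24C")) / ew("24C")
#> [1] 0.5340516
```

so the recovered index sits within sampling error of the planted effect.
The same records score sleep, and a synthetic cooling step at night is
quantified against its tdTomato partner:

```r
scoreSleep(recs[[1]])
#> SleepSeries: 37 bouts, 819 sleep min of 1440

proto <- temperatureProtocol(24, data.frame(onset_s = 60, target_c = 18,
                                            ramp_s = 80), span_s = 300)
pair <- genTwoChannelTraces(synthConfig(7, calcium = list(noise_sd = 2)),
                            proto, zt = 18, n = 1)[[1]]
quantifyStepResponse(pair$gcamp, proto, pre_s = 40, post_s = 120,
                     tdtom = pair$tdtom)
#> TemperatureResponse DN1a_zt18.0_01 (DN1a, ZT 18.0, dT -6.0 degC): fold 0.843, inhibited
```

A 6 °C cooling step at ZT18 drops the ratiometric signal to 0.84 of
baseline — an inhibited classification, as planted. Connectome ranking
recovers planted synapse weights exactly:

```r
tab <- genSynapseTable(cfg, data.frame(type_pre = "DN1a",
                                       type_post = c("DN3", "LNd", "KC"),
                                       weight = c(50L, 30L, 10L)))
rankPartners(tab, "DN1a", "downstream")
#> PartnerRanking: downstream of DN1a (min weight 1, dropped 0)
#>   partner_type total_weight n_partner_bodies
#> 1          DN3           50                3
#> 2          LNd           30                4
#> 3           KC           10                3
```

`runReport(out_dir, seed)` executes the full chain (generate → score →
indices → curve → ranking) and writes every table plus a manifest that
reproduces the run byte-for-byte. A subcommand CLI wrapping the same
functions is in `inst/scripts/thermoclock`.

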