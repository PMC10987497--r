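# dF/F0 arithmetic, step-response quantification, saturation, clustering,
# and the locomotion comparison.

test_that("dF/F0 follows the definition and its invariances", {
  tr <- fluorescenceTrace(0:9, rep(100, 10))
  expect_equal(dffValues(computeDff(tr, c(0, 5))), rep(0, 10))
  tr2 <- fluorescenceTrace(0:9, c(rep(100, 5), 150, rep(100, 4)))
  d <- computeDff(tr2, c(0, 5))
  expect_equal(f0(d), 100)
  expect_equal(dffValues(d)[6], 50)           # (150-100)/100 x 100%
  # exact multiplicative scale invariance
  tr3 <- fluorescenceTrace(0:9, 2.7 * c(rep(100, 5), 150, rep(100, 4)))
  expect_equal(dffValues(computeDff(tr3, c(0, 5))), dffValues(d))
  # additive offsets are deliberately NOT invariant
  tr4 <- fluorescenceTrace(0:9, 50 + c(rep(100, 5), 150, rep(100, 4)))
  expect_false(isTRUE(all.equal(dffValues(computeDff(tr4, c(0, 5))),
                                dffValues(d))))
  # literal F0 = fluorescence at the first sample of the window
  tr5 <- fluorescenceTrace(0:9, c(80, rep(120, 9)))
  expect_equal(f0(computeDff(tr5, c(0, 5), f0_method = "literal")), 80)
})

test_that("dF/F0 rejects non-physical baselines and empty windows", {
  tr <- fluorescenceTrace(0:9, c(rep(0, 5), rep(10, 5)))
  expect_error(computeDff(tr, c(0, 5)), "F0")
  expect_error(computeDff(tr, c(100, 110)), "no samples")
})

test_that("max dF/F0 equals an exhaustive scan, signed variant keeps sign", {
  d <- new("DeltaFTrace", roi_id = "r", times = as.numeric(0:3),
           dff = c(0, 10, 50, 20), f0 = 100, baseline_window = c(0, 1))
  expect_equal(computeMaxDff(d, c(0, 4)), 50)
  d0 <- new("DeltaFTrace", roi_id = "r", times = as.numeric(0:3),
            dff = rep(0, 4), f0 = 100, baseline_window = c(0, 1))
  expect_equal(computeMaxDff(d0, c(0, 4)), 0)
  set.seed(9)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    d <- new("DeltaFTrace", roi_id = "r", times = as.numeric(seq_len(n)),
             dff = rnorm(n, sd = 40), f0 = 100, baseline_window = c(0, 1))
    w <- sort(sample(seq_len(n), 2))
    sel <- d@times >= w[1] & d@times < w[2]
    if (!any(sel)) next
    brute <- -Inf
    for (v in d@dff[sel]) brute <- max(brute, v)
    expect_equal(computeMaxDff(d, w), brute)
    sgn <- d@dff[sel][which.max(abs(d@dff[sel]))]
    expect_equal(computeMaxDff(d, w, signed = TRUE), sgn)
  }
  expect_error(computeMaxDff(d0, c(50, 60)), "no samples")
})

test_that("step responses classify by the baseline-SD rule", {
  proto <- coolingProtocol()
  flat <- fluorescenceTrace(seq(0, 300, 2), rep(100, 151))
  r <- quantifyStepResponse(flat, proto, pre_s = 40, post_s = 120)
  expect_equal(r@fold_change, 1)
  expect_identical(r@response_class, "nonresponsive")
  # noiseless synthetic heating with positive gain: activated, fold > 1
  cfg <- synthConfig(1, calcium = list(noise_sd = 0))
  heat <- coolingProtocol(baseline = 22, target = 30)
  pr <- genTwoChannelTraces(cfg, heat, zt = 12, n = 1)[[1]]
  r <- quantifyStepResponse(pr$gcamp, heat, pre_s = 40, post_s = 120,
                            tdtom = pr$tdtom)
  expect_gt(r@fold_change, 1)
  expect_identical(r@response_class, "activated")
  expect_equal(r@delta_t_c, 8)
  expect_error(quantifyStepResponse(flat, proto, pre_s = 40, post_s = 120,
                                    step_index = 2), "step_index")
  expect_error(quantifyStepResponse(flat, proto, pre_s = 40,
                                    post_delay_s = -120), "overlap")
})

test_that("mean fold change of noisy traces matches the noiseless expectation", {
  heat <- coolingProtocol(baseline = 22, target = 30)
  cfg0 <- synthConfig(2, calcium = list(noise_sd = 0))
  pr0 <- genTwoChannelTraces(cfg0, heat, zt = 12, n = 1)[[1]]
  expected <- quantifyStepResponse(pr0$gcamp, heat, pre_s = 40,
                                   post_s = 120,
                                   tdtom = pr0$tdtom)@fold_change
  cfg <- synthConfig(2, calcium = list(noise_sd = 3))
  prs <- genTwoChannelTraces(cfg, heat, zt = 12, n = 16)
  folds <- vapply(prs, function(pr)
    quantifyStepResponse(pr$gcamp, heat, pre_s = 40, post_s = 120,
                         tdtom = pr$tdtom)@fold_change, 0)
  se <- sd(folds) / sqrt(length(folds))
  expect_lt(abs(mean(folds) - expected), 3 * se)
})

test_that("ratiometric fold change ignores common multiplicative drift", {
  heat <- coolingProtocol(baseline = 22, target = 30)
  cfg <- synthConfig(3, calcium = list(noise_sd = 0))
  pr <- genTwoChannelTraces(cfg, heat, zt = 12, n = 1)[[1]]
  r0 <- quantifyStepResponse(pr$gcamp, heat, pre_s = 40, post_s = 120,
                             tdtom = pr$tdtom)
  drift <- exp(-traceTimes(pr$gcamp) / 150)
  g2 <- fluorescenceTrace(traceTimes(pr$gcamp),
                          traceValues(pr$gcamp) * drift, zt = 12)
  t2 <- fluorescenceTrace(traceTimes(pr$tdtom),
                          traceValues(pr$tdtom) * drift,
                          channel = "tdTomato", zt = 12)
  r1 <- quantifyStepResponse(g2, heat, pre_s = 40, post_s = 120, tdtom = t2)
  expect_equal(r1@fold_change, r0@fold_change, tolerance = 1e-9)
})

test_that("response class is monotone in the planted gain", {
  heat <- coolingProtocol(baseline = 22, target = 30)
  fold_at <- function(g) {
    cfg <- synthConfig(4, calcium = list(noise_sd = 0,
                                         gain = c(DN1a = g, LNd = 0, DN3 = 0)))
    pr <- genTwoChannelTraces(cfg, heat, zt = 12, n = 1)[[1]]
    quantifyStepResponse(pr$gcamp, heat, pre_s = 40, post_s = 120,
                         tdtom = pr$tdtom)@fold_change
  }
  folds <- vapply(c(0.01, 0.03, 0.06, 0.09), fold_at, 0)
  expect_true(all(diff(folds) > 0))
  expect_true(all(folds > 1))
})

test_that("saturation summary clamps and handles degenerate n", {
  # near-instant sensor so post-window means carry no ramp transient
  cfg <- synthConfig(5, calcium = list(noise_sd = 0, tau_sensor_s = 0.01))
  resp <- list()
  for (dt in c(-2, -4, -6, -8, -10)) {
    p <- coolingProtocol(target = 24 + dt)
    pr <- genTwoChannelTraces(cfg, p, zt = 12, n = 1)[[1]]
    resp <- c(resp, list(quantifyStepResponse(pr$gcamp, p, pre_s = 40,
                                              post_s = 120,
                                              tdtom = pr$tdtom)))
  }
  s <- saturationSummary(resp)$cooling
  means <- s$table$mean[s$table$abs_dt >= 6]
  expect_lt(diff(range(means)), 1e-6 * abs(mean(means)))
  expect_equal(s$sat_dt, 6)
  expect_true(all(is.na(s$table$sem)))  # single trace per amplitude
  expect_error(saturationSummary(resp[1]), "distinct")
})

test_that("correlation and clustering are exact on constructed traces", {
  mk <- function(v, id) new("DeltaFTrace", roi_id = id,
                            times = as.numeric(seq_along(v)), dff = v,
                            f0 = 100, baseline_window = c(0, 1))
  v <- sin(seq(0, 6, length.out = 50)) * 30
  dup <- list(a = mk(v, "a"), b = mk(v, "b"), neg = mk(-v, "neg"))
  cl <- correlateAndCluster(dup, k = 2)
  expect_equal(cl$correlation["a", "b"], 1)
  expect_equal(cl$correlation["a", "neg"], -1)
  expect_equal(cl$labels[["a"]], cl$labels[["b"]])
  expect_false(cl$labels[["a"]] == cl$labels[["neg"]])
  # zero-variance trace: NA correlations, excluded with a warning
  flat <- c(dup, list(z = mk(rep(0, 50), "z")))
  expect_warning(cl2 <- correlateAndCluster(flat), "zero-variance")
  expect_true(all(is.na(cl2$correlation["z", c("a", "b", "neg")])))
  expect_true(is.na(cl2$labels[["z"]]))
  # determinism of the leaf order
  expect_identical(cl$leaf_order, correlateAndCluster(dup, k = 2)$leaf_order)
})

test_that("locomotion change handles identical, silenced and single flies", {
  t <- seq(0, 120, 0.5)
  mkfly <- function(id, speed) data.frame(fly_id = id, time_s = t,
                                          speed = speed)
  same <- rbind(mkfly("f1", rep(2, length(t))), mkfly("f2", rep(3, length(t))))
  res <- locomotionChange(same, event_s = 60, pre_s = 60, post_s = 60)
  expect_equal(res$mean_diff, 0)
  expect_equal(res$p_value, 1)
  stopped <- rbind(mkfly("f1", ifelse(t < 60, 2, 0)),
                   mkfly("f2", ifelse(t < 60, 3, 0)))
  res2 <- locomotionChange(stopped, event_s = 60)
  expect_lt(res2$mean_diff, 0)
  single <- mkfly("f1", rep(1, length(t)))
  expect_true(is.na(locomotionChange(single, event_s = 60)$p_value))
})
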