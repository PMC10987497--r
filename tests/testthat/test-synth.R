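# Synthetic-data generator: determinism, planted-parameter structure, and
# oracle agreement.

test_that("identical config and seed give bit-identical outputs", {
  cfg <- synthConfig(7, n_flies = 3)
  expect_identical(genActivity(cfg, "24C"), genActivity(cfg, "24C"))
  proto <- coolingProtocol()
  expect_identical(genTwoChannelTraces(cfg, proto, zt = 12, n = 2),
                   genTwoChannelTraces(cfg, proto, zt = 12, n = 2))
  expect_identical(genDiurnalGroups(cfg, 3), genDiurnalGroups(cfg, 3))
})

test_that("adding flies never reshuffles earlier flies", {
  small <- genActivity(synthConfig(7, n_flies = 2), "24C")
  big <- genActivity(synthConfig(7, n_flies = 5), "24C")
  expect_identical(small, big[1:2])
})

test_that("zero-rate and always-asleep degenerate cohorts behave as stated", {
  # lambda = 0, always awake: all counts zero
  recs <- genActivity(quietConfig(n_flies = 2), "24C")
  expect_true(all(vapply(recs, function(r) sum(activityCounts(r)), 0) == 0))
  # w = 0: every epoch inactive, downstream scoring gives full-day sleep
  asleep_cfg <- synthConfig(1, n_flies = 2,
                            wake_prob = function(zt) rep(0, length(zt)))
  recs <- genActivity(asleep_cfg, "24C")
  ss <- scoreSleep(recs[[1]])
  expect_equal(sum(sleepState(ss)) * 10 / 60, 1440)
  expect_equal(nrow(sleepBouts(ss)), 1)
})

test_that("unknown condition labels fail naming the valid ones", {
  cfg <- synthConfig(1)
  expect_error(genActivity(cfg, "12C"), "valid conditions.*24C")
})

test_that("step-response function saturates exactly and monotonically", {
  dts <- seq(-12, 12, by = 0.25)
  r <- stepResponseFun(dts, dt_sat_cool = 6, dt_sat_heat = 8)
  expect_true(all(abs(r) <= 1))
  # |R| non-decreasing in |dT| on each side
  cool <- r[dts <= 0]
  expect_true(all(diff(abs(cool[order(abs(dts[dts <= 0]))])) >= 0))
  expect_identical(stepResponseFun(-6), stepResponseFun(-10))
  expect_identical(stepResponseFun(8), stepResponseFun(12))
  expect_equal(stepResponseFun(-3), -0.5)
  expect_equal(stepResponseFun(4), 0.5)
})

test_that("zero gain and zero noise give a constant GCaMP/tdTomato ratio", {
  cfg <- synthConfig(1, calcium = list(gain = c(DN1a = 0, LNd = 0, DN3 = 0),
                                       noise_sd = 0, bleach_tau_s = 600))
  pr <- genTwoChannelTraces(cfg, coolingProtocol(), zt = 12, n = 1)[[1]]
  ratio <- traceValues(pr$gcamp) / traceValues(pr$tdtom)
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("coupling inverts the evoked response sign in coupled classes", {
  cfg <- synthConfig(1, calcium = list(noise_sd = 0))
  heat <- coolingProtocol(baseline = 22, target = 30)
  pre <- function(tr) mean(traceValues(tr)[traceTimes(tr) < 60])
  post <- function(tr) mean(traceValues(tr)[traceTimes(tr) > 200])
  dn1a <- genTwoChannelTraces(cfg, heat, zt = 18, "DN1a", n = 1)[[1]]$gcamp
  dn3 <- genTwoChannelTraces(cfg, heat, zt = 18, "DN3", n = 1)[[1]]$gcamp
  expect_gt(post(dn1a), pre(dn1a))   # heating activates DN1a
  expect_lt(post(dn3), pre(dn3))     # and inhibits DN3 via the coupling
  cool <- coolingProtocol()
  dn1a_c <- genTwoChannelTraces(cfg, cool, zt = 18, "DN1a", n = 1)[[1]]$gcamp
  dn3_c <- genTwoChannelTraces(cfg, cool, zt = 18, "DN3", n = 1)[[1]]$gcamp
  expect_lt(post(dn1a_c), pre(dn1a_c))
  expect_gt(post(dn3_c), pre(dn3_c))
})

test_that("DN1a ablation removes the coupled response up to the residual", {
  base <- list(noise_sd = 0)
  cfg <- synthConfig(1, calcium = base)
  cfg_abl <- synthConfig(1, calcium = base, ablate_dn1a = TRUE)
  heat <- coolingProtocol(baseline = 22, target = 30)
  resp <- function(cfg) {
    tr <- genTwoChannelTraces(cfg, heat, zt = 18, "DN3", n = 1)[[1]]$gcamp
    mean(traceValues(tr)[traceTimes(tr) > 200]) -
      mean(traceValues(tr)[traceTimes(tr) < 60])
  }
  expect_lt(resp(cfg), 0)
  expect_equal(resp(cfg_abl), 0, tolerance = 1e-9)
})

test_that("expected_window_mean trivials and two computation routes agree", {
  cfg <- flatAwakeConfig(lambda = 1)
  ew <- expectedWindowMean(cfg, "24C", c(0, 24))
  expect_equal(ew$expected, rep(180, 48))   # 180 epochs per 30-min bin
  asleep <- synthConfig(1, wake_prob = function(zt) rep(0, length(zt)))
  expect_equal(expectedWindowMean(asleep, "24C", c(0, 24))$window_mean, 0)
  # analytic chain-marginal integration vs direct cohort simulation
  cfg <- synthConfig(11)
  an <- expectedWindowMean(cfg, "18C", c(6, 12))
  si <- expectedWindowMean(cfg, "18C", c(6, 12), method = "simulation",
                           n_sim = 4000)
  expect_equal(si$window_mean, an$window_mean,
               tolerance = 0.05 * an$window_mean)
  expect_identical(an$method, "analytic")
})

test_that("empirical cohort means match the analytic oracle within 3 SE", {
  cfg <- synthConfig(5, n_flies = 200)
  recs <- genActivity(cfg, "24C")
  m <- vapply(recs, function(r) {
    bins <- bruteForceBin(activityCounts(r))
    mean(bins[13:24])   # ZT6-12
  }, 0)
  an <- expectedWindowMean(cfg, "24C", c(6, 12))$window_mean
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - an), 3 * se)
})

test_that("diurnal groups cover ZT 0-24 in four contiguous 6-h windows", {
  cfg <- synthConfig(1, calcium = list(ratio_noise_sd = 0))
  groups <- genDiurnalGroups(cfg, 2)
  expect_equal(vapply(groups, function(g) g@shift_h, 0), c(0, 6, 12, 18))
  covered <- sort(unique(unlist(lapply(groups, function(g)
    (g@data$local_time_h + g@shift_h) %% 24))))
  expect_equal(covered, seq(0, 23.5, by = 0.5))
  # noiseless constant baseline: every ratio sample equal
  cfg_const <- synthConfig(1, calcium = list(
    baseline_fun = function(zt) rep(2, length(zt)), ratio_noise_sd = 0))
  g <- genDiurnalGroups(cfg_const, 2)[[1]]
  expect_equal(g@data$gcamp / g@data$tdtom, rep(2, nrow(g@data)))
  expect_equal(length(unique(g@data$local_time_h)), 13)
})

test_that("synapse tables recover planted type-pair weights exactly", {
  cfg <- synthConfig(3)
  planted <- data.frame(type_pre = "DN1a",
                        type_post = c("DN3", "LNd", "KC"),
                        weight = c(50L, 30L, 10L))
  tab <- genSynapseTable(cfg, planted)
  con <- connections(tab)
  agg <- tapply(con$weight, con$type_post, sum)
  expect_equal(as.numeric(agg[c("DN3", "LNd", "KC")]), c(50, 30, 10))
  expect_false(any(duplicated(paste(con$bodyId_pre, con$bodyId_post))))
  expect_equal(nrow(connections(genSynapseTable(cfg, planted[0, ]))), 0)
})

test_that("random planted maps round-trip through aggregation", {
  set.seed(42)
  for (trial in 1:20) {
    k <- sample(2:6, 1)
    planted <- data.frame(
      type_pre = sample(c("A", "B"), k, replace = TRUE),
      type_post = paste0("P", seq_len(k)),
      weight = sample(1:200, k, replace = TRUE))
    con <- connections(genSynapseTable(synthConfig(trial), planted))
    agg <- tapply(con$weight,
                  paste(con$type_pre, con$type_post, sep = "->"), sum)
    want <- tapply(planted$weight,
                   paste(planted$type_pre, planted$type_post, sep = "->"),
                   sum)
    expect_equal(agg[names(want)], want)
  }
})

test_that("config validation rejects broken invariants", {
  expect_error(synthConfig(1, wake_prob = function(zt) zt / 10 - 0.5),
               "wake_prob")
  expect_error(synthConfig(1, calcium = list(
    gating_fun = function(zt) rep(-1, length(zt)))), "gating_fun")
  expect_error(synthConfig(1, activity = list(sigma_e = -1)), "widths")
})
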