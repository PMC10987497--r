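# Sleep scoring, activity binning, evening-peak timing, the four indices,
# and group statistics with compact letters.

test_that("sleep scoring handles the degenerate extremes", {
  all0 <- activityRecord(rep(0L, 8640))
  ss <- scoreSleep(all0)
  expect_equal(nrow(sleepBouts(ss)), 1)
  expect_equal(sleepBouts(ss)$length_epochs, 8640)
  expect_equal(sum(sleepState(ss)) * 10 / 60, 1440)
  # a count every 29th epoch: no inactivity run reaches 30 epochs
  counts <- integer(8640)
  counts[seq(29, 8640, by = 29)] <- 1L
  expect_equal(sum(sleepState(scoreSleep(activityRecord(counts)))), 0)
})

test_that("sleep scoring equals the brute-force run-length scanner", {
  set.seed(31)
  for (i in 1:200) {
    p <- runif(1, 0.005, 0.2)
    counts <- as.integer(rbinom(8640, 1, p) * rpois(8640, 2))
    ss <- scoreSleep(activityRecord(counts))
    oracle <- bruteForceSleepScan(counts)
    expect_identical(sleepState(ss), oracle$sleep)
    expect_equal(sleepBouts(ss), oracle$bouts)
    # conservation: sleep + wake minutes = 1440
    expect_equal(sum(sleepState(ss)) * 10 / 60 +
                   sum(!sleepState(ss)) * 10 / 60, 1440)
  }
})

test_that("scoring respects the inactivity threshold and bout length knobs", {
  counts <- integer(8640)
  counts[1:360] <- 1L            # one hour of count-1 epochs
  # threshold 0: the hour is active; threshold 1: it is one long bout
  expect_equal(sum(sleepState(scoreSleep(activityRecord(counts)))[1:360]), 0)
  expect_equal(sum(sleepState(scoreSleep(activityRecord(counts),
                                         inactive_threshold = 1L))), 8640)
  # a 40-epoch quiet gap: sleeps under the 5-min rule, not under 10 min
  counts2 <- rep(1L, 8640)
  counts2[101:140] <- 0L
  expect_equal(sum(sleepState(scoreSleep(activityRecord(counts2)))), 40)
  expect_equal(sum(sleepState(scoreSleep(activityRecord(counts2),
                                         min_bout_min = 10))), 0)
})

test_that("binned activity matches a naive double loop", {
  const <- activityRecord(rep(1L, 8640))
  prof <- binActivity(list(const))
  expect_equal(unname(binMeans(prof)), rep(180, 48))
  expect_true(all(is.na(binSems(prof))))   # single fly: SEM missing
  set.seed(7)
  recs <- lapply(1:3, function(i)
    activityRecord(as.integer(rpois(8640, 0.3)), fly_id = paste0("f", i)))
  prof <- binActivity(recs)
  brute <- sapply(recs, function(r) bruteForceBin(activityCounts(r)))
  expect_equal(unname(binMeans(prof)), unname(rowMeans(brute)))
  expect_equal(unname(binSems(prof)),
               unname(apply(brute, 1, sd) / sqrt(3)))
  expect_error(binActivity(recs, bin_min = 7), "divide")
})

test_that("activity indices are exact on constructed records", {
  # identical conditions: index 0
  base <- recordWithBins(rep(60L, 48), fly_id = "f1", temp_condition = "24C")
  same <- recordWithBins(rep(60L, 48), fly_id = "f1", temp_condition = "18C")
  idx <- suppressWarnings(epeakAdvanceIndex(list(base, same)))
  expect_equal(idx@mean, 0)
  # cold window mean exactly 2x control: index 1.0
  cold2 <- recordWithBins(rep(120L, 48), fly_id = "f1",
                          temp_condition = "18C")
  expect_equal(epeakAdvanceIndex(list(base, cold2))@mean, 1)
  # hot 1.5x control in ZT12-18: offset delay 0.5
  c22 <- recordWithBins(rep(60L, 48), fly_id = "f1", temp_condition = "22C")
  h30 <- recordWithBins(c(rep(60L, 24), rep(90L, 12), rep(60L, 12)),
                        fly_id = "f1", temp_condition = "30C")
  expect_equal(epeakOffsetDelayIndex(list(c22, h30))@mean, 0.5)
})

test_that("sleep indices carry the published signs", {
  # control: quiet (asleep) everywhere -> sleep 30 min per bin
  asleep24 <- activityRecord(rep(0L, 8640), fly_id = "f1",
                             temp_condition = "24C")
  asleep22 <- activityRecord(rep(0L, 8640), fly_id = "f1",
                             temp_condition = "22C")
  # cold day: alternating awake/asleep half-hours in ZT6-12 halve evening
  # sleep; awake bins end in a movement epoch so no quiet run reaches 5 min
  cold <- rep(0L, 8640)
  for (b in 12:23) if (b %% 2 == 0)
    cold[b * 180 + c(seq(1, 180, by = 25), 180)] <- 1L
  cold18 <- activityRecord(cold, fly_id = "f1", temp_condition = "18C")
  idx <- epeakSleepReductionIndex(list(asleep24, cold18), "cold")
  expect_equal(idx@mean, -0.5)
  # hot night: all sleep abolished -> night sleep reduction 1.0
  hot <- rep(0L, 8640)
  hot[seq(4321, 8640, by = 25)] <- 1L   # ZT12-24 never quiet for 5 min
  hot30 <- activityRecord(hot, fly_id = "f1", temp_condition = "30C")
  expect_equal(nightSleepReductionIndex(list(asleep22, hot30))@mean, 1)
  idx_hot <- epeakSleepReductionIndex(list(asleep22, hot30), "hot")
  expect_equal(idx_hot@mean, -1)  # as printed: (30C - 22C)/22C
})

test_that("zero denominators exclude flies with a warning, all-zero fails", {
  quiet <- recordWithBins(rep(0L, 48), fly_id = "f1",
                          temp_condition = "24C")
  cold <- recordWithBins(rep(10L, 48), fly_id = "f1",
                         temp_condition = "18C")
  expect_error(suppressWarnings(epeakAdvanceIndex(list(quiet, cold))),
               "excluded")
  active <- recordWithBins(rep(10L, 48), fly_id = "f2",
                           temp_condition = "24C")
  cold2 <- recordWithBins(rep(10L, 48), fly_id = "f2",
                          temp_condition = "18C")
  expect_warning(idx <- epeakAdvanceIndex(list(quiet, cold, active, cold2)),
                 "zero denominator")
  expect_equal(nrow(perFly(idx)), 1)
  expect_identical(idx@excluded, "f1")
})

test_that("planted cold and hot effects are recovered within 3 SE of the oracle", {
  cfg <- synthConfig(21, n_flies = 32)
  recs <- c(genActivity(cfg, "24C"), genActivity(cfg, "18C"))
  idx <- epeakAdvanceIndex(recs)
  e18 <- expectedWindowMean(cfg, "18C", c(6, 12))$window_mean
  e24 <- expectedWindowMean(cfg, "24C", c(6, 12))$window_mean
  expect_lt(abs(idx@mean - (e18 - e24) / e24), 3 * idx@sem)
  recs2 <- c(genActivity(cfg, "22C"), genActivity(cfg, "30C"))
  idx2 <- epeakOffsetDelayIndex(recs2)
  e30 <- expectedWindowMean(cfg, "30C", c(12, 18))$window_mean
  e22 <- expectedWindowMean(cfg, "22C", c(12, 18))$window_mean
  expect_lt(abs(idx2@mean - (e30 - e22) / e22), 3 * idx2@sem)
})

test_that("the oracle index is strictly monotone in the planted rate effect", {
  means <- vapply(c(1.1, 1.3, 1.5), function(m) {
    cfg <- synthConfig(1, temp_effects = list(
      "18C" = tempEffect(rate_mult = m)))
    e18 <- expectedWindowMean(cfg, "18C", c(6, 12))$window_mean
    e24 <- expectedWindowMean(cfg, "24C", c(6, 12))$window_mean
    (e18 - e24) / e24
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_equal(means, c(0.1, 0.3, 0.5), tolerance = 1e-9)
})

test_that("evening-peak timing finds peak, onset and offset", {
  mkprof <- function(v) new("ActivityProfile",
                            bin_centers = seq(0.25, 23.75, 0.5),
                            mean = v, sem = rep(NA_real_, 48), n = 1L)
  tri <- rep(0, 48)
  tri[19:27] <- c(1, 2, 3, 4, 5, 4, 3, 2, 1) * 10   # peak in bin 23
  tim <- epeakTiming(mkprof(tri))
  expect_equal(tim$peak_zt, 11.25)
  expect_equal(tim$onset_zt, 10.25)   # first bin >= 50% rise
  expect_equal(tim$offset_zt, 12.25)
  # two equal maxima: earlier bin wins (documented tie-break)
  twin <- rep(0, 48)
  twin[c(20, 24)] <- 50
  expect_equal(epeakTiming(mkprof(twin))$peak_zt, 9.75)
  flat <- epeakTiming(mkprof(rep(3, 48)))
  expect_true(all(is.na(unlist(flat))))
  # a planted evening-peak advance moves the onset by about the shift
  cfg <- synthConfig(33, n_flies = 24)
  t24 <- epeakTiming(binActivity(genActivity(cfg, "24C")))
  t18 <- epeakTiming(binActivity(genActivity(cfg, "18C")))
  expect_lt(abs((t24$onset_zt - t18$onset_zt) - 1), 0.51)
})

test_that("group statistics produce letters consistent with the tests", {
  # identically distributed groups: one shared letter via the ANOVA path
  vals <- rep(c(1, 2, 3), times = 3)
  gs <- groupStats(vals, rep(c("g1", "g2", "g3"), each = 3))
  expect_equal(length(unique(gs$letters)), 1)
  # exact ties everywhere: test skipped with a message, letters by equality
  expect_message(gs0 <- groupStats(rep(5, 9), rep(c("g1", "g2", "g3"),
                                                  each = 3)),
                 "zero within-group variance")
  expect_equal(length(unique(gs0$letters)), 1)
  expect_identical(gs0$method, "degenerate (zero variance)")
  # two clearly separated groups: t-test path, distinct letters
  set.seed(5)
  v2 <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  gs2 <- groupStats(v2, rep(c("a", "b"), each = 10))
  expect_identical(gs2$method, "two-tailed t test")
  expect_false(gs2$letters[["a"]] == gs2$letters[["b"]])
  # four groups, two clusters: letters share within, differ between
  v4 <- c(rnorm(8, 0, 0.2), rnorm(8, 0.1, 0.2), rnorm(8, 6, 0.2),
          rnorm(8, 6.1, 0.2))
  gs4 <- groupStats(v4, rep(c("w", "x", "y", "z"), each = 8))
  expect_identical(gs4$letters[["w"]], gs4$letters[["x"]])
  expect_identical(gs4$letters[["y"]], gs4$letters[["z"]])
  expect_false(gs4$letters[["w"]] == gs4$letters[["y"]])
})

test_that("compact letters match the significance matrix exactly", {
  sharesLetter <- function(a, b)
    length(intersect(strsplit(a, "")[[1]], strsplit(b, "")[[1]])) > 0
  set.seed(99)
  for (i in 1:40) {
    centers <- sample(0:3, 4, replace = TRUE) * runif(1, 0, 3)
    vals <- unlist(lapply(centers, function(m) rnorm(6, m, 1)))
    gs <- groupStats(vals, rep(paste0("g", 1:4), each = 6))
    for (a in paste0("g", 1:4)) for (b in paste0("g", 1:4)) {
      if (a >= b) next
      expect_identical(sharesLetter(gs$letters[[a]], gs$letters[[b]]),
                       gs$p_matrix[a, b] >= 0.05,
                       info = sprintf("trial %d pair %s-%s", i, a, b))
    }
  }
})
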