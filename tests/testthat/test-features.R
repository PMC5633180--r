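test_that("tilt sine matches closed forms and flags the undefined pose", {
  expect_equal(as.numeric(tilt_sine(0, 1)), 0)
  expect_equal(as.numeric(tilt_sine(1, 0)), 1)
  expect_equal(as.numeric(tilt_sine(0.5, 0.5)), sin(pi / 4))
  z <- tilt_sine(0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flag"))
  # quadrant correctness: leaning backwards past horizontal
  expect_equal(as.numeric(tilt_sine(-1, 0)), -1)
})

test_that("trunk yaw/roll match closed forms with limit conventions", {
  a <- trunk_angles(af = 1, av = 1, al = 0)
  expect_equal(as.numeric(a$yaw), 0)
  expect_equal(as.numeric(a$roll), 0)
  a <- trunk_angles(af = 1, av = 0.5, al = 1)
  expect_equal(as.numeric(a$yaw), pi / 4)
  a <- trunk_angles(af = 0.5, av = 0, al = 1)
  expect_equal(as.numeric(a$roll), pi / 2)
  a <- trunk_angles(af = 0, av = 0, al = 0)
  expect_equal(as.numeric(a$yaw), 0)
  expect_true(attr(a$yaw, "flag"))
})

test_that("resultant acceleration is the euclidean magnitude", {
  expect_equal(resultant_accel(1, 0, 0), 1)
  expect_equal(resultant_accel(0.6, 0.8, 0), 1)
  expect_equal(resultant_accel(1, 1, 1), sqrt(3))
})

test_that("segments are closed on both ends and include the anchor", {
  rec <- toy_record(6, t = 0:5)
  seg <- build_segment(rec, 6, feature_config(T_seg = 4))
  expect_equal(seg$readings$t, 1:5)  # t = 1 is on the closed boundary
  expect_equal(seg$n, 5)
  seg1 <- build_segment(rec, 1, feature_config(T_seg = 4))
  expect_equal(seg1$n, 1)
  # uniform 10 reads/s over 4 s: 41 samples in the closed interval
  rec2 <- toy_record(101, t = seq(0, 10, by = 0.1))
  seg2 <- build_segment(rec2, 101, feature_config(T_seg = 4))
  expect_equal(seg2$n, 41)
})

test_that("vertical displacement matches kinematics and a dense oracle", {
  # constant av with de-meaning: nothing moves
  seg <- make_segment(t = seq(0, 4, by = 0.1), av = 0.98)
  expect_equal(as.numeric(vertical_displacement(seg, demean = TRUE)), 0)
  # constant av without de-meaning: d = 1/2 * (g*c) * tau^2
  cval <- 0.3
  tau <- 4
  seg <- make_segment(t = seq(0, tau, by = 0.005), av = cval)
  d <- as.numeric(vertical_displacement(seg, demean = FALSE))
  expect_equal(d, 0.5 * 9.80665 * cval * tau^2, tolerance = 1e-4)
  # random smooth signal on irregular stamps vs dense double integral of the
  # linear interpolant (independent midpoint-rule oracle)
  set.seed(99)
  for (rep in 1:10) {
    t <- sort(seq(0, 4, length.out = 120) + runif(120, 0, 0.015))
    av <- sin(2 * pi * t / 3) + rnorm(1)
    seg <- make_segment(t = t, av = av)
    got <- as.numeric(vertical_displacement(seg, demean = TRUE))
    a0 <- (av - mean(av)) * 9.80665
    td <- seq(min(t), max(t), length.out = 20001)
    ad <- approx(t, a0, td)$y
    h <- diff(td)
    vmid <- cumsum(c(0, (ad[-1] + ad[-length(ad)]) / 2 * h))
    dmid <- sum((vmid[-1] + vmid[-length(vmid)]) / 2 * h)
    expect_lt(abs(got - dmid), 0.01 * max(1, abs(dmid)))
  }
  # degenerate single-reading segment
  seg <- make_segment(t = 0, av = 1)
  v <- vertical_displacement(seg)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "flag"))
})

test_that("bed-chair mutual information counts qualifying pairs", {
  expect_equal(mutual_info_bed_chair(make_segment(t = 0:3, aid = c(2, 2, 2, 2))), 0)
  expect_equal(mutual_info_bed_chair(make_segment(t = 0:3, aid = c(3, 1, 3, 1))), 0.75)
  expect_equal(mutual_info_bed_chair(make_segment(t = 0:1, aid = c(2, 1))), 0.5)
  # brute force over random antenna sequences
  set.seed(7)
  for (rep in 1:50) {
    aid <- sample(1:3, sample(2:12, 1), replace = TRUE)
    seg <- make_segment(t = seq_along(aid), aid = aid)
    n <- length(aid)
    brute <- 0
    for (i in 1:(n - 1)) {
      p <- sort(c(aid[i], aid[i + 1]))
      if (identical(p, c(1L, 2L)) || identical(p, c(1L, 3L))) brute <- brute + 1
    }
    expect_equal(mutual_info_bed_chair(seg), brute / n)
  }
})

test_that("phase-rate summaries match hand enumeration", {
  # constant phase at fixed (antenna, channel): all CFPR summaries 0
  seg <- make_segment(t = 0:4, aid = 3L, freq = 922.25, phase = 1.2)
  pr <- phase_rate_features(seg)
  expect_equal(pr$cfpr_median_ant3, 0)
  expect_equal(pr$cfpr_sd_ant3, 0)
  # phase [0.1, 0.3, 0.6] at one (antenna, channel): diffs [0.2, 0.3]
  seg <- make_segment(t = 0:2, aid = 1L, freq = 922.25,
                      phase = c(0.1, 0.3, 0.6))
  pr <- phase_rate_features(seg)
  expect_equal(pr$cfpr_median_ant1, 0.25)
  # VFPR: phase [0, 1] across channels [920, 921] on antenna 3
  seg <- make_segment(t = 0:1, aid = 3L, freq = c(920, 921), phase = c(0, 1))
  # single VFPR value -> sd degenerates to 0; check the quotient directly
  sub <- seg$readings
  expect_equal(diff(sub$phase) / diff(sub$freq), 1.0)
  # pairs at equal frequency are skipped for VFPR
  seg <- make_segment(t = 0:3, aid = 3L, freq = c(920, 920, 921, 922),
                      phase = c(0, 0.5, 1.5, 1.0))
  pr <- phase_rate_features(seg)
  vals <- c(1.0, -0.5)  # phase diffs over unequal-channel pairs
  expect_equal(pr$vfpr_sd_ant3, sd(vals))
  # phase differences are wrapped: 0.1 -> 6.2 is a small negative step
  seg <- make_segment(t = 0:1, aid = 1L, freq = 922, phase = c(0.1, 6.2))
  pr <- phase_rate_features(seg)
  expect_equal(pr$cfpr_median_ant1, 6.2 - 0.1 - 2 * pi)
})

test_that("RSSI and acceleration segment statistics match hand values", {
  seg <- make_segment(t = 0:2, av = c(1, 2, 3), af = c(1, 2, 3))
  expect_equal(rssi_and_accel_stats(seg)$pearson_r, 1)
  seg <- make_segment(t = 0:2, av = c(1, 2, 3), af = c(-1, -2, -3))
  expect_equal(rssi_and_accel_stats(seg)$pearson_r, -1)
  seg <- make_segment(t = 0:2, av = c(1, 2, 3), af = c(1, 3, 2))
  expect_equal(rssi_and_accel_stats(seg)$pearson_r, 0.5)
  # zero variance -> 0 with flag
  seg <- make_segment(t = 0:2, av = 1, af = c(1, 2, 3))
  st <- rssi_and_accel_stats(seg)
  expect_equal(st$pearson_r, 0)
  expect_true(st$flag[["pearson"]])
  # per-antenna RSSI stats and counts
  seg <- make_segment(t = 0:3, aid = c(1, 3, 3, 2), rssi = c(-60, -50, -54, -40))
  st <- rssi_and_accel_stats(seg)
  expect_equal(st$n_ant2, 1)
  expect_equal(st$rssi_mean_ant1, -60)
  expect_equal(st$rssi_sd_ant1, 0)
  expect_equal(st$rssi_mean_ant3, -52)
  expect_equal(st$rssi_sd_ant3, sd(c(-50, -54)))
  expect_equal(st$argmin_rssi_ant, 1)
  expect_equal(st$argmax_rssi_ant, 2)
})

test_that("feature extraction flows per reading with dt and gender encoded", {
  rec <- toy_record(1)
  fm <- extract_features(rec)
  expect_equal(nrow(fm), 1)
  expect_equal(fm$vert_disp, 0)
  expect_equal(fm$dt, 0)
  rec <- patient_record("two", "male", toy_readings(2, t = c(0, 0.5)))
  fm <- extract_features(rec)
  expect_equal(fm$dt, c(0, 0.5))
  expect_equal(unique(fm$gender), 1)
  expect_equal(ncol(feature_matrix(fm)), length(default_feature_mask()))
})

test_that("features are invariant to a constant time shift", {
  rec <- synthesize_trial(trial_script(1), seed = 2)
  fm1 <- extract_features(rec)
  shifted <- rec
  shifted$readings$t <- shifted$readings$t + 1000
  fm2 <- extract_features(shifted)
  for (nm in setdiff(names(fm1), "t")) {
    expect_equal(fm2[[nm]], fm1[[nm]], tolerance = 1e-9, label = nm)
  }
})

test_that("feature bounds hold on random segments", {
  set.seed(123)
  n_cases <- 10000
  af <- runif(n_cases, -1, 1)
  av <- runif(n_cases, -1, 1)
  al <- runif(n_cases, -1, 1)
  s <- tilt_sine(af, av)
  expect_true(all(s >= -1 & s <= 1))
  expect_true(all(resultant_accel(af, av, al) >= 0))
  for (rep in 1:300) {
    n <- sample(1:8, 1)
    seg <- make_segment(t = seq_len(n), aid = sample(1:3, n, replace = TRUE),
                        av = rnorm(n), af = rnorm(n))
    m <- mutual_info_bed_chair(seg)
    expect_gte(m, 0)
    expect_lte(m, (n - 1) / n)
    r <- rssi_and_accel_stats(seg)$pearson_r
    expect_gte(r, -1)
    expect_lte(r, 1)
  }
})

test_that("extraction reproduces the audited golden fixture", {
  rec <- synthesize_trial(
    trial_script(1, durations = c(ambulating = 2, chair = 3, lying = 4,
                                  bed_sit = 2)),
    cfg = sim_config(), seed = 31, patient_id = "gold"
  )
  fm <- extract_features(rec)
  golden <- read.csv(test_path("golden_features.csv"))
  expect_equal(nrow(fm), nrow(golden))
  for (nm in names(golden)) {
    expect_equal(fm[[nm]], golden[[nm]], tolerance = 1e-6, label = nm)
  }
})
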