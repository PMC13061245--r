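# Preprocessing: midpoint velocity, pairing, segmentation, time
# normalization, cleaning and the composed build_pair path.

test_that("midpoint velocity matches hand arithmetic and the brute-force oracle", {
  # stationary midpoint -> zero speed
  still <- landmark_track(matrix(1.5, 20, 2), matrix(0.5, 20, 2), 50)
  expect_equal(midpoint_velocity(still), rep(0, 20))

  # constant drift of (0.06, 0.08) m/frame at 50 Hz -> 5.0 m/s everywhere
  n <- 40
  mid <- cbind(0.06 * (0:(n - 1)), 0.08 * (0:(n - 1)))
  trk <- landmark_track(mid + 0.1, mid - 0.1, 50)
  expect_equal(midpoint_velocity(trk), rep(5, n), tolerance = 1e-12)

  # random track vs oracle
  set.seed(42)
  c7 <- matrix(rnorm(400), 200, 2); lum <- matrix(rnorm(400), 200, 2)
  trk <- landmark_track(c7, lum, 50)
  expect_lt(max(abs(midpoint_velocity(trk) -
                      oracle_midpoint_velocity(c7, lum, 50))), 1e-10)

  short <- landmark_track(matrix(0, 2, 2), matrix(0, 2, 2), 50)
  expect_error(midpoint_velocity(short), class = "scrumforce_data_error")
})

test_that("pair mean velocity is the element-wise average", {
  v <- runif(101)
  expect_identical(pair_mean_velocity(v, v), v)
  expect_equal(pair_mean_velocity(rep(2, 10), rep(4, 10)), rep(3, 10))
  a <- rnorm(50); b <- rnorm(50)
  expect_identical(pair_mean_velocity(a, b), (a + b) / 2)
  err <- expect_error(pair_mean_velocity(rnorm(5), rnorm(7)),
                      class = "scrumforce_shape_error")
  expect_match(conditionMessage(err), "5")
  expect_match(conditionMessage(err), "7")
})

test_that("segmentation runs from first crossing to the force maximum", {
  expect_equal(unname(segment_engagement(c(0, 5, 12, 300, 900, 400), 10)[1:2]),
               c(3, 5))

  # step that jumps and stays: single-sample window, flagged degenerate
  f <- c(rep(0, 9), rep(2000, 11))
  w <- segment_engagement(f, 10)
  expect_equal(unname(w[1:2]), c(10, 10))
  expect_true(attr(w, "degenerate"))

  # monotone ramp: window runs to the last sample
  ramp <- seq(0, 49) * 1.5          # crosses 10 N at index 8 (1-based)
  w <- segment_engagement(ramp, 10)
  expect_equal(unname(w[1:2]), c(8, 50))
  expect_false(attr(w, "degenerate"))

  # ties at the maximum resolve to the first occurrence
  expect_equal(unname(segment_engagement(c(0, 50, 100, 100, 40), 10)[2]), 3)

  expect_error(segment_engagement(c(0, 1, 2), 10),
               class = "scrumforce_nocontact_error")

  # trace above threshold everywhere starts at the first sample
  expect_equal(unname(segment_engagement(c(20, 30, 900, 40), 10)[1]), 1)

  # property: matches enumeration oracle on random traces
  set.seed(7)
  for (i in 1:200) {
    f <- cumsum(rnorm(60))^2 * 10
    if (max(f) <= 10) next
    expect_identical(unname(segment_engagement(f, 10)[1:2]),
                     oracle_segment(f, 10))
  }
})

test_that("time normalization is linear interpolation onto 101 points", {
  x <- rnorm(101)
  expect_identical(time_normalize(x), x)

  ramp <- seq(3, 17, length.out = 57)
  expect_equal(time_normalize(ramp), seq(3, 17, length.out = 101),
               tolerance = 1e-12)

  set.seed(1)
  x <- cumsum(rnorm(640))
  expect_lt(max(abs(time_normalize(x) - oracle_time_normalize(x, 101))), 1e-9)

  # endpoints exact, length always 101, for any input length >= 2
  for (n in c(2, 3, 7, 101, 350, 1200)) {
    x <- rnorm(n)
    y <- time_normalize(x)
    expect_length(y, 101)
    expect_identical(y[1], x[1])
    expect_identical(y[101], x[n])
  }
  expect_error(time_normalize(3), class = "scrumforce_data_error")
})

test_that("cleaning keeps exactly the in-range pairs and is idempotent", {
  mk <- function(vp, fp, id) {
    v <- vp * (seq(0.2, 1, length.out = 101))
    f <- fp * seq(0.01, 1, length.out = 101)
    vf_pair(v, f, meta = list(trial_id = id), source = "synthetic")
  }
  expect_length(clean_trials(list(mk(3, 2500, "ok")))$kept, 1)

  bad_v <- clean_trials(list(mk(5, 2500, "v")))
  expect_length(bad_v$kept, 0)
  expect_equal(bad_v$log$reason, "velocity-range")

  # boundary peaks are inclusive on both ends
  expect_length(clean_trials(list(mk(2.5, 1000, "lo"), mk(4.5, 4000, "hi")))$kept, 2)

  set.seed(3)
  good <- lapply(1:7, function(i) mk(runif(1, 2.6, 4.4), runif(1, 1100, 3900),
                                     paste0("g", i)))
  bad <- list(mk(2.2, 2000, "b1"), mk(3.0, 4500, "b2"), mk(4.9, 900, "b3"))
  res <- clean_trials(c(good, bad))
  expect_length(res$kept, 7)
  expect_setequal(res$log$trial_id, c("b1", "b2", "b3"))
  expect_match(res$log$reason[res$log$trial_id == "b3"], "velocity-range")
  expect_match(res$log$reason[res$log$trial_id == "b3"], "force-range")

  again <- clean_trials(res$kept)
  expect_identical(again$kept, res$kept)
  expect_equal(nrow(again$log), 0)

  expect_warning(out <- clean_trials(list()), "empty")
  expect_length(out$kept, 0)
})

test_that("build_pair recovers a constant approach velocity", {
  # two players closing at constant speed, clean force pulse:
  # velocity channel must be flat at the known value
  vr <- 50; fr <- 500
  n <- 100
  mid_a <- cbind(1.5 * (0:(n - 1)) / vr, 0)    # 1.5 m/s
  mid_b <- cbind(10 - 2.5 * (0:(n - 1)) / vr, 0)  # 2.5 m/s -> pair mean 2.0
  ta <- landmark_track(mid_a + 0.2, mid_a - 0.2, vr, "A1")
  tb <- landmark_track(mid_b + 0.2, mid_b - 0.2, vr, "B3")
  ft <- c(rep(0, 200), seq(12, 2500, length.out = 500), rep(100, 100))
  trial <- engagement_trial("const", "CTS", "A1L-B3", ta, tb,
                            force_trace(ft, fr))
  pr <- suppressWarnings(build_pair(trial))
  expect_s3_class(pr, "vf_pair")
  expect_lt(max(abs(pr$velocity - 2.0)) / 2.0, 0.02)
  expect_equal(pr$force[101], max(pr$force))
  expect_equal(pr$meta$technique, "CTS")
})

test_that("build_pair propagates failures with trial context", {
  vr <- 50
  mid <- cbind(seq(0, 2, length.out = 100), 0)
  trk <- landmark_track(mid + 0.2, mid - 0.2, vr, "A1")
  quiet <- engagement_trial("quiet-1", "CTPE", "A1L-B3", trk, trk,
                            force_trace(rep(3, 1000), 500))
  err <- expect_error(suppressWarnings(build_pair(quiet)),
                      class = "scrumforce_nocontact_error")
  expect_match(conditionMessage(err), "quiet-1")
})

test_that("raw simulated trials round-trip through preprocessing", {
  # tolerance measured once on the noise-free chain and frozen: the force
  # peak survives within 1%; the velocity peak is flattened by 50 Hz
  # central differences plus near-Nyquist filtering, within 7%
  cfg <- sim_config(jitter_sd = 0)
  set.seed(11)
  for (i in 1:5) {
    tr <- simulate_raw_trial(cfg, paste0("rt", i))
    pr <- suppressWarnings(build_pair(tr$trial))
    expect_lt(max(abs(pr$velocity - tr$pair$velocity)) / max(tr$pair$velocity),
              0.07)
    expect_lt(abs(max(pr$force) - max(tr$pair$force)) / max(tr$pair$force),
              0.01)
    expect_equal(pr$force[101], max(pr$force))
    expect_true(all(pr$velocity >= 0))
  }
})
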