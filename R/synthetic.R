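# Seeded synthetic scrum-engagement generator.
#
# Emulates the statistical structure of measured engagements -- velocity
# peaks of 2.5-4.5 m/s, monotone force rises ending at a 1-4 kN peak, a
# noisy positive velocity-force association, and lower PreBind peaks --
# with a known, exposed velocity-to-force ground truth so the prediction
# pipeline can be tested against an irreducible-error floor. Realism is
# deliberately statistical, not biomechanical.
#
# Ground-truth mapping: the engagement-velocity profile is a smooth
# unimodal bump v(t) reaching its sampled peak; contact builds as the
# normalized cumulative squared speed s(t) = cumsum(v^2)/sum(v^2), and the
# noise-free force is
#   f(t) = floor + (F_peak - floor) * s(t)^gamma,
#   F_peak = (slope * v_peak + intercept) * technique_scale,
# with technique_scale < 1 for PreBind. The realized (measured) force
# multiplies the rise by a log-normal trial-level amplitude factor,
# truncated so peaks stay inside the cleaning ranges. With noise_sd = 0 the
# realized force equals the ground truth exactly.

#' Synthetic-data configuration
#'
#' @param n_trials number of trials for [simulate_dataset()].
#' @param seed integer seed.
#' @param v_peak_range uniform range of velocity peaks, m/s.
#' @param f_peak_range admissible force-peak range, N (realized peaks are
#'   kept inside it).
#' @param technique_mix named probabilities over CTPE/CTS/PreBind.
#' @param prebind_force_scale multiplicative force reduction for PreBind
#'   (< 1; default 0.8).
#' @param noise_sd SD of the log-normal amplitude noise on the realized
#'   force (0 disables noise).
#' @param mapping ground-truth coefficients: `slope` (N per m/s),
#'   `intercept` (N), `gamma` (rise shape), `contact_floor` (force at the
#'   window start, just above the 10 N contact threshold).
#' @param jitter_sd positional jitter SD (m) on raw landmark tracks.
#' @param video_rate_hz,force_rate_hz raw sampling rates.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 42, seed = 1L,
                       v_peak_range = c(2.5, 4.5),
                       f_peak_range = c(1000, 4000),
                       technique_mix = c(CTPE = 1/3, CTS = 1/3, PreBind = 1/3),
                       prebind_force_scale = 0.8,
                       noise_sd = 0.25,
                       mapping = list(slope = 850, intercept = -600,
                                      gamma = 1.5, contact_floor = 12),
                       jitter_sd = 0.002,
                       video_rate_hz = 50, force_rate_hz = 500) {
  if (n_trials < 1) stop_config("n_trials must be >= 1")
  if (abs(sum(technique_mix) - 1) > 1e-8)
    stop_config("technique_mix probabilities must sum to 1 (sum %g)",
                sum(technique_mix))
  if (!all(names(technique_mix) %in% TECHNIQUES))
    stop_config("technique_mix names must be among %s",
                paste(TECHNIQUES, collapse = ", "))
  if (prebind_force_scale <= 0 || prebind_force_scale >= 1.5)
    stop_config("prebind_force_scale must be a positive scale factor")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  structure(list(n_trials = as.integer(n_trials), seed = as.integer(seed),
                 v_peak_range = v_peak_range, f_peak_range = f_peak_range,
                 technique_mix = technique_mix,
                 prebind_force_scale = prebind_force_scale,
                 noise_sd = noise_sd, mapping = mapping,
                 jitter_sd = jitter_sd,
                 video_rate_hz = video_rate_hz, force_rate_hz = force_rate_hz),
            class = "sim_config")
}

#' Ground-truth force curve of the synthetic mapping
#'
#' Exposed so tests can compute the irreducible-error floor of predictors
#' trained on simulated data.
#'
#' @param velocity 101-point velocity curve, m/s.
#' @param technique engagement technique label.
#' @param cfg a [sim_config()].
#' @return the noise-free 101-point force curve, N.
#' @export
ground_truth_force <- function(velocity, technique, cfg = sim_config()) {
  mp <- cfg$mapping
  s <- cumsum(velocity^2)
  s <- s / s[length(s)]
  tech <- if (technique == "PreBind") cfg$prebind_force_scale else 1
  f_peak <- (mp$slope * max(velocity) + mp$intercept) * tech
  f_peak <- min(max(f_peak, cfg$f_peak_range[1] * 1.02), cfg$f_peak_range[2] * 0.98)
  mp$contact_floor + (f_peak - mp$contact_floor) * s^mp$gamma
}

#' Simulate one velocity-force pair
#'
#' Draws from the current RNG state (seed it, or use [simulate_dataset()]).
#'
#' @param cfg a [sim_config()].
#' @param trial_id label for the pair's metadata.
#' @return list with `pair` (a [vf_pair()], `source = "synthetic"`) and
#'   `ground_truth` (noise-free force curve plus the drawn parameters).
#' @export
simulate_pair <- function(cfg = sim_config(), trial_id = "sim-1") {
  technique <- sample(names(cfg$technique_mix), 1L, prob = cfg$technique_mix)
  pairing <- sample(PAIRINGS, 1L)
  v_peak <- stats::runif(1, cfg$v_peak_range[1], cfg$v_peak_range[2])
  tv <- stats::runif(1, 0.35, 0.5)   # peak time, normalized
  w <- stats::runif(1, 0.15, 0.25)   # bump width
  tt <- seq(0, 1, length.out = N_POINTS)
  prof <- exp(-((tt - tv) / w)^2)
  velocity <- v_peak * (prof + 0.05) / 1.05

  gt <- ground_truth_force(velocity, technique, cfg)
  floor_ <- cfg$mapping$contact_floor
  rise <- gt - floor_
  eta <- exp(stats::rnorm(1, 0, cfg$noise_sd))
  # keep the realized peak inside the admissible range
  eta_lim <- c(cfg$f_peak_range[1] * 1.005 - floor_,
               cfg$f_peak_range[2] * 0.995 - floor_) / rise[N_POINTS]
  eta <- min(max(eta, eta_lim[1]), eta_lim[2])
  force <- floor_ + eta * rise

  pair <- vf_pair(velocity, force,
                  meta = list(trial_id = trial_id, technique = technique,
                              pairing = pairing),
                  source = "synthetic")
  list(pair = pair,
       ground_truth = list(force = gt, v_peak = v_peak, technique = technique,
                           eta = eta, tv = tv, w = w))
}

#' Simulate one raw engagement trial
#'
#' Inverts a simulated pair into raw signals: 50 Hz landmark tracks whose
#' C7-lumbar midpoint speed follows the engagement-velocity curve (with
#' optional positional jitter), and a 500 Hz force trace with a
#' sub-threshold pre-contact segment and a post-peak decay, so the full
#' preprocessing path (filter, differentiate, segment, normalize)
#' approximately recovers the stored pair.
#'
#' @param cfg a [sim_config()].
#' @param trial_id label.
#' @return object of class `sim_trial`: `trial` (an [engagement_trial()]),
#'   `pair` (the source [vf_pair()]), `ground_truth`, and the raw-timing
#'   parameters.
#' @export
simulate_raw_trial <- function(cfg = sim_config(), trial_id = "sim-1") {
  sp <- simulate_pair(cfg, trial_id)
  pair <- sp$pair
  # engagement duration, s, quantized to the video frame grid so the
  # force-peak time falls on a frame and the round trip is not blurred by
  # window rounding
  d_eng <- round(stats::runif(1, 0.4, 0.7) * cfg$video_rate_hz) / cfg$video_rate_hz
  t_pre <- 0.4; t_post <- 0.2

  ## velocity at video rate over pre + engagement + post
  vr <- cfg$video_rate_hz
  t_all <- seq(0, t_pre + d_eng + t_post, by = 1 / vr)
  t_norm <- (t_all - t_pre) / d_eng
  v_eng <- function(u) stats::approx(seq(0, 1, length.out = N_POINTS),
                                     pair$velocity, u, rule = 2)$y
  v0 <- pair$velocity[1]; v1 <- pair$velocity[N_POINTS]
  v_all <- ifelse(t_norm < 0, v0 * pmax(1 + t_norm * d_eng / t_pre, 0)^2,
           ifelse(t_norm > 1, v1 * exp(-(t_norm - 1) * d_eng / 0.1),
                  v_eng(pmax(pmin(t_norm, 1), 0))))

  ## integrate to midpoint paths; both players share the speed profile so
  ## the pair mean equals it
  path <- (cumsum(v_all) - (v_all - v_all[1]) / 2) / vr  # trapezoid rule
  mk_track <- function(direction, player_id) {
    mid <- cbind(direction * path, 0)
    off <- matrix(rep(c(0.30, 0.08), each = length(t_all)), ncol = 2)
    j <- function() matrix(stats::rnorm(2 * length(t_all), 0, cfg$jitter_sd),
                           ncol = 2)
    landmark_track(mid + off + j(), mid - off + j(), rate_hz = vr,
                   player_id = player_id)
  }
  track_a <- mk_track(+1, substr(pair$meta$pairing, 1, 2))
  track_b <- mk_track(-1, sub("^.*-", "", pair$meta$pairing))

  ## force at 500 Hz: sub-threshold noise, engagement rise, post-peak decay
  fr <- cfg$force_rate_hz
  n_pre <- round(t_pre * fr)
  n_eng <- round(d_eng * fr) + 1L
  n_post <- round(t_post * fr)
  f_pre <- stats::runif(n_pre, 0, 5)
  f_eng <- stats::approx(seq(0, 1, length.out = N_POINTS), pair$force,
                         seq(0, 1, length.out = n_eng))$y
  f_peak <- pair$force[N_POINTS]
  f_post <- f_peak * 0.97 * exp(-seq_len(n_post) / (0.05 * fr))
  shoulder <- if (grepl("^A.L", pair$meta$pairing)) "left" else "right"
  force <- force_trace(c(f_pre, f_eng, f_post), rate_hz = fr, shoulder = shoulder)

  structure(list(trial = engagement_trial(trial_id, pair$meta$technique,
                                          pair$meta$pairing, track_a, track_b,
                                          force),
                 pair = pair, ground_truth = sp$ground_truth,
                 timing = list(t_pre = t_pre, d_engage = d_eng,
                               t_post = t_post)),
            class = "sim_trial")
}

#' Simulate a dataset of raw trials
#'
#' @param cfg a [sim_config()]; `cfg$n_trials` and `cfg$seed` control size
#'   and reproducibility.
#' @param dir optional directory; when given, each trial is also written in
#'   the CSV+JSON dialect via [write_trial()].
#' @return list of `sim_trial` objects.
#' @export
simulate_dataset <- function(cfg = sim_config(), dir = NULL) {
  trials <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_trials), function(i)
      simulate_raw_trial(cfg, trial_id = sprintf("sim-%03d", i)))
  })
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (tr in trials) write_trial(tr$trial, dir)
  }
  trials
}
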