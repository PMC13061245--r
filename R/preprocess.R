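# Raw trial -> 101-point velocity-force pair.
#
# Pipeline per trial: low-pass filter landmarks (20 Hz) and force (100 Hz),
# differentiate the C7-lumbar midpoint to an engagement speed per player,
# average the paired players, segment the force trace between first contact
# (> threshold) and the force peak, map that window to video frames, and
# time-normalize both channels to 101 points.

#' Engagement speed of a player's trunk midpoint
#'
#' Computes the Euclidean norm of the finite-difference derivative of the
#' midpoint between the C7 and lumbar landmarks. Central differences are used
#' on interior frames and one-sided differences at the ends, scaled by the
#' sampling rate, so the result has the same length as the track.
#'
#' @param track a [landmark_track()].
#' @return numeric vector of speeds (m/s), one per frame, all `>= 0`.
#' @export
midpoint_velocity <- function(track) {
  if (!inherits(track, "landmark_track"))
    stop_data("midpoint_velocity expects a landmark_track")
  n <- track$frames
  if (n < 3L)
    stop_data("track '%s' has %d frames; at least 3 are needed to differentiate",
              track$player_id, n)
  mid <- (track$c7_xy + track$lumbar_xy) / 2
  d <- matrix(0, n, 2L)
  d[1, ] <- mid[2, ] - mid[1, ]
  d[n, ] <- mid[n, ] - mid[n - 1, ]
  if (n > 2L)
    d[2:(n - 1), ] <- (mid[3:n, ] - mid[1:(n - 2), ]) / 2
  sqrt(rowSums(d^2)) * track$rate_hz
}

#' Mean engagement velocity of a player pair
#'
#' @param v_a,v_b speed series of the two paired players, equal length.
#' @return element-wise arithmetic mean.
#' @export
pair_mean_velocity <- function(v_a, v_b) {
  if (length(v_a) != length(v_b))
    stop_shape("velocity series differ in length: %d vs %d", length(v_a), length(v_b))
  (v_a + v_b) / 2
}

#' Segment the engagement window of a force trace
#'
#' The analyzed window runs from the first sample where the contact force
#' exceeds `threshold` to the sample of the global force maximum (first
#' occurrence on ties). Indices are 1-based and the window is closed.
#' A single-sample window (`start == end`) is returned with attribute
#' `degenerate = TRUE`; [build_pair()] rejects such windows because they
#' cannot be interpolated to a curve.
#'
#' @param force a [force_trace()] or numeric vector of forces (N).
#' @param threshold contact-detection threshold, N (default 10).
#' @return integer vector `c(start, end)`.
#' @export
segment_engagement <- function(force, threshold = 10) {
  f <- if (inherits(force, "force_trace")) force$samples else as.numeric(force)
  check_numeric_vector(f, "force", min_len = 2L)
  above <- which(f > threshold)
  if (length(above) == 0L)
    stop(errorCondition(
      sprintf("no contact: force never exceeds %.3g N (max %.3g N)", threshold, max(f)),
      class = c("scrumforce_nocontact_error", "scrumforce_data_error", "scrumforce_error")))
  start <- above[1L]
  end <- which.max(f)
  win <- c(start = start, end = end)
  attr(win, "degenerate") <- start == end
  win
}

#' Time-normalize a signal to a fixed number of points
#'
#' Linearly interpolates the signal onto `n_points` equally spaced samples of
#' normalized time `[0, 1]`. The first and last samples are preserved
#' exactly, so a window ending at the force peak still ends at the peak.
#'
#' @param x numeric signal, length >= 2.
#' @param n_points output length (default 101).
#' @return numeric vector of length `n_points`.
#' @export
time_normalize <- function(x, n_points = N_POINTS) {
  check_numeric_vector(x, "x", min_len = 2L)
  if (n_points < 2L)
    stop_config("n_points must be >= 2 (got %d)", n_points)
  n <- length(x)
  if (n == n_points) return(as.numeric(x))
  stats::approx(x = seq(0, 1, length.out = n), y = x,
                xout = seq(0, 1, length.out = n_points), method = "linear")$y
}

#' Remove trials with implausible peak values
#'
#' Keeps exactly the pairs whose peak velocity lies in
#' `[v_peak_min, v_peak_max]` and peak force in `[f_peak_min, f_peak_max]`
#' (bounds inclusive). Values outside these ranges indicate tracking or
#' sensing faults rather than real engagements.
#'
#' @param pairs list of [vf_pair()] objects.
#' @param cfg a [cleaning_config()].
#' @return list with `kept` (the retained pairs) and `log`, a data frame of
#'   rejections (`trial_id`, `reason`).
#' @export
clean_trials <- function(pairs, cfg = cleaning_config()) {
  if (!inherits(cfg, "cleaning_config"))
    stop_config("cfg must be a cleaning_config")
  if (length(pairs) == 0L) {
    warning("clean_trials: empty input", call. = FALSE)
    return(list(kept = list(),
                log = data.frame(trial_id = character(), reason = character(),
                                 stringsAsFactors = FALSE)))
  }
  ids <- character(0); reasons <- character(0); keep <- logical(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    vp <- max(p$velocity); fp <- max(p$force)
    bad <- character(0)
    if (vp < cfg$v_peak_min || vp > cfg$v_peak_max) bad <- c(bad, "velocity-range")
    if (fp < cfg$f_peak_min || fp > cfg$f_peak_max) bad <- c(bad, "force-range")
    keep[i] <- length(bad) == 0L
    if (!keep[i]) {
      ids <- c(ids, as.character(p$meta$trial_id %||% NA_character_))
      reasons <- c(reasons, paste(bad, collapse = ";"))
    }
  }
  list(kept = pairs[keep],
       log = data.frame(trial_id = ids, reason = reasons, stringsAsFactors = FALSE))
}

#' Build the velocity-force pair of one engagement trial
#'
#' Runs the full preprocessing chain on a raw trial: landmark tracks are
#' low-pass filtered at `landmark_cutoff_hz` and the force trace at
#' `force_cutoff_hz` (zero phase), midpoint speeds of the two players are
#' averaged, the engagement window is segmented on the filtered force trace,
#' the window's start/end times are mapped to the nearest video frames, and
#' both channels are independently time-normalized to 101 points.
#'
#' @param trial an [engagement_trial()].
#' @param cfg a [cleaning_config()]; only `contact_threshold` is used here
#'   (range cleaning is a separate, dataset-level step: [clean_trials()]).
#' @param landmark_cutoff_hz,force_cutoff_hz filter cutoffs, Hz.
#' @return a [vf_pair()] with `source = "measured"`.
#' @export
build_pair <- function(trial, cfg = cleaning_config(),
                       landmark_cutoff_hz = 20, force_cutoff_hz = 100) {
  if (!inherits(trial, "engagement_trial"))
    stop_data("build_pair expects an engagement_trial")
  with_trial_context(trial$trial_id, {
    fa <- filter_track(trial$track_a, landmark_cutoff_hz)
    fb <- filter_track(trial$track_b, landmark_cutoff_hz)
    f_filt <- butter_lowpass(trial$force$samples, trial$force$rate_hz, force_cutoff_hz)
    v <- pair_mean_velocity(midpoint_velocity(fa), midpoint_velocity(fb))

    win <- segment_engagement(f_filt, cfg$contact_threshold)
    if (isTRUE(attr(win, "degenerate")))
      stop(errorCondition(
        sprintf("degenerate single-sample engagement window at force sample %d", win[["start"]]),
        class = c("scrumforce_degenerate_window_error", "scrumforce_data_error",
                  "scrumforce_error")))

    # Force-time window -> video frames (nearest frame), both 1-based.
    f_rate <- trial$force$rate_hz; v_rate <- trial$track_a$rate_hz
    fs <- round((win[["start"]] - 1L) / f_rate * v_rate) + 1L
    fe <- round((win[["end"]] - 1L) / f_rate * v_rate) + 1L
    fs <- max(1L, min(fs, length(v))); fe <- max(1L, min(fe, length(v)))
    if (fe - fs < 1L)
      stop(errorCondition(
        sprintf("engagement window maps to fewer than 2 video frames (%d..%d)", fs, fe),
        class = c("scrumforce_degenerate_window_error", "scrumforce_data_error",
                  "scrumforce_error")))

    vf_pair(velocity = time_normalize(v[fs:fe]),
            force = time_normalize(f_filt[win[["start"]]:win[["end"]]]),
            meta = list(trial_id = trial$trial_id, technique = trial$technique,
                        pairing = trial$pairing,
                        force_window = unname(win), frame_window = c(fs, fe)),
            source = "measured")
  })
}

filter_track <- function(track, cutoff_hz) {
  flt <- function(m) apply(m, 2L, butter_lowpass, rate_hz = track$rate_hz,
                           cutoff_hz = cutoff_hz)
  # The near-Nyquist warning would repeat once per coordinate column;
  # keep the first and muffle the rest.
  seen <- character(0)
  withCallingHandlers(
    landmark_track(flt(track$c7_xy), flt(track$lumbar_xy),
                   rate_hz = track$rate_hz, player_id = track$player_id),
    warning = function(w) {
      if (conditionMessage(w) %in% seen) invokeRestart("muffleWarning")
      seen <<- c(seen, conditionMessage(w))
    })
}

# Re-raise any package error with the trial id prepended, preserving classes.
with_trial_context <- function(trial_id, expr) {
  withCallingHandlers(expr, scrumforce_error = function(e) {
    if (!isTRUE(attr(e, "scrumforce_ctx"))) {
      e2 <- errorCondition(sprintf("trial '%s': %s", trial_id, conditionMessage(e)),
                           class = setdiff(class(e), "condition"))
      attr(e2, "scrumforce_ctx") <- TRUE
      stop(e2)
    }
  })
}
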