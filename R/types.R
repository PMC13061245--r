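# Domain containers. Plain lists with light S3 classes: the package's
# currency is the 101-point velocity-force pair ("vf_pair"); everything
# upstream of it describes one shoulder-contact event.

#' Engagement techniques and shoulder pairings
#'
#' The three referee-cadence engagement techniques (crouch-touch-pause-engage,
#' crouch-touch-set, and pre-bound props) and the six instrumented-shoulder
#' pairings between the two front rows. `A2L-B3` means the left shoulder of
#' prop A2 contacting opposing player B3; the shoulder label used in grouped
#' reports (`A2-L`) is derived from the pairing.
#'
#' @name scrum-labels
#' @keywords internal
NULL

TECHNIQUES <- c("CTPE", "CTS", "PreBind")
PAIRINGS   <- c("A1L-B3", "A1R-B3", "A2L-B3", "A2R-B2", "A3L-B2", "A3R-B1")
N_POINTS   <- 101L

#' Shoulder label from an engagement pairing
#'
#' @param pairing one of the six pairing codes, e.g. `"A1L-B3"`.
#' @return shoulder label, e.g. `"A1-L"`.
#' @examples
#' pairing_shoulder("A3R-B1")
#' @export
pairing_shoulder <- function(pairing) {
  pairing <- match.arg(pairing, PAIRINGS, several.ok = FALSE)
  sub("^(A[123])([LR])-.*$", "\\1-\\2", pairing)
}

#' Landmark track for one player
#'
#' Per-frame 2D positions (metres, top view) of the C7 vertebra and a lumbar
#' point, sampled from video at `rate_hz`. Gaps are a load-time error: both
#' landmark series must be complete and equally long.
#'
#' @param c7_xy,lumbar_xy numeric matrices, frames x 2, metres.
#' @param rate_hz video sampling rate in Hz (default 50).
#' @param player_id player label, `A1..A3` or `B1..B3`.
#' @return an object of class `landmark_track`.
#' @export
landmark_track <- function(c7_xy, lumbar_xy, rate_hz = 50, player_id = "A1") {
  c7_xy <- as.matrix(c7_xy); lumbar_xy <- as.matrix(lumbar_xy)
  if (ncol(c7_xy) != 2L || ncol(lumbar_xy) != 2L)
    stop_shape("landmark coordinates must be n x 2 matrices (got %d and %d columns)",
               ncol(c7_xy), ncol(lumbar_xy))
  if (nrow(c7_xy) != nrow(lumbar_xy))
    stop_shape("c7 and lumbar tracks differ in length: %d vs %d frames",
               nrow(c7_xy), nrow(lumbar_xy))
  if (!all(is.finite(c7_xy)) || !all(is.finite(lumbar_xy)))
    stop_data("landmark track for '%s' has missing or non-finite samples", player_id)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop_config("rate_hz must be a single positive number (got %s)", format(rate_hz))
  structure(list(frames = nrow(c7_xy), rate_hz = rate_hz,
                 c7_xy = unname(c7_xy), lumbar_xy = unname(lumbar_xy),
                 player_id = player_id),
            class = "landmark_track")
}

#' Raw shoulder force trace
#'
#' @param samples numeric vector of forces in newtons.
#' @param rate_hz sampling rate in Hz (default 500, shoulder pressure sensors).
#' @param shoulder `"left"` or `"right"`.
#' @return an object of class `force_trace`.
#' @export
force_trace <- function(samples, rate_hz = 500, shoulder = c("left", "right")) {
  shoulder <- match.arg(shoulder)
  check_numeric_vector(samples, "samples", min_len = 2L)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop_config("rate_hz must be a single positive number (got %s)", format(rate_hz))
  structure(list(samples = as.numeric(samples), rate_hz = rate_hz,
                 shoulder = shoulder),
            class = "force_trace")
}

#' One shoulder-contact engagement trial
#'
#' Bundles the two paired players' landmark tracks with the instrumented
#' shoulder's force trace and the trial metadata.
#'
#' @param trial_id label.
#' @param technique engagement technique, one of `CTPE`, `CTS`, `PreBind`.
#' @param pairing one of the six shoulder pairings (see [pairing_shoulder()]).
#' @param track_a,track_b [landmark_track()] objects for the two players.
#' @param force a [force_trace()].
#' @return an object of class `engagement_trial`.
#' @export
engagement_trial <- function(trial_id, technique, pairing, track_a, track_b, force) {
  if (!technique %in% TECHNIQUES)
    stop_config("unknown technique '%s' (expected one of %s)", technique,
                paste(TECHNIQUES, collapse = ", "))
  if (!pairing %in% PAIRINGS)
    stop_config("unknown pairing '%s' (expected one of %s)", pairing,
                paste(PAIRINGS, collapse = ", "))
  if (!inherits(track_a, "landmark_track") || !inherits(track_b, "landmark_track"))
    stop_data("trial '%s': track_a/track_b must be landmark_track objects", trial_id)
  if (!inherits(force, "force_trace"))
    stop_data("trial '%s': force must be a force_trace object", trial_id)
  structure(list(trial_id = as.character(trial_id), technique = technique,
                 pairing = pairing, track_a = track_a, track_b = track_b,
                 force = force),
            class = "engagement_trial")
}

#' 101-point velocity-force pair
#'
#' The pipeline's central object: the engagement-velocity curve (m/s) and the
#' contact-force curve (N) of one shoulder contact, time-normalized to 101
#' points between first contact (force > threshold) and the force peak.
#' Measured and synthetic pairs are guaranteed to have non-negative velocity
#' and a force curve ending at its maximum; GAN-generated curves are stored
#' as emitted by the generator.
#'
#' @param velocity,force numeric vectors of length 101.
#' @param meta list with `trial_id`, `technique`, `pairing` (all optional).
#' @param source provenance: `measured`, `gan`, `mixup` or `synthetic`.
#' @return an object of class `vf_pair`.
#' @export
vf_pair <- function(velocity, force, meta = list(),
                    source = c("measured", "gan", "mixup", "synthetic")) {
  source <- match.arg(source)
  check_numeric_vector(velocity, "velocity", min_len = N_POINTS)
  check_numeric_vector(force, "force", min_len = N_POINTS)
  if (length(velocity) != N_POINTS || length(force) != N_POINTS)
    stop_shape("vf_pair channels must have exactly %d samples (got %d and %d)",
               N_POINTS, length(velocity), length(force))
  if (source %in% c("measured", "synthetic")) {
    if (any(velocity < 0))
      stop_data("velocity magnitudes must be non-negative")
    if (force[N_POINTS] < max(force) - 1e-9 * max(abs(force), 1))
      stop_data("force curve must attain its maximum at the final sample (window ends at the peak)")
  }
  meta$shoulder <- meta$shoulder %||%
    (if (!is.null(meta$pairing) && meta$pairing %in% PAIRINGS)
      pairing_shoulder(meta$pairing) else NA_character_)
  structure(list(velocity = as.numeric(velocity), force = as.numeric(force),
                 meta = meta, source = source),
            class = "vf_pair")
}

#' @export
print.vf_pair <- function(x, ...) {
  cat(sprintf("<vf_pair %s> trial=%s technique=%s pairing=%s\n",
              x$source, x$meta$trial_id %||% "?", x$meta$technique %||% "?",
              x$meta$pairing %||% "?"))
  cat(sprintf("  peak velocity %.2f m/s, peak force %.0f N, %d points\n",
              max(x$velocity), max(x$force), length(x$force)))
  invisible(x)
}

#' Trial-cleaning thresholds
#'
#' Physiologically plausible ranges used to reject mis-tracked or mis-sensed
#' trials: peak engagement velocity within 2.5-4.5 m/s and peak contact force
#' within 1-4 kN (both bounds inclusive), plus the 10 N contact-detection
#' threshold used for segmentation.
#'
#' @param v_peak_min,v_peak_max velocity-peak range, m/s.
#' @param f_peak_min,f_peak_max force-peak range, N.
#' @param contact_threshold contact-detection force, N.
#' @return an object of class `cleaning_config`.
#' @export
cleaning_config <- function(v_peak_min = 2.5, v_peak_max = 4.5,
                            f_peak_min = 1000, f_peak_max = 4000,
                            contact_threshold = 10) {
  if (v_peak_min >= v_peak_max)
    stop_config("velocity range invalid: min %.3f >= max %.3f", v_peak_min, v_peak_max)
  if (f_peak_min >= f_peak_max)
    stop_config("force range invalid: min %.1f >= max %.1f", f_peak_min, f_peak_max)
  if (contact_threshold <= 0)
    stop_config("contact_threshold must be positive (got %.3f)", contact_threshold)
  structure(list(v_peak_min = v_peak_min, v_peak_max = v_peak_max,
                 f_peak_min = f_peak_min, f_peak_max = f_peak_max,
                 contact_threshold = contact_threshold),
            class = "cleaning_config")
}
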