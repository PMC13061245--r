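# Plain-text interchange formats.
#
# Raw trials: <id>_landmarks.csv (frame, player_id, c7_x, c7_y, lum_x,
# lum_y; metres), <id>_force.csv (sample, force_n) and <id>_meta.json
# (trial_id, technique, pairing, video_rate_hz, force_rate_hz, shoulder).
#
# Processed pairs: <id>.csv (t_norm, velocity_ms, force_n; 101 rows) plus
# <id>.json metadata. A directory of such files is the dataset format all
# downstream stages consume, so any external deposit of engagement trials
# can be used by exporting it to this dialect.

#' Write / read a velocity-force pair
#'
#' @param pair a [vf_pair()].
#' @param prefix file path without extension; `.csv` and `.json` are added.
#' @return `write_pair` returns `prefix` invisibly; `read_pair` returns the
#'   [vf_pair()].
#' @export
write_pair <- function(pair, prefix) {
  if (!inherits(pair, "vf_pair")) stop_data("write_pair expects a vf_pair")
  utils::write.csv(data.frame(t_norm = seq(0, 1, length.out = N_POINTS),
                              velocity_ms = pair$velocity,
                              force_n = pair$force),
                   paste0(prefix, ".csv"), row.names = FALSE)
  meta <- pair$meta
  meta$source <- pair$source
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_pair
#' @export
read_pair <- function(prefix) {
  csv <- paste0(prefix, ".csv"); js <- paste0(prefix, ".json")
  if (!file.exists(csv)) stop_data("pair file not found: %s", csv)
  d <- utils::read.csv(csv)
  if (!all(c("velocity_ms", "force_n") %in% names(d)))
    stop_data("%s lacks velocity_ms/force_n columns", csv)
  meta <- if (file.exists(js)) jsonlite::read_json(js, simplifyVector = TRUE)
          else list()
  src <- meta$source %||% "measured"
  meta$source <- NULL
  vf_pair(d$velocity_ms, d$force_n, meta = meta, source = src)
}

#' Write / read a directory of pairs
#'
#' @param pairs list of [vf_pair()]s.
#' @param dir directory (created if needed).
#' @return `write_pair_dataset` returns `dir` invisibly; `read_pair_dataset`
#'   returns the list of pairs, ordered by file name.
#' @export
write_pair_dataset <- function(pairs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(pairs)) {
    id <- pairs[[i]]$meta$trial_id %||% sprintf("pair-%04d", i)
    write_pair(pairs[[i]], file.path(dir, id))
  }
  invisible(dir)
}

#' @rdname write_pair_dataset
#' @export
read_pair_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop_data("no pair CSV files in %s", dir)
  lapply(sub("\\.csv$", "", files), read_pair)
}

#' Write / read a raw engagement trial
#'
#' @param trial an [engagement_trial()].
#' @param dir directory (created if needed); files are named by trial id.
#' @param trial_id trial to read back.
#' @return `write_trial` returns the file prefix invisibly; `read_trial`
#'   returns the [engagement_trial()].
#' @export
write_trial <- function(trial, dir) {
  if (!inherits(trial, "engagement_trial")) stop_data("write_trial expects an engagement_trial")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pre <- file.path(dir, trial$trial_id)
  lm <- function(tk) data.frame(frame = seq_len(tk$frames) - 1L,
                                player_id = tk$player_id,
                                c7_x = tk$c7_xy[, 1], c7_y = tk$c7_xy[, 2],
                                lum_x = tk$lumbar_xy[, 1],
                                lum_y = tk$lumbar_xy[, 2])
  utils::write.csv(rbind(lm(trial$track_a), lm(trial$track_b)),
                   paste0(pre, "_landmarks.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample = seq_along(trial$force$samples) - 1L,
                              force_n = trial$force$samples),
                   paste0(pre, "_force.csv"), row.names = FALSE)
  jsonlite::write_json(list(trial_id = trial$trial_id,
                            technique = trial$technique,
                            pairing = trial$pairing,
                            video_rate_hz = trial$track_a$rate_hz,
                            force_rate_hz = trial$force$rate_hz,
                            shoulder = trial$force$shoulder),
                       paste0(pre, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(pre)
}

#' @rdname write_trial
#' @export
read_trial <- function(dir, trial_id) {
  pre <- file.path(dir, trial_id)
  meta <- jsonlite::read_json(paste0(pre, "_meta.json"), simplifyVector = TRUE)
  lmk <- utils::read.csv(paste0(pre, "_landmarks.csv"))
  need <- c("frame", "player_id", "c7_x", "c7_y", "lum_x", "lum_y")
  if (!all(need %in% names(lmk)))
    stop_data("%s_landmarks.csv needs columns %s", pre, paste(need, collapse = ", "))
  ids <- unique(lmk$player_id)
  if (length(ids) != 2L)
    stop_data("trial '%s': expected 2 players in landmark file, found %d",
              trial_id, length(ids))
  mk <- function(pid) {
    d <- lmk[lmk$player_id == pid, ]
    d <- d[order(d$frame), ]
    if (any(diff(d$frame) != 1L))
      stop_data("trial '%s': player %s has frame gaps", trial_id, pid)
    landmark_track(cbind(d$c7_x, d$c7_y), cbind(d$lum_x, d$lum_y),
                   rate_hz = meta$video_rate_hz, player_id = pid)
  }
  frc <- utils::read.csv(paste0(pre, "_force.csv"))
  engagement_trial(meta$trial_id, meta$technique, meta$pairing,
                   mk(ids[1]), mk(ids[2]),
                   force_trace(frc$force_n, rate_hz = meta$force_rate_hz,
                               shoulder = meta$shoulder %||% "left"))
}

#' List trial ids available in a raw-trial directory
#' @param dir directory written by [write_trial()].
#' @return character vector of trial ids.
#' @export
list_trials <- function(dir) {
  sub("_meta\\.json$", "",
      basename(list.files(dir, pattern = "_meta\\.json$")))
}
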