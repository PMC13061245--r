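# Agreement statistics between measured and predicted force curves:
# per-trial Pearson correlation (with qualitative ranking), RMSE and peak
# difference with percentages normalized to the measured maximum,
# Bland-Altman limits of agreement on peak forces, and grouped summaries
# by engagement technique or shoulder.

#' Qualitative ranking of a Pearson correlation
#'
#' Bands: poor (up to 0.5), moderate (above 0.5 up to 0.75), good (above
#' 0.75 up to 0.9), excellent (above 0.9). Upper endpoints belong to the
#' lower band, so r = 0.75 is moderate and r = 0.9 is good; negative r is
#' poor.
#'
#' @param r Pearson correlation in `[-1, 1]`.
#' @return factor level: `poor`, `moderate`, `good` or `excellent`.
#' @export
rank_correlation <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < -1 - 1e-12) ||
      any(r > 1 + 1e-12))
    stop_data("r must be a finite correlation in [-1, 1]")
  cut(r, breaks = c(-1 - 1e-9, 0.5, 0.75, 0.9, 1 + 1e-9),
      labels = c("poor", "moderate", "good", "excellent"), right = TRUE)
}

#' Per-trial agreement between measured and predicted force curves
#'
#' @param measured,predicted numeric force curves (N), equal length >= 3;
#'   the measured curve must not be constant.
#' @param meta optional list with `trial_id`, `technique`, `shoulder` (or
#'   `pairing`, from which the shoulder is derived).
#' @return one-row data frame of class `agreement_record`: `trial_id`,
#'   `technique`, `shoulder`, `correlation`, `rmse` (N), `nrmse_pct` (% of
#'   the measured maximum), `peak_diff` (N, absolute), `npeak_pct` (%),
#'   `rank`.
#' @export
agreement <- function(measured, predicted, meta = list()) {
  check_numeric_vector(measured, "measured", min_len = 3L)
  check_numeric_vector(predicted, "predicted", min_len = 3L)
  if (length(measured) != length(predicted))
    stop_shape("curve lengths differ: %d vs %d", length(measured), length(predicted))
  if (stats::sd(measured) == 0)
    stop_data("measured curve is constant; correlation is undefined")
  r <- stats::cor(measured, predicted)
  if (!is.finite(r)) r <- 0  # constant prediction: no linear association
  rmse <- sqrt(mean((measured - predicted)^2))
  peak <- abs(max(measured) - max(predicted))
  fmax <- max(measured)
  shoulder <- meta$shoulder %||%
    (if (!is.null(meta$pairing)) pairing_shoulder(meta$pairing) else NA_character_)
  out <- data.frame(trial_id = meta$trial_id %||% NA_character_,
                    technique = meta$technique %||% NA_character_,
                    shoulder = shoulder,
                    correlation = r, rmse = rmse,
                    nrmse_pct = 100 * rmse / fmax,
                    peak_diff = peak, npeak_pct = 100 * peak / fmax,
                    rank = as.character(rank_correlation(r)),
                    stringsAsFactors = FALSE)
  class(out) <- c("agreement_record", class(out))
  out
}

#' Bland-Altman limits of agreement for peak forces
#'
#' Differences are taken as `predicted - measured`, so a positive bias means
#' the model overestimates peaks. Limits of agreement are
#' `bias +/- 1.96 * SD` with the n-1 standard deviation. When group labels
#' are supplied (e.g. engagement technique), per-group sub-results are
#' computed on the label subsets.
#'
#' @param peaks_measured,peaks_predicted numeric vectors, equal length >= 2.
#' @param group_labels optional character/factor vector of the same length.
#' @return object of class `bland_altman`: `bias`, `loa_lower`, `loa_upper`
#'   (N), `sd`, `n`, `differences`, `means`, and `groups` (a data frame of
#'   per-group results, or `NULL`).
#' @export
bland_altman <- function(peaks_measured, peaks_predicted, group_labels = NULL) {
  check_numeric_vector(peaks_measured, "peaks_measured", min_len = 2L)
  if (length(peaks_measured) != length(peaks_predicted))
    stop_shape("peak vectors differ in length: %d vs %d",
               length(peaks_measured), length(peaks_predicted))
  d <- peaks_predicted - peaks_measured
  bias <- mean(d)
  s <- stats::sd(d)
  groups <- NULL
  if (!is.null(group_labels)) {
    if (length(group_labels) != length(d))
      stop_shape("group_labels length %d does not match %d peaks",
                 length(group_labels), length(d))
    groups <- do.call(rbind, lapply(split(d, group_labels), function(di) {
      bi <- mean(di); si <- if (length(di) > 1L) stats::sd(di) else 0
      data.frame(n = length(di), bias = bi,
                 loa_lower = bi - 1.96 * si, loa_upper = bi + 1.96 * si)
    }))
    groups <- cbind(group = rownames(groups), groups)
    rownames(groups) <- NULL
  }
  structure(list(bias = bias, sd = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 n = length(d), differences = d,
                 means = (peaks_predicted + peaks_measured) / 2,
                 groups = groups),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (predicted - measured), n = %d\n", x$n))
  cat(sprintf("  bias %.1f N, limits of agreement [%.1f, %.1f] N\n",
              x$bias, x$loa_lower, x$loa_upper))
  if (!is.null(x$groups)) {
    cat("  per group:\n")
    print(x$groups, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences, xlab = "mean peak force (N)",
                 ylab = "predicted - measured (N)", pch = 19,
                 col = grDevices::adjustcolor("steelblue", 0.7), ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2), col = "grey30")
  invisible(x)
}

#' Grouped agreement report
#'
#' Aggregates per-trial agreement records by engagement technique or
#' shoulder: mean and SD of correlation, RMSE and peak difference. The
#' percentage columns are recomputed against the maximum force over the
#' group's measured curves (not the per-trial maxima), so they describe
#' the error relative to the group's force scale.
#'
#' @param records data frame of rows produced by [agreement()].
#' @param by `"technique"` or `"shoulder"`.
#' @param raw_measured list of the measured force curves (numeric vectors),
#'   aligned with the rows of `records`; used for the group normalization
#'   basis.
#' @return data frame, one row per group: means and SDs with `_pct`
#'   companions, plus `group_max_force`, the normalization basis.
#' @export
grouped_report <- function(records, by = c("technique", "shoulder"),
                           raw_measured) {
  by <- match.arg(by)
  if (!by %in% names(records)) stop_data("records lack a '%s' column", by)
  if (length(raw_measured) != nrow(records))
    stop_shape("raw_measured has %d curves for %d records",
               length(raw_measured), nrow(records))
  labels <- records[[by]]
  if (anyNA(labels)) stop_data("missing %s labels in records", by)
  out <- lapply(split(seq_len(nrow(records)), labels), function(ix) {
    gmax <- max(vapply(raw_measured[ix], max, numeric(1)))
    r <- records[ix, ]
    sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
    data.frame(n = length(ix),
               correlation_mean = mean(r$correlation),
               correlation_sd = sd0(r$correlation),
               rmse_mean = mean(r$rmse), rmse_sd = sd0(r$rmse),
               rmse_pct_mean = 100 * mean(r$rmse) / gmax,
               rmse_pct_sd = 100 * sd0(r$rmse) / gmax,
               peak_diff_mean = mean(r$peak_diff), peak_diff_sd = sd0(r$peak_diff),
               peak_pct_mean = 100 * mean(r$peak_diff) / gmax,
               peak_pct_sd = 100 * sd0(r$peak_diff) / gmax,
               group_max_force = gmax)
  })
  res <- do.call(rbind, out)
  cbind(setNames(data.frame(rownames(res), stringsAsFactors = FALSE), by),
        res, row.names = NULL)
}
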