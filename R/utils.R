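# Internal helpers: condition classes, seeded evaluation, small checks.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scrumforce_config_error", "scrumforce_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scrumforce_data_error", "scrumforce_error")))
}

stop_shape <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scrumforce_shape_error", "scrumforce_data_error",
                                "scrumforce_error")))
}

stop_divergence <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("scrumforce_divergence_error", "scrumforce_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a fixed RNG state, restoring the caller's stream.
# All stochastic stages funnel through this so one integer seed makes a
# whole pipeline run reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(expr)
}

check_numeric_vector <- function(x, name, min_len = 1L, finite = TRUE) {
  if (!is.numeric(x) || length(x) < min_len)
    stop_data("'%s' must be a numeric vector of length >= %d (got length %d)",
              name, min_len, length(x))
  if (finite && !all(is.finite(x)))
    stop_data("'%s' contains non-finite values", name)
  invisible(x)
}
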