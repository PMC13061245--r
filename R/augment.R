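# Mixup augmentation and assembly of the augmented training set.

#' Mixup of two velocity-force pairs
#'
#' Forms the convex combination `lam * a + (1 - lam) * b` of both channels.
#' With the default constant coefficient 0.5 the result is the plain average
#' of the two parent curves, a physically plausible intermediate engagement.
#'
#' @param a,b [vf_pair()] objects.
#' @param lam mixing coefficient in `[0, 1]` (default 0.5).
#' @return a [vf_pair()] with `source = "mixup"`.
#' @export
mixup_pair <- function(a, b, lam = 0.5) {
  if (!inherits(a, "vf_pair") || !inherits(b, "vf_pair"))
    stop_data("mixup_pair expects two vf_pair objects")
  if (length(a$velocity) != length(b$velocity) ||
      length(a$force) != length(b$force))
    stop_shape("pair lengths differ: %d/%d vs %d/%d", length(a$velocity),
               length(a$force), length(b$velocity), length(b$force))
  if (!is.numeric(lam) || lam < 0 || lam > 1)
    stop_config("lam must lie in [0, 1] (got %s)", format(lam))
  vf_pair(lam * a$velocity + (1 - lam) * b$velocity,
          lam * a$force + (1 - lam) * b$force,
          meta = list(parents = c(a$meta$trial_id %||% NA_character_,
                                  b$meta$trial_id %||% NA_character_),
                      lam = lam),
          source = "mixup")
}

#' Build the augmented training dataset
#'
#' Generates `n_gan` pairs from the trained GAN, then forms `n_mix` Mixup
#' pairs by averaging random distinct members of the GAN pool (coefficient
#' 0.5). Measured pairs can optionally join the Mixup pool. The whole
#' construction is deterministic under `seed`.
#'
#' @param measured list of measured [vf_pair()]s (used only when
#'   `include_measured = TRUE`).
#' @param model a trained [train_gan()] model.
#' @param n_gan,n_mix counts of GAN and Mixup pairs (`>= 0`).
#' @param seed integer seed.
#' @param include_measured if `TRUE`, measured pairs join the Mixup pool.
#' @return list of [vf_pair()]s, GAN pairs first, with provenance in
#'   `$source`.
#' @export
build_augmented_dataset <- function(measured, model, n_gan = 1000, n_mix = 0,
                                    seed = 1L, include_measured = FALSE) {
  if (n_gan < 0 || n_mix < 0) stop_config("n_gan and n_mix must be >= 0")
  gan_pairs <- if (n_gan > 0) generate_pairs(model, n_gan, seed = seed) else list()
  pool <- gan_pairs
  if (include_measured) pool <- c(pool, measured)
  if (n_mix > 0 && length(pool) < 2L)
    stop_config("Mixup needs a pool of at least 2 pairs (have %d)", length(pool))
  mix <- if (n_mix > 0) with_seed(seed + 1L, {
    lapply(seq_len(n_mix), function(i) {
      ij <- sample.int(length(pool), 2L)  # distinct parents
      mixup_pair(pool[[ij[1]]], pool[[ij[2]]], lam = 0.5)
    })
  }) else list()
  c(gan_pairs, mix)
}
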