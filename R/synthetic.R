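#' Specification for a synthetic microarray-like dataset
#'
#' Describes the generator regime the package is exercised with: a few tens of
#' samples per class, a few thousand Gaussian-noise features, and a small
#' informative subset whose class means are shifted. The defaults mirror a
#' typical two-class expression study at desk scale: 30 samples per class,
#' 2000 features of which 20 are informative, a two-noise-sd class shift and
#' unit noise. Class imbalance is expressed through `n_per_class`
#' (e.g. `c(134, 15)`).
#'
#' @param n_per_class integer vector: samples per class (length = class count).
#' @param n_features total feature count.
#' @param n_informative how many leading features carry class signal.
#' @param shift class-mean shift of informative features, in units of
#'   `noise_sd`.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param block_size informative features share a latent factor in blocks of
#'   this size (1 = independent features).
#' @param block_rho within-block correlation induced by the latent factor.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = c(30, 30), n_features = 2000,
                           n_informative = 20, shift = 2, noise_sd = 1,
                           block_size = 1, block_rho = 0.5) {
  stopifnot(n_informative <= n_features, shift >= 0, noise_sd > 0,
            all(n_per_class >= 2), block_size >= 1,
            block_rho >= 0, block_rho < 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 shift = shift, noise_sd = noise_sd,
                 block_size = as.integer(block_size), block_rho = block_rho),
            class = "synthetic_spec")
}

# Distinct mean patterns per class on the informative features: class k gets
# a +/-shift sign pattern alternating with period k, so any two classes
# differ (by 2*shift) on at least half of the informative features.
class_mean_patterns <- function(n_classes, n_informative, shift) {
  t(vapply(seq_len(n_classes), function(k) {
    signs <- ifelse(((seq_len(n_informative) - 1) %/% k) %% 2 == 0, 1, -1)
    shift * signs
  }, numeric(n_informative)))
}

#' Generate a synthetic labeled dataset
#'
#' Draws `sum(n_per_class)` samples of `n_features` Gaussian features
#' (sd `noise_sd`); the first `n_informative` features additionally receive a
#' class-specific `+/-shift` mean pattern (so two classes differing in sign on
#' a feature are `2 * shift` noise-sds apart there). With
#' `block_size > 1` the informative features share latent factors in blocks,
#' inducing within-block correlation `block_rho`. Deterministic given the
#' seed set before the call.
#'
#' @param spec a [synthetic_spec()].
#' @param seed optional seed set before generation.
#' @return a [labeled_dataset()] with classes `1..length(n_per_class)`.
#' @export
make_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- sum(spec$n_per_class)
  c_ <- length(spec$n_per_class)
  y <- rep(seq_len(c_), spec$n_per_class)
  x <- matrix(stats::rnorm(n * spec$n_features, sd = spec$noise_sd),
              nrow = n, ncol = spec$n_features)
  if (spec$n_informative > 0 && spec$shift > 0) {
    mu <- class_mean_patterns(c_, spec$n_informative, spec$shift * spec$noise_sd)
    x[, seq_len(spec$n_informative)] <-
      x[, seq_len(spec$n_informative), drop = FALSE] + mu[y, , drop = FALSE]
  }
  if (spec$block_size > 1 && spec$n_informative > 0) {
    rho <- spec$block_rho
    blocks <- split(seq_len(spec$n_informative),
                    (seq_len(spec$n_informative) - 1) %/% spec$block_size)
    for (b in blocks) {
      z <- stats::rnorm(n, sd = spec$noise_sd)
      x[, b] <- sqrt(1 - rho) * x[, b, drop = FALSE] + sqrt(rho) * z
    }
  }
  labeled_dataset(x, y,
                  sample_ids = paste0("s", seq_len(n)),
                  feature_ids = paste0("g", seq_len(spec$n_features)))
}

#' Generate a synthetic vote matrix with known truth
#'
#' Builds `n_classifiers` independent `-1/+1` vote vectors by flipping a
#' balanced truth vector at per-classifier error rates — a test harness for
#' the fusion and committee-selection machinery that involves no trees at all.
#'
#' @param n_classifiers number of vote columns.
#' @param n_samples number of samples.
#' @param error_rates scalar or per-classifier flip probability in `[0, 1]`.
#' @param seed optional seed.
#' @return list with `votes` (samples x classifiers matrix) and `truth`
#'   (`-1/+1`, balanced up to rounding).
#' @export
make_vote_matrix <- function(n_classifiers, n_samples, error_rates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  error_rates <- rep_len(error_rates, n_classifiers)
  if (any(error_rates < 0 | error_rates > 1)) stop("error rates must lie in [0, 1]")
  truth <- rep(c(-1, 1), length.out = n_samples)
  votes <- vapply(error_rates, function(e) {
    flip <- stats::runif(n_samples) < e
    ifelse(flip, -truth, truth)
  }, numeric(n_samples))
  list(votes = matrix(votes, nrow = n_samples), truth = truth)
}
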