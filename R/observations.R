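#' Draw a sparse simplex weight vector
#'
#' Draws "true" agromanagement mixture weights: a random subset of
#' `n_active` combinations receives Dirichlet(`concentration`) weights, the
#' rest are zero.
#'
#' @param n_combos grid size.
#' @param n_active number of combinations with non-zero weight.
#' @param concentration Dirichlet concentration parameter.
#' @param seed integer seed.
#' @return numeric vector of length `n_combos` on the simplex.
#' @export
draw_weights <- function(n_combos, n_active = 12, concentration = 1,
                         seed = 1L) {
  set.seed(seed)
  n_active <- min(n_active, n_combos)
  idx <- sample.int(n_combos, n_active)
  g <- stats::rgamma(n_active, shape = concentration)
  if (sum(g) <= 0) g <- rep(1, n_active)
  w <- numeric(n_combos)
  w[idx] <- g / sum(g)
  w
}

check_simplex <- function(w, tol = 1e-6) {
  if (any(w < -tol) || abs(sum(w) - 1) > tol) {
    stop("weights are off the probability simplex", call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a county-year observation record from a simulation ensemble
#'
#' Mixes the ensemble with hidden "true" weights to produce the observed
#' county yield (after the yield-gap reduction), the observed season length
#' (maturity minus emergence), and the per-day phenological stage-fraction
#' curves, with additive Gaussian noise on the two scalars.
#'
#' @param sim output of [run_surrogate_grid()] for one county-year.
#' @param true_weights simplex weight vector, one entry per combination.
#' @param yield_gap_factor fraction by which attainable yields are reduced
#'   (default 0.15).
#' @param noise_sds list with `yield` (Mg ha^-1) and `season` (days).
#' @param seed integer seed for the observation noise.
#' @return a list of class `simcal_observation` with `observed_yield`,
#'   `observed_season_length`, `stage_fractions` (stage x day matrix whose
#'   columns sum to 1) and the hidden `true_weights`.
#' @export
generate_observations <- function(sim, true_weights, yield_gap_factor = 0.15,
                                  noise_sds = list(yield = 0, season = 0),
                                  seed = 1L) {
  check_simplex(true_weights)
  if (length(true_weights) != length(sim$final_yield)) {
    stop("true_weights length does not match the ensemble size", call. = FALSE)
  }
  if (yield_gap_factor < 0 || yield_gap_factor >= 1) {
    stop("yield_gap_factor must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  y <- (1 - yield_gap_factor) * sum(true_weights * sim$final_yield) +
    stats::rnorm(1, 0, noise_sds$yield)
  p <- sum(true_weights * sim$season_length) +
    stats::rnorm(1, 0, noise_sds$season)

  n_stages <- 6L
  nd <- nrow(sim$stage)
  frac <- matrix(0, n_stages, nd,
                 dimnames = list(paste0("stage", seq_len(n_stages)), NULL))
  for (m in seq_len(n_stages)) {
    frac[m, ] <- as.numeric((sim$stage == m) %*% true_weights)
  }
  structure(
    list(observed_yield = max(y, 0), observed_season_length = p,
         stage_fractions = frac, true_weights = true_weights),
    class = "simcal_observation"
  )
}
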