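#' Per-timestep cross-validated retrieval metrics
#'
#' For every time step (and variable), computes across county-years the
#' R-squared of the out-of-fold predictions against the targets, the
#' cross-validated RMSE of the predictions, the cross-validated RMSE of the
#' leave-fold-out mean baseline (for each county-year, the target mean over
#' all other folds at that step), and the percentage uncertainty reduced,
#' `PRU = 100 * (1 - CVRMSE_predicted / CVRMSE_mean)`.
#'
#' @param predictions out-of-fold predictions: `(n, steps)` matrix or
#'   `(n, steps, vars)` array.
#' @param targets same shape as `predictions`.
#' @param folds integer fold label per county-year (row).
#' @return a data.frame with columns `variable`, `step`, `r2`, `pru`,
#'   `cvrmse_pred`, `cvrmse_mean`.
#' @export
per_timestep_metrics <- function(predictions, targets, folds) {
  if (length(dim(predictions)) == 2L) {
    predictions <- array(predictions, c(dim(predictions), 1L))
    targets <- array(targets, c(dim(targets), 1L))
  }
  stopifnot(all(dim(predictions) == dim(targets)))
  n <- dim(predictions)[1L]
  if (n < 2L) stop("need at least two county-years", call. = FALSE)
  n_steps <- dim(predictions)[2L]
  nv <- dim(predictions)[3L]
  vnames <- dimnames(predictions)[[3L]]
  if (is.null(vnames)) vnames <- dimnames(targets)[[3L]]
  if (is.null(vnames)) vnames <- paste0("var", seq_len(nv))

  out <- vector("list", nv)
  ufolds <- unique(folds)
  for (v in seq_len(nv)) {
    r2 <- pru <- rp <- rm <- rep(NA_real_, n_steps)
    for (t in seq_len(n_steps)) {
      p <- predictions[, t, v]
      y <- targets[, t, v]
      ok <- is.finite(p) & is.finite(y)
      if (sum(ok) < 2L) next
      r <- suppressWarnings(stats::cor(p[ok], y[ok]))
      r2[t] <- if (is.finite(r)) r^2 else 0
      rp[t] <- sqrt(mean((p[ok] - y[ok])^2))
      # leave-fold-out mean baseline
      base <- rep(NA_real_, n)
      for (f in ufolds) {
        inf <- folds == f
        base[inf] <- mean(y[!inf & ok])
      }
      rm[t] <- sqrt(mean((base[ok] - y[ok])^2))
      pru[t] <- 100 * (1 - rp[t] / rm[t])
    }
    out[[v]] <- data.frame(variable = vnames[v], step = seq_len(n_steps),
                           r2 = r2, pru = pru, cvrmse_pred = rp,
                           cvrmse_mean = rm, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Derive specific leaf area from retrieved LAI and leaf biomass
#'
#' `SLA = (LAI * 1e4 m^2 ha^-1) / leaf biomass (kg ha^-1)` in m^2 kg^-1,
#' masked (`NA`) wherever LAI <= 0.1 or leaf biomass <= 1 kg ha^-1.
#'
#' @param lai LAI values (any shape).
#' @param leaf_biomass total leaf biomass, kg ha^-1, same shape.
#' @return SLA with the mask applied.
#' @export
derive_sla <- function(lai, leaf_biomass) {
  if (any(lai < 0, na.rm = TRUE) || any(leaf_biomass < 0, na.rm = TRUE)) {
    stop("negative inputs to SLA", call. = FALSE)
  }
  out <- (lai * 1e4) / leaf_biomass
  out[!(lai > 0.1 & leaf_biomass > 1)] <- NA_real_
  out
}

#' Derive leaf nitrogen percentage from retrieved leaf N and leaf biomass
#'
#' `LNP = leaf N biomass / leaf biomass` (a fraction), masked wherever leaf
#' biomass <= 1 kg ha^-1 or leaf N biomass <= 0.001 kg ha^-1.
#'
#' @param leaf_n leaf nitrogen biomass, kg ha^-1.
#' @param leaf_biomass total leaf biomass, kg ha^-1, same shape.
#' @return LNP with the mask applied.
#' @export
derive_lnp <- function(leaf_n, leaf_biomass) {
  if (any(leaf_n < 0, na.rm = TRUE) || any(leaf_biomass < 0, na.rm = TRUE)) {
    stop("negative inputs to LNP", call. = FALSE)
  }
  out <- leaf_n / leaf_biomass
  out[!(leaf_biomass > 1 & leaf_n > 0.001)] <- NA_real_
  out
}

#' Mean transition date from a cumulative transition curve
#'
#' Given the fraction of fields that have experienced a transition at each
#' day of a time grid, enforces monotonicity by a running maximum,
#' interprets the curve as piecewise linear between grid days, and returns
#' the mean of the implied transition-date distribution (with any mass
#' beyond the last grid day at the first/last day, and renormalised when
#' the curve does not reach 1). `NA` when the curve never exceeds 0.5.
#'
#' @param days numeric day-of-year grid.
#' @param cdf fractions in [0, 1] at those days.
#' @param also_median return a named vector with both mean and median.
#' @return the mean transition date (or a named vector when
#'   `also_median = TRUE`).
#' @export
transition_date_from_cdf <- function(days, cdf, also_median = FALSE) {
  stopifnot(length(days) == length(cdf))
  cdf <- cummax(pmin(pmax(cdf, 0), 1))
  total <- cdf[length(cdf)]
  if (total <= 0.5) {
    return(if (also_median) c(mean = NA_real_, median = NA_real_) else NA_real_)
  }
  dF <- diff(c(0, cdf))
  # mass in the first element sits at the first grid day; interior mass is
  # uniform on its segment, contributing at the segment midpoint
  mids <- c(days[1L], (days[-1L] + days[-length(days)]) / 2)
  mean_date <- sum(mids * dF) / total
  if (!also_median) return(mean_date)
  med_level <- total / 2
  i <- which(cdf >= med_level)[1L]
  med <- if (i == 1L) days[1L] else {
    stats::approx(cdf[(i - 1L):i], days[(i - 1L):i], med_level,
                  ties = "ordered")$y
  }
  c(mean = mean_date, median = med)
}

#' Transition dates from a stage-probability matrix
#'
#' For each of the five transitions between consecutive merged stages,
#' builds the cumulative curve "fraction of fields at or past the
#' post-transition stage" over the time grid and extracts the mean
#' transition date with [transition_date_from_cdf()].
#'
#' @param stage_probs row-stochastic steps x stages matrix (or daily
#'   fraction curves with days as rows).
#' @param days day-of-year per row (default the 29-step grid).
#' @return named numeric vector of dates, one per transition (`NA` where
#'   the transition is not reached).
#' @export
transition_dates <- function(stage_probs, days = time_grid()) {
  stopifnot(nrow(stage_probs) == length(days))
  n_stages <- ncol(stage_probs)
  out <- vapply(2:n_stages, function(m) {
    cdf <- rowSums(stage_probs[, m:n_stages, drop = FALSE])
    transition_date_from_cdf(days, cdf)
  }, 0)
  names(out) <- transition_names()[seq_len(n_stages - 1L)]
  out
}

#' Stage confusion matrix and Cohen's kappa
#'
#' The predicted stage at each step is the argmax of the stage
#' probabilities; predictions are pooled over all county-years and steps
#' into a confusion matrix against the reference stages, from which the
#' standard Cohen's kappa is computed.
#'
#' @param pred_probs `(n, steps, stages)` array (or `(steps, stages)`
#'   matrix) of predicted stage probabilities.
#' @param reference_stages integer array/matrix of reference stage codes
#'   (1-based), shape `(n, steps)` (or vector of length `steps`).
#' @param n_stages number of stages.
#' @return list with `confusion` (reference rows x predicted columns) and
#'   `kappa`.
#' @export
stage_confusion <- function(pred_probs, reference_stages, n_stages = 6L) {
  if (length(dim(pred_probs)) == 2L) {
    pred_probs <- array(pred_probs, c(1L, dim(pred_probs)))
    reference_stages <- matrix(reference_stages, 1L)
  }
  n <- dim(pred_probs)[1L]; n_steps <- dim(pred_probs)[2L]
  pred_stage <- apply(pred_probs, c(1L, 2L), which.max)
  ref <- as.integer(reference_stages)
  prd <- as.integer(pred_stage)
  if (length(intersect(unique(ref), seq_len(n_stages))) == 0L) {
    stop("reference labels share no classes with the predictions",
         call. = FALSE)
  }
  conf <- table(factor(ref, levels = seq_len(n_stages)),
                factor(prd, levels = seq_len(n_stages)))
  conf <- unclass(conf)
  dimnames(conf) <- list(reference = stage_names()[seq_len(n_stages)],
                         predicted = stage_names()[seq_len(n_stages)])
  total <- sum(conf)
  po <- sum(diag(conf)) / total
  pe <- sum(rowSums(conf) * colSums(conf)) / total^2
  kappa <- if (abs(1 - pe) < 1e-12) 0 else (po - pe) / (1 - pe)
  list(confusion = conf, kappa = kappa)
}

#' Aggregate county values to regions
#'
#' @param county_values named numeric vector (names = county ids) or a
#'   data.frame with `county_id` and `value`.
#' @param region_map named vector mapping county id to region id.
#' @param weights optional named per-county weights (unweighted by default).
#' @return named numeric vector of per-region means.
#' @export
aggregate_to_region <- function(county_values, region_map, weights = NULL) {
  if (is.data.frame(county_values)) {
    county_values <- stats::setNames(county_values$value,
                                     county_values$county_id)
  }
  regions <- region_map[names(county_values)]
  if (anyNA(regions)) stop("unmapped counties: ",
                           paste(names(county_values)[is.na(regions)][1:3],
                                 collapse = ", "), call. = FALSE)
  if (is.null(weights)) {
    out <- tapply(county_values, regions, mean)
  } else {
    w <- weights[names(county_values)]
    out <- tapply(seq_along(county_values), regions, function(ii)
      sum(county_values[ii] * w[ii]) / sum(w[ii]))
  }
  empty <- setdiff(unique(region_map), names(out))
  if (length(empty) > 0L) stop("region(s) with no counties: ",
                               paste(empty, collapse = ", "), call. = FALSE)
  stats::setNames(as.numeric(out), names(out))
}

#' Transition-date truth from an observation record
#'
#' Extracts the five reference transition dates from the daily true
#' stage-fraction curves of a synthetic observation record.
#'
#' @param observation a `simcal_observation`.
#' @return named numeric vector of dates.
#' @export
observed_transition_dates <- function(observation) {
  frac <- observation$stage_fractions  # stages x days
  transition_dates(t(frac), days = seq_len(ncol(frac)))
}
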