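#' Weighted ensemble prediction of a continuous variable
#'
#' The calibrated model predicts any continuous variable as the
#' weight-vector mixture of the per-combination simulated values.
#'
#' @param weights simplex weight vector.
#' @param per_combo_values numeric vector, one value per combination.
#' @return the mixture value `sum(w_i * x_i)`.
#' @export
predict_continuous <- function(weights, per_combo_values) {
  if (length(weights) != length(per_combo_values)) {
    stop("weights and values have different lengths", call. = FALSE)
  }
  check_simplex(weights)
  sum(weights * per_combo_values)
}

#' Predicted fraction of fields per phenological stage on a day
#'
#' Interprets the weights as the share of fields grown under each
#' agromanagement combination: the fraction of fields in stage `m` on day
#' `d` is the summed weight of the combinations whose stage sequence is in
#' stage `m` on that day.
#'
#' @param weights simplex weight vector.
#' @param stage_matrix integer day x combo matrix of stage codes.
#' @param day day index into the rows of `stage_matrix`.
#' @param n_stages number of stage codes.
#' @return named numeric vector of per-stage fractions (sums to 1).
#' @export
predict_stage_fractions <- function(weights, stage_matrix, day,
                                    n_stages = 6L) {
  check_simplex(weights)
  if (day < 1 || day > nrow(stage_matrix)) {
    stop("day outside the simulated calendar", call. = FALSE)
  }
  s <- stage_matrix[day, ]
  out <- vapply(seq_len(n_stages), function(m) sum(weights[s == m]), 0)
  names(out) <- paste0("stage", seq_len(n_stages))
  out
}

#' Apply the yield-gap reduction to simulated attainable yields
#'
#' Simulated yields are attainable (water- and nitrogen-limited) yields;
#' actual yields are lower because of pests, weeds and other unmodelled
#' factors. Each yield is multiplied by `1 - gap_factor` (default 15%).
#'
#' @param simulated_yields non-negative yields, Mg ha^-1.
#' @param gap_factor fraction in [0, 1).
#' @return adjusted yields.
#' @export
apply_yield_gap <- function(simulated_yields, gap_factor = 0.15) {
  if (gap_factor < 0 || gap_factor >= 1) {
    stop("gap_factor must lie in [0, 1)", call. = FALSE)
  }
  if (any(simulated_yields < 0)) {
    stop("negative simulated yields", call. = FALSE)
  }
  simulated_yields * (1 - gap_factor)
}

#' Assemble a calibration set
#'
#' Collects, for a subset of county-years, the gap-adjusted simulated yields
#' and simulated season lengths of every combination together with the
#' observed yields and season lengths, and the normalising standard
#' deviations of the two observed series.
#'
#' @param dataset a `simcal_dataset`.
#' @param record_idx integer indices of the county-years to include
#'   (default: all).
#' @param gap_factor yield-gap factor applied to the simulated yields.
#' @param sigma optional list with `yield` and `season` normalisers to use
#'   when the subset's own standard deviations are degenerate (zero or
#'   undefined); without it a degenerate subset is an error.
#' @return a list of class `simcal_calset` with matrices `Ysim`, `Psim`
#'   (county-year x combo), vectors `yobs`, `pobs`, scalars `sigma_y`,
#'   `sigma_p`, and the index data.frame `meta`.
#' @export
make_calibration_set <- function(dataset, record_idx = NULL,
                                 gap_factor = dataset$config$observation$yield_gap,
                                 sigma = NULL) {
  if (is.null(record_idx)) record_idx <- seq_along(dataset$records)
  recs <- dataset$records[record_idx]
  Ysim <- do.call(rbind, lapply(recs, `[[`, "yields"))
  Ysim <- apply_yield_gap(Ysim, gap_factor)
  Psim <- do.call(rbind, lapply(recs, `[[`, "season_lengths"))
  yobs <- vapply(recs, function(r) r$observation$observed_yield, 0)
  pobs <- vapply(recs, function(r) r$observation$observed_season_length, 0)
  sigma_y <- stats::sd(yobs)
  sigma_p <- stats::sd(pobs)
  if (!is.finite(sigma_y) || sigma_y <= 0) {
    sigma_y <- if (!is.null(sigma)) sigma$yield else NA_real_
  }
  if (!is.finite(sigma_p) || sigma_p <= 0) {
    sigma_p <- if (!is.null(sigma)) sigma$season else NA_real_
  }
  if (!is.finite(sigma_y) || sigma_y <= 0 || !is.finite(sigma_p) ||
      sigma_p <= 0) {
    stop("degenerate calibration set: observed yields or season lengths ",
         "have zero variance", call. = FALSE)
  }
  meta <- dataset_index(dataset)[record_idx, , drop = FALSE]
  structure(list(Ysim = Ysim, Psim = Psim, yobs = yobs, pobs = pobs,
                 sigma_y = sigma_y, sigma_p = sigma_p, meta = meta),
            class = "simcal_calset")
}

# Primal active-set solver for min ||A w - b||^2 over the probability
# simplex. Convex QP with a tiny ridge so every equality-constrained
# subproblem is well posed; terminates with KKT-optimal weights.
solve_simplex_ls <- function(A, b, tol = 1e-9, max_iter = 2000L) {
  n <- ncol(A)
  G <- crossprod(A)
  cvec <- drop(crossprod(A, b))
  ridge <- max(1e-12 * mean(diag(G)), 1e-14)
  diag(G) <- diag(G) + ridge

  # feasible start: best single combination
  f_single <- diag(G) - 2 * cvec
  S <- which.min(f_single)
  w <- numeric(n)
  w[S] <- 1

  solve_eqp <- function(S) {
    k <- length(S)
    K <- rbind(cbind(2 * G[S, S, drop = FALSE], rep(1, k)),
               c(rep(1, k), 0))
    rhs <- c(2 * cvec[S], 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      qr.solve(K + diag(1e-10, k + 1L), rhs)
    })
    list(w = sol[seq_len(k)], lambda = sol[k + 1L])
  }

  gscale <- max(abs(cvec), 1)
  for (it in seq_len(max_iter)) {
    sol <- solve_eqp(S)
    wS <- sol$w
    if (all(wS >= -1e-12)) {
      w[] <- 0
      w[S] <- pmax(wS, 0)
      w <- w / sum(w)
      g <- 2 * (drop(G %*% w) - cvec)
      lambda <- mean(g[S])
      viol <- lambda - g
      viol[S] <- -Inf
      j <- which.max(viol)
      if (viol[j] <= tol * gscale) break
      S <- sort(c(S, j))
    } else {
      # step toward the subproblem solution until a weight hits zero
      wS_cur <- w[S]
      d <- wS - wS_cur
      blocking <- which(wS < 0 & d < 0)
      alpha <- min(-wS_cur[blocking] / d[blocking])
      alpha <- min(max(alpha, 0), 1)
      wS_new <- wS_cur + alpha * d
      w[] <- 0
      w[S] <- pmax(wS_new, 0)
      drop_i <- S[which.min(wS_new)]
      S <- setdiff(S, drop_i)
      if (length(S) == 0L) S <- which.min(f_single)
    }
  }
  w / sum(w)
}

#' Fit ensemble weights by simplex-constrained least squares
#'
#' Minimises the dual objective summed over the county-years of the
#' calibration set,
#' `sum_k [(yobs_k - sum_i w_i Ysim_ik)^2 / sigma_y^2 +
#'         (pobs_k - sum_i w_i Psim_ik)^2 / sigma_p^2]`,
#' subject to `w_i >= 0` and `sum_i w_i = 1`, with a primal active-set
#' quadratic-programming solver. Deterministic given its inputs.
#'
#' @param calibration_set a `simcal_calset` from [make_calibration_set()].
#' @return a list of class `simcal_calresult` with the fitted `weights`,
#'   per-county-year `fitted_yield` and `fitted_season`, and the `objective`
#'   value.
#' @export
fit_weights <- function(calibration_set) {
  cs <- calibration_set
  A <- rbind(cs$Ysim / cs$sigma_y, cs$Psim / cs$sigma_p)
  b <- c(cs$yobs / cs$sigma_y, cs$pobs / cs$sigma_p)
  w <- solve_simplex_ls(A, b)
  fitted_yield <- drop(cs$Ysim %*% w)
  fitted_season <- drop(cs$Psim %*% w)
  objective <- sum((cs$yobs - fitted_yield)^2) / cs$sigma_y^2 +
    sum((cs$pobs - fitted_season)^2) / cs$sigma_p^2
  structure(list(weights = w, fitted_yield = fitted_yield,
                 fitted_season = fitted_season, objective = objective),
            class = "simcal_calresult")
}

#' Leave-one-out ensemble-weight calibration
#'
#' For every county-year, refits the weights on the county-years that share
#' neither its county nor its year (restricted to its cluster when a cluster
#' assignment is given) and predicts its yield and season length from the
#' refitted mixture. County-years whose exclusion rule leaves an empty (or
#' degenerate) training subset are flagged with a warning and omitted.
#'
#' @param dataset a `simcal_dataset`.
#' @param cluster_assignment optional named vector or `simcal_clusters`
#'   object mapping `county_id` to a cluster id.
#' @return data.frame with one row per predicted county-year: `county_id`,
#'   `year`, `cluster`, `pred_yield`, `pred_season`, `obs_yield`,
#'   `obs_season`.
#' @export
loo_calibrate <- function(dataset, cluster_assignment = NULL) {
  idx <- dataset_index(dataset)
  if (length(unique(idx$county_id)) < 2L || length(unique(idx$year)) < 2L) {
    warning("need at least two counties and two years; all predictions omitted")
    return(idx[0, c("county_id", "year")])
  }
  if (inherits(cluster_assignment, "simcal_clusters")) {
    cluster_assignment <- cluster_assignment$assignment
  }
  cl <- if (is.null(cluster_assignment)) {
    stats::setNames(rep(0L, length(unique(idx$county_id))),
                    unique(idx$county_id))
  } else cluster_assignment
  cluster_of <- cl[idx$county_id]

  # fall-back normalisers for training subsets too small to carry their own;
  # unit scales when the whole dataset is itself degenerate
  sane <- function(s) if (is.finite(s) && s > 0) s else 1
  sigma_full <- list(yield = sane(stats::sd(idx$observed_yield)),
                     season = sane(stats::sd(idx$observed_season_length)))
  rows <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    train <- which(idx$county_id != idx$county_id[k] &
                     idx$year != idx$year[k] &
                     cluster_of == cluster_of[k])
    if (length(train) == 0L) {
      warning("county-year ", idx$county_id[k], "/", idx$year[k],
              " has an empty training subset; prediction omitted")
      next
    }
    cs <- tryCatch(make_calibration_set(dataset, train, sigma = sigma_full),
                   error = function(e) NULL)
    if (is.null(cs)) {
      warning("county-year ", idx$county_id[k], "/", idx$year[k],
              " has a degenerate training subset; prediction omitted")
      next
    }
    fit <- fit_weights(cs)
    rec <- dataset$records[[k]]
    gap <- dataset$config$observation$yield_gap
    rows[[k]] <- data.frame(
      county_id = idx$county_id[k], year = idx$year[k],
      cluster = unname(cluster_of[k]),
      pred_yield = sum(fit$weights * apply_yield_gap(rec$yields, gap)),
      pred_season = sum(fit$weights * rec$season_lengths),
      obs_yield = idx$observed_yield[k],
      obs_season = idx$observed_season_length[k],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Calibration evaluation metrics
#'
#' Computes the leave-one-out R-squared (both as the squared Pearson
#' correlation, the headline number, and as `1 - SSE/SST`), the RMSE, and
#' the per-county explained standard deviation
#' `ESTD = 100 * (1 - LOO RMSE_county / sigma_overall)` (%).
#'
#' @param predictions numeric vector of predictions.
#' @param observations numeric vector of observations, same length.
#' @param sigma_overall overall standard deviation used by the ESTD
#'   (default: sd of `observations`).
#' @param county_id optional vector of county ids for the per-county ESTD.
#' @return list with `r2`, `r2_sse`, `rmse`, and (when `county_id` is given)
#'   a data.frame `estd_by_county`.
#' @export
calibration_metrics <- function(predictions, observations,
                                sigma_overall = stats::sd(observations),
                                county_id = NULL) {
  if (length(predictions) != length(observations) ||
      length(predictions) < 2L) {
    stop("need at least two paired predictions and observations",
         call. = FALSE)
  }
  rmse <- sqrt(mean((predictions - observations)^2))
  r2 <- suppressWarnings(stats::cor(predictions, observations))^2
  if (!is.finite(r2)) r2 <- 0
  sst <- sum((observations - mean(observations))^2)
  r2_sse <- if (sst > 0) 1 - sum((observations - predictions)^2) / sst else NA_real_
  out <- list(r2 = r2, r2_sse = r2_sse, rmse = rmse)
  if (!is.null(county_id)) {
    rc <- tapply(seq_along(predictions), county_id, function(ii)
      sqrt(mean((predictions[ii] - observations[ii])^2)))
    out$estd_by_county <- data.frame(
      county_id = names(rc),
      estd = 100 * (1 - as.numeric(rc) / sigma_overall),
      stringsAsFactors = FALSE)
  }
  out
}

#' Explained standard deviation
#'
#' `ESTD = 100 * (1 - rmse_county / sigma_overall)` (%): 100 at zero error,
#' 0 when the county error equals the overall standard deviation.
#'
#' @param rmse_county county-level LOO RMSE.
#' @param sigma_overall overall standard deviation of the observed variable.
#' @return ESTD in percent.
#' @export
estd <- function(rmse_county, sigma_overall) {
  if (sigma_overall <= 0) stop("sigma_overall must be positive", call. = FALSE)
  100 * (1 - rmse_county / sigma_overall)
}
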