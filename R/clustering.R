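#' Monthly-climatology feature vector per county
#'
#' For each county, the per-calendar-month means of daily minimum
#' temperature, daily maximum temperature, and precipitation over all study
#' years (12 x 3 = 36 features), standardised to zero mean and unit variance
#' across counties.
#'
#' @param weather_by_county a named list (one entry per county) of daily
#'   weather data.frames (possibly several years concatenated) with columns
#'   `doy`, `tmax`, `tmin`, `prcp`.
#' @return a counties x 36 numeric matrix with county ids as row names;
#'   columns `tmin_1..12`, `tmax_1..12`, `prcp_1..12`. Features that are
#'   constant across counties are left centred at zero.
#' @export
weather_feature_vector <- function(weather_by_county) {
  feat_one <- function(w) {
    if (nrow(w) < 365L) stop("weather history must span a full year",
                             call. = FALSE)
    mon <- month_of_doy[((w$doy - 1L) %% 365L) + 1L]
    if (length(unique(mon)) < 12L) stop("missing months in weather history",
                                        call. = FALSE)
    c(tapply(w$tmin, mon, mean)[as.character(1:12)],
      tapply(w$tmax, mon, mean)[as.character(1:12)],
      tapply(w$prcp, mon, mean)[as.character(1:12)])
  }
  X <- t(vapply(weather_by_county, feat_one, numeric(36)))
  colnames(X) <- c(paste0("tmin_", 1:12), paste0("tmax_", 1:12),
                   paste0("prcp_", 1:12))
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  Xs[!is.finite(Xs)] <- 0
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  Xs
}

#' Cluster counties by weather climatology or geography
#'
#' k-means (10 restarts, best inertia kept) on either the standardised
#' 36-dimensional monthly climatology features or on county centroid
#' coordinates.
#'
#' @param features_or_coords matrix with one row per county (row names =
#'   county ids): climatology features for `mode = "weather"`, a 2-column
#'   lat/lon matrix for `mode = "geographic"`.
#' @param k number of clusters (1 to the number of counties).
#' @param mode `"weather"` or `"geographic"`.
#' @param seed integer seed for the k-means restarts.
#' @return an object of class `simcal_clusters`: list with `assignment`
#'   (named integer vector, cluster ids 0..k-1), `mode`, `k`, `centers`.
#' @export
cluster_counties <- function(features_or_coords, k,
                             mode = c("weather", "geographic"), seed = 1L) {
  mode <- match.arg(mode)
  X <- as.matrix(features_or_coords)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(X)) stop("k exceeds the number of counties", call. = FALSE)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  if (k == 1L) {
    assignment <- stats::setNames(rep(0L, nrow(X)), ids)
    centers <- matrix(colMeans(X), 1L)
  } else if (k == nrow(X)) {
    assignment <- stats::setNames(seq_len(nrow(X)) - 1L, ids)
    centers <- X
  } else {
    set.seed(seed)
    km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
    assignment <- stats::setNames(as.integer(km$cluster) - 1L, ids)
    centers <- km$centers
  }
  structure(list(assignment = assignment, mode = mode, k = as.integer(k),
                 centers = centers),
            class = "simcal_clusters")
}

#' Select well-modelled clusters
#'
#' Keeps the clusters whose leave-one-out yield R-squared is strictly above
#' the threshold (default 0.40).
#'
#' @param per_cluster_loo_r2 named numeric vector, one R-squared per cluster
#'   (names = cluster ids).
#' @param threshold selection threshold.
#' @return the selected cluster ids (names of the input), possibly empty.
#' @export
select_clusters <- function(per_cluster_loo_r2, threshold = 0.40) {
  names(per_cluster_loo_r2)[per_cluster_loo_r2 > threshold]
}

#' Per-cluster calibration R-squared from LOO predictions
#'
#' @param loo data.frame from [loo_calibrate()] (needs `cluster`,
#'   `pred_yield`, `obs_yield`).
#' @return named numeric vector of squared Pearson correlations per cluster.
#' @export
cluster_loo_r2 <- function(loo) {
  sp <- split(loo, loo$cluster)
  vapply(sp, function(d) {
    if (nrow(d) < 3L) return(NA_real_)
    r <- suppressWarnings(stats::cor(d$pred_yield, d$obs_yield))
    if (is.finite(r)) r^2 else 0
  }, 0)
}
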