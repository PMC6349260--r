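#' Merged phenological stage names
#'
#' Six merged stages used for the phenology head and the stage-fraction
#' targets: pre-emergence (sown or fallow), emergence to end of the juvenile
#' phase, floral initiation to pre-silking, silking/flowering, grain fill,
#' and maturity/post-harvest. The five transitions between consecutive
#' stages are emergence, floral initiation, silking, start of grain fill,
#' and maturity.
#'
#' @return character vector of length 6.
#' @export
stage_names <- function() {
  c("pre_emergence", "emergence_juvenile", "floral_init_presilking",
    "silking_flowering", "grain_fill", "mature")
}

#' Transition names between consecutive merged stages
#' @return character vector of length 5.
#' @export
transition_names <- function() {
  c("emergence", "floral_initiation", "silking", "start_grain_fill",
    "maturity")
}

#' Assign counties to cross-validation folds
#'
#' Random balanced partition of counties into `n_folds` folds (fold sizes
#' differ by at most one); all years of a county share its fold.
#'
#' @param county_ids character vector of distinct county ids.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return an object of class `simcal_folds`: named integer vector mapping
#'   county id to fold index 0..n_folds-1.
#' @export
assign_folds <- function(county_ids, n_folds = 10L, seed = 1L) {
  county_ids <- unique(county_ids)
  if (length(county_ids) < n_folds) {
    stop("fewer counties than folds", call. = FALSE)
  }
  set.seed(seed)
  ord <- sample(county_ids)
  fold <- (seq_along(ord) - 1L) %% n_folds
  structure(stats::setNames(fold[match(county_ids, ord)], county_ids),
            n_folds = as.integer(n_folds), class = "simcal_folds")
}

#' Build retrieval targets from the ensemble and calibrated weights
#'
#' Applies the calibrated mixture weights to each county-year's ensemble:
#' continuous targets are the weighted state trajectories sampled on the
#' 29-step grid; the yield target is the weighted gap-adjusted final yield;
#' the phenology targets are the per-step merged-stage fractions implied by
#' the weights.
#'
#' @param dataset a `simcal_dataset`.
#' @param weights either a single simplex weight vector (clusterless), or a
#'   list of per-cluster vectors together with `cluster_assignment`.
#' @param cluster_assignment optional named county -> cluster map when
#'   `weights` is a list indexed by cluster id (as character).
#' @return a list of class `simcal_targets` with `x` (reflectance array
#'   `(n, 29, 7)`), `physical` (`(n, 29, n_vars)`), `yield` (length n),
#'   `phenology` (`(n, 29, 6)`), and `meta` (county/year data.frame).
#' @export
build_targets <- function(dataset, weights, cluster_assignment = NULL) {
  recs <- dataset$records
  n <- length(recs)
  n_steps <- length(dataset$grid_days)
  svars <- dataset$state_vars
  nv <- length(svars)
  gap <- dataset$config$observation$yield_gap

  weight_for <- function(county_id) {
    if (is.list(weights)) {
      if (is.null(cluster_assignment)) {
        stop("cluster_assignment is required with per-cluster weights",
             call. = FALSE)
      }
      w <- weights[[as.character(cluster_assignment[[county_id]])]]
      if (is.null(w)) stop("missing weights for the cluster of county ",
                           county_id, call. = FALSE)
      w
    } else weights
  }

  x <- array(0, c(n, n_steps, 7L))
  phys <- array(0, c(n, n_steps, nv), dimnames = list(NULL, NULL, svars))
  yld <- numeric(n)
  phen <- array(0, c(n, n_steps, 6L),
                dimnames = list(NULL, NULL, stage_names()))
  for (k in seq_len(n)) {
    r <- recs[[k]]
    w <- weight_for(r$county_id)
    check_simplex(w)
    x[k, , ] <- r$reflectance
    wt <- matrix(r$states %*% w, n_steps, nv)
    phys[k, , ] <- wt
    yld[k] <- sum(w * apply_yield_gap(r$yields, gap))
    for (m in 1:6) phen[k, , m] <- (r$stage_step == m) %*% w
  }
  structure(list(x = x, physical = phys, yield = yld, phenology = phen,
                 meta = dataset_index(dataset)[, c("county_id", "year")],
                 state_vars = svars),
            class = "simcal_targets")
}

target_for_head <- function(targets, head) {
  switch(head, physical = targets$physical, yield = targets$yield,
         phenology = targets$phenology)
}

#' County-blocked k-fold cross-validation of a retrieval network
#'
#' For each evaluated fold, the counties of that fold are held out entirely;
#' of the remaining nine folds, six (cyclically following the test fold)
#' form the training set and three the validation set for early stopping.
#' Input reflectance and continuous targets are z-scored with statistics
#' estimated on the training folds only. Every county-year of an evaluated
#' fold receives exactly one out-of-fold prediction from a network that
#' never saw its county.
#'
#' @param targets a `simcal_targets`.
#' @param spec a `simcal_netspec`.
#' @param folds a `simcal_folds` assignment.
#' @param seed integer seed (per-fold seeds derived from it).
#' @param rounds fold indices (0-based) to evaluate; default all.
#' @param verbose print per-fold progress.
#' @return a list of class `simcal_cv` with `predictions` (same shape as
#'   the head target, `NA` for rows not in an evaluated fold), `evaluated`
#'   (logical per county-year), `fold_of` (per county-year fold index),
#'   `networks` (per-round training metadata), `spec`.
#' @export
kfold_cross_validate <- function(targets, spec, folds, seed = 1L,
                                 rounds = NULL, verbose = FALSE) {
  n_folds <- attr(folds, "n_folds")
  fold_of <- unname(folds[targets$meta$county_id])
  if (anyNA(fold_of)) stop("fold assignment is missing counties", call. = FALSE)
  if (is.null(rounds)) rounds <- 0:(n_folds - 1L)
  y_all <- target_for_head(targets, spec$head)

  pred <- if (spec$head == "yield") rep(NA_real_, length(y_all))
  else array(NA_real_, dim(y_all), dimnames = dimnames(y_all))
  evaluated <- rep(FALSE, nrow(targets$meta))
  nets <- list()

  n_val <- 3L
  for (f in rounds) {
    val_folds <- (f + seq_len(n_val)) %% n_folds
    test_idx <- which(fold_of == f)
    val_idx <- which(fold_of %in% val_folds)
    train_idx <- which(!(fold_of %in% c(f, val_folds)))
    if (length(intersect(train_idx, c(test_idx, val_idx))) > 0L) {
      stop("fold leakage detected", call. = FALSE)
    }

    xs <- fit_scaler(targets$x[train_idx, , , drop = FALSE])
    x_tr <- apply_scaler(xs, targets$x[train_idx, , , drop = FALSE])
    x_va <- apply_scaler(xs, targets$x[val_idx, , , drop = FALSE])
    x_te <- apply_scaler(xs, targets$x[test_idx, , , drop = FALSE])

    if (spec$head == "phenology") {
      y_tr <- y_all[train_idx, , , drop = FALSE]
      y_va <- y_all[val_idx, , , drop = FALSE]
      ys <- NULL
    } else if (spec$head == "yield") {
      ys <- fit_scaler(y_all[train_idx])
      y_tr <- apply_scaler(ys, y_all[train_idx])
      y_va <- apply_scaler(ys, y_all[val_idx])
    } else {
      ys <- fit_scaler(y_all[train_idx, , , drop = FALSE])
      y_tr <- apply_scaler(ys, y_all[train_idx, , , drop = FALSE])
      y_va <- apply_scaler(ys, y_all[val_idx, , , drop = FALSE])
    }

    net <- train_network(spec, x_tr, y_tr, x_va, y_va,
                         seed = derive_seed(seed, f, 0L, 9L))
    p <- predict(net, x_te)
    if (!is.null(ys)) p <- apply_scaler(ys, p, invert = TRUE)
    if (spec$head == "yield") {
      pred[test_idx] <- p
    } else {
      pred[test_idx, , ] <- p
    }
    evaluated[test_idx] <- TRUE
    nets[[length(nets) + 1L]] <- list(fold = f, best_epoch = net$best_epoch,
                                      stopped_epoch = net$stopped_epoch)
    if (verbose) message("fold ", f, ": stopped at epoch ", net$stopped_epoch,
                         " (best ", net$best_epoch, ")")
  }
  structure(list(predictions = pred, evaluated = evaluated,
                 fold_of = fold_of, networks = nets, spec = spec),
            class = "simcal_cv")
}
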