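#' Run the full pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic dataset),
#' `calibrate` (clusterless ensemble-weight fit plus leave-one-out
#' evaluation), `cluster` (county clustering and per-cluster selection),
#' `train` (county-blocked cross-validated retrieval networks for the three
#' heads) and `evaluate` (per-timestep metrics, transition dates, stage
#' confusion). Stage outputs are written as CSV/JSON under `out_dir`
#' together with a manifest recording the config hash and seeds. A stage
#' whose outputs already exist is skipped unless `force = TRUE`.
#'
#' @param config configuration list (see [default_config()]) or a path to a
#'   YAML file.
#' @param seed integer base seed.
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("simulate", "calibrate", "cluster", "train", "evaluate")`.
#' @param loo run the (slower) leave-one-out calibration during the
#'   `calibrate` stage.
#' @param rounds fold indices to evaluate during `train` (default all 10).
#' @param force re-run stages whose outputs exist.
#' @param verbose print progress.
#' @return a list with the in-memory results of the executed stages.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = tempfile("simcal_run_"),
                         stages = c("simulate", "calibrate", "cluster",
                                    "train", "evaluate"),
                         loo = TRUE, rounds = NULL, force = FALSE,
                         verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  manifest <- list(
    seed = seed, stages = stages,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("simcal")),
    r_version = R.version.string,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )
  res <- list(config = config, seed = seed, out_dir = out_dir)

  dataset <- NULL
  need_dataset <- function() {
    if (is.null(dataset)) {
      say("simulating dataset")
      dataset <<- simulate_dataset(config, seed)
    }
    dataset
  }

  if ("simulate" %in% stages) {
    marker <- file.path(out_dir, "observations.csv")
    if (force || !file.exists(marker)) {
      write_dataset(need_dataset(), out_dir)
      say("simulate: wrote dataset tables")
    } else say("simulate: outputs exist, skipping (use force = TRUE)")
    res$dataset <- need_dataset()
  }

  if ("calibrate" %in% stages) {
    ds <- need_dataset()
    cs <- make_calibration_set(ds)
    fit <- fit_weights(cs)
    utils::write.csv(
      data.frame(combo_id = ds$combos$combo_id, weight = fit$weights),
      file.path(out_dir, "calibration_weights.csv"), row.names = FALSE)
    res$fit <- fit
    if (loo) {
      say("calibrate: leave-one-out evaluation")
      loo_df <- loo_calibrate(ds)
      utils::write.csv(loo_df, file.path(out_dir, "loo_predictions.csv"),
                       row.names = FALSE)
      met <- calibration_metrics(loo_df$pred_yield, loo_df$obs_yield,
                                 county_id = loo_df$county_id)
      met_season <- calibration_metrics(loo_df$pred_season, loo_df$obs_season)
      res$loo <- loo_df
      res$calibration_metrics <- list(yield = met, season = met_season)
      jsonlite::write_json(
        list(yield = met[c("r2", "r2_sse", "rmse")],
             season = met_season[c("r2", "r2_sse", "rmse")]),
        file.path(out_dir, "calibration_metrics.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  if ("cluster" %in% stages) {
    ds <- need_dataset()
    say("cluster: weather features + k-means")
    wx <- lapply(seq_len(nrow(ds$counties)), function(i) {
      do.call(rbind, lapply(seq_along(ds$years), function(j)
        generate_weather(ds$climate[[i]], ds$years[j],
                         derive_seed(ds$seed, i, j, 3L))))
    })
    names(wx) <- ds$counties$county_id
    feats <- weather_feature_vector(wx)
    k <- min(config$clustering$k, nrow(ds$counties))
    cl <- cluster_counties(feats, k, mode = "weather",
                           seed = derive_seed(seed, 0L, 0L, 11L))
    utils::write.csv(
      data.frame(county_id = names(cl$assignment),
                 cluster = unname(cl$assignment)),
      file.path(out_dir, "clusters.csv"), row.names = FALSE)
    res$clusters <- cl
  }

  cv <- NULL
  if ("train" %in% stages) {
    ds <- need_dataset()
    if (is.null(res$fit)) res$fit <- fit_weights(make_calibration_set(ds))
    targets <- build_targets(ds, res$fit$weights)
    folds <- assign_folds(ds$counties$county_id,
                          config$network$n_folds,
                          seed = derive_seed(seed, 0L, 0L, 10L))
    cv <- list()
    for (head in c("physical", "yield", "phenology")) {
      say("train: ", head, " head")
      spec <- network_spec(head,
                           layers = config$network$layers,
                           units = config$network$units,
                           learning_rate = config$network$learning_rate,
                           batch_size = config$network$batch_size,
                           patience = config$network$patience,
                           max_epochs = config$network$max_epochs)
      cv[[head]] <- kfold_cross_validate(targets, spec, folds, seed = seed,
                                         rounds = rounds, verbose = verbose)
      write_network_json(spec, file.path(out_dir,
                                         paste0("network_", head, ".json")))
    }
    ev <- cv$yield$evaluated
    utils::write.csv(
      data.frame(targets$meta[ev, ], pred_yield = cv$yield$predictions[ev],
                 target_yield = targets$yield[ev]),
      file.path(out_dir, "predictions_yield.csv"), row.names = FALSE)
    res$targets <- targets
    res$folds <- folds
    res$cv <- cv
  }

  if ("evaluate" %in% stages) {
    ds <- need_dataset()
    if (is.null(res$cv)) {
      stop("the evaluate stage needs the train stage in the same run",
           call. = FALSE)
    }
    say("evaluate: metrics")
    res$evaluation <- evaluate_run(ds, res$targets, res$cv)
    utils::write.csv(res$evaluation$timestep_metrics,
                     file.path(out_dir, "timestep_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(res$evaluation$transition_dates,
                     file.path(out_dir, "transition_dates.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(res$evaluation$confusion),
                     file.path(out_dir, "confusion_matrix.csv"),
                     row.names = TRUE)
    jsonlite::write_json(res$evaluation$summary,
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res
}

#' Evaluate cross-validated retrieval results
#'
#' Computes the per-timestep metrics of all heads, the predicted and
#' reference transition dates with their RMSE/R-squared, and the pooled
#' stage confusion matrix and kappa, over the county-years that have
#' out-of-fold predictions.
#'
#' @param dataset the `simcal_dataset`.
#' @param targets the `simcal_targets` used in training.
#' @param cv named list of `simcal_cv` results (`physical`, `yield`,
#'   `phenology`).
#' @return list with `timestep_metrics`, `yield_metrics`,
#'   `transition_dates` (long data.frame), `date_stats`, `confusion`,
#'   `kappa`, `summary`.
#' @export
evaluate_run <- function(dataset, targets, cv) {
  ev <- cv$physical$evaluated
  folds <- cv$physical$fold_of[ev]

  ts_phys <- per_timestep_metrics(cv$physical$predictions[ev, , , drop = FALSE],
                                  targets$physical[ev, , , drop = FALSE],
                                  folds)
  # derived SLA / LNP series from the physical head outputs
  p <- cv$physical$predictions[ev, , , drop = FALSE]
  y <- targets$physical[ev, , , drop = FALSE]
  sla_p <- derive_sla(pmax(p[, , "lai"], 0), pmax(p[, , "leaf_biomass"], 0))
  sla_y <- derive_sla(y[, , "lai"], y[, , "leaf_biomass"])
  lnp_p <- derive_lnp(pmax(p[, , "leaf_n"], 0), pmax(p[, , "leaf_biomass"], 0))
  lnp_y <- derive_lnp(y[, , "leaf_n"], y[, , "leaf_biomass"])
  ts_sla <- per_timestep_metrics(array(sla_p, c(dim(sla_p), 1L)),
                                 array(sla_y, c(dim(sla_y), 1L)), folds)
  ts_sla$variable <- "sla"
  ts_lnp <- per_timestep_metrics(array(lnp_p, c(dim(lnp_p), 1L)),
                                 array(lnp_y, c(dim(lnp_y), 1L)), folds)
  ts_lnp$variable <- "lnp"
  timestep_metrics <- rbind(ts_phys, ts_sla, ts_lnp)

  evy <- cv$yield$evaluated
  yield_metrics <- calibration_metrics(cv$yield$predictions[evy],
                                       targets$yield[evy])

  # transition dates: predicted from the phenology head, reference from the
  # hidden true stage-fraction curves
  evp <- which(cv$phenology$evaluated)
  date_rows <- lapply(evp, function(k) {
    pd <- transition_dates(cv$phenology$predictions[k, , ],
                           days = dataset$grid_days)
    rd <- observed_transition_dates(dataset$records[[k]]$observation)
    data.frame(county_id = targets$meta$county_id[k],
               year = targets$meta$year[k],
               transition = transition_names(),
               predicted = unname(pd), reference = unname(rd),
               stringsAsFactors = FALSE)
  })
  dates <- do.call(rbind, date_rows)
  date_stats <- do.call(rbind, lapply(split(dates, dates$transition),
                                      function(d) {
    ok <- is.finite(d$predicted) & is.finite(d$reference)
    data.frame(transition = d$transition[1L], n = sum(ok),
               rmse = sqrt(mean((d$predicted[ok] - d$reference[ok])^2)),
               r2 = {
                 r <- suppressWarnings(stats::cor(d$predicted[ok],
                                                  d$reference[ok]))
                 if (is.finite(r)) r^2 else NA_real_
               },
               bias = mean(d$predicted[ok] - d$reference[ok]),
               stringsAsFactors = FALSE)
  }))
  rownames(date_stats) <- NULL

  ref_stage <- t(vapply(evp, function(k) {
    apply(dataset$records[[k]]$observation$stage_fractions[
      , dataset$grid_days, drop = FALSE], 2L, which.max)
  }, integer(length(dataset$grid_days))))
  conf <- stage_confusion(cv$phenology$predictions[evp, , , drop = FALSE],
                          ref_stage)

  list(
    timestep_metrics = timestep_metrics,
    yield_metrics = yield_metrics,
    transition_dates = dates,
    date_stats = date_stats,
    confusion = conf$confusion,
    kappa = conf$kappa,
    summary = list(
      yield_cv_r2 = yield_metrics$r2,
      yield_cv_rmse = yield_metrics$rmse,
      kappa = conf$kappa,
      date_rmse = stats::setNames(as.list(date_stats$rmse),
                                  date_stats$transition)
    )
  )
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10)
  # small stable hash without extra dependencies
  v <- utf8ToInt(as.character(s))
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}
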