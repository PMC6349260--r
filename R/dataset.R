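#' Names and order of the continuous state variables carried through the
#' pipeline (the retrieval targets of the physical head)
#' @return character vector of length 9.
#' @export
state_var_names <- function() {
  c("lai", "leaf_biomass", "leaf_n", "agb", "harvest_biomass",
    "sw_surface", "sw_sub1", "sw_sub2", "sw_sub3")
}

#' Simulate a full synthetic county-year dataset
#'
#' Runs the generator end to end for every county-year: weather, the
#' surrogate simulator over the whole agromanagement grid, mixture-based
#' observations from hidden true weights, and the forward reflectance series
#' from the true weighted state trajectory. The result is bit-reproducible
#' from `(config, seed)`.
#'
#' @param config configuration list, see [default_config()].
#' @param seed integer base seed; all county-year streams are derived from it.
#' @param verbose print progress.
#' @return an object of class `simcal_dataset`: a list with the `config`,
#'   `seed`, `counties`, `years`, `combos`, `grid_days`, hidden-weight info
#'   (`weight_assignment`, `weight_table`), and `records` — one entry per
#'   county-year holding the condensed ensemble (per-combo yields, season
#'   lengths, key dates, state trajectories on the 29-step grid, stage
#'   codes), the observation record and the reflectance matrix.
#' @export
simulate_dataset <- function(config = default_config(), seed = 1L,
                             verbose = FALSE) {
  validate_config(config)
  geo <- make_counties(config, derive_seed(seed, 0L, 0L, 1L))
  combos <- build_parameter_grid(config$grid)
  n_combos <- nrow(combos)
  years <- config$years
  grid_days <- time_grid()
  svars <- state_var_names()

  counties <- geo$counties
  n_c <- nrow(counties)

  # hidden true weights, shared at the configured level
  sharing <- config$weights$sharing
  if (sharing == "global") {
    unit_of <- rep(1L, n_c)
  } else if (sharing == "county") {
    unit_of <- seq_len(n_c)
  } else if (sharing == "cluster") {
    k <- min(config$clustering$k, n_c)
    set.seed(derive_seed(seed, 0L, 0L, 7L))
    km <- stats::kmeans(cbind(counties$lat, counties$lon), centers = k,
                        nstart = 10)
    unit_of <- km$cluster
  } else {
    stop("unknown weight sharing mode: ", sharing, call. = FALSE)
  }
  n_units <- max(unit_of)
  weight_table <- lapply(seq_len(n_units), function(u)
    draw_weights(n_combos, config$weights$n_active,
                 config$weights$concentration,
                 seed = derive_seed(seed, u, 0L, 2L)))

  records <- vector("list", n_c * length(years))
  r <- 0L
  for (i in seq_len(n_c)) {
    soil <- make_soil(config, counties$whc_factor[i], counties$soil_bright[i])
    w_true <- weight_table[[unit_of[i]]]
    for (j in seq_along(years)) {
      r <- r + 1L
      weather <- generate_weather(geo$climate[[i]], years[j],
                                  derive_seed(seed, i, j, 3L))
      pdates <- planting_percentiles(
        weather, config$grid$planting_date_percentile)
      planting_doys <- pdates[as.character(combos$planting_date_percentile)]
      sim <- run_surrogate_grid(combos, planting_doys, weather, soil,
                                config$surrogate)
      obs <- generate_observations(
        sim, w_true, config$observation$yield_gap,
        list(yield = config$observation$yield_noise_sd,
             season = config$observation$season_noise_sd),
        seed = derive_seed(seed, i, j, 4L))

      # condensed per-combo states on the 29-step grid: (29 * n_vars) x combos
      S <- do.call(rbind, lapply(svars, function(v)
        sim$states[[v]][grid_days, , drop = FALSE]))

      # true weighted trajectory drives the observed reflectance
      wtraj <- matrix(S %*% w_true, nrow = length(grid_days),
                      dimnames = list(NULL, NULL))
      dim(wtraj) <- c(length(grid_days), length(svars))
      colnames(wtraj) <- svars
      lnp <- ifelse(wtraj[, "leaf_biomass"] > 1,
                    wtraj[, "leaf_n"] / wtraj[, "leaf_biomass"], 0.02)
      wet_sub <- (wtraj[, c("sw_sub1", "sw_sub2", "sw_sub3")] - soil$ll) /
        (soil$dul - soil$ll)
      traj <- data.frame(
        doy = grid_days, lai = wtraj[, "lai"], lnp = lnp,
        sw_surface = wtraj[, "sw_surface"],
        wetness = rowMeans(pmin(pmax(wet_sub, 0), 1)))
      refl <- forward_reflectance(traj, soil, config$reflectance$noise_sd,
                                  seed = derive_seed(seed, i, j, 5L))
      if (config$reflectance$drop_prob > 0) {
        set.seed(derive_seed(seed, i, j, 6L))
        if (stats::runif(1) < config$reflectance$drop_prob) {
          nd <- sample.int(config$reflectance$max_drop, 1L)
          refl <- drop_and_fill_steps(refl, nd,
                                      seed = derive_seed(seed, i, j, 8L))
        }
      }

      records[[r]] <- list(
        county_id = counties$county_id[i], year = years[j],
        yields = sim$final_yield, season_lengths = sim$season_length,
        key_dates = sim$key_dates,
        states = S,                      # (29 * n_vars) x n_combos
        stage_step = sim$stage[grid_days, , drop = FALSE],
        observation = obs, reflectance = refl)
      if (verbose && r %% 50L == 0L) {
        message("simulated ", r, " county-years")
      }
    }
  }

  structure(list(
    config = config, seed = seed, counties = counties, climate = geo$climate,
    years = years, combos = combos, grid_days = grid_days,
    state_vars = svars, weight_assignment = unit_of,
    weight_table = weight_table, records = records
  ), class = "simcal_dataset")
}

#' @export
print.simcal_dataset <- function(x, ...) {
  cat("simcal synthetic dataset:", nrow(x$counties), "counties x",
      length(x$years), "years =", length(x$records), "county-years;",
      nrow(x$combos), "combos; seed", x$seed, "\n")
  invisible(x)
}

#' County-year index of a dataset
#'
#' @param dataset a `simcal_dataset`.
#' @return data.frame with `county_id`, `year`, `observed_yield` and
#'   `observed_season_length`, one row per record (record order).
#' @export
dataset_index <- function(dataset) {
  data.frame(
    county_id = vapply(dataset$records, `[[`, "", "county_id"),
    year = vapply(dataset$records, `[[`, 0, "year"),
    observed_yield = vapply(dataset$records,
                            function(r) r$observation$observed_yield, 0),
    observed_season_length = vapply(
      dataset$records, function(r) r$observation$observed_season_length, 0),
    stringsAsFactors = FALSE
  )
}

#' Write a dataset's tabular views to disk
#'
#' Writes `ensemble_summary.csv` (per-combo scalars and key dates; the full
#' per-day ensemble trajectories are not materialised on disk),
#' `observations.csv`, `reflectance.csv`, `truth_weights.csv` and a JSON
#' `manifest.json` capturing the config and seed.
#'
#' @param dataset a `simcal_dataset`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- dataset_index(dataset)
  ens <- do.call(rbind, lapply(dataset$records, function(r) {
    data.frame(county_id = r$county_id, year = r$year,
               combo_id = dataset$combos$combo_id,
               final_yield = r$yields, season_length = r$season_lengths,
               r$key_dates, stringsAsFactors = FALSE)
  }))
  utils::write.csv(ens, file.path(dir, "ensemble_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(idx, file.path(dir, "observations.csv"), row.names = FALSE)
  refl <- do.call(rbind, lapply(dataset$records, function(r) {
    data.frame(county_id = r$county_id, year = r$year,
               step_day = as.integer(rownames(r$reflectance)),
               r$reflectance, stringsAsFactors = FALSE)
  }))
  utils::write.csv(refl, file.path(dir, "reflectance.csv"), row.names = FALSE)
  tw <- do.call(rbind, lapply(seq_along(dataset$weight_table), function(u)
    data.frame(unit = u, combo_id = dataset$combos$combo_id,
               weight = dataset$weight_table[[u]])))
  utils::write.csv(tw, file.path(dir, "truth_weights.csv"), row.names = FALSE)
  manifest <- list(seed = dataset$seed, n_counties = nrow(dataset$counties),
                   years = dataset$years, n_combos = nrow(dataset$combos),
                   config = dataset$config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
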