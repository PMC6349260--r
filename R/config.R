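#' Default pipeline configuration
#'
#' Returns the full configuration list used by the synthetic-data generator,
#' the calibration, the clustering, and the retrieval networks. All surrogate
#' simulator constants are artifact choices of this package and live here so
#' that a single object documents the study conditions.
#'
#' The default scale is 50 counties over the eight study years 2008--2011 and
#' 2013--2016 (the drought year 2012 is excluded), i.e. 400 county-years.
#'
#' @param noise one of `"default"` or `"low"`. The `"low"` preset reduces the
#'   observation and reflectance noise standard deviations and is the regime
#'   used for the reduced-scale end-to-end checks.
#' @return a nested named list; see the methods vignette for a walk-through of
#'   every block.
#' @export
default_config <- function(noise = c("default", "low")) {
  noise <- match.arg(noise)
  cfg <- list(
    grid = list(
      planting_density = c(6, 7.5, 9),                        # plants m^-2
      seed_brand = c("A", "B"),
      relative_maturity = c(80, 90, 100, 105, 110, 115, 120, 130),  # days
      nitrogen_applied = c(200, 300),                          # kg ha^-1
      planting_date_percentile = c(25, 50, 75)                 # % progress
    ),
    counties = list(
      n_counties = 50,
      lat_span = 6,          # degrees of latitude covered by the domain
      lon_span = 10,
      temp_lat_gradient = -0.45, # deg C of July tmax per degree latitude
      prcp_lon_gradient = -2.5,  # mm/month per degree longitude
      county_temp_sd = 0.4,      # county-level deviation, deg C
      county_prcp_sd = 6,        # county-level deviation, mm/month
      soil_whc = c(25, 45, 60, 70),  # plant-available water capacity, mm/layer
      soil_whc_lsd = 0.22,       # log-sd of county soil-capacity factor
      soil_bright_sd = 0.08      # sd of county soil brightness factor
    ),
    years = c(2008:2011, 2013:2016),
    weather = list(
      tmax_jul = 30, tmax_jan = 0, dtr = 11,          # deg C
      prcp_jul = 105, prcp_jan = 45,                  # mm/month climatology
      srad_max = 24, srad_min = 7,                    # MJ m^-2 d^-1
      wet_frac = 0.33,                                # fraction of wet days
      temp_year_sd = 0.9,     # interannual county-year temperature anomaly
      prcp_year_lsd = 0.22,   # interannual log-sd of precipitation factor
      temp_day_sd = 2.2,      # daily AR(1) temperature noise
      temp_day_ar = 0.6,
      prcp_noise = 1,         # 0 switches daily precip to the climatology
      srad_day_sd = 2.0
    ),
    surrogate = list(
      t_base = 10, t_cap_max = 30, t_floor_min = 10,  # GDD rules, deg C
      tt_emerge = 105,             # GDD planting -> emergence
      tt_fi_coef = 3.3,            # GDD per relative-maturity day, emergence ref
      tt_silk_coef = c(A = 6.6, B = 6.2),
      tt_sgf_coef = 1.5,           # extra GDD/RM-day, silking -> grain fill
      tt_mat_coef = 11.5,
      lai_max_per_density = 0.72,  # peak LAI per plant m^-2
      lai_logistic_k = 10,
      lai_logistic_mid = 0.55,     # in normalised emergence->silking time
      sen_exp_lai = 1.2,           # senescence shape exponents
      sen_exp_leafb = 0.7,
      sen_exp_leafn = 1.6,
      rue = 1.85,                  # radiation-use efficiency, g MJ^-1
      rue_brand = c(A = 1.0, B = 0.97),
      k_ext = 0.65,                # canopy light extinction
      leaf_frac = 0.45,            # leaf share of aboveground biomass
      hi_max = 0.50,               # final harvest index
      pet_coef = 0.26,             # mm of PET per MJ m^-2 of radiation
      evap_coef = 0.55,
      uptake_rate = 0.09,          # daily extractable fraction per layer
      root_open_tt = c(0, 100, 250, 420),  # GDD at which each layer opens
      soil_dul = 0.30, soil_ll = 0.12,     # volumetric moisture bounds
      soil_init_fill = 0.65,
      np_max = 0.035, np_min = 0.012,      # leaf N dilution curve
      np_dilution_exp = 0.25,
      n_ref = 280, n_min_factor = 0.72     # response to applied nitrogen
    ),
    reflectance = list(
      noise_sd = 0.01,
      drop_prob = 0.10,     # probability a county-year loses reflectance steps
      max_drop = 2          # at most this many steps dropped, then re-filled
    ),
    observation = list(
      yield_gap = 0.15,
      yield_noise_sd = 0.55,     # Mg ha^-1
      season_noise_sd = 4        # days
    ),
    weights = list(
      sharing = "global",        # "global", "cluster" or "county"
      n_active = 12,             # combos with non-zero true weight
      concentration = 1.0        # Dirichlet concentration on the active set
    ),
    clustering = list(mode = "weather", k = 20, r2_threshold = 0.40),
    network = list(
      layers = 3, units = 30,
      learning_rate = 3e-3, batch_size = 32,
      patience = 30, max_epochs = 300,
      n_folds = 10, n_validation_folds = 3
    )
  )
  if (noise == "low") {
    cfg$reflectance$noise_sd <- 0.004
    cfg$reflectance$drop_prob <- 0
    cfg$observation$yield_noise_sd <- 0.15
    cfg$observation$season_noise_sd <- 1.5
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list against the structure produced by
#' [default_config()]. Missing or malformed fields raise an error naming the
#' offending field.
#'
#' @param config a configuration list.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  check_block <- function(block, ref_block, path) {
    if (!is.list(block)) stop("config field '", path, "' must be a list", call. = FALSE)
    missing <- setdiff(names(ref_block), names(block))
    if (length(missing) > 0L) {
      stop("config field '", paste0(path, "$", missing[1L]), "' is missing", call. = FALSE)
    }
    for (nm in names(ref_block)) {
      if (is.list(ref_block[[nm]]) && !is.list(block[[nm]])) {
        stop("config field '", paste0(path, "$", nm), "' must be a list", call. = FALSE)
      }
      if (is.list(ref_block[[nm]])) check_block(block[[nm]], ref_block[[nm]], paste0(path, "$", nm))
    }
  }
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  missing <- setdiff(names(ref), names(config))
  if (length(missing) > 0L) stop("config field '", missing[1L], "' is missing", call. = FALSE)
  for (nm in names(ref)) {
    if (is.list(ref[[nm]]) && !is.data.frame(ref[[nm]])) {
      check_block(config[[nm]], ref[[nm]], nm)
    }
  }
  if (!is.numeric(config$observation$yield_gap) ||
      config$observation$yield_gap < 0 || config$observation$yield_gap >= 1) {
    stop("config field 'observation$yield_gap' must lie in [0, 1)", call. = FALSE)
  }
  for (f in names(ref$grid)) {
    if (length(config$grid[[f]]) < 1L) {
      stop("config field 'grid$", f, "' must have at least one level", call. = FALSE)
    }
  }
  invisible(config)
}

#' Read a configuration from a YAML file
#'
#' Loads a YAML file, merges it over [default_config()] (so partial files are
#' allowed), and validates the result.
#'
#' @param path path to a YAML file.
#' @return a validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        base[[nm]] <- merge_lists(base[[nm]], over[[nm]])
      } else {
        base[[nm]] <- over[[nm]]
      }
    }
    base
  }
  cfg <- merge_lists(default_config(), user)
  validate_config(cfg)
  cfg
}

# Derive a reproducible sub-seed for a (county, year) cell from a base seed.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, county_idx, year_idx, salt = 0L) {
  as.integer((as.numeric(seed) * 2654435.0 + county_idx * 97003 +
                year_idx * 7919 + salt * 131071) %% 2147483647)
}
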