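#' Make a county soil parameter set
#'
#' @param config configuration list.
#' @param whc_factor county-level multiplier on the layer capacities.
#' @param soil_bright county-level soil brightness factor (used by the
#'   forward reflectance model).
#' @return a list with per-layer plant-available water capacity `whc` (mm,
#'   layer 1 is the surface), volumetric bounds `dul`/`ll`, the initial fill
#'   fraction, and `soil_bright`.
#' @export
make_soil <- function(config = default_config(), whc_factor = 1,
                      soil_bright = 1) {
  sc <- config$surrogate
  list(
    whc = config$counties$soil_whc * whc_factor,
    dul = sc$soil_dul, ll = sc$soil_ll,
    init_fill = sc$soil_init_fill,
    soil_bright = soil_bright
  )
}

#' Run the surrogate crop simulator over a set of agromanagement combinations
#'
#' A daily water- and nitrogen-limited maize growth model, vectorised across
#' combinations that share one weather series and one soil. Phenology is
#' driven by growing degree days (GDD, base 10 deg C with a 30/10 cap/floor)
#' with stage thresholds that scale with the relative maturity; leaf area
#' expands logistically in thermal time (amplitude proportional to planting
#' density), is reduced by stress, and senesces after the start of grain
#' fill; biomass accumulates as intercepted radiation times a radiation-use
#' efficiency reduced by the water and nitrogen stress factors; grain grows
#' by a harvest-index ramp after the start of grain fill; soil water follows
#' a cascading four-layer bucket; leaf nitrogen follows a dilution curve
#' scaled by the applied nitrogen. Deterministic given its inputs.
#'
#' Stages are coded 1 pre-emergence (includes pre-planting), 2 emergence to
#' end of the juvenile phase, 3 floral initiation to pre-silking, 4 silking/
#' flowering, 5 grain fill, 6 mature. A crop that has not matured by day 365
#' is censored at day 365; a crop that never emerges keeps stage 1, zero
#' trajectories, and `NA` key dates.
#'
#' @param combos data.frame of combinations from [build_parameter_grid()].
#' @param planting_doys integer vector, planting day of year per combination.
#' @param weather daily weather data.frame from [generate_weather()].
#' @param soil soil list from [make_soil()].
#' @param constants the `surrogate` block of the configuration.
#' @return a list with `states` (list of day x combo matrices: `lai`,
#'   `leaf_biomass`, `leaf_n`, `agb`, `harvest_biomass`, `sw_surface`,
#'   `sw_sub1`..`sw_sub3`, plus `water_stress`), `stage` (day x combo integer
#'   matrix), `key_dates` (combo x 5 matrix: emergence, floral_initiation,
#'   silking, start_grain_fill, maturity), `final_yield` (Mg ha^-1) and
#'   `season_length` (days, 0 when the crop never emerges).
#' @export
run_surrogate_grid <- function(combos, planting_doys, weather, soil,
                               constants = default_config()$surrogate) {
  sc <- constants
  n <- nrow(combos)
  if (length(planting_doys) == 1L) planting_doys <- rep(planting_doys, n)
  stopifnot(length(planting_doys) == n)
  nd <- nrow(weather)
  if (any(planting_doys < 1 | planting_doys > nd)) {
    stop("planting date outside the weather calendar", call. = FALSE)
  }

  # thermal time per day (shared by all combos)
  tt_day <- pmax(0, (pmin(weather$tmax, sc$t_cap_max) +
                       pmax(weather$tmin, sc$t_floor_min)) / 2 - sc$t_base)
  ctt <- cumsum(tt_day)
  # TT[d, i] = GDD accumulated strictly after planting day of combo i
  TT <- matrix(ctt, nd, n) - matrix(ctt[planting_doys], nd, n, byrow = TRUE)
  TT[TT < 0] <- 0
  planted <- row(TT) > matrix(planting_doys, nd, n, byrow = TRUE)
  TT[!planted] <- 0

  rm_ <- combos$relative_maturity
  tt_fi <- sc$tt_emerge + sc$tt_fi_coef * rm_
  tt_silk <- sc$tt_emerge + sc$tt_silk_coef[combos$seed_brand] * rm_
  tt_sgf <- tt_silk + sc$tt_sgf_coef * rm_
  tt_mat <- sc$tt_emerge + sc$tt_mat_coef * rm_

  stage <- 1L + (TT >= sc$tt_emerge) +
    (TT >= matrix(tt_fi, nd, n, byrow = TRUE)) +
    (TT >= matrix(tt_silk, nd, n, byrow = TRUE)) +
    (TT >= matrix(tt_sgf, nd, n, byrow = TRUE)) +
    (TT >= matrix(tt_mat, nd, n, byrow = TRUE))
  storage.mode(stage) <- "integer"

  first_day <- function(th) {
    # TT is non-decreasing in d, so the first crossing is nd - #crossings + 1
    nhit <- .colSums(TT >= matrix(th, nd, n, byrow = TRUE), nd, n)
    d <- nd - as.integer(nhit) + 1L
    d[nhit == 0] <- NA_integer_
    d
  }
  d_eme <- first_day(rep(sc$tt_emerge, n))
  d_fi <- first_day(tt_fi)
  d_silk <- first_day(tt_silk)
  d_sgf <- first_day(tt_sgf)
  d_mat <- first_day(tt_mat)
  # censor maturity (and earlier unreached stages stay NA)
  matured <- !is.na(d_mat)
  d_mat[!matured & !is.na(d_eme)] <- nd

  laimax <- sc$lai_max_per_density * combos$planting_density
  # potential LAI trajectory in normalised emergence->silking thermal time
  xnorm <- sweep(sweep(TT, 2L, sc$tt_emerge), 2L, tt_silk - sc$tt_emerge, "/")
  pot <- matrix(laimax, nd, n, byrow = TRUE) /
    (1 + exp(-sc$lai_logistic_k * (xnorm - sc$lai_logistic_mid)))
  pot[TT < sc$tt_emerge] <- 0
  dpot <- rbind(pot[1L, , drop = FALSE], diff(pot))
  dpot[dpot < 0] <- 0

  # senescence fraction after start of grain fill
  sgf_m <- matrix(tt_sgf, nd, n, byrow = TRUE)
  mat_m <- matrix(tt_mat, nd, n, byrow = TRUE)
  sen <- pmin(pmax((mat_m - TT) / (mat_m - sgf_m), 0), 1)
  sen[TT <= sgf_m] <- 1

  fN <- pmin(1, sc$n_min_factor +
               (1 - sc$n_min_factor) * combos$nitrogen_applied / sc$n_ref)
  rue_i <- sc$rue * sc$rue_brand[combos$seed_brand]

  nl <- length(soil$whc)
  W <- matrix(soil$whc * soil$init_fill, n, nl, byrow = TRUE)
  cap <- matrix(soil$whc, n, nl, byrow = TRUE)

  # root access to each layer opens progressively in thermal time
  FR <- lapply(seq_len(nl), function(j) {
    f <- (TT - sc$root_open_tt[j]) / 200
    f[f < 0] <- 0; f[f > 1] <- 1
    if (j == 1L) f[TT > 0] <- 1  # surface layer reachable once planted
    f
  })
  sen_lai <- sen^sc$sen_exp_lai
  sen_lb <- sen^sc$sen_exp_leafb
  sen_ln <- sen^sc$sen_exp_leafn
  hi_frac <- sweep(sweep(TT, 2L, tt_sgf), 2L, tt_mat - tt_sgf, "/")
  hi_frac[hi_frac < 0] <- 0; hi_frac[hi_frac > 1] <- 1

  lai_grow <- numeric(n)   # growth-phase LAI (before senescence applies)
  lai_sgf <- rep(-1, n)    # captured at the start-grain-fill crossing
  agb <- numeric(n)
  lb_silk <- rep(-1, n)

  M_lai <- matrix(0, nd, n); M_agb <- matrix(0, nd, n)
  M_harv <- matrix(0, nd, n); M_lb <- matrix(0, nd, n)
  M_ln <- matrix(0, nd, n); M_ws <- matrix(1, nd, n)
  M_sw <- lapply(seq_len(nl), function(j) matrix(0, nd, n))

  tmean <- (weather$tmax + weather$tmin) / 2
  pet_all <- pmax(0, sc$pet_coef * weather$srad *
                    pmin(pmax((tmean + 2) / 26, 0.15), 1.25))
  dul_ll <- soil$dul - soil$ll
  lai_prev <- numeric(n)

  for (d in seq_len(nd)) {
    ttd <- TT[d, ]
    growing <- (ttd > 0) & (ttd < tt_mat)

    fcover <- 1 - exp(-sc$k_ext * lai_prev)
    pet <- pet_all[d]
    demand <- pet * fcover * 1.1
    supply <- 0
    for (j in seq_len(nl)) supply <- supply + W[, j] * FR[[j]][d, ] *
        sc$uptake_rate
    ws <- pmin(1, supply / pmax(demand, 1e-9))
    ws[demand <= 1e-9] <- 1
    transp <- pmin(demand, supply)
    frac <- transp / pmax(supply, 1e-9)
    for (j in seq_len(nl)) W[, j] <- W[, j] -
        W[, j] * FR[[j]][d, ] * sc$uptake_rate * frac

    sevap_i <- pmin(W[, 1L], pet * sc$evap_coef * (1 - fcover))
    W[, 1L] <- W[, 1L] - sevap_i

    # infiltration cascade
    inflow <- weather$prcp[d]
    for (j in seq_len(nl)) {
      Wj <- W[, j] + inflow
      over <- Wj - cap[, j]
      over[over < 0] <- 0
      W[, j] <- Wj - over
      inflow <- over
    }

    stress <- pmin(ws, fN)
    lai_grow <- lai_grow + dpot[d, ] * (0.25 + 0.75 * stress) * growing
    crossing <- (lai_sgf < 0) & (ttd > tt_sgf)
    lai_sgf[crossing] <- lai_grow[crossing]
    post <- lai_sgf >= 0
    lai_now <- lai_grow
    lai_now[post] <- lai_sgf[post] * sen_lai[d, ][post]
    lai_now[ttd >= tt_mat] <- 0

    dagb <- rue_i * 0.5 * weather$srad[d] *
      (1 - exp(-sc$k_ext * lai_now)) * stress * 10   # kg ha^-1 d^-1
    agb <- agb + dagb * (growing & ttd >= sc$tt_emerge)

    lb_now <- sc$leaf_frac * agb
    crossed_silk <- (lb_silk < 0) & (ttd >= tt_silk)
    lb_silk[crossed_silk] <- lb_now[crossed_silk]
    posts <- lb_silk >= 0
    lb_now[posts] <- lb_silk[posts] * sen_lb[d, ][posts]
    lb_now[ttd >= tt_mat] <- 0

    np <- pmin(pmax(sc$np_max * (pmax(agb, 500) / 1000)^(-sc$np_dilution_exp),
                    sc$np_min), sc$np_max) * fN
    ln_now <- lb_now * np * sen_ln[d, ]

    M_lai[d, ] <- lai_now
    M_agb[d, ] <- agb
    M_harv[d, ] <- sc$hi_max * hi_frac[d, ] * agb
    M_lb[d, ] <- lb_now
    M_ln[d, ] <- ln_now
    ws_out <- ws; ws_out[ttd <= 0] <- 1
    M_ws[d, ] <- ws_out
    for (j in seq_len(nl)) M_sw[[j]][d, ] <- soil$ll + (W[, j] / cap[, j]) * dul_ll
    lai_prev <- lai_now
  }

  never <- is.na(d_eme)
  final_yield <- M_harv[nd, ] / 1000
  final_yield[never] <- 0
  season <- ifelse(never, 0, d_mat - d_eme)

  key_dates <- cbind(emergence = d_eme, floral_initiation = d_fi,
                     silking = d_silk, start_grain_fill = d_sgf,
                     maturity = d_mat)

  states <- list(
    lai = M_lai, leaf_biomass = M_lb, leaf_n = M_ln, agb = M_agb,
    harvest_biomass = M_harv,
    sw_surface = M_sw[[1L]],
    sw_sub1 = M_sw[[2L]], sw_sub2 = M_sw[[3L]], sw_sub3 = M_sw[[4L]],
    water_stress = M_ws
  )
  list(states = states, stage = stage, key_dates = key_dates,
       final_yield = final_yield, season_length = season)
}

#' Run the surrogate simulator for a single combination
#'
#' Convenience wrapper around [run_surrogate_grid()] for one agromanagement
#' combination.
#'
#' @param combo a one-row data.frame (or list coercible to one) with the
#'   combination's fields.
#' @param weather daily weather data.frame.
#' @param soil soil list from [make_soil()].
#' @param planting_doy planting day of year.
#' @param constants surrogate constant block.
#' @return a list with a daily `trajectory` data.frame, the integer `stage`
#'   sequence, the named `key_dates`, `final_yield` (Mg ha^-1) and
#'   `season_length` (days).
#' @export
run_surrogate <- function(combo, weather, soil, planting_doy,
                          constants = default_config()$surrogate) {
  combo <- as.data.frame(combo, stringsAsFactors = FALSE)
  out <- run_surrogate_grid(combo, planting_doy, weather, soil, constants)
  traj <- data.frame(
    doy = weather$doy,
    lapply(out$states, function(m) m[, 1L])
  )
  list(trajectory = traj, stage = out$stage[, 1L],
       key_dates = out$key_dates[1L, ], final_yield = out$final_yield[1L],
       season_length = out$season_length[1L])
}
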