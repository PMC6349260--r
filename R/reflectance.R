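#' The 8-day analysis time grid
#'
#' Day-of-year values of the 8-day reflectance time grid, Julian day 109 to
#' 333, which spans the maize growing season with margin: 29 steps.
#'
#' @return integer vector of length 29.
#' @export
time_grid <- function() seq(109L, 333L, by = 8L)

#' Band names of the 7-band reflectance series
#' @return character vector of length 7.
#' @export
band_names <- function() {
  c("red", "nir", "blue", "green", "nir2", "swir1", "swir2")
}

# band-wise spectral constants: dry-soil reflectance, vegetation asymptote
# base, and canopy extinction used in the two-flux mixing model
.refl_const <- list(
  soil_dry = c(red = 0.16, nir = 0.22, blue = 0.09, green = 0.12,
               nir2 = 0.26, swir1 = 0.30, swir2 = 0.28),
  k = c(red = 0.60, nir = 0.45, blue = 0.65, green = 0.55,
        nir2 = 0.45, swir1 = 0.50, swir2 = 0.55)
)

# vegetation asymptote as a function of leaf nitrogen percentage (greenness)
# and canopy water status (0 = fully watered, 1 = dry): SWIR rises and NIR
# falls slightly as the canopy dries; red/green fall as leaves green up.
.veg_spectrum <- function(lnp, canopy_dry) {
  g <- pmin(pmax(lnp / 0.03, 0.3), 1.3)
  cbind(
    red = 0.075 - 0.030 * g,
    nir = 0.46 - 0.05 * canopy_dry,
    blue = 0.035,
    green = 0.105 - 0.025 * g,
    nir2 = 0.42 - 0.04 * canopy_dry,
    swir1 = 0.17 + 0.11 * canopy_dry,
    swir2 = 0.075 + 0.10 * canopy_dry
  )
}

#' Forward-simulate a 7-band reflectance series from canopy state
#'
#' Two-flux mixing model: for each band b, the surface reflectance is
#' `rho_soil_b * exp(-k_b * LAI) + rho_veg_b * (1 - exp(-k_b * LAI))`, where
#' the soil term darkens with surface soil moisture and the vegetation
#' asymptote depends on the leaf nitrogen percentage (visible bands) and on
#' canopy water status (SWIR bands). The trajectory is sampled on the 29-step
#' 8-day grid and additive Gaussian noise is applied, with the result clipped
#' to [0, 1]. By construction NIR increases, and red decreases, with LAI.
#'
#' @param trajectory a data.frame covering at least days 109--333 with
#'   columns `doy`, `lai`, `lnp` (leaf N fraction of leaf biomass),
#'   `sw_surface` (volumetric surface moisture) and `wetness` (0--1 root-zone
#'   wetness; 1 = field capacity).
#' @param soil soil list from [make_soil()] (uses `soil_bright`, `dul`, `ll`).
#' @param noise_sd standard deviation of the additive reflectance noise.
#' @param seed integer seed for the noise.
#' @return a 29 x 7 matrix (rows = time steps, columns = bands), with the
#'   grid day of year in `rownames`.
#' @export
forward_reflectance <- function(trajectory, soil, noise_sd = 0.01, seed = 1L) {
  grid <- time_grid()
  if (min(trajectory$doy) > min(grid) || max(trajectory$doy) < max(grid)) {
    stop("trajectory must cover days 109 to 333", call. = FALSE)
  }
  if (any(trajectory$lai < 0)) {
    stop("negative LAI in input trajectory", call. = FALSE)
  }
  idx <- match(grid, trajectory$doy)
  if (anyNA(idx)) {
    at <- function(col) stats::approx(trajectory$doy, trajectory[[col]], grid)$y
  } else {
    at <- function(col) trajectory[[col]][idx]
  }
  lai <- at("lai")
  lnp <- at("lnp")
  sws <- at("sw_surface")
  wetness <- at("wetness")

  wet_norm <- pmin(pmax((sws - soil$ll) / (soil$dul - soil$ll), 0), 1)
  soil_spec <- outer(1 - 0.35 * wet_norm,
                     .refl_const$soil_dry * soil$soil_bright)
  canopy_dry <- pmin(pmax(1 - wetness, 0), 1)
  veg_spec <- .veg_spectrum(lnp, canopy_dry)

  att <- exp(-outer(lai, .refl_const$k))
  refl <- soil_spec * att + veg_spec * (1 - att)

  if (noise_sd > 0) {
    set.seed(seed)
    refl <- refl + matrix(stats::rnorm(length(refl), 0, noise_sd),
                          nrow(refl), ncol(refl))
  }
  refl <- pmin(pmax(refl, 0), 1)
  dimnames(refl) <- list(grid, band_names())
  refl
}

#' Drop reflectance steps and refill by linear interpolation in time
#'
#' Emulates occasional missing satellite retrievals: up to `max_drop`
#' interior time steps are removed at random and refilled by linear
#' interpolation along the time axis, band by band.
#'
#' @param refl a 29 x 7 reflectance matrix.
#' @param n_drop number of steps to drop (0 leaves the input untouched).
#' @param seed integer seed.
#' @return a matrix of the same shape with no missing values.
#' @export
drop_and_fill_steps <- function(refl, n_drop, seed = 1L) {
  if (n_drop <= 0) return(refl)
  set.seed(seed)
  ns <- nrow(refl)
  drop <- sample(2:(ns - 1L), min(n_drop, ns - 2L))
  keep <- setdiff(seq_len(ns), drop)
  grid <- as.numeric(rownames(refl))
  for (b in seq_len(ncol(refl))) {
    refl[drop, b] <- stats::approx(grid[keep], refl[keep, b], grid[drop])$y
  }
  refl
}
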