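# Small configurations and cached fixtures shared across test files.

# reduced 8-combo grid over 6 counties x 3 years; cheap enough for loops
tiny_config <- function(noise = "low") {
  cfg <- default_config(noise)
  cfg$grid <- list(
    planting_density = c(6, 9),
    seed_brand = "A",
    relative_maturity = c(90, 110),
    nitrogen_applied = 200,
    planting_date_percentile = c(25, 75)
  )
  cfg$counties$n_counties <- 6
  cfg$years <- 2008:2010
  cfg$weights$n_active <- 3
  cfg
}

# exact-arithmetic regime: no observation or reflectance noise at all
noisefree_config <- function(base = tiny_config()) {
  base$observation$yield_noise_sd <- 0
  base$observation$season_noise_sd <- 0
  base$reflectance$noise_sd <- 0
  base$reflectance$drop_prob <- 0
  base
}

.fixture_env <- new.env(parent = emptyenv())

# memoised datasets so several test files can share one simulation
cached_dataset <- function(key, config, seed) {
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- simulate_dataset(config, seed)
  }
  .fixture_env[[key]]
}

# constant-weather series builder for surrogate unit tests
constant_weather <- function(tmax, tmin, prcp = 4, srad = 20, days = 365) {
  data.frame(doy = seq_len(days), tmax = tmax, tmin = tmin,
             prcp = prcp, srad = srad, year = 2000)
}

flat_soil <- function(config = default_config()) make_soil(config, 1, 1)

# brute-force minimum of ||A w - b||^2 over the simplex on a resolution-0.01
# grid (3 or 4 combos); the independent oracle for the constrained fit
brute_force_simplex_min <- function(A, b, step = 0.01) {
  n <- ncol(A)
  m <- round(1 / step)
  if (n == 3L) {
    g <- expand.grid(i = 0:m, j = 0:m)
    g <- g[g$i + g$j <= m, ]
    W <- cbind(g$i, g$j, m - g$i - g$j) / m
  } else if (n == 4L) {
    g <- expand.grid(i = 0:m, j = 0:m, k = 0:m)
    g <- g[g$i + g$j + g$k <= m, ]
    W <- cbind(g$i, g$j, g$k, m - g$i - g$j - g$k) / m
  } else stop("oracle supports 3 or 4 combos")
  R <- W %*% t(A)
  R <- sweep(R, 2L, b)
  min(rowSums(R^2))
}

objective_of <- function(A, b, w) sum((drop(A %*% w) - b)^2)
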