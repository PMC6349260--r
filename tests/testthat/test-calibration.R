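make_calset <- function(Ysim, Psim, yobs, pobs, sy = 1, sp = 1) {
  structure(list(Ysim = Ysim, Psim = Psim, yobs = yobs, pobs = pobs,
                 sigma_y = sy, sigma_p = sp, meta = NULL),
            class = "simcal_calset")
}

test_that("weighted predictions are simplex mixtures", {
  w <- c(0, 1, 0)
  expect_equal(predict_continuous(w, c(5, 7, 9)), 7)
  expect_equal(predict_continuous(c(0.5, 0.5), c(2, 4)), 3)
  expect_equal(predict_continuous(c(0.25, 0.75), c(0, 4)), 3)
  expect_error(predict_continuous(c(0.5, 0.5), c(1, 2, 3)), "length")
  expect_error(predict_continuous(c(0.7, 0.7), c(1, 2)), "simplex")
})

test_that("stage fractions follow the indicator mixture", {
  stage <- rbind(c(2L, 1L), c(3L, 4L), c(6L, 6L))  # days x combos
  f1 <- predict_stage_fractions(c(1, 0), stage, day = 1)
  expect_equal(unname(f1), c(0, 1, 0, 0, 0, 0))   # h(2,2)=1, h(2,m!=2)=0
  f2 <- predict_stage_fractions(c(0.5, 0.5), stage, day = 2)
  expect_equal(unname(f2[3:4]), c(0.5, 0.5))
  f3 <- predict_stage_fractions(c(0.3, 0.7), stage, day = 3)
  expect_equal(unname(f3[6]), 1)                  # all combos in one stage
  expect_equal(sum(f3), 1)
  expect_error(predict_stage_fractions(c(1, 0), stage, day = 9), "calendar")
})

test_that("the yield gap scales yields by one minus the gap", {
  expect_equal(apply_yield_gap(10, 0.15), 8.5)
  expect_equal(apply_yield_gap(c(2, 4), 0), c(2, 4))
  expect_equal(apply_yield_gap(0, 0.15), 0)
  expect_error(apply_yield_gap(-1, 0.15), "negative")
  expect_error(apply_yield_gap(5, 1.2), "gap_factor")
})

test_that("two-combo fit with inert season term recovers the exact mixture", {
  # yields {2, 4}, equal season lengths, one observation of 3:
  # 2 w1 + 4 w2 = 3 with w1 + w2 = 1 has the unique solution (0.5, 0.5)
  cs <- make_calset(Ysim = matrix(c(2, 4), 1), Psim = matrix(c(100, 100), 1),
                    yobs = 3, pobs = 100)
  fit <- fit_weights(cs)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(fit$fitted_yield, 3, tolerance = 1e-8)
  expect_lt(fit$objective, 1e-12)
})

test_that("an observation matching one combo concentrates its weight", {
  cs <- make_calset(Ysim = matrix(c(3, 9, 12), 1),
                    Psim = matrix(c(110, 150, 170), 1),
                    yobs = 3, pobs = 110)
  fit <- fit_weights(cs)
  expect_gt(fit$weights[1], 0.999)
  # observation above every simulated yield: all weight on the max combo
  cs2 <- make_calset(Ysim = matrix(c(3, 9, 12), 1),
                     Psim = matrix(c(130, 130, 130), 1),
                     yobs = 20, pobs = 130)
  fit2 <- fit_weights(cs2)
  expect_equal(fit2$weights, c(0, 0, 1), tolerance = 1e-8)
})

test_that("fitted weights always satisfy the simplex constraints", {
  set.seed(77)
  for (i in 1:20) {
    K <- sample(1:4, 1); n <- sample(2:6, 1)
    cs <- make_calset(matrix(runif(K * n, 2, 12), K),
                      matrix(runif(K * n, 90, 160), K),
                      runif(K, 2, 12), runif(K, 90, 160),
                      sy = runif(1, 0.5, 3), sp = runif(1, 3, 20))
    w <- fit_weights(cs)$weights
    expect_true(all(w >= -1e-10))
    expect_equal(sum(w), 1, tolerance = 1e-8)
  }
})

test_that("active-set optimum matches the brute-force simplex grid", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:4, 1); K <- sample(1:3, 1)
    Ysim <- matrix(runif(K * n, 2, 12), K)
    Psim <- matrix(runif(K * n, 90, 160), K)
    cs <- make_calset(Ysim, Psim, runif(K, 2, 12), runif(K, 90, 160),
                      sy = 2, sp = 12)
    A <- rbind(Ysim / 2, Psim / 12)
    b <- c(cs$yobs / 2, cs$pobs / 12)
    fit <- fit_weights(cs)
    expect_lte(objective_of(A, b, fit$weights),
               brute_force_simplex_min(A, b) + 1e-6)
  }
})

test_that("noise-free observations from hidden weights are fit exactly", {
  cfg <- noisefree_config()
  ds <- cached_dataset("tiny_nf", cfg, 55)
  cs <- make_calibration_set(ds)
  fit <- fit_weights(cs)
  rmse <- sqrt(mean((fit$fitted_yield - cs$yobs)^2))
  expect_lt(rmse, 1e-6 * cs$sigma_y)
})

test_that("LOO training sets exclude the county and the year", {
  cfg <- noisefree_config()
  cfg$counties$n_counties <- 2
  cfg$years <- 2008:2009
  ds <- simulate_dataset(cfg, 90)
  idx <- dataset_index(ds)
  loo <- loo_calibrate(ds)
  expect_equal(nrow(loo), 4)
  # the prediction for (county A, year 1) must come from a fit on the single
  # record (county B, year 2) alone
  for (k in 1:4) {
    other <- which(idx$county_id != idx$county_id[k] & idx$year != idx$year[k])
    expect_length(other, 1)
    cs1 <- make_calibration_set(ds, other,
                                sigma = list(yield = sd(idx$observed_yield),
                                             season = sd(idx$observed_season_length)))
    f1 <- fit_weights(cs1)
    gap <- cfg$observation$yield_gap
    expected <- sum(f1$weights *
                      apply_yield_gap(ds$records[[k]]$yields, gap))
    expect_equal(loo$pred_yield[loo$county_id == idx$county_id[k] &
                                  loo$year == idx$year[k]], expected)
  }
})

test_that("a single county-year is omitted from LOO with a warning", {
  cfg <- noisefree_config()
  cfg$counties$n_counties <- 1
  cfg$years <- 2008
  ds <- simulate_dataset(cfg, 91)
  expect_warning(out <- loo_calibrate(ds), "omitted")
  expect_equal(nrow(out), 0)
})

test_that("identical noise-free county-years give zero LOO error", {
  # all county-years share weather, soil and hidden weights; symmetry makes
  # every held-out record exactly predictable
  cfg <- noisefree_config()
  cfg$counties$county_temp_sd <- 0
  cfg$counties$county_prcp_sd <- 0
  cfg$counties$soil_whc_lsd <- 0
  cfg$counties$soil_bright_sd <- 0
  cfg$counties$lat_span <- 0
  cfg$counties$lon_span <- 0
  cfg$weather$temp_year_sd <- 0
  cfg$weather$prcp_year_lsd <- 0
  cfg$weather$temp_day_sd <- 0
  cfg$weather$prcp_noise <- 0
  cfg$weather$srad_day_sd <- 0
  cfg$counties$n_counties <- 3
  cfg$years <- 2008:2009
  ds <- simulate_dataset(cfg, 12)
  idx <- dataset_index(ds)
  expect_equal(sd(idx$observed_yield), 0, tolerance = 1e-12)
  loo <- loo_calibrate(ds)
  expect_lt(sqrt(mean((loo$pred_yield - loo$obs_yield)^2)), 1e-6)
})

test_that("LOO yield skill degrades as observation noise grows", {
  r2_at_noise <- function(noise_sd, seeds) {
    vapply(seeds, function(s) {
      cfg <- tiny_config()
      cfg$observation$yield_noise_sd <- noise_sd
      cfg$observation$season_noise_sd <- noise_sd * 6
      ds <- simulate_dataset(cfg, s)
      loo <- loo_calibrate(ds)
      calibration_metrics(loo$pred_yield, loo$obs_yield)$r2
    }, 0)
  }
  seeds <- 201:210
  lo <- r2_at_noise(0.05, seeds)
  hi <- r2_at_noise(1.5, seeds)
  expect_gt(mean(lo), mean(hi) + 0.1)
})

test_that("calibration metrics and ESTD identities hold", {
  obs <- c(4, 5, 6, 7)
  m <- calibration_metrics(obs, obs, county_id = c("a", "a", "b", "b"))
  expect_equal(m$r2, 1)
  expect_equal(m$rmse, 0)
  expect_equal(m$estd_by_county$estd, c(100, 100))
  expect_equal(estd(0, 2), 100)
  expect_equal(estd(2, 2), 0)
  expect_equal(estd(1, 2), 50)
  expect_error(calibration_metrics(1, 1), "two")
  expect_error(estd(1, 0), "positive")
})

test_that("degenerate calibration sets are rejected", {
  cfg <- noisefree_config()
  cfg$counties$n_counties <- 1
  cfg$years <- 2008
  ds <- simulate_dataset(cfg, 3)
  expect_error(make_calibration_set(ds), "degenerate")
})
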