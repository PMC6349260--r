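test_that("per-timestep metrics hit their identities", {
  set.seed(2)
  n <- 12
  y <- matrix(rnorm(n * 4, 10), n, 4)
  folds <- rep(0:2, each = 4)
  perfect <- per_timestep_metrics(y, y, folds)
  expect_equal(perfect$r2, rep(1, 4))
  expect_equal(perfect$pru, rep(100, 4))
  # predictions equal to the leave-fold-out means give PRU exactly 0
  base <- y
  for (f in 0:2) for (t in 1:4) base[folds == f, t] <- mean(y[folds != f, t])
  m0 <- per_timestep_metrics(base, y, folds)
  expect_equal(m0$pru, rep(0, 4), tolerance = 1e-12)
  expect_error(per_timestep_metrics(y[1, , drop = FALSE],
                                    y[1, , drop = FALSE], 0), "two")
})

test_that("PRU matches a hand-worked two-fold example", {
  # 4 county-years, 2 folds, 1 step
  y <- matrix(c(2, 4, 6, 8), 4, 1)
  p <- matrix(c(2.5, 3.5, 6.5, 7.5), 4, 1)
  folds <- c(0, 0, 1, 1)
  # by hand: rmse_pred = 0.5
  # baselines: fold 0 rows use mean(y[fold 1]) = 7; fold 1 rows use 3
  # rmse_mean = sqrt((25 + 9 + 9 + 25) / 4) = sqrt(17)
  m <- per_timestep_metrics(p, y, folds)
  expect_equal(m$cvrmse_pred, 0.5)
  expect_equal(m$cvrmse_mean, sqrt(17))
  expect_equal(m$pru, 100 * (1 - 0.5 / sqrt(17)))
})

test_that("SLA derivation converts units and masks thin canopies", {
  expect_equal(derive_sla(2.0, 2000), 10)     # m^2 kg^-1
  expect_true(is.na(derive_sla(0.05, 2000)))  # LAI below 0.1
  expect_true(is.na(derive_sla(2.0, 0.5)))    # biomass below 1 kg/ha
  expect_true(is.na(derive_sla(0.1, 2000)))   # strict threshold
  expect_error(derive_sla(-1, 100), "negative")
})

test_that("LNP derivation is a masked ratio", {
  expect_equal(derive_lnp(60, 2000), 0.03)
  expect_true(is.na(derive_lnp(60, 1.0)))      # strict biomass threshold
  expect_true(is.na(derive_lnp(0.0005, 2000))) # leaf N below 0.001
  expect_error(derive_lnp(1, -5), "negative")
})

test_that("transition dates follow the cumulative-curve mean", {
  # point mass: everything transitions at the first grid day
  expect_equal(transition_date_from_cdf(c(180, 190, 200), c(1, 1, 1)), 180)
  # uniform between 170 and 190: mean exactly 180
  days <- c(160, 170, 180, 190, 200)
  cdf <- c(0, 0, 0.5, 1, 1)
  expect_identical(transition_date_from_cdf(days, cdf), 180)
  both <- transition_date_from_cdf(days, cdf, also_median = TRUE)
  expect_equal(unname(both["median"]), 180)
  # never transitions
  expect_true(is.na(transition_date_from_cdf(days, rep(0, 5))))
  expect_true(is.na(transition_date_from_cdf(days, rep(0.4, 5))))
})

test_that("non-monotone curves are repaired by the running maximum", {
  days <- seq(100, 140, by = 10)
  wobble <- c(0, 0.6, 0.4, 1, 0.9)
  d <- transition_date_from_cdf(days, wobble)
  # repaired curve is c(0, .6, .6, 1, 1): mass .6 on (100,110], .4 on (120,130]
  expect_equal(d, 0.6 * 105 + 0.4 * 125)
})

test_that("stage-matrix transitions reproduce known crossing days", {
  days <- time_grid()
  n <- length(days)
  probs <- matrix(0, n, 6)
  stage_of <- cut(days, c(-Inf, 150, 180, 200, 215, 260, Inf), labels = FALSE)
  for (t in seq_len(n)) probs[t, stage_of[t]] <- 1
  d <- transition_dates(probs, days)
  expect_equal(length(d), 5)
  expect_named(d, transition_names())
  expect_true(all(diff(d) > 0))
  # the silking transition (stage 4) happens between grid days 197 and 205
  expect_gte(d[["silking"]], 197)
  expect_lte(d[["silking"]], 205)
})

test_that("stage confusion and kappa behave at the extremes", {
  n <- 6; steps <- 10
  ref <- matrix(sample(1:6, n * steps, replace = TRUE), n, steps)
  probs <- array(0, c(n, steps, 6))
  for (i in 1:n) for (t in 1:steps) probs[i, t, ref[i, t]] <- 1
  perfect <- stage_confusion(probs, ref)
  expect_equal(perfect$kappa, 1)
  expect_equal(sum(perfect$confusion), n * steps)
  # constant predictions against a uniform truth: kappa is exactly 0
  ref_u <- matrix(rep(1:6, times = 10), 6, 10)
  probs1 <- array(0, c(6, 10, 6)); probs1[, , 3] <- 1
  k0 <- stage_confusion(probs1, ref_u)
  expect_equal(k0$kappa, 0)
})

test_that("regional aggregation averages counties", {
  map <- c(a = "r1", b = "r2", c = "r2")
  expect_equal(aggregate_to_region(c(a = 5), map["a"]), c(r1 = 5))
  v <- c(a = 1, b = 2, c = 4)
  expect_equal(aggregate_to_region(v, map), c(r1 = 1, r2 = 3))
  expect_equal(aggregate_to_region(v[c(3, 1, 2)], map), c(r1 = 1, r2 = 3))
  expect_equal(aggregate_to_region(v, map, weights = c(a = 1, b = 3, c = 1)),
               c(r1 = 1, r2 = 2.5))
  expect_error(aggregate_to_region(c(z = 1), map), "unmapped")
})

test_that("observed transition dates line up with the generator's key dates", {
  ds <- cached_dataset("tiny", tiny_config(), 31)
  r <- ds$records[[1]]
  d <- observed_transition_dates(r$observation)
  w <- r$observation$true_weights
  expected_eme <- sum(w * r$key_dates[, "emergence"]) - 0.5
  # the curve steps daily, so the mean date sits within a day of the
  # weighted key dates
  expect_lt(abs(d[["emergence"]] - expected_eme), 1)
  expect_lt(abs(d[["silking"]] - sum(w * r$key_dates[, "silking"])), 1.5)
})
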