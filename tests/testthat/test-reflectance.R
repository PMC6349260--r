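soil <- flat_soil()
base_traj <- function(lai) {
  data.frame(doy = 100:340, lai = lai, lnp = 0.03,
             sw_surface = 0.21, wetness = 0.6)
}

test_that("the time grid has 29 8-day steps from day 109 to 333", {
  g <- time_grid()
  expect_length(g, 29)
  expect_equal(g[1], 109L)
  expect_equal(g[29], 333L)
  expect_true(all(diff(g) == 8L))
})

test_that("zero LAI returns the bare-soil spectrum", {
  refl <- forward_reflectance(base_traj(0), soil, noise_sd = 0)
  wet <- (0.21 - soil$ll) / (soil$dul - soil$ll)
  expected <- simcal:::.refl_const$soil_dry * soil$soil_bright * (1 - 0.35 * wet)
  for (t in c(1, 15, 29)) {
    expect_equal(unname(refl[t, ]), unname(expected), tolerance = 1e-12)
  }
})

test_that("dense canopy approaches the vegetation asymptote", {
  refl <- forward_reflectance(base_traj(12), soil, noise_sd = 0)
  veg <- simcal:::.veg_spectrum(0.03, 1 - 0.6)[1, ]
  expect_equal(unname(refl[15, ]), unname(veg), tolerance = 0.01)
})

test_that("NIR rises and red falls monotonically with LAI", {
  lais <- seq(0, 8, by = 0.5)
  series <- t(vapply(lais, function(l)
    forward_reflectance(base_traj(l), soil, noise_sd = 0)[15, ], numeric(7)))
  expect_true(all(diff(series[, "nir"]) >= 0))
  expect_true(all(diff(series[, "red"]) <= 0))
})

test_that("reflectance output is 29 x 7 in [0, 1] and seeded noise reproduces", {
  r1 <- forward_reflectance(base_traj(3), soil, noise_sd = 0.02, seed = 4)
  r2 <- forward_reflectance(base_traj(3), soil, noise_sd = 0.02, seed = 4)
  expect_identical(r1, r2)
  expect_equal(dim(r1), c(29L, 7L))
  expect_true(all(r1 >= 0 & r1 <= 1))
})

test_that("invalid trajectories are rejected", {
  tr <- base_traj(1); tr$lai[5] <- -0.2
  expect_error(forward_reflectance(tr, soil, 0), "negative LAI")
  short <- base_traj(1)[1:100, ]
  expect_error(forward_reflectance(short, soil, 0), "cover")
})

test_that("dropped steps are refilled by linear interpolation in time", {
  refl <- forward_reflectance(base_traj(2), soil, noise_sd = 0)
  filled <- drop_and_fill_steps(refl, n_drop = 2, seed = 8)
  expect_false(anyNA(filled))
  expect_equal(dim(filled), dim(refl))
  expect_equal(filled[1, ], refl[1, ])
  expect_equal(filled[29, ], refl[29, ])
  set.seed(8)
  dropped <- sample(2:28, 2)
  grid <- time_grid()
  for (d in dropped) {
    lin <- stats::approx(grid[-dropped], refl[-dropped, 2], grid[d])$y
    expect_equal(unname(filled[d, 2]), lin)
  }
})
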