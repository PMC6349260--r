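cfg <- default_config()
soil <- flat_soil(cfg)
grid2 <- build_parameter_grid(list(
  planting_density = 7.5, seed_brand = "A",
  relative_maturity = c(80, 130), nitrogen_applied = 300,
  planting_date_percentile = 50))

test_that("a season too cold for emergence yields nothing", {
  w <- constant_weather(tmax = 8, tmin = -2)
  out <- run_surrogate(grid2[1, ], w, soil, planting_doy = 120)
  expect_equal(out$final_yield, 0)
  expect_equal(out$season_length, 0)
  expect_true(all(out$stage == 1L))
  expect_true(all(is.na(out$key_dates)))
  expect_true(all(out$trajectory$lai == 0))
})

test_that("emergence follows hand-accumulated growing degree days", {
  # 30/20 C against base 10 gives exactly 15 GDD per day; the 105 GDD
  # emergence threshold is reached 7 days after planting
  w <- constant_weather(tmax = 30, tmin = 20)
  out <- run_surrogate(grid2[1, ], w, soil, planting_doy = 120)
  expect_equal(unname(out$key_dates["emergence"]), 127)
})

test_that("season length increases strictly with relative maturity", {
  w <- constant_weather(tmax = 30, tmin = 20)
  sim <- run_surrogate_grid(grid2, c(120, 120), w, soil)
  expect_true(all(is.finite(sim$season_length)))
  expect_gt(sim$season_length[2], sim$season_length[1])  # RM 130 vs RM 80
})

test_that("trajectories satisfy the structural invariants", {
  geo <- make_counties(cfg, 4)
  w <- generate_weather(geo$climate[[1]], 2013, 21)
  g <- build_parameter_grid(tiny_config()$grid)
  pd <- planting_percentiles(w)
  sim <- run_surrogate_grid(g, pd[as.character(g$planting_date_percentile)],
                            w, soil)
  for (v in c("lai", "leaf_biomass", "leaf_n", "agb", "harvest_biomass")) {
    expect_true(all(sim$states[[v]] >= 0), info = v)
  }
  expect_true(all(sim$states$harvest_biomass <= sim$states$agb + 1e-9))
  # zero before emergence
  for (i in seq_len(nrow(g))) {
    eme <- sim$key_dates[i, "emergence"]
    expect_true(all(sim$states$lai[seq_len(eme - 1L), i] == 0))
    expect_true(all(sim$states$agb[seq_len(eme - 1L), i] == 0))
  }
  # stage sequences are non-decreasing and key dates ordered
  expect_true(all(apply(sim$stage, 2L, function(s) all(diff(s) >= 0))))
  ok <- stats::complete.cases(sim$key_dates)
  expect_true(any(ok))
  kd <- sim$key_dates[ok, , drop = FALSE]
  expect_true(all(kd[, "emergence"] < kd[, "floral_initiation"]))
  expect_true(all(kd[, "floral_initiation"] < kd[, "silking"]))
  expect_true(all(kd[, "silking"] < kd[, "start_grain_fill"]))
  expect_true(all(kd[, "start_grain_fill"] < kd[, "maturity"]))
  # soil moisture within the volumetric bounds
  expect_true(all(sim$states$sw_surface >= soil$ll - 1e-9))
  expect_true(all(sim$states$sw_surface <= soil$dul + 1e-9))
})

test_that("planting outside the calendar is rejected", {
  w <- constant_weather(30, 20)
  expect_error(run_surrogate(grid2[1, ], w, soil, planting_doy = 400),
               "calendar")
})

test_that("denser planting raises peak LAI and nitrogen raises leaf N", {
  w <- constant_weather(28, 18, prcp = 6)
  gd <- build_parameter_grid(list(
    planting_density = c(6, 9), seed_brand = "A", relative_maturity = 105,
    nitrogen_applied = c(200, 300), planting_date_percentile = 50))
  sim <- run_surrogate_grid(gd, rep(120, 4), w, soil)
  peak <- apply(sim$states$lai, 2L, max)
  expect_gt(peak[3], peak[1])   # 9 vs 6 plants m^-2 at N 200
  ln_peak <- apply(sim$states$leaf_n, 2L, max)
  expect_gt(ln_peak[2], ln_peak[1])  # 300 vs 200 kg N
})
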