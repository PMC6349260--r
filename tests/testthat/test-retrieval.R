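test_that("fold assignment is a balanced, reproducible county partition", {
  ids <- sprintf("c%03d", 1:100)
  f1 <- assign_folds(ids, 10, seed = 3)
  f2 <- assign_folds(ids, 10, seed = 3)
  expect_identical(f1, f2)
  expect_equal(as.vector(table(f1)), rep(10L, 10))
  expect_setequal(names(f1), ids)
  f3 <- assign_folds(sprintf("c%02d", 1:23), 10, seed = 1)
  expect_true(max(table(f3)) - min(table(f3)) <= 1)
  expect_error(assign_folds(ids[1:5], 10), "fewer counties")
})

test_that("targets follow the weight mixture over the ensemble", {
  ds <- cached_dataset("tiny", tiny_config(), 31)
  n_combos <- nrow(ds$combos)
  gap <- ds$config$observation$yield_gap
  # one-hot weights reproduce that combo's own trajectory and yield
  w1 <- numeric(n_combos); w1[3] <- 1
  tg <- build_targets(ds, w1)
  r <- ds$records[[2]]
  expect_equal(tg$physical[2, , "lai"],
               unname(matrix(r$states[, 3], 29)[, 1]))
  expect_equal(tg$yield[2], (1 - gap) * r$yields[3])
  # stage targets sum to one at every step
  sums <- apply(tg$phenology, c(1, 2), sum)
  expect_equal(unname(as.vector(sums)), rep(1, length(sums)))
  # uniform weights over two combos give midpoint trajectories
  w2 <- numeric(n_combos); w2[c(1, 4)] <- 0.5
  tg2 <- build_targets(ds, w2)
  s <- matrix(r$states[, 1], 29, length(ds$state_vars))
  s4 <- matrix(r$states[, 4], 29, length(ds$state_vars))
  expect_equal(tg2$physical[2, , "agb"], unname((s[, 4] + s4[, 4]) / 2))
})

test_that("scalers are exact round trips fitted on training data only", {
  set.seed(8)
  x <- array(rnorm(40 * 29 * 3, mean = 5, sd = 2), c(40, 29, 3))
  sc <- fit_scaler(x[1:25, , , drop = FALSE])
  z <- apply_scaler(sc, x)
  back <- apply_scaler(sc, z, invert = TRUE)
  expect_equal(back, x, tolerance = 1e-10)
  ztr <- apply_scaler(sc, x[1:25, , , drop = FALSE])
  expect_equal(mean(matrix(ztr, ncol = 3)[, 2]), 0, tolerance = 1e-12)
  # leakage tripwire: including test rows changes the scaler
  sc_leaky <- fit_scaler(x)
  expect_false(isTRUE(all.equal(sc$mean, sc_leaky$mean)))
})

test_that("network specs validate their structure", {
  sp <- network_spec("physical")
  expect_equal(sp$layers, 3L)
  expect_equal(sp$units, 30L)
  expect_equal(sp$n_out, 9L)
  expect_equal(network_spec("yield")$n_out, 1L)
  expect_equal(network_spec("phenology")$n_out, 6L)
  expect_error(network_spec("physical", layers = 0), "positive")
  expect_error(network_spec("physical", patience = 0), "patience")
})

test_that("a zero network with an output bias predicts that constant", {
  sp <- network_spec("yield", layers = 2, units = 4)
  n <- blstm_n_params(7L, 4L, 2L, 1L)
  params <- numeric(n)
  params[n] <- 2.5  # output bias only
  net <- structure(list(params = params, spec = sp), class = "simcal_network")
  x <- array(rnorm(3 * 29 * 7), c(3, 29, 7))
  expect_equal(predict(net, x), rep(2.5, 3))
  expect_error(predict(net, x[, 1:5, ]), "array")
})

test_that("phenology head rows are probability vectors", {
  sp <- network_spec("phenology", layers = 1, units = 5)
  net <- structure(list(params = simcal:::init_params(sp, 2), spec = sp),
                   class = "simcal_network")
  x <- array(rnorm(4 * 29 * 7), c(4, 29, 7))
  p <- predict(net, x)
  expect_equal(dim(p), c(4L, 29L, 6L))
  expect_equal(as.vector(apply(p, c(1, 2), sum)), rep(1, 4 * 29),
               tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("training tracks the best validation epoch and stops on patience", {
  set.seed(4)
  n <- 24
  x <- array(rnorm(n * 29 * 7), c(n, 29, 7))
  y <- array(0, c(n, 29, 1))
  for (i in 1:n) y[i, , 1] <- 0.8 * x[i, , 1] + 0.1 * rnorm(29)
  sp <- network_spec("physical", n_out = 1, layers = 1, units = 8,
                     patience = 10, max_epochs = 500, batch_size = 8,
                     learning_rate = 5e-3)
  net <- train_network(sp, x[1:16, , , drop = FALSE], y[1:16, , , drop = FALSE],
                       x[17:24, , , drop = FALSE], y[17:24, , , drop = FALSE],
                       seed = 6)
  h <- net$history
  best_so_far <- cummin(h$val_loss)
  expect_true(all(diff(best_so_far) <= 0))
  expect_equal(h$val_loss[net$best_epoch], min(h$val_loss))
  # halts no more than `patience` epochs after the last improvement
  expect_lte(net$stopped_epoch - net$best_epoch, sp$patience)
  # reproducibility
  net2 <- train_network(sp, x[1:16, , , drop = FALSE], y[1:16, , , drop = FALSE],
                        x[17:24, , , drop = FALSE], y[17:24, , , drop = FALSE],
                        seed = 6)
  expect_identical(net$params, net2$params)
})

test_that("a small training set can be memorised", {
  set.seed(9)
  n <- 5
  x <- array(rnorm(n * 29 * 7), c(n, 29, 7))
  y <- array(0, c(n, 29, 1))
  for (i in 1:n) y[i, , 1] <- sin(seq(0, 3, length.out = 29) + i) +
    0.3 * x[i, , 2]
  sp <- network_spec("physical", n_out = 1, patience = 1000,
                     max_epochs = 400, batch_size = 8, learning_rate = 1e-2)
  net <- train_network(sp, x, y, x, y, seed = 3)
  pr <- predict(net, x)
  expect_lt(sqrt(mean((pr - y)^2)), 0.05 * sd(y))
})

test_that("county-blocked cross-validation predicts each record once", {
  cfg <- tiny_config()
  cfg$counties$n_counties <- 12
  cfg$years <- 2008:2009
  ds <- cached_dataset("cv12", cfg, 44)
  fit <- fit_weights(make_calibration_set(ds))
  tg <- build_targets(ds, fit$weights)
  folds <- assign_folds(ds$counties$county_id, 10, seed = 2)
  sp <- network_spec("yield", layers = 1, units = 4, max_epochs = 2,
                     patience = 2, batch_size = 16)
  cv <- kfold_cross_validate(tg, sp, folds, seed = 1)
  expect_true(all(cv$evaluated))
  expect_false(anyNA(cv$predictions))
  expect_length(cv$networks, 10)
  # blocking: a county's fold is never among its round's train or val folds
  for (f in 0:9) {
    val_folds <- (f + 1:3) %% 10
    test_counties <- names(folds)[folds == f]
    expect_false(any(folds[test_counties] %in% val_folds))
  }
})
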