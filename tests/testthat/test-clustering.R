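make_history <- function(climate, years = 2008:2009, seed = 1) {
  do.call(rbind, lapply(seq_along(years), function(j)
    generate_weather(climate, years[j], seed + j)))
}

test_that("monthly climatology features behave as locality demands", {
  geo <- make_counties(default_config(), 3)
  h1 <- make_history(geo$climate[[1]])
  h2 <- make_history(geo$climate[[2]])
  X <- weather_feature_vector(list(a = h1, b = h2, a2 = h1))
  expect_equal(dim(X), c(3L, 36L))
  expect_equal(unname(X["a", ]), unname(X["a2", ]))  # identical weather
  # doubling one county's precipitation only moves its 12 precip features
  h2b <- h2; h2b$prcp <- h2b$prcp * 2
  X2 <- weather_feature_vector(list(a = h1, b = h2b, a2 = h1))
  tcols <- 1:24; pcols <- 25:36
  expect_equal(X2[, tcols], X[, tcols])
  expect_false(isTRUE(all.equal(X2["b", pcols], X["b", pcols])))
  expect_error(weather_feature_vector(list(a = h1[1:100, ])), "full year")
})

test_that("constant weather gives constant monthly means", {
  h <- constant_weather(20, 10, prcp = 3)
  mon <- tapply(h$prcp, simcal:::month_of_doy, mean)
  expect_true(all(abs(mon - 3) < 1e-12))
})

test_that("degenerate k choices collapse to the obvious partitions", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(sprintf("c%02d", 1:10), NULL))
  one <- cluster_counties(X, 1, "geographic")
  expect_true(all(one$assignment == 0))
  all_ <- cluster_counties(X, 10, "geographic")
  expect_equal(sort(unique(all_$assignment)), 0:9)
  expect_error(cluster_counties(X, 0, "weather"), "at least 1")
  expect_error(cluster_counties(X, 11, "weather"), "exceeds")
})

test_that("two well-separated climate regimes are recovered exactly", {
  set.seed(5)
  X <- rbind(matrix(rnorm(12 * 3, 0, 0.2), 12),
             matrix(rnorm(8 * 3, 10, 0.2), 8))
  rownames(X) <- sprintf("c%02d", 1:20)
  cl <- cluster_counties(X, 2, "weather", seed = 6)
  a <- cl$assignment
  expect_equal(length(unique(a[1:12])), 1)
  expect_equal(length(unique(a[13:20])), 1)
  expect_false(a[1] == a[13])
  # reproducible given the seed
  cl2 <- cluster_counties(X, 2, "weather", seed = 6)
  expect_identical(cl$assignment, cl2$assignment)
})

test_that("cluster selection is strict at the 0.40 threshold and monotone", {
  r2 <- c("0" = 0.5, "1" = 0.3)
  expect_equal(select_clusters(r2), "0")
  expect_equal(select_clusters(c("0" = 0.2, "1" = 0.39)), character(0))
  expect_equal(select_clusters(c("0" = 0.40)), character(0))  # strict
  r2b <- c("0" = 0.45, "1" = 0.62, "2" = 0.41, "3" = 0.2)
  for (th in seq(0, 1, by = 0.1)) {
    expect_true(all(select_clusters(r2b, th + 0.1) %in%
                      select_clusters(r2b, th)))
  }
})
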