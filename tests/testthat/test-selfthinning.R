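test_that("thinning-space transform applies the per-hectare mass conversion", {
  s <- make_series(3, Cwood = rep(10, 3), nstem = rep(1000, 3))
  struct <- size_structure(data.frame(
    year = 0:2, class_label = "<15",
    nstem_size = rep(1000, 3), cwood_size = rep(5, 3)))
  pts <- to_thinning_space(s, struct)
  expect_equal(pts$lnN, rep(log(1000), 3))
  expect_equal(pts$lnM, rep(log(50), 3))  # 5 kgC m-2 * 1e4 / 1000 trees
  expect_identical(attr(pts, "source"), "size_structure")
})

test_that("classes below the dbh threshold are excluded entirely", {
  struct <- size_structure(data.frame(
    year = 0:2, class_label = "<5",
    nstem_size = rep(1000, 3), cwood_size = rep(5, 3)))
  pts <- quiet(to_thinning_space(make_series(3), struct, min_dbh = 10))
  expect_identical(nrow(pts), 0L)
})

test_that("without a size structure, totals are used and the deviation recorded", {
  s <- make_series(5, Cwood = rep(10, 5), Cwood_AG = rep(7.5, 5),
                   nstem = rep(500, 5))
  pts <- quiet(to_thinning_space(s, NULL))
  expect_identical(attr(pts, "source"), "totals")
  expect_equal(pts$lnM, rep(log(7.5 * 1e4 / 500), 5))
  s_no_n <- make_series(5)
  expect_error(quiet(to_thinning_space(s_no_n, NULL)), "nstem")
})

test_that("Method 1 needs the diagnostic column and matches the percentile oracle", {
  # a single spike decade in a 200-yr run: the spike years alone exceed the
  # 95th percentile of the whole-run diagnostic
  s <- make_series(200, selfthin_mort_rate = c(rep(0.1, 95), rep(5, 10), rep(0.1, 95)))
  sel <- detect_m1(s)
  expect_identical(sel, s$year[96:105])
  expect_identical(sel, oracle_top5(s$selfthin_mort_rate, s$year))
  expect_error(detect_m1(make_series(10)), "Methods 2-4")
  # a constant diagnostic selects nothing
  const <- make_series(50, selfthin_mort_rate = rep(1, 50))
  expect_warning(sel_const <- detect_m1(const), "equal")
  expect_length(sel_const, 0)
  # pointwise rule: permuting years permutes the selection identically
  perm <- s[sample(nrow(s)), ]
  perm$year <- s$year
  expect_setequal(detect_m1(perm),
                  perm$year[perm$selfthin_mort_rate == 5])
})

test_that("Method 2 selects the top 5% of total mortality rate", {
  set.seed(7)
  s <- make_series(20, Cwood = rep(10, 20), Cmort = runif(20, 0.05, 0.4))
  r <- mortality_rate(s)
  sel <- detect_m2(r)
  expect_length(sel, 1L)  # ceiling(0.05 * 20) distinct values
  expect_identical(sel, r$year[which.max(r$cmort_rate)])
  expect_warning(detect_m2(mortality_rate(make_series(30))), "equal")
})

test_that("Methods 1-2 agree with the sort-and-threshold oracle on random series", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(20:200, 1)
    vals <- runif(n)
    yrs <- 0:(n - 1)
    s <- make_series(n, selfthin_mort_rate = vals)
    expect_identical(detect_m1(s), oracle_top5(vals, yrs))
    r <- structure(data.frame(year = yrs, cmort_rate = vals),
                   class = c("rate_series", "data.frame"))
    expect_identical(detect_m2(r), oracle_top5(vals, yrs))
  }
})

test_that("Method 3 picks the run between the density maximum and minimum", {
  lnN <- log(c(500, 900, 850, 700, 600, 500, 400, 300, 310, 305))
  pts <- structure(data.frame(year = 0:9, lnN = lnN, lnM = -lnN),
                   class = c("thinning_points", "data.frame"))
  expect_identical(detect_m3(pts), 1:7)  # from the 900 year to the 300 year
  expect_identical(detect_m3(pts), oracle_density_run(lnN, 0:9))
  # strictly monotone decline selects every year
  mono <- structure(data.frame(year = 0:9, lnN = log(seq(1000, 100, length = 10)),
                               lnM = 1:10),
                    class = c("thinning_points", "data.frame"))
  expect_identical(detect_m3(mono), 0:9)
  # never-declining density
  up <- structure(data.frame(year = 0:4, lnN = log(c(10, 20, 30, 40, 50)),
                             lnM = 1:5),
                  class = c("thinning_points", "data.frame"))
  expect_length(quiet(detect_m3(up)), 0)
})

test_that("Method 3 equals brute-force span maximisation on random instances", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(10:200, 1)
    lnN <- cumsum(rnorm(n, 0, 0.3))
    pts <- structure(data.frame(year = 0:(n - 1), lnN = lnN, lnM = rnorm(n)),
                     class = c("thinning_points", "data.frame"))
    got <- quiet(detect_m3(pts))
    expect_identical(as.numeric(got), as.numeric(oracle_density_run(lnN, 0:(n - 1))))
  }
})

test_that("Method 3 selection covers the imposed thinning window", {
  sim <- simulate_stand(sim_config(years = 250))
  pts <- quiet(to_thinning_space(sim$series, sim$structure))
  sel <- detect_m3(pts)
  inner <- 49:129  # imposed window minus edge years
  expect_true(all(inner %in% sel))
})

test_that("Method 4 is the literal manual range", {
  sel <- detect_m4(c(40, 80))
  expect_equal(sel, seq(40, 80), ignore_attr = TRUE)
  expect_identical(attr(sel, "provenance"), "manual")
  expect_error(detect_m4(c(80, 40)), "reversed")
  expect_error(detect_m4(c(40, 80), series_years = 0:50), "outside")
})

test_that("noise-free slope recovery is exact across the exponent range", {
  for (p in c(-2.6, -2.0, -1.5, -1.0)) {
    sim <- simulate_stand(thinning_only_config(p))
    pts <- quiet(to_thinning_space(sim$series, sim$structure))
    fit <- fit_slope(pts, method = 4)
    expect_equal(fit$slope, p, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_equal(fit$slope, oracle_slope(pts$lnN, pts$lnM), tolerance = 1e-12)
  }
})

test_that("within-bounds flag is inclusive at both reference boundaries", {
  mk <- function(p) {
    sim <- simulate_stand(thinning_only_config(p))
    fit_slope(quiet(to_thinning_space(sim$series, sim$structure)))
  }
  expect_true(mk(-1.0)$within_bounds)
  expect_true(mk(-2.612)$within_bounds)
  expect_false(mk(-0.8)$within_bounds)
  expect_false(mk(-2.8)$within_bounds)
})

test_that("degenerate point sets are rejected", {
  pts <- structure(data.frame(year = 0:1, lnN = c(1, 2), lnM = c(1, 2)),
                   class = c("thinning_points", "data.frame"))
  expect_error(fit_slope(pts), "insufficient thinning trajectory")
  flat <- structure(data.frame(year = 0:4, lnN = rep(1, 5), lnM = rnorm(5)),
                    class = c("thinning_points", "data.frame"))
  expect_error(fit_slope(flat), "insufficient thinning trajectory")
})

test_that("slope is invariant to log base and mass-unit rescaling", {
  sim <- simulate_stand(thinning_only_config(-1.5, seed = 3))
  pts <- quiet(to_thinning_space(sim$series, sim$structure))
  base <- fit_slope(pts)
  log10_pts <- pts
  log10_pts$lnN <- pts$lnN / log(10)
  log10_pts$lnM <- pts$lnM / log(10)
  expect_lt(abs(fit_slope(log10_pts)$slope - base$slope), 1e-9)
  gC_pts <- pts
  gC_pts$lnM <- pts$lnM + log(1000)  # kgC -> gC
  fit_g <- fit_slope(gC_pts)
  expect_lt(abs(fit_g$slope - base$slope), 1e-9)
  expect_equal(fit_g$intercept, base$intercept + log(1000), tolerance = 1e-9)
})

test_that("noisy slope estimates are unbiased within the Monte-Carlo band", {
  slopes <- vapply(1:200, function(s) {
    sim <- simulate_stand(thinning_only_config(-1.5, seed = s, noise_sd = 0.05))
    pts <- quiet(to_thinning_space(sim$series, sim$structure))
    fit_slope(pts, years = 0:49)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) + 1.5), 0.05)
})
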