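test_that("age bins keep the occupancy rule and the percentile statistics", {
  recs <- data.frame(age = rep(10, 25), Cwood_AG = rep(4.2, 25))
  env <- bin_chronosequence(recs)
  expect_identical(nrow(env), 1L)
  expect_identical(env$n, 25L)
  expect_equal(c(env$low, env$median, env$high), rep(4.2, 3))

  under <- data.frame(age = c(rep(10, 19), rep(30, 20)),
                      Cwood_AG = runif(39, 1, 5))
  env2 <- bin_chronosequence(under)
  expect_identical(env2$cell, "[20,40)")  # the 19-record bin is absent
  expect_warning(bin_chronosequence(data.frame(age = 1:5, Cwood_AG = 1:5)),
                 "minimum occupancy")
})

test_that("bin statistics equal a brute-force group-then-quantile oracle", {
  set.seed(31)
  for (i in 1:20) {
    recs <- simulate_chronosequence(sample(100:600, 1), max_age = 220,
                                    noise_sd = 0.3, seed = i)
    env <- suppressWarnings(bin_chronosequence(recs))
    lower <- floor(recs$age / 20) * 20
    counts <- table(lower)
    kept <- as.numeric(names(counts))[counts >= 20]
    expect_identical(env$lower, sort(kept))
    for (lo in kept) {
      vals <- recs$Cwood_AG[lower == lo]
      q <- quantile(vals, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
      row <- env[env$lower == lo, ]
      expect_equal(c(row$low, row$median, row$high), q)
      expect_identical(row$n, length(vals))
    }
    expect_true(all(env$low <= env$median & env$median <= env$high))
  }
})

test_that("spatial bootstrap is deterministic and degenerates sensibly", {
  plot <- simulate_plot(400, width = 600, height = 600, seed = 5)
  env <- bootstrap_plot(plot, n_boot = 100, seed = 9)
  expect_identical(as.data.frame(env),
                   as.data.frame(bootstrap_plot(plot, n_boot = 100, seed = 9)))
  expect_true(all(env$low <= env$median & env$median <= env$high))
  one <- bootstrap_plot(plot, n_boot = 1, seed = 3)
  expect_equal(one$low, one$median)
  expect_equal(one$high, one$median)
  # a plot with no stems collapses the envelope to a point at zero
  empty <- bootstrap_plot(simulate_plot(0, width = 300, height = 300, seed = 1),
                          n_boot = 50, seed = 1)
  expect_true(all(empty$low == 0 & empty$high == 0))
  expect_error(bootstrap_plot(simulate_plot(10, width = 100, height = 100, seed = 1)),
               "larger than the plot")
})

test_that("relative bootstrap spread narrows as stem density rises", {
  rel_width <- vapply(c(50, 500), function(dens) {
    plot <- simulate_plot(dens, width = 500, height = 500, seed = 2)
    env <- bootstrap_plot(plot, n_boot = 200, seed = 4)
    tot <- env[env$variable == "nstem_size" & env$cell == "total", ]
    (tot$high - tot$low) / tot$median
  }, numeric(1))
  expect_lt(rel_width[2], rel_width[1])
})

test_that("min-max envelopes match a sort oracle", {
  one <- minmax_envelope(data.frame(plot = 1, cell = "<20", value = 7))
  expect_equal(c(one$low, one$median, one$high), rep(7, 3))
  vals <- data.frame(plot = 1:5, cell = "<30", value = c(2, 3, 3.5, 4, 40))
  env <- minmax_envelope(vals)
  expect_identical(env$high, 40)
  expect_identical(env$low, 2)
  expect_identical(env$median, sort(vals$value)[3])
  set.seed(8)
  multi <- expand.grid(plot = 1:7, cell = c("<20", "<30", "<40"))
  multi$value <- runif(nrow(multi))
  env2 <- minmax_envelope(multi)
  for (cl in unique(multi$cell)) {
    v <- sort(multi$value[multi$cell == cl])
    row <- env2[env2$cell == cl, ]
    expect_equal(c(row$low, row$median, row$high),
                 c(v[1], median(v), v[7]))
  }
})

test_that("scoring is inclusive at the bounds and fractions sum to one", {
  env <- bin_chronosequence(data.frame(age = rep(10, 25),
                                       Cwood_AG = c(rep(2, 5), rep(3, 15), rep(4, 5))))
  at <- function(v) score(data.frame(cell = "[0,20)", value = v), env)
  expect_identical(at(env$median)$status, "inside")
  expect_identical(at(env$high)$status, "inside")   # bounds inclusive
  expect_identical(at(env$low)$status, "inside")
  below <- at(env$low - 0.5)
  expect_identical(below$status, "below")
  expect_equal(below$distance, -0.5)
  above <- at(env$high + 0.25)
  expect_identical(above$status, "above")
  expect_equal(above$distance, 0.25)
  expect_equal(unname(rowSums(attr(above, "summary"))), 1)
  expect_error(score(data.frame(cell = "[200,220)", value = 1), env), "disjoint")
})

test_that("a model on the envelope's generating curve scores inside", {
  chron <- simulate_chronosequence(3000, max_age = 200, noise_sd = 0.25, seed = 12)
  env <- bin_chronosequence(chron)
  curve <- attr(chron, "curve")
  mids <- env$lower + 10
  model <- data.frame(cell = env$cell,
                      value = curve[["c_max"]] * (1 - exp(-curve[["rate"]] * mids)))
  card <- score(model, env)
  expect_gte(attr(card, "summary")$inside, 0.9)
})

test_that("model series map onto the envelope's age bins by bin means", {
  sim <- simulate_stand(sim_config(years = 100, phase_boundaries = c(12, 48, 90)))
  cells <- series_to_age_cells(sim$series, width = 20)
  expect_identical(cells$cell[1], "[0,20)")
  expect_equal(cells$value[1], mean(sim$series$Cwood_AG[1:20]))
  expect_identical(nrow(cells), 5L)
})
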