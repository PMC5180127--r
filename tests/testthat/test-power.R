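sey <- function() population_estimate("seychelles", 469, 557)
nin <- function() population_estimate("ningaloo", 320, 440)
mal <- function() population_estimate("maldives", 77, 98.5)

test_that("the kernel reproduces closed-form arithmetic", {
  expect_equal(required_sink_sample(0.8, 0.05, 59, 513, 380),
               0.8 * (380 + 0.05 * 513) / (0.05 * 59))
  expect_equal(required_sink_sample(0.8, 0.05, 59, 513, 380), 110.0,
               tolerance = 1e-3)
  expect_equal(required_sink_sample(0.8, 0.05, 104, 380, 87.75),
               0.8 * (87.75 + 0.05 * 380) / (0.05 * 104))
  expect_equal(required_sink_sample(0, 0.1, 59, 513, 380), 0)
  expect_error(required_sink_sample(0.8, 0, 59, 513, 380), "mr")
  expect_error(required_sink_sample(0.8, 0.1, -5, 513, 380), "positive")
})

test_that("kernel monotonicity and the MR -> 1 limit hold on grids", {
  mr <- seq(0.01, 1, by = 0.01)
  req <- required_sink_sample(0.8, mr, 59, 513, 380)
  expect_true(all(diff(req) < 0))                     # decreasing in MR
  expect_true(all(required_sink_sample(0.8, 0.1, 59, 513, seq(100, 800, 50))
                  == cummax(required_sink_sample(0.8, 0.1, 59, 513,
                                                 seq(100, 800, 50)))))
  ns <- seq(10, 200, 10)
  expect_true(all(diff(required_sink_sample(0.8, 0.1, ns, 513, 380)) < 0))
  # linear in DP
  expect_equal(required_sink_sample(0.4, 0.1, 59, 513, 380),
               0.5 * required_sink_sample(0.8, 0.1, 59, 513, 380))
  # MR -> 1 closed form
  expect_equal(required_sink_sample(0.8, 1, 59, 513, 380),
               0.8 * (380 + 513) / 59)
  # yield orientation is the algebraic reciprocal (up to DP^2 scaling)
  expect_equal(required_sink_sample(0.8, 0.05, 59, 513, 380) *
                 required_sink_sample(0.8, 0.05, 59, 513, 380,
                                      orientation = "yield"),
               0.8^2)
})

test_that("degenerate SEs collapse the Monte Carlo curve onto the kernel", {
  p_src <- list(site = "src", mean = 513, se = 0)
  p_snk <- list(site = "snk", mean = 380, se = 0)
  fit <- migration_power(59, p_src, p_snk, dp = 0.8, n_draws = 200,
                         seed = 1, n_source_se = 0)
  kern <- required_sink_sample(0.8, fit$curve$mr, 59, 513, 380)
  expect_equal(fit$curve$median, kern)
  expect_equal(fit$curve$lower, kern)
  expect_equal(fit$curve$upper, kern)
})

test_that("Monte Carlo curve is seed-deterministic, ordered and decreasing", {
  f1 <- migration_power(59, sey(), nin(), n_draws = 2000, seed = 7)
  f2 <- migration_power(59, sey(), nin(), n_draws = 2000, seed = 7)
  expect_identical(f1$curve, f2$curve)
  expect_true(all(f1$curve$lower <= f1$curve$median))
  expect_true(all(f1$curve$median <= f1$curve$upper))
  expect_true(all(diff(f1$curve$median) < 0))
})

test_that("large-draw median stays close to the kernel point value", {
  fit <- migration_power(59, sey(), nin(), dp = 0.8, n_draws = 1e5, seed = 3)
  kern <- required_sink_sample(0.8, fit$curve$mr, 59, 513, 380)
  expect_true(all(abs(fit$curve$median - kern) / kern < 0.02))
})

test_that("missing (n.d.) population estimates refuse to run", {
  tab <- indian_ocean_sites()
  moz <- list(site = "mozambique",
              mean = tab$p_mean[tab$site == "mozambique"], se = 10)
  expect_error(migration_power(77, moz, nin(), n_draws = 100, seed = 1),
               "n.d.")
  expect_error(migration_power(59, sey(), list(site = "x", mean = -40, se = 20),
                               n_draws = 100, seed = 1),
               "degenerate input")
})

test_that("detection threshold solves the median crossing with interpolation", {
  fit <- migration_power(59, sey(), nin(), dp = 0.8, n_draws = 5000,
                         seed = 2, sink_obs = 104)
  thr <- detection_threshold(fit)
  expect_true(thr$detectable)
  expect_false(thr$saturated)
  # interpolated value lies inside the bracketing grid points, at which the
  # median curve straddles the observed count
  expect_gte(thr$mr_star, thr$bracket[1])
  expect_lte(thr$mr_star, thr$bracket[2])
  med <- fit$curve$median
  i <- match(thr$mr_grid_star, fit$curve$mr)
  expect_lte(med[i], 104)
  expect_gt(med[i - 1], 104)

  # observed line above the whole curve -> saturation at the smallest rate
  sat <- detection_threshold(fit, n_sink_obs = 1e6)
  expect_true(sat$saturated)
  expect_equal(sat$mr_star, fit$curve$mr[1])
  # observed line below the whole curve -> not detectable on grid
  none <- detection_threshold(fit, n_sink_obs = 1)
  expect_false(none$detectable)
  expect_true(is.na(none$mr_star))
  expect_error(detection_threshold(fit, n_sink_obs = 0), "positive")
})

test_that("predict interpolates the fitted curve and reports the kernel", {
  fit <- migration_power(59, sey(), nin(), n_draws = 2000, seed = 5)
  pr <- predict(fit, mr = c(0.05, 0.0525, 0.1))
  expect_equal(pr$kernel,
               required_sink_sample(0.8, c(0.05, 0.0525, 0.1), 59, 513, 380))
  on_grid <- predict(fit)
  expect_equal(on_grid$median, fit$curve$median)
  expect_error(predict(fit, mr = 0.9), "outside")
  expect_named(coef(fit),
               c("dp", "n_source", "n_source_se", "p_source", "p_source_se",
                 "p_sink", "p_sink_se"))
})

test_that("plot method draws without error", {
  fit <- migration_power(59, sey(), nin(), n_draws = 500, seed = 6,
                         sink_obs = 104)
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_no_error(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("sampling oracle agrees with the hypergeometric expectation", {
  set.seed(20)
  for (mr in c(0.05, 0.1, 0.2)) {
    for (n_sink in c(30, 60, 104)) {
      o <- simulate_detection_oracle(p_source = 513, p_sink = 380,
                                     n_source = 59, n_sink = n_sink,
                                     mr = mr, n_reps = 10000)
      mc_se <- sd_bound <- sqrt(o$expected_matches / o$n_reps)  # Poisson-ish
      expect_lt(abs(o$mean_matches - o$expected_matches),
                3 * sqrt(o$expected_matches / o$n_reps) + 1e-9)
      # detection probability bracketed by the two DP conventions
      expect_gte(o$detection_prob + 3 * mc_se,
                 1 - exp(-o$expected_matches) - 3 * mc_se)
      expect_lte(o$detection_prob, min(1, o$expected_matches) + 3 * mc_se)
    }
  }
  # no migrants -> no detection
  expect_equal(simulate_detection_oracle(100, 100, 50, 50, 0)$detection_prob, 0)
  # census sampling of both pools detects any migrant
  full <- simulate_detection_oracle(p_source = 50, p_sink = 40, n_source = 50,
                                    n_sink = 45, mr = 0.1, n_reps = 200,
                                    seed = 1)
  expect_equal(full$detection_prob, 1)
})
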