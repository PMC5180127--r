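test_that("site-year summaries count individuals once per year and split new/resight", {
  # one individual seen three times in one year contributes 1
  rec <- make_catalogue(id = rep("a1", 3), site = "A",
                        date = c("2005-03-01", "2005-04-01", "2005-05-01"))
  summ <- site_year_summaries(rec)
  expect_equal(summ$n_unique, 1L)

  # toy catalogue: A seen 2005 & 2006, B seen 2006 only
  summ <- site_year_summaries(toy_two_year())
  expect_equal(summ$year, c(2005, 2006))
  expect_equal(summ$n_unique, c(1L, 2L))
  expect_equal(summ$n_new, c(1L, 1L))
  expect_equal(summ$n_resight, c(0L, 1L))
  # invariants: n_unique = n_new + n_resight; first year has no resights
  expect_equal(summ$n_unique, summ$n_new + summ$n_resight)
  expect_equal(summ$n_resight[1], 0L)
})

test_that("sum of yearly new individuals equals total unique individuals", {
  cfg <- world_config(sites = list(site_spec("A", 80, 0.5),
                                   site_spec("B", 40, 0.7)),
                      years = c(2004, 2010), seed = 13)
  rec <- simulate_world(cfg)$records
  summ <- site_year_summaries(rec)
  for (s in unique(summ$site)) {
    expect_equal(sum(summ$n_new[summ$site == s]),
                 length(unique(rec$individual_id[rec$site == s])))
  }
})

test_that("proportion resighted drops each site's first sampled year", {
  prop <- proportion_resighted_per_year(site_year_summaries(toy_two_year()))
  expect_equal(nrow(prop), 1L)
  expect_equal(prop$year, 2006)
  expect_equal(prop$prop_resight, 0.5)

  # single-year site excluded with warning
  one <- make_catalogue("b1", "B", "2007-01-01")
  expect_warning(out <- proportion_resighted_per_year(site_year_summaries(one)),
                 "single year")
  expect_null(out)

  # all individuals resighted every year -> proportion 1 in non-first years
  rec <- make_catalogue(id = rep(c("x", "y"), each = 3), site = "A",
                        date = rep(c("2005-06-01", "2006-06-01", "2007-06-01"), 2))
  prop <- proportion_resighted_per_year(site_year_summaries(rec))
  expect_equal(prop$prop_resight, c(1, 1))
})

test_that("years-observed distribution pools the top categories and sums to uniques", {
  # individual seen in all six window years lands in "5-6"
  rec <- make_catalogue(id = rep("a", 6), site = "A",
                        date = sprintf("%d-06-01", 2005:2010))
  tab <- years_observed_distribution(rec, list(A = c(2005, 2010)))
  expect_equal(colnames(tab), c("1", "2", "3", "4", "5-6"))
  expect_equal(unname(tab["A", "5-6"]), 1L)

  # 10-individual toy: hand-counted distribution
  ids <- sprintf("s%02d", 1:10)
  n_years <- c(1, 1, 1, 1, 2, 2, 3, 4, 5, 6)
  rec <- do.call(rbind, lapply(seq_along(ids), function(i) {
    make_catalogue(id = rep(ids[i], n_years[i]), site = "A",
                   date = sprintf("%d-06-01", seq(2005, by = 1,
                                                  length.out = n_years[i])))
  }))
  class(rec) <- c("sighting_catalogue", "data.frame")
  tab <- years_observed_distribution(rec, list(A = c(2005, 2010)))
  expect_equal(unname(tab["A", ]), c(4L, 2L, 1L, 1L, 2L))
  expect_equal(sum(tab["A", ]), 10L)
  tab6 <- years_observed_distribution(rec, list(A = c(2005, 2010)),
                                      pool_top = FALSE)
  expect_equal(unname(tab6["A", ]), c(4L, 2L, 1L, 1L, 1L, 1L))

  # a window outside the sampled years errors naming the site
  expect_error(years_observed_distribution(rec, list(A = c(1990, 1995))),
               "site A")
  expect_error(years_observed_distribution(rec, list(A = c(2005, 2011))),
               "six consecutive years")
})

test_that("mean years observed matches hand computation", {
  rec <- make_catalogue(id = c("x", "y", "y", "y"), site = "A",
                        date = c("2005-06-01", "2005-06-02", "2006-06-01",
                                 "2007-06-01"))
  m <- mean_years_observed(rec)
  expect_equal(m$mean_years, 2.0)  # individuals seen 1 and 3 years
  expect_equal(m$se, sd(c(1, 3)) / sqrt(2))
  # all individuals seen one year: mean 1, se 0
  rec1 <- make_catalogue(id = c("x", "y"), site = "A",
                         date = c("2005-06-01", "2005-07-01"))
  m1 <- mean_years_observed(rec1)
  expect_equal(m1$mean_years, 1.0)
  expect_equal(m1$se, 0)
})

test_that("longest consecutive-year run is computed per individual and site", {
  rec <- make_catalogue(id = rep("a", 4), site = "A",
                        date = c("2005-06-01", "2006-06-01", "2007-06-01",
                                 "2010-06-01"))
  expect_equal(max_consecutive_years(rec)$max_run, 3L)
  rec1 <- make_catalogue("b", "A", "2005-06-01")
  expect_equal(max_consecutive_years(rec1)$max_run, 1L)

  # against generator truth: per-site-year presence reconstructed from records
  cfg <- world_config(sites = list(site_spec("A", 50, 0.8)),
                      years = c(2001, 2008), seed = 17)
  rec <- simulate_world(cfg)$records
  runs <- max_consecutive_years(rec)
  yr <- as.integer(format(rec$date, "%Y"))
  oracle <- vapply(runs$individual_id, function(id) {
    y <- sort(unique(yr[rec$individual_id == id]))
    best <- run <- 1L
    if (length(y) > 1) for (i in 2:length(y)) {
      run <- if (y[i] == y[i - 1] + 1L) run + 1L else 1L
      best <- max(best, run)
    }
    best
  }, integer(1))
  expect_equal(runs$max_run, unname(oracle))
})

test_that("cross-site matches list between-site legs with speed", {
  # planted migrant: January record at M, September record at S
  rec <- make_catalogue(id = c("mig", "mig", "stay"),
                        site = c("mozambique", "seychelles", "mozambique"),
                        date = c("2010-01-22", "2010-08-31", "2010-02-01"))
  dist <- data.frame(from = "mozambique", to = "seychelles", km = 3000)
  m <- cross_site_matches(rec, distances = dist)
  expect_equal(nrow(m), 1L)
  expect_equal(m$individual_id, "mig")
  expect_equal(m$days, 221)
  expect_equal(round(m$km_per_day, 1), 13.6)
  # individual at one site only excluded
  expect_false("stay" %in% m$individual_id)
})

test_that("minimum travel speed is distance over days", {
  expect_equal(round(min_travel_speed(3000, 221), 1), 13.6)
  expect_equal(min_travel_speed(57, 57), 1.0)
  expect_equal(min_travel_speed(100, 8), 12.5)
  expect_error(min_travel_speed(0, 10), "positive")
  expect_error(min_travel_speed(10, -1), "positive")
})

test_that("sex composition uses unique individuals with fixed per-shark sex", {
  rec <- make_catalogue(id = c("a", "a", "b"), site = "A",
                        date = c("2005-01-01", "2005-02-01", "2005-03-01"),
                        sex = c("male", "male", "male"))
  comp <- sex_composition(rec)
  expect_equal(comp$male, 1)
  expect_equal(comp$female, 0)

  # indeterminate records resolve to the first determinate value
  rec2 <- make_catalogue(id = c("a", "a"), site = "A",
                         date = c("2005-01-01", "2006-01-01"),
                         sex = c("indeterminate", "female"))
  expect_equal(sex_composition(rec2)$female, 1)

  # fixture with known 39% male truth is recovered
  n <- 100
  sexes <- rep(c("male", "female", "indeterminate"), c(39, 20, 41))
  rec3 <- make_catalogue(id = sprintf("i%03d", 1:n), site = "A",
                         date = rep("2005-06-01", n), sex = sexes)
  comp3 <- sex_composition(rec3)
  expect_equal(comp3$male, 0.39)
  expect_equal(comp3$n_individuals, 100L)

  expect_warning(sex_composition(make_catalogue(character(0), character(0),
                                                character(0), character(0),
                                                character(0))),
                 "empty")
})
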