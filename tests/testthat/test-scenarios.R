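test_that("year-to-generation conversion rounds half away from zero", {
  expect_identical(generations_from_years(21000, 15), 1400L)
  expect_identical(generations_from_years(0, 15), 0L)
  expect_identical(generations_from_years(6000, 15), 400L)
  expect_identical(generations_from_years(22.5, 15), 2L)  # 1.5 rounds up
  expect_error(generations_from_years(100, 0), "generation_time")
  expect_error(generations_from_years(-5, 15), "age_years")
})

test_that("growth rate is the exponential closed form with endpoint identity", {
  expect_equal(growth_rate(10000, 10000, 1400), 0)
  expect_equal(growth_rate(10000, 20000, 1400), log(2) / 1400,
               tolerance = 1e-12)
  # round trip: N0 * exp(g t) recovers N1 for assorted trajectories
  cases <- list(c(1e4, 1e3, 1400), c(500, 5e4, 100), c(7, 7, 9),
                c(123.5, 77.2, 33))
  for (cs in cases) {
    tr <- deme_trajectory(1, cs[1], cs[2], cs[3])
    expect_equal(deme_size_at(tr, 0), cs[1], tolerance = 1e-12)
    expect_equal(deme_size_at(tr, cs[3]), cs[2], tolerance = 1e-12)
  }
  expect_error(growth_rate(1e4, 0, 10), "extinct")
})

test_that("deme size interpolation is geometric in time", {
  tr <- deme_trajectory(1, 10000, 40000, 1400)
  expect_equal(deme_size_at(tr, 700), 20000, tolerance = 1e-9)
  expect_error(deme_size_at(tr, -1), "tau")
  expect_error(deme_size_at(tr, 1401), "tau")
})

test_that("extinct demes shrink linearly to one copy at the horizon", {
  tr <- deme_trajectory(2, 1000, 1000, 100, extinct_before_horizon = TRUE)
  expect_equal(deme_size_at(tr, 0), 1000)
  expect_equal(deme_size_at(tr, 100), 1)
  expect_equal(deme_size_at(tr, 50), (1000 + 1) / 2, tolerance = 1e-9)
  # shorter window: flat before it starts
  tr2 <- deme_trajectory(2, 1000, 1000, 100, extinct_before_horizon = TRUE,
                         extinction_window = 20)
  expect_equal(deme_size_at(tr2, 79), 1000)
  expect_equal(deme_size_at(tr2, 100), 1)
})

test_that("hypothesis builders encode the four scenario geometries", {
  s <- build_hypothesis_scenario("PPPH")
  expect_s3_class(s, "scenario")
  expect_length(s$demes, 17)
  expect_equal(s$migration_prob, 0.01)
  expect_equal(s$horizon_generations, 1400L)
  ext <- vapply(s$demes, function(d) d$extinct_before_horizon, logical(1))
  expect_equal(sum(ext), 16)
  expect_false(ext[s$source_deme])
  expect_equal(s$demes[[1]]$N1, 1000)   # source expands (ratio 0.1)

  p <- build_hypothesis_scenario("PLAH")
  expect_false(any(vapply(p$demes, function(d) d$extinct_before_horizon,
                          logical(1))))
  expect_equal(p$demes[[1]]$N1, 10000)  # source constant
  expect_equal(p$demes[[2]]$N1, 1000)

  b <- build_hypothesis_scenario("BOTH")
  expect_equal(b$demes[[1]]$N1, 5000)
  expect_equal(b$demes[[3]]$N1, 1000)

  r <- build_hypothesis_scenario("RETRACTION")
  expect_equal(r$demes[[1]]$N1, 100000)
  expect_true(r$demes[[2]]$extinct_before_horizon)

  # pure function: identical on repeat call
  expect_identical(build_hypothesis_scenario("PPPH"),
                   build_hypothesis_scenario("PPPH"))
  expect_error(build_hypothesis_scenario("XYZ"), "unknown hypothesis")
})

test_that("horizon default is consistent with the generation-time conversion", {
  s <- build_hypothesis_scenario("PLAH")
  expect_identical(
    generations_from_years(21000, s$generation_time_years),
    s$horizon_generations)
})

test_that("theta-to-Ne conversion is the ploidy-scaled ratio and linear", {
  expect_equal(theta_to_ne(0, mu = 1e-7), 0)
  mu <- 0.0009 / (2 * 2433.09)
  expect_equal(theta_to_ne(0.0009, mu), 2433.09, tolerance = 1e-9)
  # linear in theta; halving with doubled ploidy factor
  expect_equal(theta_to_ne(3 * 0.01, mu), 3 * theta_to_ne(0.01, mu))
  expect_equal(theta_to_ne(0.01, mu, ploidy_factor = 4),
               theta_to_ne(0.01, mu, ploidy_factor = 2) / 2)
  expect_error(theta_to_ne(0.1, mu = 0), "mu")
  expect_error(theta_to_ne(0.1, mu = 1e-8, ploidy_factor = 3), "ploidy")
})

test_that("scenarios serialize and parse back identically", {
  for (nm in c("PLAH", "PPPH", "BOTH", "RETRACTION")) {
    s <- build_hypothesis_scenario(nm)
    f <- withr::local_tempfile(fileext = ".txt")
    write_scenario(s, f)
    expect_identical(read_scenario(f), s)
  }
})
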