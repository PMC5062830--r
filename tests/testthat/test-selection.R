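test_that("two-tailed simulation probability follows the doubling rule", {
  sims <- c(rep(1, 360), rep(-1, 1640))   # 360 of 2000 above observed 0
  expect_equal(two_tailed_probability(sims, 0), 0.360)
  expect_equal(two_tailed_probability(c(1, 2, 3), 5), 0)
  expect_equal(two_tailed_probability(c(1, 2, 3), 0), 1)   # capped
  # ties count below: observed equal to every simulated value
  expect_equal(two_tailed_probability(rep(2, 10), 2), 0)
  expect_error(two_tailed_probability(numeric(0), 1), "no simulated")
})

test_that("two-tailed probability is monotone non-increasing in the observation", {
  set.seed(3)
  sims <- rnorm(500)
  obs <- sort(runif(50, -3, 3))
  p <- vapply(obs, function(o) two_tailed_probability(sims, o), 0)
  expect_true(all(diff(p) <= 0))
})

test_that("empirical log-likelihood is the modal-height ratio", {
  vals <- c(rep(0.5, 50), rep(1.5, 100), rep(2.5, 25))
  d <- empirical_distribution(vals)
  # modal bin -> lnL = 0
  expect_equal(empirical_log_likelihood(d, 1.5), 0)
  # half-height bin -> ln(0.5)
  expect_equal(empirical_log_likelihood(d, 0.5), log(0.5), tolerance = 1e-9)
  # outside the simulated range -> -Inf (AIC +Inf)
  expect_identical(empirical_log_likelihood(d, 99), -Inf)
  expect_identical(aic(-Inf), Inf)
  expect_error(empirical_log_likelihood(d, NaN), "finite")
  # degenerate: all mass at one value
  d0 <- empirical_distribution(rep(3, 100))
  expect_equal(empirical_log_likelihood(d0, 3), 0)
  expect_identical(empirical_log_likelihood(d0, 10), -Inf)
})

test_that("histogram bin counts sum to the replicate count", {
  set.seed(17)
  vals <- rgamma(2000, 2)
  d <- empirical_distribution(vals)
  expect_equal(sum(d$counts), 2000)
  expect_true(all(d$counts >= 0))
})

test_that("AIC and Akaike weights follow their closed forms", {
  expect_equal(aic(0, 2), 4)
  expect_equal(aic(-1, 2), 6)
  expect_error(aic(0, -1), "K")
  w <- akaike_weights(c(10, 12))
  expect_equal(w$delta_aic, c(0, 2))
  expect_equal(w$weight, c(exp(0), exp(-1)) / (exp(0) + exp(-1)),
               tolerance = 1e-9)
  expect_equal(round(w$weight, 4), c(0.7311, 0.2689))
  expect_equal(w$plausible, c(TRUE, FALSE))  # strict dAIC < 2 rule
  w3 <- akaike_weights(c(5, 7.5, Inf))
  expect_equal(sum(w3$weight), 1, tolerance = 1e-9)
  expect_equal(sum(w3$delta_aic == 0), 1)
  expect_false(w3$plausible[3])
  expect_equal(akaike_weights(4)$weight, 1)
  expect_error(akaike_weights(c(Inf, Inf)), "infinite")
})

test_that("scenario fitting produces the full comparison table and methods work", {
  scns <- list(
    SMALL = build_hypothesis_scenario("PPPH", n_demes = 3, N0 = 300,
                                      horizon_generations = 200L),
    BIG = build_hypothesis_scenario("RETRACTION", n_demes = 3, N0 = 300,
                                    horizon_generations = 200L))
  part <- list(toy = partition_spec(
    "toy", build_substitution_model("HKY", kappa = 1.5), 300, 2e-6))
  samples <- sample_config(c(4, 3, 3))
  obs <- list(toy = list(h = 0.5, pi = 0.002))
  fit <- fit_scenarios(obs, scns, part, samples, n_sim = 120, seed = 5)
  expect_s3_class(fit, "scenario_fit")
  expect_equal(nrow(fit$table), 4)      # 2 scenarios x 2 statistics
  expect_setequal(fit$table$scenario, c("SMALL", "BIG"))
  for (st in c("h", "pi")) {
    sub <- fit$table[fit$table$statistic == st, ]
    expect_equal(sum(sub$AICw), 1, tolerance = 1e-9)
    expect_equal(sum(sub$delta_AIC == 0), 1)
  }
  expect_true(all(fit$table$P >= 0 & fit$table$P <= 1))
  # deterministic under the master seed
  fit2 <- fit_scenarios(obs, scns, part, samples, n_sim = 120, seed = 5)
  expect_identical(fit$table, fit2$table)
  # methods
  expect_output(print(fit), "scenario selection")
  sm <- summary(fit)
  expect_true(sm$best_overall %in% c("SMALL", "BIG"))
  cf <- coef(fit)
  expect_equal(sum(cf), 2 / 2, tolerance = 1e-9)  # mean weights sum to 1
  sims <- simulate(fit, nsim = 5, scenario = "SMALL")
  expect_equal(nrow(sims$toy), 5)
  expect_true(all(c("h", "pi") %in% names(sims$toy)))
  expect_error(fit_scenarios(obs, scns[1], part, samples, n_sim = 120),
               "two scenarios")
  expect_error(fit_scenarios(obs, scns, part, samples, n_sim = 10), "n_sim")
})

test_that("byte-identical scenarios split the Akaike weight evenly", {
  base <- build_hypothesis_scenario("PLAH", n_demes = 2, N0 = 400,
                                    horizon_generations = 100L)
  scns <- list(A = base, B = base)
  part <- list(toy = partition_spec(
    "toy", build_substitution_model("HKY", kappa = 1), 300, 2e-6))
  obs <- list(toy = list(h = 0.6, pi = 0.002))
  fit <- fit_scenarios(obs, scns, part, sample_config(c(5, 5)),
                       n_sim = 400, seed = 8, statistics = "h")
  w <- fit$table$AICw
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_lt(abs(w[1] - 0.5), 0.3)   # equal up to Monte-Carlo noise
})
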