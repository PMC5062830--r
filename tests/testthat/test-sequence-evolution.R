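test_that("substitution model generators are valid and nest correctly", {
  jc <- build_substitution_model("HKY", kappa = 1)
  expect_equal(unname(rowSums(jc$Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(diag(jc$Q)), rep(-1, 4), tolerance = 1e-12)
  # HKY with kappa = 1 and uniform frequencies equals Jukes-Cantor
  expect_equal(unname(jc$Q[1, 2]), 1 / 3, tolerance = 1e-12)

  hky <- build_substitution_model("HKY", kappa = 1.5, alpha = 0.017)
  expect_equal(unname(rowSums(hky$Q)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(hky$Q["A", "G"] / hky$Q["A", "C"]), 1.5,
               tolerance = 1e-12)
  expect_equal(hky$alpha, 0.017)

  tim <- build_substitution_model("TIM1", rates = c(AG = 4, CT = 8, AT = 2),
                                  freqs = c(0.3, 0.2, 0.2, 0.3))
  # TIM1 ties: r(AC) = r(GT), r(AT) = r(CG)
  ex <- tim$exchangeabilities
  expect_equal(unname(ex["AC"]), unname(ex["GT"]))
  expect_equal(unname(ex["AT"]), unname(ex["CG"]))
  expect_equal(unname(rowSums(tim$Q)), rep(0, 4), tolerance = 1e-12)
  # stationarity of the generator: detailed balance pi_i q_ij = pi_j q_ji
  P <- tim$freqs
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(P[i] * tim$Q[i, j], P[j] * tim$Q[j, i], tolerance = 1e-12)
  }

  expect_error(build_substitution_model("HKY", kappa = -1), "kappa")
  expect_error(build_substitution_model("HKY", freqs = c(-0.1, 0.4, 0.4, 0.3)),
               "freqs")
})

test_that("discrete gamma categories have mean one and match phangorn", {
  for (alpha in c(0.01, 0.017, 0.5, 1, 10)) {
    for (k in c(1, 4, 8)) {
      r <- gamma_category_rates(alpha, k)
      expect_length(r, k)
      expect_equal(mean(r), 1, tolerance = 1e-9)
    }
  }
  expect_equal(gamma_category_rates(0.5, 1), 1)
  skip_if_not_installed("phangorn")
  expect_equal(gamma_category_rates(0.017, 4),
               phangorn::discrete.gamma(0.017, 4), tolerance = 1e-6)
  expect_equal(gamma_category_rates(1.3, 6),
               phangorn::discrete.gamma(1.3, 6), tolerance = 1e-6)
})

test_that("tiny gamma shape gives extreme among-site heterogeneity", {
  r <- gamma_category_rates(0.017, 4)
  expect_lt(min(r), 1e-6 * max(r))
  rates <- draw_site_rates(0.017, 4, 1000, seed = 1)
  expect_length(rates, 1000)
  expect_true(all(rates %in% r))
})

test_that("zero mutation rate yields identical sequences", {
  scn <- panmictic_scenario(N = 100)
  g <- simulate_genealogy(scn, sample_config(6), seed = 5)
  m <- build_substitution_model("HKY", kappa = 2)
  aln <- evolve_alignment(g, m, length = 50, mu = 0, seed = 6)
  expect_equal(nrow(aln), 6)
  expect_equal(ncol(aln), 50)
  expect_true(all(apply(aln, 2, function(col) length(unique(col)) == 1)))
  expect_error(evolve_alignment(g, m, length = 0, mu = 1e-8), "length")
})

test_that("segregating sites match Watterson's expectation", {
  N <- 1000; n <- 10; L <- 1000; mu <- 1e-6
  scn <- panmictic_scenario(N = N)
  m <- build_substitution_model("HKY", kappa = 1, ncat = 1)
  set.seed(21)
  S <- replicate(2000, {
    g <- simulate_genealogy(scn, sample_config(n))
    core <- coalsel:::evolve_core(g, m, L, mu,
                                  site_rates = rep(1, L))
    coalsel:::stats_from_core(core)[["S"]]
  })
  a_n <- sum(1 / seq_len(n - 1))
  expected <- 2 * N * mu * L * a_n
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("high kappa makes almost all observed changes transitions", {
  g <- two_leaf_genealogy(5e4)
  m <- build_substitution_model("HKY", kappa = 100, ncat = 1)
  aln <- evolve_alignment(g, m, length = 5000, mu = 1e-6, seed = 8)
  diff <- which(aln[1, ] != aln[2, ])
  expect_gt(length(diff), 50)
  is_transition <- function(a, b) {
    paste0(pmin(a, b), pmax(a, b)) %in% c("AG", "CT")
  }
  frac <- mean(is_transition(aln[1, diff], aln[2, diff]))
  expect_gt(frac, 0.9)
})

test_that("leaf base composition converges to the stationary frequencies", {
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  m <- build_substitution_model("HKY", kappa = 2, freqs = freqs, ncat = 1)
  # branch long enough for ~10 substitutions per site: leaves stationary
  g <- two_leaf_genealogy(1e7)
  aln <- evolve_alignment(g, m, length = 3000, mu = 1e-6, seed = 9)
  counts <- table(factor(aln, levels = c("A", "C", "G", "T")))
  test <- stats::chisq.test(counts, p = freqs)
  expect_gt(test$p.value, 0.01)
})

test_that("sequence evolution is deterministic under a fixed seed", {
  scn <- panmictic_scenario(N = 500)
  g <- simulate_genealogy(scn, sample_config(8), seed = 13)
  m <- build_substitution_model("HKY", kappa = 1.5, alpha = 0.5)
  a1 <- evolve_alignment(g, m, 200, 1e-5, seed = 14)
  a2 <- evolve_alignment(g, m, 200, 1e-5, seed = 14)
  expect_identical(a1, a2)
})

test_that("variant-site fast path equals statistics on the full alignment", {
  scn <- build_hypothesis_scenario("BOTH", n_demes = 3, N0 = 2000,
                                   horizon_generations = 500L)
  m <- build_substitution_model("HKY", kappa = 1.5, alpha = 0.5)
  for (s in 1:5) {
    g <- simulate_genealogy(scn, sample_config(c(5, 5, 5)), seed = s)
    set.seed(100 + s)
    rates <- draw_site_rates(m$alpha, m$ncat, 500)
    set.seed(200 + s)
    aln <- evolve_alignment(g, m, 500, 5e-6, site_rates = rates)
    set.seed(200 + s)
    core <- coalsel:::evolve_core(g, m, 500L, 5e-6, rates)
    fast <- coalsel:::stats_from_core(core)
    expect_equal(unname(fast["h"]),
                 haplotype_diversity(haplotype_counts(aln)))
    expect_equal(unname(fast["pi"]), nucleotide_diversity(aln))
    expect_equal(unname(fast["S"]), segregating_sites(aln))
  }
})
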