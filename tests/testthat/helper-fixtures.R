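# Shared fixtures, built in code.

# a small single-deme constant-size scenario (panmictic Wright-Fisher)
panmictic_scenario <- function(N = 1000, horizon = 1L) {
  build_hypothesis_scenario("PLAH", n_demes = 1, N0 = N,
                            horizon_generations = horizon)
}

# hand-built two-leaf genealogy joined at time T (for substitution tests)
two_leaf_genealogy <- function(T) {
  structure(list(parent = c(3L, 3L, 0L), time = c(0, 0, T),
                 n_leaves = 2L, leaf_deme = c(1L, 1L),
                 leaf_labels = c("a", "b"), n_migrations = 0,
                 scenario_name = "manual"),
            class = "genealogy")
}

# tiny alignment matrix from a character vector of equal-length strings
aln_from_strings <- function(x, labels = sprintf("s%d", seq_along(x))) {
  m <- do.call(rbind, strsplit(x, ""))
  rownames(m) <- labels
  m
}

# brute-force one-level AMOVA from the full squared-distance matrix,
# via the textbook sums-of-squares identities (independent of the
# package's vectorized implementation)
amova_oracle <- function(aln, pop) {
  n <- nrow(aln)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(aln[i, ] != aln[j, ])
    }
  }
  d2 <- d^2
  ssd_tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ssd_tot <- ssd_tot + d2[i, j]
  ssd_tot <- ssd_tot / n
  ssd_wp <- 0
  sizes <- c()
  for (p in unique(pop)) {
    idx <- which(pop == p)
    sizes <- c(sizes, length(idx))
    if (length(idx) > 1) {
      s <- 0
      for (a in 1:(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) s <- s + d2[idx[a], idx[b]]
      }
      ssd_wp <- ssd_wp + s / length(idx)
    }
  }
  K <- length(unique(pop))
  sigma_w <- (ssd_wp) / (n - K)
  n_c <- (n - sum(sizes^2) / n) / (K - 1)
  sigma_a <- ((ssd_tot - ssd_wp) / (K - 1) - sigma_w) / n_c
  sigma_a / (sigma_a + sigma_w)
}

# all permutations of 1..n (for exact Mantel enumeration at tiny n)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# exact analytic sampler of Kingman coalescent TMRCA for n lineages in a
# constant-size haploid population of N copies (sum of exponentials)
kingman_tmrca_sample <- function(nrep, n, N) {
  replicate(nrep, {
    t <- 0
    for (k in n:2) t <- t + rexp(1, rate = choose(k, 2) / N)
    t
  })
}
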