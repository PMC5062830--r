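# Analysis of molecular variance (AMOVA) on haplotype pairwise distances,
# one level (among vs within populations), with a permutation test on
# phiST.  Distances are counts of differing sites between sequences.

pairwise_diff_matrix <- function(aln) {
  aln <- clean_alignment(aln)
  n <- nrow(aln)
  d <- matrix(0, n, n)
  if (n > 1) {
    num <- matrix(match(aln, BASES), nrow = n)
    for (i in 1:(n - 1)) {
      di <- colSums(t(num[(i + 1):n, , drop = FALSE]) != num[i, ])
      d[i, (i + 1):n] <- di
      d[(i + 1):n, i] <- di
    }
  }
  d
}

phist_from_dist <- function(d2, pop) {
  # d2: squared distances; Excoffier-style one-level decomposition
  N <- length(pop)
  K <- length(unique(pop))
  ssd_total <- sum(d2[lower.tri(d2)]) / N
  ssd_wp <- 0
  sizes <- integer(0)
  for (p in unique(pop)) {
    idx <- which(pop == p)
    sizes <- c(sizes, length(idx))
    if (length(idx) > 1) {
      sub <- d2[idx, idx, drop = FALSE]
      ssd_wp <- ssd_wp + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  ssd_ap <- ssd_total - ssd_wp
  df_ap <- K - 1
  df_wp <- N - K
  sigma_w <- if (df_wp > 0) ssd_wp / df_wp else 0
  n_c <- (N - sum(sizes^2) / N) / df_ap
  sigma_a <- (ssd_ap / df_ap - sigma_w) / n_c
  tot <- sigma_a + sigma_w
  phi <- if (tot == 0) 0 else sigma_a / tot
  list(phi_st = phi, sigma_among = sigma_a, sigma_within = sigma_w,
       ssd_among = ssd_ap, ssd_within = ssd_wp, df_among = df_ap,
       df_within = df_wp)
}

#' AMOVA phiST with a permutation test
#'
#' One-level analysis of molecular variance on squared pairwise sequence
#' distances (number of differing sites): partitions molecular variance
#' among and within populations and returns
#' `phiST = sigma2_among / (sigma2_among + sigma2_within)`, the
#' haplotype-distance analogue of FST. Significance is the plain
#' proportion of random population-label permutations whose phiST is at
#' least the observed value.
#'
#' Negative variance components (possible when true differentiation is
#' absent) are reported as computed; `phi_st_clamped` additionally clips
#' the statistic to `[-1, 1]`.
#'
#' @param aln character matrix of sequences with labelled rows.
#' @param popmap data frame with columns `label`, `population` (or a
#'   vector of population codes aligned with the rows).
#' @param n_perm number of label permutations (default 10,000; 0 skips
#'   the test).
#' @param seed optional integer seed for the permutations.
#' @return List with `phi_st`, `phi_st_clamped`, variance components,
#'   degrees of freedom and permutation `p_value`.
#' @export
amova_phist <- function(aln, popmap, n_perm = 10000, seed = NULL) {
  aln <- clean_alignment(aln)
  pop <- resolve_pops(aln, popmap)
  if (length(unique(pop)) < 2) {
    stop_invalid("AMOVA needs at least two populations")
  }
  if (!is.null(seed)) set.seed(seed)
  d2 <- pairwise_diff_matrix(aln)^2
  obs <- phist_from_dist(d2, pop)
  p <- NA_real_
  if (n_perm > 0) {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(pop)
      if (phist_from_dist(d2, perm)$phi_st >= obs$phi_st) ge <- ge + 1L
    }
    p <- ge / n_perm
  }
  c(obs, list(phi_st_clamped = min(max(obs$phi_st, -1), 1),
              p_value = p, n_perm = n_perm))
}

resolve_pops <- function(aln, popmap) {
  if (is.data.frame(popmap)) {
    pop <- popmap$population[match(rownames(aln), popmap$label)]
    if (anyNA(pop)) {
      stop_invalid("unmapped sequence labels: %s",
                   paste(head(rownames(aln)[is.na(pop)], 5), collapse = ", "))
    }
    as.character(pop)
  } else {
    if (length(popmap) != nrow(aln)) stop_invalid("population vector length mismatch")
    as.character(popmap)
  }
}

#' Pairwise phiST matrix between populations
#'
#' Applies [amova_phist()] to every population pair; optionally returns
#' the linearized transform `phi / (1 - phi)` used for isolation by
#' distance.
#'
#' @inheritParams amova_phist
#' @param linearized if `TRUE` return `phi/(1-phi)` (values of 1 map to
#'   `Inf`).
#' @return List with matrices `phi_st` (or its linearization) and
#'   `p_value`, both symmetric with zero/NA diagonals.
#' @export
pairwise_phist <- function(aln, popmap, n_perm = 0, seed = NULL,
                           linearized = FALSE) {
  aln <- clean_alignment(aln)
  pop <- resolve_pops(aln, popmap)
  if (!is.null(seed)) set.seed(seed)
  pops <- sort(unique(pop))
  K <- length(pops)
  if (K < 2) stop_invalid("need at least two populations")
  M <- matrix(0, K, K, dimnames = list(pops, pops))
  P <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  for (i in 1:(K - 1)) {
    for (j in (i + 1):K) {
      idx <- which(pop %in% c(pops[i], pops[j]))
      res <- amova_phist(aln[idx, , drop = FALSE], pop[idx], n_perm = n_perm)
      M[i, j] <- M[j, i] <- res$phi_st
      P[i, j] <- P[j, i] <- res$p_value
    }
  }
  if (linearized) {
    M <- M / (1 - M)
    diag(M) <- 0
  }
  list(phi_st = M, p_value = P, linearized = linearized)
}
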