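# Nucleotide sequence evolution on simulated genealogies.
#
# Models are materialized as constrained GTR generators (HKY via kappa,
# TIM1 via its exchangeability ties), normalized to one expected
# substitution per site per unit of mutation length, with discrete-gamma
# among-site rate variation.

BASES <- c("A", "C", "G", "T")

#' Build a nucleotide substitution model
#'
#' Supported families:
#' * `"HKY"`: transitions (A-G, C-T) scaled by `kappa` relative to
#'   transversions, arbitrary base frequencies.
#' * `"TIM1"`: GTR with ties `r(AC) = r(GT)` and `r(AT) = r(CG)`; free
#'   parameters `r(AG)`, `r(CT)`, `r(AT)` relative to `r(AC) = 1`.
#' * `"GTR"`: all six exchangeabilities free.
#'
#' The generator is scaled so the expected substitution rate at
#' stationarity is 1; branch-specific rates enter through the mutation
#' rate and the per-site gamma multipliers.
#'
#' @param family `"HKY"`, `"TIM1"` or `"GTR"`.
#' @param kappa transition/transversion rate ratio (HKY).
#' @param rates named exchangeabilities for TIM1 (`AG`, `CT`, `AT`) or
#'   GTR (`AC`, `AG`, `AT`, `CG`, `CT`, `GT`).
#' @param freqs stationary base frequencies (A, C, G, T); must be
#'   non-negative and are renormalized to sum to 1.
#' @param alpha gamma shape for among-site rate variation (`Inf` or
#'   `NULL` for uniform rates).
#' @param ncat number of discrete gamma categories (default 4).
#' @return Object of class `subst_model` with the scaled generator `Q`.
#' @examples
#' cp <- build_substitution_model("HKY", kappa = 1.5, alpha = 0.017)
#' @export
build_substitution_model <- function(family = c("HKY", "TIM1", "GTR"),
                                     kappa = 1, rates = NULL,
                                     freqs = rep(0.25, 4),
                                     alpha = NULL, ncat = 4L) {
  family <- match.arg(family)
  if (length(freqs) != 4 || any(freqs < 0) || sum(freqs) <= 0) {
    stop_invalid("freqs must be 4 non-negative values")
  }
  freqs <- freqs / sum(freqs)
  ex <- c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1, GT = 1)
  if (family == "HKY") {
    if (kappa < 0) stop_invalid("kappa must be >= 0")
    ex["AG"] <- kappa
    ex["CT"] <- kappa
  } else if (family == "TIM1") {
    r <- c(AG = 2, CT = 2, AT = 1)
    if (!is.null(rates)) r[names(rates)] <- rates
    if (any(r < 0)) stop_invalid("rates must be >= 0")
    ex["AG"] <- r[["AG"]]; ex["CT"] <- r[["CT"]]
    ex["AT"] <- r[["AT"]]; ex["CG"] <- r[["AT"]]   # TIM1 ties
    ex["AC"] <- 1; ex["GT"] <- 1
  } else {
    if (!is.null(rates)) ex[names(rates)] <- rates
    if (any(ex < 0)) stop_invalid("rates must be >= 0")
  }
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S["A", "C"] <- ex["AC"]; S["A", "G"] <- ex["AG"]; S["A", "T"] <- ex["AT"]
  S["C", "G"] <- ex["CG"]; S["C", "T"] <- ex["CT"]; S["G", "T"] <- ex["GT"]
  S <- S + t(S)
  Q <- S * rep(freqs, each = 4)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  if (scale <= 0) stop_invalid("degenerate model: zero substitution rate")
  Q <- Q / scale
  if (is.null(alpha)) alpha <- Inf
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  if (ncat < 1) stop_invalid("ncat must be >= 1")
  structure(
    list(family = family, Q = Q, freqs = freqs, exchangeabilities = ex,
         kappa = if (family == "HKY") kappa else NA_real_,
         alpha = alpha, ncat = as.integer(ncat)),
    class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model", x$family))
  if (x$family == "HKY") cat(sprintf(" (kappa = %g)", x$kappa))
  cat(sprintf("\n  freqs: %s\n", paste(sprintf("%s=%.3f", BASES, x$freqs),
                                       collapse = " ")))
  if (is.finite(x$alpha)) {
    cat(sprintf("  gamma rates: alpha = %g, %d categories\n",
                x$alpha, x$ncat))
  } else cat("  uniform site rates\n")
  invisible(x)
}

#' Mean rates of equiprobable discrete gamma categories
#'
#' Discretizes a Gamma(shape = alpha, rate = alpha) distribution (mean 1)
#' into `ncat` equal-probability categories and returns each category's
#' conditional mean, which average exactly to 1.
#'
#' @param alpha gamma shape, `> 0` (may be `Inf` for uniform rates).
#' @param ncat number of categories, `>= 1`.
#' @return Numeric vector of `ncat` mean rates.
#' @export
gamma_category_rates <- function(alpha, ncat) {
  if (ncat < 1) stop_invalid("ncat must be >= 1")
  if (!is.finite(alpha)) return(rep(1, ncat))
  if (alpha <= 0) stop_invalid("alpha must be > 0")
  ncat <- as.integer(ncat)
  if (ncat == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1),
                     shape = alpha, rate = alpha)
  # E[X; a < X <= b] for X ~ Gamma(alpha, alpha) equals
  # F_{alpha+1}(b) - F_{alpha+1}(a) (mean-1 identity)
  p1 <- stats::pgamma(b, shape = alpha + 1, rate = alpha)
  ncat * diff(p1)
}

#' Assign discrete-gamma rate multipliers to sites
#'
#' Each site is placed in one of `ncat` equiprobable categories uniformly
#' at random and receives that category's mean rate.
#'
#' @param alpha gamma shape.
#' @param ncat number of categories.
#' @param length number of sites.
#' @param seed optional integer seed.
#' @return Numeric vector of per-site rate multipliers.
#' @export
draw_site_rates <- function(alpha, ncat, length, seed = NULL) {
  if (length < 1) stop_invalid("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cats <- gamma_category_rates(alpha, ncat)
  cats[sample.int(length(cats), length, replace = TRUE)]
}

# descendant leaf indices for every node of a genealogy (children merge
# strictly before parents, so ascending node-time order is a valid
# bottom-up traversal)
descendant_leaves <- function(g) {
  ntot <- length(g$parent)
  n <- g$n_leaves
  desc <- vector("list", ntot)
  for (i in seq_len(n)) desc[[i]] <- i
  if (ntot > n) {
    ord <- setdiff(order(g$time), seq_len(n))
    kids <- split(which(g$parent > 0), g$parent[g$parent > 0])
    for (v in ord) {
      desc[[v]] <- unlist(desc[kids[[as.character(v)]]], use.names = FALSE)
    }
  }
  desc
}

# Core substitution sampler: exact uniformization on the genealogy.
# Returns root states plus leaf states at the sites hit by at least one
# substitution event; every other site is the root state in all leaves.
evolve_core <- function(g, model, L, mu, site_rates) {
  n <- g$n_leaves
  root_states <- sample.int(4L, L, replace = TRUE, prob = model$freqs)
  out <- list(root_states = root_states, L = L,
              var_sites = integer(0),
              var_states = matrix(integer(0), nrow = n, ncol = 0))
  if (n < 2 || mu <= 0 || !any(site_rates > 0)) return(out)
  Q <- model$Q
  nu <- max(-diag(Q))
  J <- diag(4) + Q / nu
  nonroot <- which(g$parent > 0)
  blen <- g$time[g$parent[nonroot]] - g$time[nonroot]
  tlen <- sum(blen)
  M <- rpois(1, nu * mu * tlen * sum(site_rates))
  if (M == 0) return(out)
  ev_site <- sample.int(L, M, replace = TRUE, prob = site_rates)
  ev_edge <- sample.int(length(nonroot), M, replace = TRUE, prob = blen)
  ev_node <- nonroot[ev_edge]               # child node below the branch
  ev_age <- g$time[ev_node] + runif(M) * blen[ev_edge]
  desc <- descendant_leaves(g)
  sites <- unique(ev_site)
  states <- matrix(0L, nrow = n, ncol = length(sites))
  for (k in seq_along(sites)) {
    s <- sites[k]
    leafstate <- rep.int(root_states[s], n)
    sel <- which(ev_site == s)
    # oldest first: an event on a branch is always older than any event
    # inside the subtree below it, so the subtree is homogeneous when
    # the event is applied
    for (e in sel[order(ev_age[sel], decreasing = TRUE)]) {
      idx <- desc[[ev_node[e]]]
      st <- leafstate[idx[1]]
      leafstate[idx] <- sample.int(4L, 1L, prob = J[st, ])
    }
    states[, k] <- leafstate
  }
  out$var_sites <- sites
  out$var_states <- states
  out
}

#' Evolve a nucleotide alignment on a genealogy
#'
#' The root sequence is drawn from the model's stationary frequencies;
#' substitutions are placed on branches by an exact uniformization scheme
#' (a dominating Poisson process at the fastest leaving rate, thinned by
#' the jump matrix `I + Q/nu`), with per-site discrete-gamma rate
#' multipliers. Only leaf sequences are returned.
#'
#' @param g a `genealogy` from [simulate_genealogy()].
#' @param model a [build_substitution_model()] object.
#' @param length alignment length in base pairs, `> 0`.
#' @param mu mutation rate per site per generation, `>= 0`.
#' @param seed optional integer seed.
#' @param site_rates optional precomputed per-site rate multipliers;
#'   drawn from the model's gamma settings when `NULL`.
#' @return Character matrix (sequences in rows, labelled) of A/C/G/T.
#' @examples
#' scn <- build_hypothesis_scenario("PLAH", n_demes = 2, N0 = 200)
#' g <- simulate_genealogy(scn, sample_config(c(3, 3)), seed = 1)
#' m <- build_substitution_model("HKY", kappa = 1.5)
#' aln <- evolve_alignment(g, m, length = 100, mu = 1e-4, seed = 2)
#' @export
evolve_alignment <- function(g, model, length, mu, seed = NULL,
                             site_rates = NULL) {
  stopifnot(inherits(g, "genealogy"), inherits(model, "subst_model"))
  if (length <= 0) stop_invalid("length must be > 0")
  if (mu < 0) stop_invalid("mu must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  if (is.null(site_rates)) {
    site_rates <- draw_site_rates(model$alpha, model$ncat, L)
  }
  if (length(site_rates) != L) stop_invalid("site_rates length mismatch")

  n <- g$n_leaves
  core <- evolve_core(g, model, L, mu, site_rates)
  seqs <- matrix(core$root_states, nrow = max(n, 1), ncol = L, byrow = TRUE)
  if (length(core$var_sites)) seqs[, core$var_sites] <- core$var_states
  out <- matrix(BASES[seqs], nrow = max(n, 1), ncol = L)
  rownames(out) <- g$leaf_labels
  attr(out, "site_rates") <- site_rates
  out
}

# Pooled summary statistics straight from the variant-site core, without
# materializing the full alignment (identical values, much faster).
stats_from_core <- function(core) {
  n <- nrow(core$var_states)
  if (n < 2) stop_invalid("need n >= 2 for summary statistics")
  k <- length(core$var_sites)
  if (k == 0) return(c(h = 0, pi = 0, S = 0))
  key <- apply(core$var_states, 1, paste, collapse = ",")
  cnt <- as.integer(table(key))
  # per-site allele counts: pairwise differences summed per column
  ac <- matrix(0L, 4, k)
  for (b in 1:4) ac[b, ] <- colSums(core$var_states == b)
  same_pairs <- colSums(ac * (ac - 1) / 2)
  npairs <- choose(n, 2)
  tot <- sum(npairs - same_pairs)
  S <- sum(colSums(ac > 0) > 1)
  c(h = haplotype_diversity(cnt),
    pi = tot / npairs / core$L,
    S = S)
}
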