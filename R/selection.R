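# Scenario selection: simulate each demographic hypothesis, build
# empirical distributions of the summary statistics, and score scenarios
# against observed values with two-tailed probabilities, empirical
# log-likelihoods and Akaike weights.

#' Two-tailed simulation probability
#'
#' `P = min(1, 2 * #(simulated > observed) / n_sim)`: twice the
#' proportion of simulated statistic values strictly above the observed
#' one. A high P means the scenario readily reproduces values as extreme
#' as the observation (failure to reject); the doubling can push the raw
#' formula above 1, so it is capped.
#'
#' @param sim_values simulated statistic values (non-empty).
#' @param observed observed statistic value.
#' @return `P` in `[0, 1]`.
#' @export
two_tailed_probability <- function(sim_values, observed) {
  if (length(sim_values) < 1) stop_invalid("no simulated values")
  min(1, 2 * sum(sim_values > observed) / length(sim_values))
}

#' Empirical distribution of a simulated summary statistic
#'
#' Bins the simulated values with the Freedman-Diaconis rule (falling
#' back to 50 equal-width bins when the IQR is zero); the histogram is
#' what the empirical likelihood is read from.
#'
#' @param values simulated statistic values.
#' @param statistic statistic name (for labelling).
#' @param scenario scenario name (for labelling).
#' @return Object of class `empirical_distribution` with bin edges and
#'   counts.
#' @export
empirical_distribution <- function(values, statistic = "stat",
                                   scenario = "scenario") {
  if (!length(values) || any(!is.finite(values))) {
    stop_invalid("simulated values must be finite and non-empty")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    edges <- c(rng[1] - 0.5, rng[1] + 0.5)
  } else {
    iqr <- IQR(values)
    if (iqr > 0) {
      bw <- 2 * iqr / length(values)^(1 / 3)
      nb <- max(1, ceiling(diff(rng) / bw))
    } else {
      nb <- 50
    }
    edges <- seq(rng[1], rng[2], length.out = nb + 1)
  }
  counts <- .bincode_counts(values, edges)
  structure(list(values = values, edges = edges, counts = counts,
                 statistic = statistic, scenario = scenario,
                 bin_rule = "Freedman-Diaconis (50 equal bins if IQR = 0)"),
            class = "empirical_distribution")
}

.bincode_counts <- function(values, edges) {
  # half-open [lo, hi) bins, last bin closed
  idx <- findInterval(values, edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx[idx == length(edges)] <- length(edges) - 1
  tabulate(idx, nbins = length(edges) - 1)
}

#' Empirical log-likelihood of an observed value
#'
#' The likelihood is the height of the histogram bin containing the
#' observed value divided by the maximum bin height, so the modal bin has
#' `lnL = 0` and an observation outside the simulated range has zero
#' support (`lnL = -Inf`, giving an infinite AIC).
#'
#' @param dist an [empirical_distribution()].
#' @param observed observed statistic value (finite).
#' @return `lnL <= 0` (possibly `-Inf`).
#' @export
empirical_log_likelihood <- function(dist, observed) {
  stopifnot(inherits(dist, "empirical_distribution"))
  if (!is.finite(observed)) stop_invalid("observed value must be finite")
  edges <- dist$edges
  if (observed < edges[1] || observed > edges[length(edges)]) return(-Inf)
  idx <- findInterval(observed, edges, rightmost.closed = TRUE)
  idx <- min(idx, length(edges) - 1)
  h <- dist$counts[idx]
  if (h == 0) return(-Inf)
  log(h / max(dist$counts))
}

#' Akaike information criterion
#'
#' `AIC = -2 lnL + 2K` with `K` free parameters (2 for all the
#' demographic scenarios: deme size and migration).
#'
#' @param lnL log-likelihood (may be `-Inf`).
#' @param K number of free parameters, `>= 0`.
#' @return AIC (possibly `+Inf`).
#' @export
aic <- function(lnL, K = 2) {
  if (any(K < 0)) stop_invalid("K must be >= 0")
  -2 * lnL + 2 * K
}

#' Delta AIC, Akaike weights and the plausibility flag
#'
#' `dAIC_i = AIC_i - min(AIC)`; raw weights `exp(-dAIC/2)` are
#' normalized to sum to 1; models with `dAIC < 2` are flagged as
#' equally plausible.
#'
#' @param aics vector of AIC values; at least one must be finite.
#' @return List with `delta_aic`, `weight`, `plausible`.
#' @export
akaike_weights <- function(aics) {
  if (!any(is.finite(aics))) stop_invalid("all AIC values are infinite")
  d <- aics - min(aics)
  w <- exp(-0.5 * d)
  list(delta_aic = d, weight = w / sum(w), plausible = d < 2)
}

# simulate one replicate's pooled summary statistics under a scenario
# (variant-site fast path; values identical to computing h and pi on the
# full evolved alignment)
simulate_stats_once <- function(scn, samples, partition, seed) {
  g <- simulate_genealogy(scn, samples, seed = seed,
                          size_multiplier = partition$size_multiplier %||% 1)
  model <- partition$model
  rates <- draw_site_rates(model$alpha, model$ncat, partition$length)
  core <- evolve_core(g, model, partition$length, partition$mu, rates)
  stats_from_core(core)[c("h", "pi")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition specification for scenario fitting
#'
#' Bundles the substitution model, alignment length and mutation rate of
#' one sequence partition (e.g. chloroplast or nuclear ITS).
#'
#' @param name partition tag.
#' @param model a [build_substitution_model()].
#' @param length alignment length in bp.
#' @param mu mutation rate per site per generation.
#' @param size_multiplier deme size multiplier for this partition
#'   (default 1; e.g. maternally inherited haploid loci may use a
#'   different effective copy number).
#' @return A `partition_spec` list.
#' @export
partition_spec <- function(name, model, length, mu, size_multiplier = 1) {
  stopifnot(inherits(model, "subst_model"))
  if (length <= 0) stop_invalid("length must be > 0")
  if (mu < 0) stop_invalid("mu must be >= 0")
  structure(list(name = name, model = model, length = as.integer(length),
                 mu = mu, size_multiplier = size_multiplier),
            class = "partition_spec")
}

#' Fit competing demographic scenarios to observed diversity statistics
#'
#' The model-selection engine: for each scenario, `n_sim` genealogies are
#' simulated and sequence alignments evolved per partition; pooled
#' haplotype diversity `h` and nucleotide diversity `pi` are computed per
#' replicate; each observed statistic is then scored against the
#' empirical distribution by a two-tailed probability, an empirical
#' log-likelihood, AIC (K = 2), delta AIC and Akaike weights (normalized
#' per statistic x partition).
#'
#' @param observed named list: for each partition name, a list or named
#'   vector with observed `h` and `pi`.
#' @param scenarios named list of [scenario()] objects (>= 2).
#' @param partitions named list of [partition_spec()] objects; names must
#'   match `observed`.
#' @param samples a [sample_config()] of present-day lineage counts per
#'   deme.
#' @param n_sim simulated replicates per scenario and partition
#'   (default 2,000; at least 100).
#' @param seed master seed; every replicate uses a derived stream.
#' @param statistics which statistics to score (subset of `c("h","pi")`).
#' @param K free parameters for AIC (default 2).
#' @return Object of class `scenario_fit` with the comparison `table`,
#'   the `distributions`, and provenance (`seed`, `n_sim`).
#' @seealso [print.scenario_fit()], [summary.scenario_fit()],
#'   [coef.scenario_fit()], [plot.scenario_fit()]
#' @export
fit_scenarios <- function(observed, scenarios, partitions, samples,
                          n_sim = 2000, seed = 1,
                          statistics = c("h", "pi"), K = 2) {
  if (length(scenarios) < 2) stop_invalid("need at least two scenarios")
  if (n_sim < 100) stop_invalid("n_sim must be >= 100")
  statistics <- match.arg(statistics, c("h", "pi"), several.ok = TRUE)
  if (is.null(names(scenarios))) {
    names(scenarios) <- vapply(scenarios, function(s) s$name, "")
  }
  if (!all(names(partitions) %in% names(observed))) {
    stop_invalid("observed statistics missing for some partitions")
  }
  sims <- list()
  for (pn in names(partitions)) {
    part <- partitions[[pn]]
    for (sn in names(scenarios)) {
      scn <- scenarios[[sn]]
      vals <- matrix(NA_real_, n_sim, 2,
                     dimnames = list(NULL, c("h", "pi")))
      for (r in seq_len(n_sim)) {
        rs <- derive_seed(seed, pn, sn, r)
        vals[r, ] <- tryCatch(
          simulate_stats_once(scn, samples, part, rs),
          error = function(e) {
            stop_invalid("replicate %d (%s/%s) failed: %s",
                         r, pn, sn, conditionMessage(e))
          })
      }
      sims[[pn]][[sn]] <- vals
    }
  }
  rows <- list()
  dists <- list()
  for (pn in names(partitions)) {
    for (st in statistics) {
      obs <- observed[[pn]][[st]]
      if (is.null(obs) || !is.finite(obs)) {
        stop_invalid("observed %s missing for partition %s", st, pn)
      }
      per <- lapply(names(scenarios), function(sn) {
        v <- sims[[pn]][[sn]][, st]
        d <- empirical_distribution(v, statistic = st, scenario = sn)
        dists[[paste(pn, st, sn, sep = ".")]] <<- d
        data.frame(partition = pn, statistic = st, scenario = sn,
                   observed = obs,
                   P = two_tailed_probability(v, obs),
                   lnL = empirical_log_likelihood(d, obs),
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, per)
      tab$AIC <- aic(tab$lnL, K)
      aw <- akaike_weights(tab$AIC)
      tab$delta_AIC <- aw$delta_aic
      tab$AICw <- aw$weight
      tab$plausible <- aw$plausible
      rows[[paste(pn, st, sep = ".")]] <- tab
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, distributions = dists,
                 scenarios = scenarios, partitions = partitions,
                 observed = observed, samples = samples,
                 n_sim = n_sim, seed = seed, K = K),
            class = "scenario_fit")
}

#' @describeIn fit_scenarios Table-style display of the comparison.
#' @param x,object a `scenario_fit`.
#' @param digits significant digits for display.
#' @param ... unused.
#' @export
print.scenario_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Demographic scenario selection: %d scenarios, %d simulations each\n",
              length(x$scenarios), x$n_sim))
  cat(sprintf("(master seed %s; K = %d free parameters)\n\n", x$seed, x$K))
  tab <- x$table
  tab$P <- round(tab$P, digits)
  tab$lnL <- round(tab$lnL, digits)
  tab$AIC <- round(tab$AIC, digits)
  tab$delta_AIC <- round(tab$delta_AIC, digits)
  tab$AICw <- round(tab$AICw, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @describeIn fit_scenarios Best scenario per statistic and overall
#'   (summed AIC across statistics and partitions).
#' @export
summary.scenario_fit <- function(object, ...) {
  tab <- object$table
  best <- do.call(rbind, lapply(split(tab, paste(tab$partition, tab$statistic)),
    function(d) d[which.min(d$AIC), c("partition", "statistic", "scenario",
                                      "delta_AIC", "AICw")]))
  rownames(best) <- NULL
  tot <- tapply(tab$AIC, tab$scenario, sum)
  overall <- names(tot)[which.min(tot)]
  out <- list(best_per_statistic = best, total_aic = tot,
              best_overall = overall)
  class(out) <- "summary.scenario_fit"
  out
}

#' @export
print.summary.scenario_fit <- function(x, ...) {
  cat("Best scenario per statistic:\n")
  print(x$best_per_statistic, row.names = FALSE)
  cat("\nTotal AIC (summed over statistics and partitions):\n")
  print(round(x$total_aic, 3))
  cat(sprintf("\nBest-supported scenario overall: %s\n", x$best_overall))
  invisible(x)
}

#' @describeIn fit_scenarios Akaike weights, averaged over statistics and
#'   partitions, as the fitted `coefficients` of the comparison.
#' @export
coef.scenario_fit <- function(object, ...) {
  tab <- object$table
  w <- tapply(tab$AICw, tab$scenario, mean)
  w[order(-w)]
}

#' @describeIn fit_scenarios Histogram of each scenario's simulated
#'   statistic with the observed value marked.
#' @param statistic,partition which panel set to draw.
#' @importFrom graphics abline hist par
#' @export
plot.scenario_fit <- function(x, statistic = "h",
                              partition = names(x$partitions)[1], ...) {
  sel <- paste(partition, statistic, names(x$scenarios), sep = ".")
  sel <- sel[sel %in% names(x$distributions)]
  if (!length(sel)) stop_invalid("no distributions for that panel")
  old <- par(mfrow = c(ceiling(length(sel) / 2), 2), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  obs <- x$observed[[partition]][[statistic]]
  for (nm in sel) {
    d <- x$distributions[[nm]]
    hist(d$values, breaks = d$edges, main = d$scenario,
         xlab = sprintf("%s (%s)", statistic, partition), ...)
    abline(v = obs, col = "red", lwd = 2)
  }
  invisible(x)
}

#' @describeIn fit_scenarios Draw new simulated statistic replicates
#'   under one fitted scenario.
#' @param nsim number of replicates to draw.
#' @param scenario scenario name to simulate from.
#' @importFrom stats simulate
#' @export
simulate.scenario_fit <- function(object, nsim = 100, seed = NULL,
                                  scenario = names(object$scenarios)[1],
                                  ...) {
  if (is.null(seed)) seed <- object$seed
  scn <- object$scenarios[[scenario]]
  if (is.null(scn)) stop_invalid("unknown scenario '%s'", scenario)
  out <- list()
  for (pn in names(object$partitions)) {
    vals <- t(vapply(seq_len(nsim), function(r) {
      simulate_stats_once(scn, object$samples, object$partitions[[pn]],
                          derive_seed(seed, "simulate", pn, scenario, r))
    }, c(h = 0, pi = 0)))
    out[[pn]] <- as.data.frame(vals)
  }
  out
}
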