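# Demographic scenarios: deme trajectories, the four competing hypotheses,
# and the size/time arithmetic they need.

#' Convert an age in years to generations
#'
#' Divides by the generation time and rounds half away from zero, so that
#' 21,000 years at 15 years per generation gives exactly 1,400 generations
#' (the horizon used for the Last Glacial Maximum).
#'
#' @param age_years age in years, `>= 0`.
#' @param generation_time_years generation time in years, `> 0`.
#' @return Integer number of generations.
#' @examples
#' generations_from_years(21000, 15)  # 1400
#' @export
generations_from_years <- function(age_years, generation_time_years) {
  if (any(generation_time_years <= 0)) {
    stop_invalid("generation_time_years must be > 0")
  }
  if (any(age_years < 0)) stop_invalid("age_years must be >= 0")
  x <- age_years / generation_time_years
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Exponential growth rate between present and horizon deme sizes
#'
#' Returns the per-generation rate `g = log(N1/N0) / t_span` such that a
#' deme of present size `N0` interpolated backward in time as
#' `N(tau) = N0 * exp(g * tau)` reaches size `N1` at the horizon. Positive
#' `g` means the deme was larger at the horizon than at present; in the
#' forward-time reading that is a shrinking population, and negative `g`
#' is a forward-time expansion (coalescent scenarios run backward).
#'
#' @param N0 present-day effective size (lineage copies), `> 0`.
#' @param N1 effective size at the horizon, `> 0` (extinct demes are
#'   handled by the `extinct_before_horizon` flag, not by `N1 = 0`).
#' @param t_span horizon in generations, `> 0`.
#' @return Per-generation exponential rate.
#' @export
growth_rate <- function(N0, N1, t_span) {
  if (any(N0 <= 0)) stop_invalid("N0 must be > 0")
  if (any(N1 <= 0)) stop_invalid("N1 must be > 0 (use extinct_before_horizon for extinction)")
  if (any(t_span <= 0)) stop_invalid("t_span must be > 0")
  log(N1 / N0) / t_span
}

#' Deme trajectory: one deme's size history between present and horizon
#'
#' @param deme_id integer deme index (1-based).
#' @param N0 effective size at present.
#' @param N1 effective size at the horizon.
#' @param t_span horizon in generations.
#' @param extinct_before_horizon logical; if `TRUE` the deme shrinks
#'   linearly to a single lineage copy over `extinction_window` generations
#'   ending at the horizon (backward in time the deme appears, grows from
#'   nothing; forward in time it goes extinct).
#' @param extinction_window generations over which the linear shrink to 1
#'   happens; defaults to the full span.
#' @return An object of class `deme_trajectory`.
#' @export
deme_trajectory <- function(deme_id, N0, N1, t_span,
                            extinct_before_horizon = FALSE,
                            extinction_window = t_span) {
  if (N0 <= 0) stop_invalid("N0 must be > 0")
  if (N1 < 0) stop_invalid("N1 must be >= 0")
  if (t_span <= 0) stop_invalid("t_span must be > 0")
  if (extinction_window <= 0 || extinction_window > t_span) {
    stop_invalid("extinction_window must be in (0, t_span]")
  }
  structure(
    list(deme_id = as.integer(deme_id), N0 = as.numeric(N0),
         N1 = as.numeric(N1), t_span = as.numeric(t_span),
         extinct_before_horizon = isTRUE(extinct_before_horizon),
         extinction_window = as.numeric(extinction_window)),
    class = "deme_trajectory")
}

#' Deme size at a time before present
#'
#' Exponential interpolation `N(tau) = N0 * exp(g * tau)` between the
#' present size and the horizon size; extinct demes instead shrink
#' linearly to one lineage copy over the extinction window ending at the
#' horizon, and follow their `N0` before the window starts.
#'
#' @param traj a [deme_trajectory()].
#' @param tau generations before present, in `[0, t_span]`.
#' @return Deme size (real, `>= 1` for extinct demes within the window).
#' @export
deme_size_at <- function(traj, tau) {
  stopifnot(inherits(traj, "deme_trajectory"))
  if (any(tau < 0 | tau > traj$t_span)) {
    stop_invalid("tau must lie in [0, t_span]")
  }
  if (traj$extinct_before_horizon) {
    start <- traj$t_span - traj$extinction_window
    sz <- ifelse(tau <= start, traj$N0,
                 traj$N0 + (1 - traj$N0) * (tau - start) / traj$extinction_window)
    return(pmax(sz, 1))
  }
  g <- growth_rate(traj$N0, traj$N1, traj$t_span)
  traj$N0 * exp(g * tau)
}

#' Demographic scenario for one hypothesis
#'
#' Bundles the deme trajectories with the migration model: backward in
#' time, every lineage outside the source deme moves into it with
#' probability `migration_prob` per generation; at the horizon all
#' surviving lineages are placed in the source deme, which then persists
#' at its horizon size until the most recent common ancestor.
#'
#' @param name scenario label.
#' @param demes list of [deme_trajectory()] objects.
#' @param source_deme deme id that receives backward migrants (refugium).
#' @param migration_prob per-lineage per-generation backward migration
#'   probability into the source deme, in `[0, 1]`.
#' @param horizon_generations generations between present and the horizon.
#' @param generation_time_years generation time used for year conversions.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, demes, source_deme = 1L, migration_prob = 0.01,
                     horizon_generations = 1400L,
                     generation_time_years = 15) {
  ids <- vapply(demes, function(d) d$deme_id, integer(1))
  if (anyDuplicated(ids)) stop_invalid("duplicate deme ids")
  if (!source_deme %in% ids) stop_invalid("source_deme is not a valid deme id")
  if (migration_prob < 0 || migration_prob > 1) {
    stop_invalid("migration_prob must lie in [0, 1]")
  }
  src <- demes[[match(source_deme, ids)]]
  if (src$extinct_before_horizon) stop_invalid("source deme cannot be extinct")
  structure(
    list(name = name, demes = demes, source_deme = as.integer(source_deme),
         migration_prob = migration_prob,
         horizon_generations = as.integer(horizon_generations),
         generation_time_years = generation_time_years),
    class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  ext <- sum(vapply(x$demes, function(d) d$extinct_before_horizon, logical(1)))
  cat(sprintf("Demographic scenario '%s': %d demes, source deme %d\n",
              x$name, length(x$demes), x$source_deme))
  cat(sprintf("  horizon %d generations (%.0f yr at %g yr/gen), migration %.3g/gen\n",
              x$horizon_generations,
              x$horizon_generations * x$generation_time_years,
              x$generation_time_years, x$migration_prob))
  cat(sprintf("  demes extinct before horizon: %d\n", ext))
  invisible(x)
}

#' Build one of the four competing demographic hypotheses
#'
#' The hypotheses describe what happened to a dry-forest tree's demes
#' between the Last Glacial Maximum (the horizon, 1,400 generations ago at
#' a 15-year generation time) and the present:
#'
#' * `PLAH` (Pleistocene Arc): glacial-time expansion across the
#'   non-source demes; each has horizon size `expansion_ratio * N0`
#'   (smaller at the horizon, i.e. forward-time growth since the LGM
#'   founding is encoded backward as shrink); the source deme is constant.
#' * `PPPH` (Amazon dry-forest): the source deme expands
#'   (`N1 = expansion_ratio * N0`) while every other deme funnels its
#'   lineages into it and shrinks to extinction before the horizon.
#' * `BOTH`: PLAH + PPPH geometry — non-source demes expand as in PLAH
#'   and the source also expands, but more weakly
#'   (`N1 = both_source_ratio * N0`) because the expansion is shared
#'   across the two directions; no deme goes extinct.
#' * `RETRACTION`: range retraction — the source deme was larger at the
#'   horizon (`N1 = retraction_ratio * N0`) and the other demes shrink to
#'   extinction as in PPPH.
#'
#' The N1/N0 ratios are explicit parameters because only the qualitative
#' geometry of the hypotheses is fixed; the defaults (0.1 for expansion,
#' 0.5 for the shared-expansion source, 10 for retraction) are package
#' choices, not estimates, and give every hypothesis a distinct
#' source-deme trajectory.
#'
#' @param name one of `"PLAH"`, `"PPPH"`, `"BOTH"`, `"RETRACTION"`.
#' @param n_demes number of demes (default 17).
#' @param N0 present-day size of every deme (default 10,000).
#' @param expansion_ratio N1/N0 for expanding demes (default 0.1).
#' @param both_source_ratio N1/N0 for the source deme under `BOTH`
#'   (default 0.5).
#' @param retraction_ratio N1/N0 for the retraction source deme (default 10).
#' @param source_deme id of the source/refugium deme (default 1).
#' @param migration_prob backward migration probability (default 0.01).
#' @param horizon_generations horizon (default 1,400).
#' @param generation_time_years generation time (default 15).
#' @return A [scenario()].
#' @examples
#' s <- build_hypothesis_scenario("PPPH")
#' s
#' @export
build_hypothesis_scenario <- function(name,
                                      n_demes = 17L,
                                      N0 = 10000,
                                      expansion_ratio = 0.1,
                                      both_source_ratio = 0.5,
                                      retraction_ratio = 10,
                                      source_deme = 1L,
                                      migration_prob = 0.01,
                                      horizon_generations = 1400L,
                                      generation_time_years = 15) {
  name <- toupper(name)
  hyp <- c("PLAH", "PPPH", "BOTH", "RETRACTION")
  if (!name %in% hyp) {
    stop_invalid("unknown hypothesis '%s' (expected one of %s)",
                 name, paste(hyp, collapse = ", "))
  }
  t_span <- horizon_generations
  mk <- function(id, N1, ext = FALSE) {
    deme_trajectory(id, N0 = N0, N1 = N1, t_span = t_span,
                    extinct_before_horizon = ext)
  }
  demes <- lapply(seq_len(n_demes), function(i) {
    is_src <- i == source_deme
    switch(name,
      PLAH = if (is_src) mk(i, N0) else mk(i, expansion_ratio * N0),
      PPPH = if (is_src) mk(i, expansion_ratio * N0) else mk(i, N0, ext = TRUE),
      BOTH = if (is_src) mk(i, both_source_ratio * N0) else mk(i, expansion_ratio * N0),
      RETRACTION = if (is_src) mk(i, retraction_ratio * N0) else mk(i, N0, ext = TRUE))
  })
  scenario(name, demes, source_deme = source_deme,
           migration_prob = migration_prob,
           horizon_generations = horizon_generations,
           generation_time_years = generation_time_years)
}

#' Default set of the four competing scenarios
#'
#' @param ... passed to [build_hypothesis_scenario()] for every hypothesis.
#' @return Named list of four [scenario()] objects.
#' @export
default_scenarios <- function(...) {
  nm <- c("PLAH", "PPPH", "BOTH", "RETRACTION")
  setNames(lapply(nm, build_hypothesis_scenario, ...), nm)
}

#' Convert the coalescent mutation parameter theta to effective size
#'
#' `theta = 2 * mu * Ne` for haploid-transmitted loci (chloroplast, with
#' maternal inheritance) and `theta = 4 * mu * Ne` for diploid nuclear
#' loci, so `Ne = theta / (ploidy_factor * mu)`.
#'
#' @param theta mutation/coalescent parameter per site, `>= 0`.
#' @param mu mutation rate per site per generation, `> 0`.
#' @param ploidy_factor 2 (haploid-transmitted) or 4 (diploid).
#' @return Effective population size.
#' @export
theta_to_ne <- function(theta, mu, ploidy_factor = 2) {
  if (any(mu <= 0)) stop_invalid("mu must be > 0")
  if (!all(ploidy_factor %in% c(2, 4))) {
    stop_invalid("ploidy_factor must be 2 or 4")
  }
  if (any(theta < 0)) stop_invalid("theta must be >= 0")
  theta / (ploidy_factor * mu)
}

# --- scenario file serialization (versioned key-value text) -----------------

#' Write a scenario to a key-value text file
#'
#' The format is a flat `key = value` text file with a schema id, one
#' `deme.<i>.*` block per deme; [read_scenario()] parses it back to an
#' identical object.
#'
#' @param scn a [scenario()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  ln <- c(
    "schema = coalsel-scenario-1",
    sprintf("name = %s", scn$name),
    sprintf("n_demes = %d", length(scn$demes)),
    sprintf("source_deme = %d", scn$source_deme),
    sprintf("migration_prob = %.17g", scn$migration_prob),
    sprintf("horizon_generations = %d", scn$horizon_generations),
    sprintf("generation_time_years = %.17g", scn$generation_time_years))
  for (d in scn$demes) {
    i <- d$deme_id
    ln <- c(ln,
      sprintf("deme.%d.N0 = %.17g", i, d$N0),
      sprintf("deme.%d.N1 = %.17g", i, d$N1),
      sprintf("deme.%d.t_span = %.17g", i, d$t_span),
      sprintf("deme.%d.extinct = %d", i, as.integer(d$extinct_before_horizon)),
      sprintf("deme.%d.extinction_window = %.17g", i, d$extinction_window))
  }
  writeLines(ln, path)
  invisible(path)
}

#' Read a scenario written by [write_scenario()]
#'
#' @param path path to a scenario key-value file.
#' @return A [scenario()].
#' @export
read_scenario <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  keys <- trimws(sub("=.*$", "", ln))
  vals <- trimws(sub("^[^=]*=", "", ln))
  get1 <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop_invalid("scenario file missing key '%s'", k)
    vals[i]
  }
  if (get1("schema") != "coalsel-scenario-1") {
    stop_invalid("unsupported scenario schema '%s'", get1("schema"))
  }
  nd <- as.integer(get1("n_demes"))
  demes <- lapply(seq_len(nd), function(i) {
    deme_trajectory(
      i,
      N0 = as.numeric(get1(sprintf("deme.%d.N0", i))),
      N1 = as.numeric(get1(sprintf("deme.%d.N1", i))),
      t_span = as.numeric(get1(sprintf("deme.%d.t_span", i))),
      extinct_before_horizon = as.integer(get1(sprintf("deme.%d.extinct", i))) == 1L,
      extinction_window = as.numeric(get1(sprintf("deme.%d.extinction_window", i))))
  })
  scenario(get1("name"), demes,
           source_deme = as.integer(get1("source_deme")),
           migration_prob = as.numeric(get1("migration_prob")),
           horizon_generations = as.integer(get1("horizon_generations")),
           generation_time_years = as.numeric(get1("generation_time_years")))
}
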