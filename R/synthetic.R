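# Study-shaped synthetic data: a 17-population template with two sequence
# partitions and toy 0.5-degree suitability rasters, so every analysis
# stage can be exercised without external data.

#' Default 17-population study template
#'
#' Emulates the shape of the real sampling design: 17 populations in
#' three regional groups with the published per-population sample sizes
#' (summing to 257 sequences), two partitions — chloroplast (1,742 bp,
#' HKY+G with kappa 1.5 and gamma shape 0.0170) and nuclear ITS (518 bp,
#' TIM1+G with gamma shape 0.010) — and a generating demographic
#' scenario. Coordinates are fictional but regionally clustered on a
#' 0.5-degree grid.
#'
#' The original per-site mutation rates are not published; the default
#' (1.85e-7 per site per generation for both partitions) is calibrated
#' from the published overall coalescent parameter and effective size
#' (`mu = theta / (2 Ne) = 0.0275 / (2 x 74,344)`), which makes the
#' simulated diversity magnitudes comparable to the observed data. The
#' rate is recorded in the truth metadata.
#'
#' @param scenario_name generating hypothesis (default `"PPPH"`).
#' @param seed master seed recorded in the template.
#' @param mu_cp,mu_its mutation rates per site per generation.
#' @param ... passed to [build_hypothesis_scenario()].
#' @return A `study_template` list: `populations` (data frame with pop,
#'   region, n, deme, lat, lon), `partitions`, `scenario`, `seed`.
#' @export
study_template <- function(scenario_name = "PPPH", seed = 1,
                           mu_cp = 1.85e-7, mu_its = 1.85e-7, ...) {
  pops <- data.frame(
    pop = c("CCM", "CRA", "POF", "SEC",
            "ALT", "ARA", "BOD", "GSV", "LUZ", "MIM", "POT", "PNA",
            "CAP", "PNI", "SAB", "SCA", "SUM"),
    region = c(rep("North-Northeast", 4), rep("Central-West", 8),
               rep("Southeast", 5)),
    n = c(20L, 9L, 27L, 4L,
          32L, 13L, 10L, 3L, 30L, 13L, 2L, 4L,
          23L, 21L, 6L, 21L, 19L),
    lat = c(-5.25, -7.25, -6.75, -8.25,
            -14.25, -15.75, -16.25, -14.75, -16.75, -15.25, -17.25, -13.75,
            -20.25, -21.75, -20.75, -22.25, -21.25),
    lon = c(-40.25, -39.25, -41.25, -38.75,
            -50.25, -49.25, -51.25, -48.25, -48.75, -52.25, -50.75, -47.75,
            -44.25, -45.25, -46.25, -44.75, -43.75),
    stringsAsFactors = FALSE)
  pops$deme <- seq_len(nrow(pops))
  partitions <- list(
    cpDNA = partition_spec(
      "cpDNA",
      build_substitution_model("HKY", kappa = 1.5, alpha = 0.0170),
      length = 1742, mu = mu_cp),
    ITS = partition_spec(
      "ITS",
      build_substitution_model("TIM1", alpha = 0.010),
      length = 518, mu = mu_its))
  scn <- build_hypothesis_scenario(scenario_name, n_demes = nrow(pops), ...)
  structure(list(populations = pops, partitions = partitions,
                 scenario = scn, seed = as.integer(seed)),
            class = "study_template")
}

#' @export
print.study_template <- function(x, ...) {
  cat(sprintf("Study template: %d populations, %d sequences, scenario %s, seed %d\n",
              nrow(x$populations), sum(x$populations$n),
              x$scenario$name, x$seed))
  for (p in x$partitions) {
    cat(sprintf("  %s: %d bp, %s model, mu = %g\n",
                p$name, p$length, p$model$family, p$mu))
  }
  invisible(x)
}

#' Generate a synthetic dataset bundle from a template
#'
#' Simulates one genealogy per partition under the template's scenario
#' and evolves alignments on them; returns (and optionally writes) the
#' alignments, the population map, population coordinates, and truth
#' metadata sufficient to regenerate the bundle exactly.
#'
#' @param template a [study_template()].
#' @param dir optional output directory; when given, writes
#'   `<partition>.fasta`, `popmap.tsv`, `coordinates.tsv` and
#'   `truth.txt`.
#' @return List with `alignments` (named character matrices), `popmap`,
#'   `coordinates` and `truth`.
#' @export
generate_dataset <- function(template, dir = NULL) {
  stopifnot(inherits(template, "study_template"))
  pops <- template$populations
  samples <- sample_config(pops$n, pops$deme)
  labels <- sprintf("%s_%02d", rep(pops$pop, pops$n),
                    unlist(lapply(pops$n, seq_len)))
  popmap <- data.frame(label = labels,
                       population = rep(pops$pop, pops$n),
                       stringsAsFactors = FALSE)
  alns <- list()
  for (pn in names(template$partitions)) {
    part <- template$partitions[[pn]]
    g <- simulate_genealogy(template$scenario, samples,
                            seed = derive_seed(template$seed, "genealogy", pn),
                            size_multiplier = part$size_multiplier %||% 1)
    aln <- evolve_alignment(g, part$model, part$length, part$mu,
                            seed = derive_seed(template$seed, "seq", pn))
    attr(aln, "site_rates") <- NULL
    rownames(aln) <- labels
    alns[[pn]] <- aln
  }
  truth <- c(
    sprintf("schema = coalsel-truth-1"),
    sprintf("scenario = %s", template$scenario$name),
    sprintf("seed = %d", template$seed),
    sprintf("n_populations = %d", nrow(pops)),
    sprintf("n_sequences = %d", sum(pops$n)),
    vapply(names(template$partitions), function(pn) {
      p <- template$partitions[[pn]]
      sprintf("partition.%s = length %d, model %s, alpha %g, mu %g",
              pn, p$length, p$model$family, p$model$alpha, p$mu)
    }, ""))
  bundle <- list(alignments = alns, popmap = popmap,
                 coordinates = pops[, c("pop", "lat", "lon")],
                 truth = truth, template = template)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (pn in names(alns)) {
      write_fasta(alns[[pn]], file.path(dir, paste0(pn, ".fasta")))
    }
    write.table(popmap, file.path(dir, "popmap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(bundle$coordinates, file.path(dir, "coordinates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(truth, file.path(dir, "truth.txt"))
    write_scenario(template$scenario, file.path(dir, "scenario.txt"))
  }
  bundle
}

#' Generate toy suitability rasters for three time slices
#'
#' Builds a smooth random field (sum of Gaussian bumps) on a 0.5-degree
#' grid, then displaces it eastward by `shift_cells` cells per step
#' between the slices (21 ka -> 6 ka -> present), so that range-centroid
#' movement and stability gradients are non-trivial. Values are clipped
#' to `[0, 1]`.
#'
#' @param template a [study_template()] (sets the grid around the
#'   populations).
#' @param seed integer seed for the random field.
#' @param shift_cells eastward displacement per time step in cells.
#' @param nrows,ncols grid dimensions.
#' @param n_bumps number of Gaussian bumps in the field.
#' @return Named list of three [suitability_raster()]s
#'   (`"21ka"`, `"6ka"`, `"present"`).
#' @export
generate_suitability_rasters <- function(template, seed = 1,
                                         shift_cells = 4L,
                                         nrows = 40L, ncols = 50L,
                                         n_bumps = 6L) {
  pops <- template$populations
  cellsize <- 0.5
  xll <- floor(min(pops$lon) / cellsize) * cellsize - 5
  yll <- floor(min(pops$lat) / cellsize) * cellsize - 5
  field <- function(shift) {
    set.seed(seed)
    v <- matrix(0, nrows, ncols)
    col <- matrix(seq_len(ncols), nrows, ncols, byrow = TRUE)
    row <- matrix(seq_len(nrows), nrows, ncols)
    for (b in seq_len(n_bumps)) {
      # bump cores kept in the western part of the grid so that the
      # displaced slices stay inside it (no mass lost at the margin)
      cx <- runif(1, 0.15 * ncols, 0.45 * ncols) + shift
      cy <- runif(1, 0.2 * nrows, 0.8 * nrows)
      s <- runif(1, 3, 8)
      amp <- runif(1, 0.4, 1)
      v <- v + amp * exp(-((col - cx)^2 + (row - cy)^2) / (2 * s^2))
    }
    pmin(pmax(v, 0), 1)
  }
  shifts <- c(`21ka` = 0, `6ka` = shift_cells, present = 2 * shift_cells)
  out <- lapply(names(shifts), function(tag) {
    suitability_raster(field(shifts[[tag]]), xll = xll, yll = yll,
                       cellsize = cellsize, tag = tag)
  })
  names(out) <- names(shifts)
  out
}
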