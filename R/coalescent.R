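# Backward-time structured coalescent simulation under a scenario.

#' Sample configuration: lineage counts per deme at present
#'
#' @param sizes integer vector of per-deme sample sizes (lineage copies at
#'   present); names or positions give deme ids.
#' @param deme_ids integer deme ids; defaults to `seq_along(sizes)`.
#' @return Object of class `sample_config`.
#' @export
sample_config <- function(sizes, deme_ids = seq_along(sizes)) {
  sizes <- as.integer(sizes)
  if (any(sizes < 0)) stop_invalid("sample sizes must be >= 0")
  if (sum(sizes) < 1) stop_invalid("at least one lineage is required")
  structure(list(sizes = sizes, deme_ids = as.integer(deme_ids)),
            class = "sample_config")
}

#' Simulate a genealogy under a demographic scenario
#'
#' Runs a discrete-generation structured coalescent backward from the
#' present: within every deme of current size `N(tau)` each unordered
#' lineage pair coalesces with probability `1/N(tau)` per generation
#' (collisions are resolved by random disjoint pairing, at most one
#' merger per lineage per generation); each lineage outside the source
#' deme migrates into it with probability `migration_prob` per
#' generation; at the horizon all surviving lineages are placed in the
#' source deme, which persists at its horizon size until the MRCA.
#'
#' Deme sizes for sequence partitions with different effective copy
#' numbers (e.g. maternally inherited chloroplast) can be rescaled with
#' `size_multiplier`.
#'
#' @param scn a [scenario()].
#' @param samples a [sample_config()] (deme ids must exist in `scn`).
#' @param seed optional integer; if given, `set.seed(seed)` is applied so
#'   the genealogy is reproducible.
#' @param size_multiplier multiplies every deme size (default 1).
#' @return Object of class `genealogy`: parent pointers (0 at the root),
#'   node times in generations before present, leaf demes and labels.
#' @examples
#' scn <- build_hypothesis_scenario("PLAH", n_demes = 3, N0 = 500)
#' g <- simulate_genealogy(scn, sample_config(c(4, 3, 3)), seed = 1)
#' tmrca(g)
#' @export
simulate_genealogy <- function(scn, samples, seed = NULL,
                               size_multiplier = 1) {
  stopifnot(inherits(scn, "scenario"), inherits(samples, "sample_config"))
  if (!is.null(seed)) set.seed(seed)
  ids <- vapply(scn$demes, function(d) d$deme_id, integer(1))
  if (!all(samples$deme_ids %in% ids)) {
    stop_invalid("sample deme ids not present in scenario")
  }
  horizon <- scn$horizon_generations
  D <- max(ids)
  size_mat <- matrix(1, nrow = D, ncol = horizon)
  tau <- seq_len(horizon)
  for (d in scn$demes) {
    size_mat[d$deme_id, ] <- deme_size_at(d, tau) * size_multiplier
  }
  src <- scn$demes[[match(scn$source_deme, ids)]]
  post_size <- deme_size_at(src, src$t_span) * size_multiplier

  leaf_deme <- rep(samples$deme_ids, samples$sizes)
  res <- sim_genealogy_cpp(as.integer(leaf_deme), size_mat,
                           as.integer(scn$source_deme),
                           scn$migration_prob, as.integer(horizon),
                           post_size)
  n <- length(leaf_deme)
  labels <- sprintf("d%02d_i%03d", leaf_deme,
                    unlist(lapply(samples$sizes, seq_len)))
  structure(
    list(parent = res$parent, time = res$time, n_leaves = n,
         leaf_deme = leaf_deme, leaf_labels = labels,
         n_migrations = res$n_migrations, scenario_name = scn$name),
    class = "genealogy")
}

#' Time to the most recent common ancestor of a genealogy
#'
#' @param g a `genealogy`.
#' @return Root node time in generations before present.
#' @export
tmrca <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  max(g$time)
}

#' Total branch length of a genealogy
#'
#' Sum over all non-root nodes of the time difference to their parent, in
#' generations.
#'
#' @param g a `genealogy`.
#' @return Total branch length in generations.
#' @export
total_branch_length <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  nonroot <- which(g$parent > 0)
  sum(g$time[g$parent[nonroot]] - g$time[nonroot])
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf("Genealogy: %d leaves, TMRCA %.1f generations, total length %.1f\n",
              x$n_leaves, tmrca(x), total_branch_length(x)))
  invisible(x)
}

#' Convert a genealogy to an ape `phylo` tree
#'
#' Branch lengths are in generations before present. Single-leaf
#' genealogies cannot be represented as a `phylo` and raise an error.
#'
#' @param g a `genealogy`.
#' @return An [ape::as.phylo] object.
#' @export
as_phylo <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  n <- g$n_leaves
  if (n < 2) stop_invalid("cannot convert a single-leaf genealogy to phylo")
  ntot <- length(g$parent)
  # ape convention: tips 1..n, root n+1, internals follow; our internal
  # node order is by merge time, root is node ntot
  new_id <- integer(ntot)
  new_id[seq_len(n)] <- seq_len(n)
  internal <- seq.int(n + 1L, ntot)
  new_id[ntot] <- n + 1L
  if (ntot > n + 1L) {
    rest <- internal[-length(internal)]
    new_id[rest] <- seq.int(n + 2L, ntot)
  }
  nonroot <- which(g$parent > 0)
  edge <- cbind(new_id[g$parent[nonroot]], new_id[nonroot])
  len <- g$time[g$parent[nonroot]] - g$time[nonroot]
  tr <- list(edge = edge, edge.length = len,
             tip.label = g$leaf_labels, Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Write a genealogy to a Newick file
#'
#' @param g a `genealogy`.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @return The path (or the Newick string when `path` is `NULL`).
#' @export
write_genealogy_newick <- function(g, path = NULL) {
  tr <- as_phylo(g)
  if (is.null(path)) {
    ape::write.tree(tr)
  } else {
    ape::write.tree(tr, file = path)
    invisible(path)
  }
}
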