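# Summary statistics computed identically on observed and simulated
# alignments: haplotype counts, Nei's haplotype diversity, nucleotide
# diversity, segregating sites, and per-population tables.

# drop columns containing anything other than A/C/G/T in any sequence
# (gap/ambiguity columns are excluded alignment-wide before any statistic)
clean_alignment <- function(aln) {
  if (!is.matrix(aln)) stop_invalid("alignment must be a character matrix")
  if (nrow(aln) == 0) stop_invalid("empty alignment")
  ok <- colSums(matrix(aln %in% BASES, nrow = nrow(aln))) == nrow(aln)
  aln[, ok, drop = FALSE]
}

#' Haplotype frequency spectrum of an alignment
#'
#' Partitions sequences into identity classes by exact string equality
#' over all retained columns (columns with gaps or ambiguity codes in any
#' sequence are excluded alignment-wide first) and returns the class
#' sizes, largest first.
#'
#' @param aln character matrix of sequences (rows).
#' @return Integer vector of haplotype counts.
#' @export
haplotype_counts <- function(aln) {
  aln <- clean_alignment(aln)
  key <- apply(aln, 1, paste, collapse = "")
  sort(as.integer(table(key)), decreasing = TRUE)
}

#' Nei's unbiased haplotype diversity
#'
#' `h = n (1 - sum p_i^2) / (n - 1)` where `p_i` are haplotype relative
#' frequencies and `n` the sample size: the probability that two
#' sequences drawn without replacement are different haplotypes.
#'
#' @param counts haplotype counts (e.g. from [haplotype_counts()]), with
#'   `sum(counts) >= 2`.
#' @return `h` in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(1, 1))   # 1
#' haplotype_diversity(c(19, 1))  # 0.1
#' @export
haplotype_diversity <- function(counts) {
  n <- sum(counts)
  if (n < 2) stop_invalid("haplotype diversity needs n >= 2")
  p <- counts / n
  h <- n * (1 - sum(p^2)) / (n - 1)
  min(max(h, 0), 1)
}

#' Nucleotide diversity per site
#'
#' Mean proportion of differing sites over all sequence pairs.
#'
#' @param aln character matrix of sequences.
#' @return `pi` per site.
#' @export
nucleotide_diversity <- function(aln) {
  aln <- clean_alignment(aln)
  n <- nrow(aln)
  if (n < 2) stop_invalid("nucleotide diversity needs n >= 2")
  L <- ncol(aln)
  if (L == 0) stop_invalid("alignment has no usable sites")
  # collapse to haplotypes first: pairwise differences between classes
  key <- apply(aln, 1, paste, collapse = "")
  tab <- table(key)
  uniq <- aln[match(names(tab), key), , drop = FALSE]
  cnt <- as.integer(tab)
  k <- length(cnt)
  tot <- 0
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        d <- sum(uniq[i, ] != uniq[j, ])
        tot <- tot + cnt[i] * cnt[j] * d
      }
    }
  }
  tot / choose(n, 2) / L
}

#' Number of segregating (polymorphic) sites
#'
#' @param aln character matrix of sequences.
#' @return Count of columns with two or more observed states.
#' @export
segregating_sites <- function(aln) {
  aln <- clean_alignment(aln)
  if (nrow(aln) < 2) stop_invalid("segregating sites needs n >= 2")
  if (ncol(aln) == 0) return(0L)
  sum(apply(aln, 2, function(col) length(unique(col)) > 1))
}

#' Per-population and overall diversity summary table
#'
#' Mirrors the usual per-population summary: sample size N, number of
#' haplotypes k, haplotype diversity h, nucleotide diversity pi, with an
#' overall row. Standard deviations of h and pi are bootstrap over sites.
#'
#' @param aln character matrix of sequences with labelled rows.
#' @param popmap a population map (see [read_popmap()]): data frame with
#'   columns `label` and `population`.
#' @param n_boot bootstrap replicates over sites for SDs (0 to skip).
#' @param seed optional seed for the bootstrap.
#' @return Data frame with one row per population plus `Overall`.
#' @export
diversity_table <- function(aln, popmap, n_boot = 0, seed = NULL) {
  aln <- clean_alignment(aln)
  pops <- popmap$population[match(rownames(aln), popmap$label)]
  if (anyNA(pops)) {
    stop_invalid("unmapped sequence labels: %s",
                 paste(head(rownames(aln)[is.na(pops)], 5), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  one <- function(sub) {
    n <- nrow(sub)
    cnt <- haplotype_counts(sub)
    h <- if (n >= 2) haplotype_diversity(cnt) else NA_real_
    pi <- if (n >= 2) nucleotide_diversity(sub) else NA_real_
    hsd <- pisd <- NA_real_
    if (n_boot > 0 && n >= 2 && ncol(sub) > 0) {
      bs <- replicate(n_boot, {
        cols <- sample.int(ncol(sub), replace = TRUE)
        b <- sub[, cols, drop = FALSE]
        c(haplotype_diversity(haplotype_counts(b)), nucleotide_diversity(b))
      })
      hsd <- sd(bs[1, ]); pisd <- sd(bs[2, ])
    }
    data.frame(N = n, k = length(cnt), h = h, h_sd = hsd,
               pi = pi, pi_sd = pisd)
  }
  rows <- lapply(split(seq_len(nrow(aln)), pops), function(idx) {
    one(aln[idx, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  out <- cbind(population = names(rows), out)
  overall <- cbind(population = "Overall", one(aln))
  rownames(out) <- rownames(overall) <- NULL
  rbind(out, overall)
}
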