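#' @useDynLib coalsel, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rpois runif setNames quantile IQR cor rexp sd
#' @importFrom utils head write.table read.table
NULL

#' Derive a reproducible child seed from a master seed and a stream label
#'
#' All randomness in the package flows from one master seed per top-level
#' call, split into named streams (one per replicate, per partition, per
#' stage) so that sub-computations are independently reproducible. The
#' derivation is a small deterministic integer hash kept below 2^31.
#'
#' @param master integer master seed.
#' @param ... further integers or strings naming the stream.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, ...) {
  parts <- c(as.character(master), vapply(list(...), as.character, ""))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(p)) {
      h <- (h * 31 + ch) %% 2147483629
    }
    h <- (h * 131 + 7) %% 2147483629
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
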