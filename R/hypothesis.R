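#' Specify the null hypothesis of a contingency-table test
#'
#' Builds the descriptor used throughout the package to identify which null
#' is being tested and which reference distributions apply.  Three hypotheses
#' are supported:
#'
#' * `"homogeneity"`: the rows of an `l x c` table are independent
#'   multinomial samples with fixed row totals, and all rows share one
#'   column-probability vector.
#' * `"independence"`: the whole table is a single multinomial sample with
#'   fixed grand total, and each cell probability factorises into
#'   row-marginal times column-marginal probability.
#' * `"hwe"`: genotype counts (AA, Aa, aa) follow Hardy-Weinberg proportions
#'   (theta^2, 2 theta (1 - theta), (1 - theta)^2) for one allele frequency.
#'
#' Two degree-of-freedom values are attached.  `df_freq` is the usual
#' dimension gap `dim(Theta) - dim(Theta_H)` used by the asymptotic
#' chi-square reference of the likelihood-ratio statistic; `df_bayes` is the
#' full dimension `dim(Theta)` used by the asymptotic e-value of the Full
#' Bayesian Significance Test.
#'
#' @param kind one of `"homogeneity"`, `"independence"`, `"hwe"`.
#' @param nrow,ncol table dimensions (ignored for `"hwe"`); both must be
#'   at least 2.
#' @return an object of class `"hypothesis_spec"` with fields `kind`,
#'   `nrow`, `ncol`, `df_freq`, `df_bayes`.
#' @examples
#' hypothesis_spec("homogeneity", 2, 2)
#' hypothesis_spec("hwe")
#' @export
hypothesis_spec <- function(kind = c("homogeneity", "independence", "hwe"),
                            nrow = NULL, ncol = NULL) {
  kind <- match.arg(kind)
  if (kind == "hwe") {
    out <- list(kind = "hwe", nrow = NULL, ncol = NULL,
                df_freq = 1L, df_bayes = 2L)
    return(structure(out, class = "hypothesis_spec"))
  }
  if (is.null(nrow) || is.null(ncol)) {
    stop("table dimensions `nrow` and `ncol` are required for the ",
         kind, " hypothesis")
  }
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (nrow < 2L || ncol < 2L) {
    stop("contingency-table hypotheses need at least 2 rows and 2 columns")
  }
  df_freq <- (nrow - 1L) * (ncol - 1L)
  df_bayes <- if (kind == "homogeneity") nrow * (ncol - 1L) else nrow * ncol - 1L
  structure(list(kind = kind, nrow = nrow, ncol = ncol,
                 df_freq = df_freq, df_bayes = df_bayes),
            class = "hypothesis_spec")
}

#' @export
print.hypothesis_spec <- function(x, ...) {
  dims <- if (x$kind == "hwe") "genotype triple" else
    paste0(x$nrow, " x ", x$ncol, " table")
  cat(sprintf("%s hypothesis (%s); df: %d (LRT), %d (FBST)\n",
              x$kind, dims, x$df_freq, x$df_bayes))
  invisible(x)
}

# Resolve a user-supplied hypothesis argument (string or spec) against an
# observed object, deriving table dimensions where needed.
resolve_hypothesis <- function(hypothesis, x = NULL) {
  if (inherits(hypothesis, "hypothesis_spec")) return(hypothesis)
  kind <- match.arg(hypothesis, c("homogeneity", "independence", "hwe"))
  if (kind == "hwe") return(hypothesis_spec("hwe"))
  if (is.null(x)) stop("table dimensions cannot be inferred; pass a hypothesis_spec")
  cnt <- if (inherits(x, "contingency_table")) x$counts else as.matrix(x)
  hypothesis_spec(kind, nrow(cnt), ncol(cnt))
}
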