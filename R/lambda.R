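# Likelihood-ratio statistics, computed in natural-log space.
#
# Every table is represented as a column of a cells matrix, flattened
# row-major.  Zero counts contribute zero to every x*log(x/m) term
# (0 log 0 = 0, 0^0 = 1), matching the limit of the likelihood.  The
# internal functions are vectorised over whole sample spaces; the exported
# lrt_lambda() wraps a single observed table.

# log lambda for homogeneity: X is (l*c) x N, margins length l (all > 0)
log_lambda_homogeneity <- function(X, margins, ncol) {
  l <- length(margins)
  n <- sum(margins)
  colj <- rep(seq_len(ncol), l)
  NJ <- rowsum(X, colj)                       # column margins, ncol x N
  num <- colSums(xlx(NJ, n))
  den <- colSums(xlx(X, rep(margins, each = ncol)))
  pmin(num - den, 0)
}

# log lambda for independence: X is (l*c) x N with column sums n
log_lambda_independence <- function(X, nrow, ncol) {
  n <- sum(X[, 1L])
  NI <- rowsum(X, rep(seq_len(nrow), each = ncol))
  NJ <- rowsum(X, rep(seq_len(ncol), nrow))
  pmin(colSums(xlx(NI, n)) + colSums(xlx(NJ, n)) - colSums(xlx(X, n)), 0)
}

# log lambda for Hardy-Weinberg: X is 3 x N genotype triples summing to n
log_lambda_hwe <- function(X, n) {
  p <- 2 * X[1L, ] + X[2L, ]                  # allele-A count, 0..2n
  q <- 2 * X[3L, ] + X[2L, ]
  th <- p / (2 * n)
  num <- X[2L, ] * log(2) + plog(p, th) + plog(q, 1 - th)
  den <- colSums(xlx(X, n))
  pmin(num - den, 0)
}

log_lambda_space <- function(X, hyp, margins = NULL, n = NULL) {
  switch(hyp$kind,
    homogeneity = log_lambda_homogeneity(X, margins, hyp$ncol),
    independence = log_lambda_independence(X, hyp$nrow, hyp$ncol),
    hwe = log_lambda_hwe(X, n))
}

# Coerce observed input to the flattened-cells column + sizes used internally.
as_observed <- function(x, hyp) {
  if (hyp$kind == "hwe") {
    g <- genotype_counts(if (inherits(x, "genotype_counts")) x$x else x)
    list(cells = matrix(g$x, 3L, 1L), n = g$n, margins = NULL, obj = g)
  } else {
    ct <- contingency_table(if (inherits(x, "contingency_table")) x$counts else x)
    if (!is.null(hyp$nrow) &&
        (nrow(ct$counts) != hyp$nrow || ncol(ct$counts) != hyp$ncol)) {
      stop("observed table is ", nrow(ct$counts), " x ", ncol(ct$counts),
           " but the hypothesis describes a ", hyp$nrow, " x ", hyp$ncol, " table")
    }
    list(cells = matrix(t(ct$counts), ncol = 1L),  # row-major flattening
         n = ct$total, margins = ct$row_margins, obj = ct)
  }
}

#' Likelihood-ratio statistic of an observed table
#'
#' Computes the LRT statistic `lambda`, the ratio of the likelihood
#' maximised over the null set to the likelihood maximised over the whole
#' parameter space, entirely in log space.  Under homogeneity the null MLE
#' is the pooled column-proportion vector; under independence it is the
#' product of the marginal proportions; under Hardy-Weinberg it is the
#' allele-frequency plug-in `theta_hat = (2 x1 + x2) / (2 n)`.
#'
#' @param x observed table: a matrix or [contingency_table()] for the table
#'   hypotheses, a length-3 vector or [genotype_counts()] for `"hwe"`.
#' @param hypothesis hypothesis kind or [hypothesis_spec()].
#' @return a list with `lambda` (in (0, 1]), `log_lambda`, `statistic`
#'   (`-2 log lambda`), the hypothesis spec, and for `"hwe"` the null MLE
#'   `theta_hat`.
#' @examples
#' lrt_lambda(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "homogeneity")$lambda # 1/4
#' lrt_lambda(c(0, 2, 0), "hwe")$lambda                                     # 1/4
#' @export
lrt_lambda <- function(x, hypothesis = "homogeneity") {
  hyp <- resolve_hypothesis(hypothesis, x)
  obs <- as_observed(x, hyp)
  if (hyp$kind == "homogeneity" && any(obs$margins == 0)) {
    stop("the homogeneity LRT statistic is undefined for a zero row margin")
  }
  if (hyp$kind != "homogeneity" && obs$n == 0) {
    stop("the LRT statistic is undefined for an empty table")
  }
  ll <- log_lambda_space(obs$cells, hyp, margins = obs$margins, n = obs$n)
  out <- list(lambda = exp(ll), log_lambda = ll, statistic = -2 * ll,
              hypothesis = hyp)
  if (hyp$kind == "hwe") {
    out$theta_hat <- (2 * obs$cells[1L, 1L] + obs$cells[2L, 1L]) / (2 * obs$n)
  }
  out
}
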