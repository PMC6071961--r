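# Integrated-likelihood weights and the exact LRT p-value.
#
# The null distribution over the enumerated sample space is built by
# eliminating the nuisance parameter from the null likelihood by
# integration with respect to the uniform measure on the appropriate
# simplex (a flat, data-free weighting).  The resulting weight h(x) is
# finite for every table and, once normalised over the sample space, gives
# the probability of each table under the null.  All weights are computed
# through log-gamma identities so that sample sizes in the hundreds do not
# overflow.
#
# Closed forms (log scale), with lf = lgamma(. + 1):
#   homogeneity : sum_i lf(n_i.) + sum_j lf(n_.j) - sum lf(x_ij) - lf(n + c - 1)
#   independence: lf(n) + sum_i lf(n_i.) + sum_j lf(n_.j) - sum lf(x_ij)
#                 - lf(n + l - 1) - lf(n + c - 1)
#   hwe         : lf(n) + x2 log 2 + lf(2 x1 + x2) + lf(2 x3 + x2)
#                 - sum lf(x_i) - lf(2 n + 1)
#
# For 2 x 2 homogeneity the weights sum to exactly 1 over the sample
# space; in general the sum is a positive constant that cancels in the
# normalisation, so any fixed rescaling of h leaves every p-value
# unchanged.

lfact <- function(x) lgamma(x + 1)

log_h_space <- function(X, hyp, margins = NULL, n = NULL) {
  switch(hyp$kind,
    homogeneity = {
      l <- length(margins); c <- hyp$ncol
      NJ <- rowsum(X, rep(seq_len(c), l))
      sum(lfact(margins)) + colSums(lfact(NJ)) - colSums(lfact(X)) -
        lfact(sum(margins) + c - 1)
    },
    independence = {
      l <- hyp$nrow; c <- hyp$ncol
      NI <- rowsum(X, rep(seq_len(l), each = c))
      NJ <- rowsum(X, rep(seq_len(c), l))
      lfact(n) + colSums(lfact(NI)) + colSums(lfact(NJ)) - colSums(lfact(X)) -
        lfact(n + l - 1) - lfact(n + c - 1)
    },
    hwe = {
      p <- 2 * X[1L, ] + X[2L, ]
      q <- 2 * X[3L, ] + X[2L, ]
      lfact(n) + X[2L, ] * log(2) + lfact(p) + lfact(q) -
        colSums(lfact(X)) - lfact(2 * n + 1)
    })
}

#' Integrated-likelihood weight of a table under the null
#'
#' The unnormalised weight `h(x)` obtained by integrating the null
#' likelihood over its nuisance parameter(s) with respect to the uniform
#' measure on the corresponding simplex.  Normalising these weights over
#' the full sample space yields the null probability of each table, the
#' basis of the exact LRT p-value.
#'
#' @inheritParams lrt_lambda
#' @return a list with `h`, `log_h` and the hypothesis spec.
#' @examples
#' h_weight(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "homogeneity")$h # 1/6
#' @export
h_weight <- function(x, hypothesis = "homogeneity") {
  hyp <- resolve_hypothesis(hypothesis, x)
  obs <- as_observed(x, hyp)
  lh <- log_h_space(obs$cells, hyp, margins = obs$margins, n = obs$n)
  list(h = exp(lh), log_h = lh, hypothesis = hyp)
}

#' Sum of the integrated-likelihood weights over a sample space
#'
#' Accumulated by streaming log-sum-exp, so arbitrary margins are handled
#' without materialising the space.  For 2 x 2 homogeneity the sum is
#' exactly 1; for an l x c homogeneity space it is `1 / (c - 1)!`; for the
#' independence and Hardy-Weinberg spaces under this construction it is
#' `1 / ((l - 1)! (c - 1)!)` and 1.
#'
#' @inheritParams table_space
#' @return the sum as a plain number.
#' @examples
#' sum_h("homogeneity", margins = c(10, 10), ncol = 2) # 1
#' @export
sum_h <- function(hypothesis, margins = NULL, n = NULL,
                  nrow = NULL, ncol = NULL, max_chunk = 2e5) {
  hyp <- space_hyp(hypothesis, margins, nrow, ncol)
  parts <- space_apply(hyp, margins = margins, n = n, f = function(cells, off) {
    logsumexp(log_h_space(cells, hyp, margins = margins, n = n))
  }, max_chunk = max_chunk)
  exp(logsumexp(unlist(parts)))
}

# resolve a hypothesis spec from space-style size arguments
space_hyp <- function(hypothesis, margins, nrow, ncol) {
  if (inherits(hypothesis, "hypothesis_spec")) return(hypothesis)
  kind <- match.arg(hypothesis, c("homogeneity", "independence", "hwe"))
  switch(kind,
    homogeneity = hypothesis_spec("homogeneity", length(margins), ncol %||% 2L),
    independence = hypothesis_spec("independence", nrow, ncol),
    hwe = hypothesis_spec("hwe"))
}

#' Null distribution of tables over an enumerated sample space
#'
#' Materialises the sample space, attaches the log integrated-likelihood
#' weight and the log likelihood-ratio statistic of every table, and
#' normalises the weights by stable log-sum-exp so that the probabilities
#' sum to one.
#'
#' @inheritParams table_space
#' @return object of class `"null_distribution"`: the [table_space()]
#'   fields plus `log_h`, `log_h_total`, `log_prob`, `log_lambda`.
#' @export
null_distribution <- function(hypothesis, margins = NULL, n = NULL,
                              nrow = NULL, ncol = NULL, max_tables = 2e6) {
  sp <- table_space(hypothesis, margins = margins, n = n,
                    nrow = nrow, ncol = ncol, max_tables = max_tables)
  hyp <- sp$hypothesis
  log_h <- log_h_space(sp$cells, hyp, margins = margins, n = n)
  log_h_total <- logsumexp(log_h)
  sp$log_h <- log_h
  sp$log_h_total <- log_h_total
  sp$log_prob <- log_h - log_h_total
  sp$log_lambda <- log_lambda_space(sp$cells, hyp, margins = margins, n = n)
  class(sp) <- c("null_distribution", "table_space")
  sp
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null distribution under", x$hypothesis$kind, "-", x$n_tables,
      "tables, sum(h) =", format(exp(x$log_h_total), digits = 12), "\n")
  invisible(x)
}

# absolute tie tolerance on the log-lambda scale: the region boundary of
# the exact p-value is the weak inequality lambda <= lambda_obs, and
# symmetry-tied tables may differ in the last ulp
LAMBDA_TIE_TOL <- 1e-9

#' Exact LRT p-value by sample-space enumeration
#'
#' The probability, under the integrated-likelihood null distribution over
#' the complete enumerated sample space, of a likelihood-ratio statistic
#' at most as large as the observed one:
#' `p = Pr(lambda(X) <= lambda(x_obs) | H)`.  The inequality is weak and
#' implemented with a small absolute tolerance on the log scale so that
#' symmetric tables with mathematically tied statistics fall inside the
#' region.  The computation streams over the space in two passes (one for
#' the normalising constant, one for the region mass), so large spaces
#' never have to be held in memory.
#'
#' @inheritParams lrt_lambda
#' @param max_chunk number of tables materialised per streaming chunk.
#' @return a list with `p`, `lambda_obs`, `log_lambda_obs`, `statistic`,
#'   `n_region` (tables in the rejection region), `n_tables`, and the
#'   hypothesis spec.
#' @examples
#' exact_lrt_pvalue(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "homogeneity")$p # 1/3
#' @export
exact_lrt_pvalue <- function(x, hypothesis = "homogeneity", max_chunk = 2e5) {
  hyp <- resolve_hypothesis(hypothesis, x)
  obs <- as_observed(x, hyp)
  if (hyp$kind == "homogeneity" && any(obs$margins == 0)) {
    stop("exact LRT p-value undefined: zero row margin")
  }
  if (hyp$kind != "homogeneity" && obs$n == 0) {
    stop("exact LRT p-value undefined for an empty table")
  }
  ll_obs <- log_lambda_space(obs$cells, hyp, margins = obs$margins, n = obs$n)
  total <- -Inf; region <- -Inf; n_region <- 0L
  space_apply(hyp, margins = obs$margins, n = obs$n, f = function(cells, off) {
    lh <- log_h_space(cells, hyp, margins = obs$margins, n = obs$n)
    ll <- log_lambda_space(cells, hyp, margins = obs$margins, n = obs$n)
    in_r <- ll <= ll_obs + LAMBDA_TIE_TOL
    total <<- logsumexp(c(total, logsumexp(lh)))
    region <<- logsumexp(c(region, logsumexp(lh[in_r])))
    n_region <<- n_region + sum(in_r)
    NULL
  }, max_chunk = max_chunk)
  list(p = min(exp(region - total), 1),
       lambda_obs = exp(ll_obs), log_lambda_obs = ll_obs,
       statistic = -2 * ll_obs, n_region = n_region,
       n_tables = n_tables(hyp, margins = obs$margins, n = obs$n),
       hypothesis = hyp)
}

# Exact p-value for every table of a materialised null distribution,
# sharing one sort of the log-lambda values.  Uses the same weak-inequality
# tie rule as exact_lrt_pvalue().
exact_pvalues_all <- function(nd) {
  o <- order(nd$log_lambda)
  ll_sorted <- nd$log_lambda[o]
  cp <- cumsum(exp(nd$log_prob[o]))
  idx <- findInterval(nd$log_lambda + LAMBDA_TIE_TOL, ll_sorted)
  pmin(cp[idx], 1)
}
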