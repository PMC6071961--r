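# Asymptotic LRT, Pearson chi-square, and Fisher's conditional exact test.

#' Asymptotic likelihood-ratio p-value
#'
#' Upper-tail probability of the chi-square distribution with
#' `df = dim(Theta) - dim(Theta_H)` degrees of freedom at the observed
#' `-2 log lambda`: df 1 for 2 x 2 homogeneity and for Hardy-Weinberg,
#' `(l - 1)(c - 1)` for the table hypotheses in general.
#'
#' @inheritParams lrt_lambda
#' @return p-value in `[0, 1]`.
#' @examples
#' lrt_pvalue(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "homogeneity")
#' @export
lrt_pvalue <- function(x, hypothesis = "homogeneity") {
  lam <- lrt_lambda(x, hypothesis)
  stats::pchisq(lam$statistic, df = lam$hypothesis$df_freq, lower.tail = FALSE)
}

# vectorised over a space: upper chi-square tail at -2 * log_lambda
lrt_pvalue_from_log_lambda <- function(log_lambda, df) {
  stats::pchisq(-2 * log_lambda, df = df, lower.tail = FALSE)
}

#' Pearson chi-square test
#'
#' The plain Pearson statistic `X^2 = sum (O - E)^2 / E` without continuity
#' correction, referred to the chi-square distribution with the same
#' degrees of freedom as the asymptotic LRT.  Expected counts are
#' `n_i. n_.j / n_..` for the table hypotheses and the plug-in
#' Hardy-Weinberg proportions `n (theta_hat^2, 2 theta_hat (1 - theta_hat),
#' (1 - theta_hat)^2)` for genotype counts.  Cells with `E = 0` (possible
#' only when the observed count is also 0) contribute nothing.
#'
#' @inheritParams lrt_lambda
#' @return a list with `statistic`, `p` and `df`.
#' @examples
#' pearson_pvalue(matrix(c(10, 0, 0, 10), 2, byrow = TRUE), "homogeneity")
#' @export
pearson_pvalue <- function(x, hypothesis = "homogeneity") {
  hyp <- resolve_hypothesis(hypothesis, x)
  obs <- as_observed(x, hyp)
  if (obs$n == 0) stop("chi-square test undefined for an empty table")
  stat <- chisq_stat_space(obs$cells, hyp, margins = obs$margins, n = obs$n)
  list(statistic = stat,
       p = stats::pchisq(stat, df = hyp$df_freq, lower.tail = FALSE),
       df = hyp$df_freq)
}

# vectorised Pearson statistic over the columns of a cells matrix
chisq_stat_space <- function(X, hyp, margins = NULL, n = NULL) {
  if (hyp$kind == "hwe") {
    th <- (2 * X[1L, ] + X[2L, ]) / (2 * n)
    E <- rbind(n * th^2, 2 * n * th * (1 - th), n * (1 - th)^2)
  } else {
    l <- if (hyp$kind == "homogeneity") length(margins) else hyp$nrow
    c <- hyp$ncol
    ntot <- if (hyp$kind == "homogeneity") sum(margins) else n
    NI <- if (hyp$kind == "homogeneity") {
      matrix(margins, l, ncol(X))
    } else {
      rowsum(X, rep(seq_len(l), each = c))
    }
    NJ <- rowsum(X, rep(seq_len(c), l))
    E <- NI[rep(seq_len(l), each = c), , drop = FALSE] *
      NJ[rep(seq_len(c), l), , drop = FALSE] / ntot
  }
  D <- (X - E)^2 / E
  D[E == 0] <- 0   # E = 0 forces O = 0 in these models
  colSums(D)
}

#' Fisher's conditional exact test for 2 x 2 tables
#'
#' Conditions on both margins, under which the first cell follows a
#' hypergeometric distribution, and sums the point probabilities of all
#' admissible tables whose probability does not exceed that of the
#' observed table (the two-sided minimum-likelihood rule, as implemented
#' in [stats::fisher.test()]).
#'
#' @param x a 2 x 2 matrix or [contingency_table()] with positive total.
#' @return the two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_pvalue(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisher_pvalue <- function(x) {
  ct <- contingency_table(if (inherits(x, "contingency_table")) x$counts else x)
  if (nrow(ct$counts) != 2L || ncol(ct$counts) != 2L) {
    stop("Fisher's exact test is computed for 2 x 2 tables only")
  }
  if (ct$total == 0L) stop("Fisher's exact test undefined for an empty table")
  stats::fisher.test(ct$counts)$p.value
}
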