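#' Significance indices for an observed contingency table
#'
#' One call computing every index applicable to the observed table under
#' the chosen null hypothesis: the exact LRT p-value (integrated-likelihood
#' null over the enumerated sample space), the asymptotic LRT and Pearson
#' chi-square p-values, Fisher's conditional exact test (2 x 2 homogeneity),
#' Barnard's unconditional exact test (2 x 2 homogeneity and
#' Hardy-Weinberg), and the FBST e-value in both its Monte Carlo and
#' asymptotic forms.  The Monte Carlo e-value is computed only when a seed
#' is supplied, so that the default result is fully deterministic.
#'
#' @inheritParams lrt_lambda
#' @param k Monte Carlo sample size for the e-value.
#' @param seed seed for the Monte Carlo e-value; `NULL` skips it.
#' @param max_tables largest sample space that will be enumerated.
#' @return an object of class `"ct_test"`; see Details for the fields.
#'
#' @details The returned list carries the observed object (`observed`),
#' the hypothesis spec, `lambda`/`log_lambda`/`statistic`, the sample-space
#' size `n_tables`, and the indices `p_exact`, `p_lrt`, `p_chisq`
#' (with `chisq_stat`), `p_fisher`, `p_barnard`, `evalue`
#' (with `evalue_se`), `evalue_asym`; indices not defined for the
#' hypothesis are `NA`.  `print()` and `summary()` format the indices;
#' `simulate()` draws tables from the exact null distribution.
#'
#' @examples
#' tt <- ct_test(matrix(c(3, 7, 8, 2), 2, byrow = TRUE), "homogeneity",
#'               seed = 1)
#' tt
#' @export
ct_test <- function(x, hypothesis = "homogeneity", k = 1e5, seed = NULL,
                    max_tables = 2e6) {
  hyp <- resolve_hypothesis(hypothesis, x)
  obs <- as_observed(x, hyp)
  if (hyp$kind == "homogeneity" && any(obs$margins == 0)) {
    stop("significance indices undefined: zero row margin")
  }
  if (obs$n == 0) stop("significance indices undefined for an empty table")
  lam <- lrt_lambda(x, hyp)
  twobytwo_homog <- hyp$kind == "homogeneity" &&
    hyp$nrow == 2L && hyp$ncol == 2L
  ex <- exact_lrt_pvalue(x, hyp, max_chunk = max_tables)
  chi <- pearson_pvalue(x, hyp)
  out <- list(
    observed = obs$obj, hypothesis = hyp,
    lambda = lam$lambda, log_lambda = lam$log_lambda,
    statistic = lam$statistic, theta_hat = lam$theta_hat,
    n_tables = ex$n_tables,
    p_exact = ex$p, n_region = ex$n_region,
    p_lrt = stats::pchisq(lam$statistic, hyp$df_freq, lower.tail = FALSE),
    chisq_stat = chi$statistic, p_chisq = chi$p,
    p_fisher = if (twobytwo_homog) fisher_pvalue(x) else NA_real_,
    p_barnard = NA_real_, barnard_theta = NA_real_,
    evalue = NA_real_, evalue_se = NA_real_,
    evalue_asym = fbst_evalue_asymptotic(x, hyp),
    k = k, seed = seed
  )
  if (twobytwo_homog || hyp$kind == "hwe") {
    bn <- barnard_pvalue(x, hyp)
    out$p_barnard <- bn$p
    out$barnard_theta <- bn$theta_at_max
  }
  if (!is.null(seed)) {
    ev <- fbst_evalue(x, hyp, k = k, seed = seed)
    out$evalue <- ev$evalue
    out$evalue_se <- ev$mc_standard_error
  }
  structure(out, class = "ct_test")
}

#' @export
print.ct_test <- function(x, digits = 4, ...) {
  hyp <- x$hypothesis
  cat("Significance indices -", hyp$kind, "hypothesis\n")
  if (hyp$kind == "hwe") {
    cat("genotype counts (AA, Aa, aa):",
        paste(x$observed$x, collapse = ", "), " n =", x$observed$n, "\n")
  } else {
    print(x$observed$counts)
  }
  cat(sprintf("lambda = %.*g, -2 log lambda = %.*g (df %d / %d), %s tables\n",
              digits, x$lambda, digits, x$statistic,
              hyp$df_freq, hyp$df_bayes, format(x$n_tables, big.mark = ",")))
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = digits,
                                                   format = "g"))
  cat("  exact LRT p-value      :", fmt(x$p_exact), "\n")
  cat("  asymptotic LRT p-value :", fmt(x$p_lrt), "\n")
  cat("  chi-square p-value     :", fmt(x$p_chisq), "\n")
  if (!is.na(x$p_fisher)) cat("  Fisher exact p-value   :", fmt(x$p_fisher), "\n")
  if (!is.na(x$p_barnard)) cat("  Barnard exact p-value  :", fmt(x$p_barnard), "\n")
  cat("  asymptotic e-value     :", fmt(x$evalue_asym), "\n")
  if (!is.na(x$evalue)) {
    cat(sprintf("  e-value (MC, k = %s) : %s  (s.e. %.2g)\n",
                format(as.integer(x$k), big.mark = ","), fmt(x$evalue),
                x$evalue_se))
  }
  invisible(x)
}

#' @export
summary.ct_test <- function(object, ...) {
  structure(list(test = object), class = "summary.ct_test")
}

#' @export
print.summary.ct_test <- function(x, ...) {
  t <- x$test
  print(t)
  cat(sprintf("rejection region: %d of %s tables with lambda <= %.6g\n",
              t$n_region, format(t$n_tables, big.mark = ","), t$lambda))
  if (!is.na(t$p_barnard)) {
    cat(sprintf("Barnard maximising theta: %.6g\n", t$barnard_theta))
  }
  if (t$hypothesis$kind == "hwe") {
    cat(sprintf("allele-frequency MLE under the null: %.6g\n", t$theta_hat))
  }
  invisible(x)
}

#' Simulate tables from the exact null distribution of a test
#'
#' Draws tables from the normalised integrated-likelihood null
#' distribution over the sample space of the fitted test (the same
#' distribution whose tail defines the exact LRT p-value).
#'
#' @param object a [ct_test()] result.
#' @param nsim number of tables to draw.
#' @param seed RNG seed.
#' @param ... unused.
#' @return for table hypotheses, a list of count matrices; for
#'   Hardy-Weinberg, a 3-row matrix of genotype triples.
#' @export
simulate.ct_test <- function(object, nsim = 1, seed = NULL, ...) {
  hyp <- object$hypothesis
  obs <- as_observed(object$observed, hyp)
  nd <- null_distribution(hyp, margins = obs$margins, n = obs$n)
  idx <- with_seed(seed, {
    sample.int(nd$n_tables, nsim, replace = TRUE, prob = exp(nd$log_prob))
  })
  if (hyp$kind == "hwe") return(nd$cells[, idx, drop = FALSE])
  lapply(idx, function(i) {
    matrix(nd$cells[, i], hyp$nrow, hyp$ncol, byrow = TRUE)
  })
}
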