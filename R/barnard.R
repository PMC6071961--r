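# Barnard's unconditional exact test.
#
# The critical region is the same lambda-defined region as the exact LRT
# p-value, R = {tables with lambda <= lambda_obs}; the null probability of
# R depends on the nuisance parameter theta (the common success probability
# under homogeneity, the allele frequency under Hardy-Weinberg), which is
# eliminated by maximisation: p = sup over theta in [0, 1] of Pr(R | theta).
# The profile Pr(R | theta) is a polynomial in theta, so a dense
# deterministic grid followed by local Brent refinement locates the maximum
# reliably.  The test is defined here for 2 x 2 homogeneity (product
# binomial null) and Hardy-Weinberg (trinomial null).

#' Barnard's unconditional exact p-value
#'
#' @inheritParams lrt_lambda
#' @param grid_n number of equally spaced grid points on `[0, 1]` used to
#'   bracket the maximising nuisance-parameter value (endpoints included;
#'   probabilities at theta in `{0, 1}` are the `0^0 = 1` limits).
#' @param refine refine the bracketed maximum with [stats::optimize()]
#'   (Brent) to tolerance `1e-10`.
#' @return a list with `p`, `theta_at_max`, `region_size`, and the
#'   hypothesis spec.
#' @examples
#' barnard_pvalue(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "homogeneity")$p # 1/2
#' barnard_pvalue(c(0, 2, 0), "hwe")$p                                     # 3/8
#' @export
barnard_pvalue <- function(x, hypothesis = "homogeneity",
                           grid_n = 1001L, refine = TRUE) {
  hyp <- resolve_hypothesis(hypothesis, x)
  if (!(hyp$kind == "hwe" ||
        (hyp$kind == "homogeneity" && hyp$nrow == 2L && hyp$ncol == 2L))) {
    stop("Barnard's exact test is computed for 2 x 2 homogeneity and ",
         "Hardy-Weinberg hypotheses only")
  }
  obs <- as_observed(x, hyp)
  if (hyp$kind == "homogeneity" && any(obs$margins == 0)) {
    stop("Barnard's exact test undefined: zero row margin")
  }
  if (hyp$kind == "hwe" && obs$n == 0) {
    stop("Barnard's exact test undefined for an empty sample")
  }
  sp <- table_space(hyp, margins = obs$margins, n = obs$n)
  ll <- log_lambda_space(sp$cells, hyp, margins = obs$margins, n = obs$n)
  ll_obs <- log_lambda_space(obs$cells, hyp, margins = obs$margins, n = obs$n)
  in_r <- ll <= ll_obs + LAMBDA_TIE_TOL
  R <- sp$cells[, in_r, drop = FALSE]
  prof <- region_profile(R, hyp, margins = obs$margins, n = obs$n)
  th <- seq(0, 1, length.out = grid_n)
  vals <- prof(th)
  i <- which.max(vals)
  p <- vals[i]; th_max <- th[i]
  if (refine) {
    lo <- th[max(i - 1L, 1L)]; hi <- th[min(i + 1L, grid_n)]
    if (hi > lo) {
      opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
      if (opt$objective > p) {
        p <- opt$objective; th_max <- opt$maximum
      }
    }
  }
  list(p = min(p, 1), theta_at_max = th_max, region_size = ncol(R),
       hypothesis = hyp)
}

# Return a function of theta (vectorised) giving the null probability of a
# region of tables.  Per-table terms are assembled in log space and summed
# in linear space (regions are small relative to overflow limits).
region_profile <- function(R, hyp, margins = NULL, n = NULL) {
  if (hyp$kind == "homogeneity") {
    n1 <- margins[1L]; n2 <- margins[2L]
    x1 <- R[1L, ]; x2 <- R[3L, ]             # first-column counts per row
    s <- x1 + x2                             # pooled successes
    f <- sum(margins) - s
    lc <- lchoose(n1, x1) + lchoose(n2, x2)
  } else {
    s <- 2 * R[1L, ] + R[2L, ]               # allele-A count
    f <- 2 * R[3L, ] + R[2L, ]
    lc <- lfact(n) - colSums(lfact(R)) + R[2L, ] * log(2)
  }
  C <- exp(lc)
  function(theta) {
    vapply(theta, function(t) {
      sum(C * pow0(t, s) * pow0(1 - t, f))
    }, 0.0)
  }
}

# Barnard p-value for every table of a materialised null distribution.
# One pass per grid theta using the shared lambda ordering: the region of
# any observed table is a prefix of the probability vector sorted by
# lambda, so Pr(R | theta) for all tables at once is a cumulative sum.
# Refinement (optional) re-maximises each table's polynomial profile.
barnard_all <- function(nd, grid_n = 1001L, refine = ncol(nd$cells) <= 2000L) {
  hyp <- nd$hypothesis
  o <- order(nd$log_lambda)
  ll_sorted <- nd$log_lambda[o]
  Xs <- nd$cells[, o, drop = FALSE]
  prof_all <- region_profile(Xs, hyp, margins = nd$margins, n = nd$n)
  # per-table prefix end: last sorted index inside its tie-tolerant region
  idx <- findInterval(nd$log_lambda + LAMBDA_TIE_TOL, ll_sorted)
  th <- seq(0, 1, length.out = grid_n)
  best <- rep(-Inf, nd$n_tables); best_th <- numeric(nd$n_tables)
  env <- environment(prof_all)
  C <- env$C; s <- env$s; f <- env$f
  for (t in th) {
    cp <- cumsum(C * pow0(t, s) * pow0(1 - t, f))[idx]
    upd <- cp > best
    best[upd] <- cp[upd]; best_th[upd] <- t
  }
  if (refine) {
    step <- 1 / (grid_n - 1)
    for (i in seq_len(nd$n_tables)) {
      pref <- seq_len(idx[i])
      prof <- function(t) sum(C[pref] * pow0(t, s[pref]) * pow0(1 - t, f[pref]))
      lo <- max(best_th[i] - step, 0); hi <- min(best_th[i] + step, 1)
      if (hi > lo) {
        opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
        if (opt$objective > best[i]) best[i] <- opt$objective
      }
    }
  }
  pmin(best, 1)
}
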