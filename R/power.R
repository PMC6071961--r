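# Power surfaces for the frequentist indices.
#
# For a fixed sample space every index is computed once per table (the
# scan cache); a power evaluation at a parameter point then only needs the
# sampling distribution of tables at that point.  Exact power sums the
# sampling probabilities of the tables whose index falls at or below
# alpha; Monte Carlo power draws `reps` tables per point and reports the
# rejection proportion, with one deterministic sub-seed per grid point so
# any execution order reproduces the surface.

power_index_choices <- c("exact", "lrt", "chisq", "fisher", "barnard")

#' Exact or Monte Carlo power surface
#'
#' Supported designs are 2 x 2 homogeneity (tables sampled as two
#' independent binomials with success probabilities `theta1`, `theta2`)
#' and Hardy-Weinberg (genotype triples sampled from the trinomial with
#' probabilities `(theta1, theta2, 1 - theta1 - theta2)`).  The decision
#' rule is `index <= alpha`.
#'
#' The parameter grid is either `grid` equally spaced midpoints per axis
#' (`(2i - 1) / (2 grid)`, interior so no degenerate binomial arises) over
#' the unit square -- restricted to the open simplex for Hardy-Weinberg --
#' or an explicit matrix of `points` (columns `theta1`, `theta2`).
#'
#' @param hypothesis `"homogeneity"` (2 x 2) or `"hwe"`.
#' @param margins row margins (homogeneity).
#' @param n sample size (hwe).
#' @param indices which frequentist indices to evaluate (default all
#'   applicable).
#' @param grid points per axis.
#' @param points optional explicit parameter points, a 2-column matrix.
#' @param alpha significance level in (0, 1).
#' @param method `"mc"` for Monte Carlo, `"exact"` for enumeration-exact
#'   power.
#' @param reps Monte Carlo tables per grid point.
#' @param seed master seed (required for `method = "mc"`).
#' @param cache optional precomputed [index_scan()] result to reuse.
#' @return a data.frame with `theta1`, `theta2`, one power column per
#'   index (named as in the scan cache), and attributes `alpha`, `reps`,
#'   `method`.
#' @examples
#' power_surface("homogeneity", margins = c(10, 10), indices = "lrt",
#'               grid = 3, method = "exact")
#' @export
power_surface <- function(hypothesis = c("homogeneity", "hwe"),
                          margins = NULL, n = NULL, indices = NULL,
                          grid = 100L, points = NULL, alpha = 0.05,
                          method = c("mc", "exact"), reps = 1000L,
                          seed = NULL, cache = NULL) {
  kind <- match.arg(hypothesis)
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1")
  }
  if (method == "mc") {
    if (reps < 1) stop("reps must be at least 1")
    if (is.null(seed)) stop("Monte Carlo power needs an explicit seed")
  }
  if (kind == "homogeneity") {
    if (is.null(margins) || length(margins) != 2L) {
      stop("2 x 2 homogeneity power needs two row margins")
    }
    hyp <- hypothesis_spec("homogeneity", 2L, 2L)
  } else {
    if (is.null(n)) stop("Hardy-Weinberg power needs the sample size n")
    hyp <- hypothesis_spec("hwe")
  }
  indices <- if (is.null(indices)) {
    intersect(default_scan_indices(hyp), power_index_choices)
  } else {
    match.arg(indices, power_index_choices, several.ok = TRUE)
  }
  if (is.null(cache)) {
    cache <- index_scan(hyp, margins = margins, n = n, indices = indices)
  }
  cols <- vapply(indices, scan_col, "")
  missing_cols <- setdiff(cols, names(cache))
  if (length(missing_cols)) stop("cache lacks columns: ",
                                 paste(missing_cols, collapse = ", "))
  if (is.null(points)) {
    axis <- (2 * seq_len(grid) - 1) / (2 * grid)
    points <- as.matrix(expand.grid(theta1 = axis, theta2 = axis))
    if (kind == "hwe") points <- points[rowSums(points) < 1, , drop = FALSE]
  } else {
    points <- as.matrix(points)
    if (ncol(points) != 2L) stop("points must have two columns")
    ok <- points[, 1L] > 0 & points[, 2L] > 0 &
      (if (kind == "hwe") rowSums(points) < 1 else
         points[, 1L] < 1 & points[, 2L] < 1)
    if (!all(ok)) stop("parameter points must lie in the open domain")
  }
  np <- nrow(points)
  reject <- lapply(cols, function(cl) cache[[cl]] <= alpha)
  names(reject) <- cols
  out <- data.frame(theta1 = points[, 1L], theta2 = points[, 2L])
  if (method == "exact") {
    for (cl in cols) {
      out[[cl]] <- exact_power_points(points, reject[[cl]], kind, margins, n)
    }
  } else {
    seeds <- sub_seeds(seed, np)
    pw <- matrix(NA_real_, np, length(cols), dimnames = list(NULL, cols))
    for (ip in seq_len(np)) {
      idx <- with_seed(seeds[ip], {
        if (kind == "homogeneity") {
          x1 <- stats::rbinom(reps, margins[1L], points[ip, 1L])
          x2 <- stats::rbinom(reps, margins[2L], points[ip, 2L])
          x1 * (margins[2L] + 1L) + x2 + 1L
        } else {
          g <- stats::rmultinom(reps, n, c(points[ip, ], 1 - sum(points[ip, ])))
          hwe_table_index(g[1L, ], g[2L, ], n)
        }
      })
      for (cl in cols) pw[ip, cl] <- mean(reject[[cl]][idx])
    }
    for (cl in cols) out[[cl]] <- pw[, cl]
  }
  attr(out, "alpha") <- alpha
  attr(out, "method") <- method
  attr(out, "reps") <- if (method == "mc") reps else NA_integer_
  attr(out, "hypothesis") <- hyp
  out
}

# lexicographic position of (x1, x2, n - x1 - x2) in the genotype space
hwe_table_index <- function(x1, x2, n) {
  x1 * (n + 1) - x1 * (x1 - 1) / 2 + x2 + 1
}

# enumeration-exact power at each parameter point for one reject vector
exact_power_points <- function(points, reject, kind, margins, n) {
  if (kind == "homogeneity") {
    n1 <- margins[1L]; n2 <- margins[2L]
    R <- matrix(reject, n1 + 1L, n2 + 1L, byrow = TRUE) # rows x11, cols x21
    th1 <- points[, 1L]; th2 <- points[, 2L]
    u1 <- unique(th1); u2 <- unique(th2)
    D1 <- vapply(u1, function(t) stats::dbinom(0:n1, n1, t), numeric(n1 + 1L))
    D2 <- vapply(u2, function(t) stats::dbinom(0:n2, n2, t), numeric(n2 + 1L))
    M <- t(D1) %*% R %*% D2  # power over the unique-theta grid
    M[cbind(match(th1, u1), match(th2, u2))]
  } else {
    X <- compositions(n, 3L)
    lmult <- lfact(n) - colSums(lfact(X))
    rej <- which(reject)
    vapply(seq_len(nrow(points)), function(ip) {
      lth <- log(c(points[ip, ], 1 - sum(points[ip, ])))
      lp <- lmult[rej] + colSums(X[, rej, drop = FALSE] * lth)
      sum(exp(lp))
    }, 0.0)
  }
}
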