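# Independent brute-force oracles: naive arithmetic (factorial / choose /
# direct products, no log-space tricks), fully materialised enumerations
# built with expand.grid rather than the package's composition generator.
# Deliberately slow and simple; used only on tiny spaces.

# direct product form of lambda with 0^0 = 1
pw <- function(b, e) ifelse(e == 0, 1, b^e)

# all 2x2 homogeneity tables with margins (n1, n2), as (x11, x21) pairs
oracle_homog_space <- function(n1, n2) {
  as.matrix(expand.grid(x11 = 0:n1, x21 = 0:n2))
}

oracle_homog_lambda <- function(x11, x21, n1, n2) {
  n <- n1 + n2; s <- x11 + x21; f <- n - s
  num <- pw(s / n, s) * pw(f / n, f)
  den <- pw(x11 / n1, x11) * pw((n1 - x11) / n1, n1 - x11) *
    pw(x21 / n2, x21) * pw((n2 - x21) / n2, n2 - x21)
  num / den
}

oracle_homog_h <- function(x11, x21, n1, n2) {
  choose(n1, x11) * choose(n2, x21) /
    (choose(n1 + n2, x11 + x21) * (n1 + n2 + 1))
}

oracle_homog_p <- function(x11, x21, n1, n2) {
  sp <- oracle_homog_space(n1, n2)
  lam <- oracle_homog_lambda(sp[, 1], sp[, 2], n1, n2)
  h <- oracle_homog_h(sp[, 1], sp[, 2], n1, n2)
  obs <- oracle_homog_lambda(x11, x21, n1, n2)
  sum(h[log(lam) <= log(obs) + 1e-9]) / sum(h)
}

# all l x c tables (flattened row-major) with grand total n
oracle_indep_space <- function(n, l, c) {
  g <- as.matrix(expand.grid(rep(list(0:n), l * c)))
  g[rowSums(g) == n, , drop = FALSE]
}

oracle_indep_lambda <- function(x, l, c) {
  m <- matrix(x, l, c, byrow = TRUE)
  n <- sum(m)
  num <- prod(pw(rowSums(m) / n, rowSums(m))) *
    prod(pw(colSums(m) / n, colSums(m)))
  num / prod(pw(m / n, m))
}

oracle_indep_h <- function(x, l, c) {
  m <- matrix(x, l, c, byrow = TRUE)
  n <- sum(m)
  factorial(n) * prod(factorial(rowSums(m))) * prod(factorial(colSums(m))) /
    (prod(factorial(m)) * factorial(n + l - 1) * factorial(n + c - 1))
}

oracle_indep_p <- function(x, l, c) {
  n <- sum(x)
  sp <- oracle_indep_space(n, l, c)
  lam <- apply(sp, 1, oracle_indep_lambda, l = l, c = c)
  h <- apply(sp, 1, oracle_indep_h, l = l, c = c)
  obs <- oracle_indep_lambda(x, l, c)
  sum(h[log(lam) <= log(obs) + 1e-9]) / sum(h)
}

oracle_hwe_space <- function(n) {
  g <- as.matrix(expand.grid(x1 = 0:n, x2 = 0:n))
  g <- g[rowSums(g) <= n, , drop = FALSE]
  cbind(g, x3 = n - rowSums(g))
}

oracle_hwe_lambda <- function(x) {
  n <- sum(x); th <- (2 * x[1] + x[2]) / (2 * n)
  num <- 2^x[2] * pw(th, 2 * x[1] + x[2]) * pw(1 - th, 2 * x[3] + x[2])
  num / prod(pw(x / n, x))
}

oracle_hwe_h <- function(x) {
  n <- sum(x)
  factorial(n) * 2^x[2] * factorial(2 * x[1] + x[2]) *
    factorial(2 * x[3] + x[2]) / (prod(factorial(x)) * factorial(2 * n + 1))
}

oracle_hwe_p <- function(x) {
  sp <- oracle_hwe_space(sum(x))
  lam <- apply(sp, 1, oracle_hwe_lambda)
  h <- apply(sp, 1, oracle_hwe_h)
  obs <- oracle_hwe_lambda(x)
  sum(h[log(lam) <= log(obs) + 1e-9]) / sum(h)
}

# Fisher two-sided minimum-likelihood rule by direct hypergeometric summation
oracle_fisher <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); s <- sum(m[, 1])
  ks <- max(0, s - r2):min(r1, s)
  pk <- dhyper(ks, r1, r2, s)
  pobs <- dhyper(m[1, 1], r1, r2, s)
  sum(pk[pk <= pobs * (1 + 1e-7)])
}

# Barnard oracle: region probability maximised on a dense theta grid
oracle_barnard_homog <- function(x11, x21, n1, n2, grid = 1e6) {
  sp <- oracle_homog_space(n1, n2)
  lam <- oracle_homog_lambda(sp[, 1], sp[, 2], n1, n2)
  obs <- oracle_homog_lambda(x11, x21, n1, n2)
  R <- sp[log(lam) <= log(obs) + 1e-9, , drop = FALSE]
  th <- seq(0, 1, length.out = grid)
  best <- 0
  for (i in seq_len(nrow(R))) {
    best <- best + dbinom(R[i, 1], n1, th) * dbinom(R[i, 2], n2, th)
  }
  max(best)
}

oracle_barnard_hwe <- function(x, grid = 1e6) {
  n <- sum(x)
  sp <- oracle_hwe_space(n)
  lam <- apply(sp, 1, oracle_hwe_lambda)
  obs <- oracle_hwe_lambda(x)
  R <- sp[log(lam) <= log(obs) + 1e-9, , drop = FALSE]
  th <- seq(0, 1, length.out = grid)
  pwv <- function(b, e) if (e == 0) rep(1, length(b)) else b^e
  best <- 0
  for (i in seq_len(nrow(R))) {
    cf <- factorial(n) / prod(factorial(R[i, ])) * 2^R[i, 2]
    best <- best + cf * pwv(th, 2 * R[i, 1] + R[i, 2]) *
      pwv(1 - th, 2 * R[i, 3] + R[i, 2])
  }
  max(best)
}

# dense-grid supremum of the log posterior density over the null set,
# parameterising the null manifold directly and evaluating the Dirichlet
# density on the whole grid at once
oracle_sup_posterior <- function(x, hypothesis, grid = 1e5) {
  t <- seq(1e-9, 1 - 1e-9, length.out = grid)
  if (hypothesis == "hwe") {
    const <- lgamma(sum(x) + 3) - sum(lgamma(x + 1))
    max(const + x[1] * log(t^2) + x[2] * log(2 * t * (1 - t)) +
          x[3] * log((1 - t)^2))
  } else if (hypothesis == "homogeneity") {
    # 2-column case: common success probability t across rows
    n_i <- rowSums(x)
    const <- sum(lgamma(n_i + 2)) - sum(lgamma(x + 1))
    max(const + sum(x[, 1]) * log(t) + sum(x[, 2]) * log(1 - t))
  } else {
    # 2 x 2 independence: theta_ij = a_i b_j; the log density separates
    # into a row-margin part in a and a column-margin part in b
    const <- lgamma(sum(x) + 4) - sum(lgamma(x + 1))
    ri <- rowSums(x); cj <- colSums(x)
    const + max(ri[1] * log(t) + ri[2] * log(1 - t)) +
      max(cj[1] * log(t) + cj[2] * log(1 - t))
  }
}
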