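test_that("posterior densities evaluate the product-Dirichlet form", {
  m <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  # Beta(2,1) x Beta(1,2) densities: 2u * 2(1-v) = 1 at (0.5, 0.5)
  th <- matrix(0.5, 2, 2)
  expect_equal(exp(posterior_density(th, m, "homogeneity")), 1)
  expect_equal(exp(posterior_density(matrix(c(.9, .1, .2, .8), 2,
                                            byrow = TRUE), m, "homogeneity")),
               2 * 0.9 * 2 * 0.8, tolerance = 1e-12)
  # no data: posterior is the prior, density 1 everywhere
  expect_equal(exp(posterior_density(matrix(c(.3, .7, .6, .4), 2, byrow = TRUE),
                                     matrix(0, 2, 2), "homogeneity")), 1)
  # HWE (1,2,1): Dirichlet(2,3,2) density at (1/4, 1/2, 1/4)
  want <- exp(lgamma(7) - lgamma(2) - lgamma(3) - lgamma(2)) *
    (1/4) * (1/2)^2 * (1/4)
  expect_equal(exp(posterior_density(c(1/4, 1/2, 1/4), c(1, 2, 1), "hwe")),
               want, tolerance = 1e-12)
  expect_error(posterior_density(c(0.5, 0.6, -0.1), c(1, 2, 1), "hwe"),
               "simplex")
})

test_that("the null supremum matches its closed form and a dense grid", {
  m <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(exp(posterior_sup_null(m, "homogeneity")), 1, tolerance = 1e-12)
  expect_equal(exp(posterior_sup_null(c(1, 2, 1), "hwe")), 5.625,
               tolerance = 1e-12)
  # when the posterior mode lies in the null set, the sup is the global mode
  bal <- matrix(c(5, 5, 5, 5), 2)
  global_mode <- posterior_density(matrix(0.5, 2, 2), bal, "homogeneity")
  expect_equal(posterior_sup_null(bal, "homogeneity"), global_mode,
               tolerance = 1e-12)
  # dense-grid oracle: closed form dominates and is attained
  set.seed(3)
  for (i in 1:8) {
    x11 <- sample(0:6, 1); x21 <- sample(0:6, 1)
    m <- matrix(c(x11, 6 - x11, x21, 6 - x21), 2, byrow = TRUE)
    grid_max <- oracle_sup_posterior(m, "homogeneity")
    expect_gte(posterior_sup_null(m, "homogeneity") + 1e-9, grid_max)
    expect_equal(posterior_sup_null(m, "homogeneity"), grid_max,
                 tolerance = 1e-6)
    g <- as.vector(rmultinom(1, 10, c(.3, .4, .3)))
    expect_equal(posterior_sup_null(g, "hwe"),
                 oracle_sup_posterior(g, "hwe"), tolerance = 1e-6)
  }
  m22 <- matrix(c(3, 1, 0, 4), 2, byrow = TRUE)
  expect_equal(posterior_sup_null(m22, "independence"),
               oracle_sup_posterior(m22, "independence"), tolerance = 1e-4)
})

test_that("the null supremum never exceeds the global posterior maximum", {
  # global mode of Dirichlet(x+1) posteriors is at the empirical proportions
  nd <- null_distribution("homogeneity", margins = c(6, 6))
  for (i in seq_len(nd$n_tables)) {
    x <- matrix(nd$cells[, i], 2, 2, byrow = TRUE)
    mode_th <- pmax(x / rowSums(x), 1e-12)
    mode_th <- mode_th / rowSums(mode_th)
    expect_lte(posterior_sup_null(x, "homogeneity"),
               posterior_density(mode_th, x, "homogeneity") + 1e-9)
  }
})

test_that("Monte Carlo e-values are reproducible and hit the analytic value", {
  m <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  e1 <- fbst_evalue(m, "homogeneity", k = 1e5, seed = 99)
  e2 <- fbst_evalue(m, "homogeneity", k = 1e5, seed = 99)
  expect_identical(e1$evalue, e2$evalue)
  expect_lte(e1$mc_standard_error, 0.5 / sqrt(1e5))
  # analytic tangent-set probability: evalue = 1/16 + log(4)/8
  analytic <- 1 / 16 + log(4) / 8
  for (sd in c(5, 17)) {
    e <- fbst_evalue(m, "homogeneity", k = 1e5, seed = sd)
    expect_lt(abs(e$evalue - analytic), 3 * e$mc_standard_error + 1e-3)
  }
  # balanced table: tangent set has posterior probability zero
  eb <- fbst_evalue(matrix(c(5, 5, 5, 5), 2), "homogeneity", k = 1e4, seed = 1)
  expect_gt(eb$evalue, 0.999)
  ek <- fbst_evalue(m, "homogeneity", k = 1, seed = 2)
  expect_true(ek$evalue %in% c(0, 1))
  expect_error(fbst_evalue(m, "homogeneity", k = 0, seed = 1), ">= 1")
})

test_that("asymptotic e-values use the full-dimension chi-square tail", {
  m <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  expect_equal(fbst_evalue_asymptotic(m, "homogeneity"), 0.25,
               tolerance = 1e-12)
  expect_equal(fbst_evalue_asymptotic(matrix(c(5, 5, 5, 5), 2),
                                      "homogeneity"), 1)
  # dominance over the asymptotic p-value across a whole space
  s <- index_scan("homogeneity", margins = c(8, 8),
                  indices = c("lrt", "evalue_asym"))
  expect_true(all(s$evalue_asym >= s$p_lrt - 1e-12))
  sh <- index_scan("hwe", n = 12, indices = c("lrt", "evalue_asym"))
  expect_true(all(sh$evalue_asym >= sh$p_lrt - 1e-12))
})
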