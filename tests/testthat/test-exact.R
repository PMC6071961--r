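test_that("integrated-likelihood weights match closed-form micro-examples", {
  m10 <- matrix(c(1, 0, 0, 1), 2, byrow = TRUE)
  m11 <- matrix(c(1, 0, 1, 0), 2, byrow = TRUE)
  expect_equal(h_weight(m10, "homogeneity")$h, 1 / 6)
  expect_equal(h_weight(m11, "homogeneity")$h, 1 / 3)
  expect_equal(h_weight(c(1, 0, 0), "hwe")$h, 1 / 3)
  # naive-arithmetic cross-checks on random tables
  set.seed(42)
  for (i in 1:20) {
    x11 <- sample(0:6, 1); x21 <- sample(0:6, 1)
    m <- matrix(c(x11, 6 - x11, x21, 6 - x21), 2, byrow = TRUE)
    expect_equal(h_weight(m, "homogeneity")$h,
                 oracle_homog_h(x11, x21, 6, 6), tolerance = 1e-12)
    g <- as.vector(stats::rmultinom(1, 9, c(.3, .4, .3)))
    expect_equal(h_weight(g, "hwe")$h, oracle_hwe_h(g), tolerance = 1e-12)
  }
})

test_that("null distributions normalise and reproduce the 4-table example", {
  nd <- null_distribution("homogeneity", margins = c(1, 1))
  expect_equal(exp(nd$log_prob), c(1/3, 1/6, 1/6, 1/3), tolerance = 1e-12)
  nd_hwe <- null_distribution("hwe", n = 1)
  expect_equal(exp(nd_hwe$log_prob), rep(1/3, 3), tolerance = 1e-12)
  for (nd in list(nd, nd_hwe,
                  null_distribution("homogeneity", margins = c(9, 4), ncol = 3),
                  null_distribution("independence", n = 7, nrow = 2, ncol = 3))) {
    expect_equal(sum(exp(nd$log_prob)), 1, tolerance = 1e-10)
    expect_equal(nd$log_prob, nd$log_h - nd$log_h_total)
  }
})

test_that("weight sums follow the simplex-volume identities", {
  for (mg in list(c(1, 1), c(5, 5), c(10, 10), c(7, 3))) {
    expect_equal(sum_h("homogeneity", margins = mg, ncol = 2), 1,
                 tolerance = 1e-10)
  }
  expect_equal(sum_h("homogeneity", margins = c(4, 5), ncol = 3), 1 / 2,
               tolerance = 1e-10)
  expect_equal(sum_h("hwe", n = 17), 1, tolerance = 1e-10)
  expect_equal(sum_h("independence", n = 6, nrow = 2, ncol = 2), 1,
               tolerance = 1e-10)
  expect_equal(sum_h("independence", n = 5, nrow = 3, ncol = 3), 1 / 4,
               tolerance = 1e-10)
})

test_that("exact p-values reproduce the analytic micro-examples", {
  ex <- exact_lrt_pvalue(matrix(c(1, 0, 0, 1), 2, byrow = TRUE), "homogeneity")
  expect_equal(ex$p, 1 / 3, tolerance = 1e-12)
  expect_equal(ex$n_region, 2L)
  expect_equal(ex$n_tables, 4)
  ex1 <- exact_lrt_pvalue(matrix(c(1, 0, 1, 0), 2, byrow = TRUE), "homogeneity")
  expect_equal(ex1$p, 1, tolerance = 1e-12)
  # HWE n = 2: region of (0,2,0) is {(0,2,0), (1,0,1)}
  exh <- exact_lrt_pvalue(c(0, 2, 0), "hwe")
  expect_equal(exh$p, 2 / 15 + 1 / 15, tolerance = 1e-12)
  expect_equal(exh$n_region, 2L)
})

test_that("p-values are invariant to rescaling the unnormalised weights", {
  nd <- null_distribution("homogeneity", margins = c(5, 5))
  p1 <- tabexact:::exact_pvalues_all(nd)
  nd2 <- nd
  nd2$log_h <- nd$log_h + log(7.3)
  nd2$log_h_total <- tabexact:::logsumexp(nd2$log_h)
  nd2$log_prob <- nd2$log_h - nd2$log_h_total
  expect_equal(tabexact:::exact_pvalues_all(nd2), p1, tolerance = 1e-12)
})

test_that("exact p-values agree with the materialised brute-force oracle", {
  for (n1 in c(2, 4, 6)) for (n2 in c(3, 6)) {
    sp <- oracle_homog_space(n1, n2)
    nd <- null_distribution("homogeneity", margins = c(n1, n2))
    want <- vapply(seq_len(ncol(nd$cells)), function(i) {
      oracle_homog_p(nd$cells[1, i], nd$cells[3, i], n1, n2)
    }, 0.0)
    expect_equal(tabexact:::exact_pvalues_all(nd), want, tolerance = 1e-10)
  }
  nd <- null_distribution("independence", n = 5, nrow = 2, ncol = 2)
  want <- apply(nd$cells, 2, oracle_indep_p, l = 2, c = 2)
  expect_equal(tabexact:::exact_pvalues_all(nd), want, tolerance = 1e-10)
  nd <- null_distribution("hwe", n = 11)
  want <- apply(nd$cells, 2, oracle_hwe_p)
  expect_equal(tabexact:::exact_pvalues_all(nd), want, tolerance = 1e-10)
})

test_that("streaming two-pass evaluation equals the single-pass result", {
  m <- matrix(c(4, 2, 1, 5), 2, byrow = TRUE)
  expect_equal(exact_lrt_pvalue(m, "homogeneity", max_chunk = 3)$p,
               exact_lrt_pvalue(m, "homogeneity")$p, tolerance = 1e-13)
  expect_equal(exact_lrt_pvalue(m, "independence", max_chunk = 5)$p,
               exact_lrt_pvalue(m, "independence")$p, tolerance = 1e-13)
  expect_equal(exact_lrt_pvalue(c(3, 2, 7), "hwe", max_chunk = 4)$p,
               exact_lrt_pvalue(c(3, 2, 7), "hwe")$p, tolerance = 1e-13)
})

test_that("the exact p-value is a valid, lambda-monotone discrete p-value", {
  for (nd in list(null_distribution("homogeneity", margins = c(8, 8)),
                  null_distribution("independence", n = 9, nrow = 2, ncol = 2),
                  null_distribution("hwe", n = 14))) {
    p <- tabexact:::exact_pvalues_all(nd)
    pr <- exp(nd$log_prob)
    for (alpha in c(0.01, 0.05, 0.1)) {
      expect_lte(sum(pr[p <= alpha]), alpha + 1e-12)
    }
    o <- order(nd$log_lambda)
    expect_true(all(diff(p[o]) >= -1e-12))
    expect_equal(max(p), 1, tolerance = 1e-12)
  }
})
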