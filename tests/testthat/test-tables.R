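test_that("table construction validates cells and derives margins", {
  ct <- contingency_table(matrix(c(5, 5, 5, 5), 2))
  expect_equal(ct$row_margins, c(10, 10))
  expect_equal(ct$col_margins, c(10, 10))
  expect_equal(ct$total, 20)
  expect_false(ct$degenerate)

  zero <- contingency_table(matrix(0, 2, 2))
  expect_equal(zero$total, 0)
  expect_true(zero$degenerate)

  expect_error(contingency_table(matrix(c(1, -1, 0, 2), 2, byrow = TRUE)),
               "row 1 column 2")
  expect_error(contingency_table(matrix(c(1.5, 0, 0, 2), 2)), "integer")
  expect_error(contingency_table(matrix(1:3, 1)), "at least 2 rows")

  g <- genotype_counts(c(1, 2, 1))
  expect_equal(g$n, 4)
  expect_error(genotype_counts(c(1, 2)), "three numbers")
  expect_error(genotype_counts(c(1, -2, 1)), "nonnegative")
})

test_that("enumerations match their closed-form counts and constraints", {
  # homogeneity: every margin vector up to (4, 4, 4), c in {2, 3}
  for (c in 2:3) {
    for (n1 in 0:4) for (n2 in 0:4) {
      sp <- table_space("homogeneity", margins = c(n1, n2), ncol = c)
      expect_equal(ncol(sp$cells),
                   n_tables("homogeneity", margins = c(n1, n2), ncol = c))
      cidx <- rep(1:2, each = c)
      expect_true(all(rowsum(sp$cells, cidx) ==
                        matrix(c(n1, n2), 2, ncol(sp$cells))))
      expect_equal(anyDuplicated(t(sp$cells)), 0L)
    }
  }
  # independence and hwe: all n <= 12 at the dimensions the package scans
  for (n in c(0:12)) {
    for (d in list(c(2, 2), c(2, 3), c(3, 3))) {
      if (n_compositions(n, prod(d)) > 2e5) next
      sp <- table_space("independence", n = n, nrow = d[1], ncol = d[2])
      expect_equal(ncol(sp$cells), n_compositions(n, prod(d)))
      expect_true(all(colSums(sp$cells) == n))
      expect_equal(anyDuplicated(t(sp$cells)), 0L)
    }
    sp <- table_space("hwe", n = n)
    expect_equal(ncol(sp$cells), choose(n + 2, 2))
    expect_true(all(colSums(sp$cells) == n))
  }
  # printed space sizes of the benchmark scenarios
  expect_equal(n_tables("homogeneity", margins = c(10, 10), ncol = 2), 121)
  expect_equal(n_tables("independence", n = 15, nrow = 2, ncol = 3), 15504)
  expect_equal(n_tables("homogeneity", margins = c(30, 30), ncol = 3), 496^2)
})

test_that("enumeration order is lexicographic and deterministic", {
  sp1 <- table_space("homogeneity", margins = c(1, 1), ncol = 2)$cells
  expect_equal(sp1, matrix(c(0, 1, 0, 1,
                             0, 1, 1, 0,
                             1, 0, 0, 1,
                             1, 0, 1, 0), 4,
                           dimnames = NULL))
  sp2 <- table_space("independence", n = 2, nrow = 2, ncol = 2)$cells
  # strictly increasing in lexicographic order of the flattened vector
  key <- apply(sp2, 2, paste, collapse = ",")
  rank <- do.call(order, as.data.frame(t(sp2)))
  expect_equal(rank, seq_len(ncol(sp2)))
  expect_identical(sp2, table_space("independence", n = 2, nrow = 2,
                                    ncol = 2)$cells)
  expect_equal(length(unique(key)), ncol(sp2))
})

test_that("chunked streaming reproduces the materialised enumeration", {
  collect <- function(...) {
    chunks <- list()
    space_apply(..., f = function(cells, off) cells, max_chunk = 7)
  }
  for (args in list(list("independence", n = 5, nrow = 2, ncol = 3),
                    list("hwe", n = 9),
                    list("homogeneity", margins = c(3, 4), ncol = 2),
                    list("homogeneity", margins = c(2, 3, 2), ncol = 3))) {
    got <- do.call(cbind, do.call(space_apply, c(args, list(
      f = function(cells, off) cells, max_chunk = 7))))
    want <- do.call(table_space, args)$cells
    expect_identical(unname(got), unname(want))
  }
  # offsets partition the space in order
  offs <- unlist(space_apply("hwe", n = 9, f = function(cells, off) off,
                             max_chunk = 7))
  expect_true(all(diff(offs) > 0) && offs[1] == 0)
})

test_that("degenerate sizes enumerate to the single empty table", {
  expect_equal(ncol(table_space("independence", n = 0, nrow = 2,
                                ncol = 2)$cells), 1)
  expect_equal(ncol(table_space("hwe", n = 0)$cells), 1)
  expect_equal(n_tables("hwe", n = 30), 496)
  expect_equal(n_tables("hwe", n = 100), 5151)
})
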