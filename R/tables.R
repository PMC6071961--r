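#' Construct a validated contingency table
#'
#' Checks that `counts` is a rectangular matrix of nonnegative integers with
#' at least two rows and two columns, and derives the row margins, column
#' margins and grand total.  Degenerate tables (grand total zero, or a zero
#' row margin) are accepted but flagged; the individual index functions
#' decide whether they are meaningful inputs.
#'
#' @param counts a numeric matrix (or object coercible to one) of
#'   nonnegative integer counts.
#' @return an object of class `"contingency_table"` with fields `counts`
#'   (integer matrix), `row_margins`, `col_margins`, `total`, `degenerate`.
#' @examples
#' contingency_table(matrix(c(5, 5, 5, 5), 2))
#' @export
contingency_table <- function(counts) {
  if (inherits(counts, "contingency_table")) return(counts)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("a contingency table needs at least 2 rows and 2 columns, got ",
         nrow(counts), " x ", ncol(counts))
  }
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8)
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    stop("invalid cell count at row ", ij[1L], " column ", ij[2L],
         ": cells must be nonnegative integers")
  }
  m <- matrix(as.integer(round(counts)), nrow(counts), ncol(counts))
  structure(list(counts = m,
                 row_margins = rowSums(m),
                 col_margins = colSums(m),
                 total = sum(m),
                 degenerate = sum(m) == 0L || any(rowSums(m) == 0L)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(nrow(x$counts), "x", ncol(x$counts), "contingency table, total",
      x$total, if (x$degenerate) "(degenerate)" else "", "\n")
  print(x$counts)
  invisible(x)
}

#' Construct validated genotype counts for a biallelic locus
#'
#' @param x numeric vector of length three with the nonnegative integer
#'   counts of the AA, Aa and aa genotypes (in that order).
#' @return an object of class `"genotype_counts"` with fields `x` (integer
#'   vector of length 3) and `n` (total).
#' @examples
#' genotype_counts(c(298, 489, 213))
#' @export
genotype_counts <- function(x) {
  if (inherits(x, "genotype_counts")) return(x)
  x <- as.numeric(x)
  if (length(x) != 3L) stop("genotype counts must be three numbers (AA, Aa, aa)")
  if (any(!is.finite(x) | x < 0 | abs(x - round(x)) > 1e-8)) {
    stop("genotype counts must be nonnegative integers")
  }
  x <- as.integer(round(x))
  structure(list(x = x, n = sum(x)), class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat("genotype counts (AA, Aa, aa):", paste(x$x, collapse = ", "),
      " n =", x$n, "\n")
  invisible(x)
}

# ---- enumeration -----------------------------------------------------------

#' All weak compositions of n into k parts
#'
#' Columns are the compositions, ordered lexicographically on the vector
#' (first part most significant, ascending).  This fixed order is the
#' canonical enumeration order for every sample space in the package, so
#' that p-value tie resolution and scan outputs are reproducible.
#'
#' @param n nonnegative integer total.
#' @param k number of parts (at least 1).
#' @return an integer matrix with `k` rows and `choose(n + k - 1, k - 1)`
#'   columns.
#' @examples
#' compositions(2, 3)
#' @export
compositions <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  stopifnot(n >= 0L, k >= 1L)
  if (k == 1L) return(matrix(n, 1L, 1L))
  blocks <- lapply(0:n, function(j) {
    rest <- compositions(n - j, k - 1L)
    rbind(matrix(j, 1L, ncol(rest)), rest, deparse.level = 0)
  })
  do.call(cbind, blocks)
}

n_compositions <- function(n, k) choose(n + k - 1, k - 1)

#' Size of an enumerated sample space
#'
#' Closed-form count of the tables compatible with the design constraints:
#' a product of `choose(n_i + c - 1, c - 1)` over rows for homogeneity
#' (fixed row margins), `choose(n + lc - 1, lc - 1)` for independence
#' (fixed grand total), and `choose(n + 2, 2)` for Hardy-Weinberg genotype
#' triples.
#'
#' @inheritParams table_space
#' @return a number (may exceed integer range for large spaces).
#' @examples
#' n_tables("homogeneity", margins = c(10, 10), ncol = 2) # 121
#' n_tables("independence", n = 15, nrow = 2, ncol = 3)   # 15504
#' @export
n_tables <- function(hypothesis, margins = NULL, n = NULL,
                     nrow = NULL, ncol = NULL) {
  kind <- if (inherits(hypothesis, "hypothesis_spec")) hypothesis$kind else
    match.arg(hypothesis, c("homogeneity", "independence", "hwe"))
  if (kind == "homogeneity") {
    ncol <- ncol %||% (if (inherits(hypothesis, "hypothesis_spec")) hypothesis$ncol else 2L)
    stopifnot(!is.null(margins), all(margins >= 0))
    prod(n_compositions(margins, ncol))
  } else if (kind == "independence") {
    if (inherits(hypothesis, "hypothesis_spec")) {
      nrow <- nrow %||% hypothesis$nrow; ncol <- ncol %||% hypothesis$ncol
    }
    stopifnot(!is.null(n), n >= 0, !is.null(nrow), !is.null(ncol))
    n_compositions(n, nrow * ncol)
  } else {
    stopifnot(!is.null(n), n >= 0)
    n_compositions(n, 3L)
  }
}

#' Enumerate the sample space of a hypothesis
#'
#' Materialises every table compatible with the design constraints as the
#' columns of one integer matrix: each column is a table flattened row-major
#' (`x11, x12, ..., x1c, x21, ...`), in lexicographic order of that vector.
#' For the homogeneity hypothesis the space is the Cartesian product of
#' per-row composition sets (row 1 most significant); for independence it
#' is all weak compositions of the grand total into `nrow * ncol` cells;
#' for Hardy-Weinberg it is all genotype triples summing to `n`.
#'
#' Spaces larger than `max_tables` are refused; use [space_apply()] to
#' stream over them in chunks instead.
#'
#' @param hypothesis hypothesis kind or [hypothesis_spec()].
#' @param margins row margins (homogeneity only).
#' @param n grand total (independence) or sample size (hwe).
#' @param nrow,ncol table dimensions where not implied.
#' @param max_tables refuse to materialise more tables than this.
#' @return object of class `"table_space"`: a list with the hypothesis
#'   spec, the `cells` matrix, the sizes, and `n_tables`.
#' @examples
#' table_space("homogeneity", margins = c(1, 1), ncol = 2)$cells
#' @export
table_space <- function(hypothesis, margins = NULL, n = NULL,
                        nrow = NULL, ncol = NULL, max_tables = 2e6) {
  kind <- if (inherits(hypothesis, "hypothesis_spec")) hypothesis$kind else
    match.arg(hypothesis, c("homogeneity", "independence", "hwe"))
  if (kind == "homogeneity") {
    stopifnot(!is.null(margins), all(margins >= 0), length(margins) >= 2L)
    ncol <- ncol %||% (if (inherits(hypothesis, "hypothesis_spec")) hypothesis$ncol else 2L)
    hyp <- hypothesis_spec("homogeneity", length(margins), ncol)
  } else if (kind == "independence") {
    if (inherits(hypothesis, "hypothesis_spec")) {
      nrow <- nrow %||% hypothesis$nrow; ncol <- ncol %||% hypothesis$ncol
    }
    stopifnot(!is.null(n), n >= 0, !is.null(nrow), !is.null(ncol))
    hyp <- hypothesis_spec("independence", nrow, ncol)
  } else {
    stopifnot(!is.null(n), n >= 0)
    hyp <- hypothesis_spec("hwe")
  }
  nt <- n_tables(hyp, margins = margins, n = n)
  if (nt > max_tables) {
    stop("sample space has ", format(nt, big.mark = ","),
         " tables; raise max_tables or stream with space_apply()")
  }
  cells <- switch(hyp$kind,
    homogeneity = {
      rows <- lapply(margins, compositions, k = hyp$ncol)
      sizes <- vapply(rows, ncol, 0L)
      # first row most significant: reverse factors so expand.grid puts it slowest
      g <- as.matrix(do.call(expand.grid, rev(lapply(sizes, seq_len))))
      g <- g[, rev(seq_along(sizes)), drop = FALSE]
      do.call(rbind, lapply(seq_along(rows), function(i) {
        rows[[i]][, g[, i], drop = FALSE]
      }))
    },
    independence = compositions(n, hyp$nrow * hyp$ncol),
    hwe = compositions(n, 3L)
  )
  structure(list(hypothesis = hyp, cells = cells, margins = margins, n = n,
                 n_tables = ncol(cells)),
            class = "table_space")
}

#' @export
print.table_space <- function(x, ...) {
  cat("sample space:", x$hypothesis$kind, "-", x$n_tables, "tables\n")
  invisible(x)
}

#' Apply a function over an enumerated sample space in chunks
#'
#' Streams the same enumeration as [table_space()] (identical order) but
#' never materialises more than roughly `max_chunk` tables at once, so that
#' spaces with tens of millions of tables can be processed in constant
#' memory.  `f(cells, offset)` is called on each chunk, where `offset` is
#' the zero-based index of the chunk's first table in the global order.
#'
#' @inheritParams table_space
#' @param f function of `(cells, offset)` called per chunk; return values
#'   are collected in a list.
#' @param max_chunk target number of tables per chunk.
#' @return invisibly, the list of values returned by `f`.
#' @export
space_apply <- function(hypothesis, margins = NULL, n = NULL,
                        nrow = NULL, ncol = NULL, f, max_chunk = 2e5) {
  kind <- if (inherits(hypothesis, "hypothesis_spec")) hypothesis$kind else
    match.arg(hypothesis, c("homogeneity", "independence", "hwe"))
  acc <- list(); ix <- 0L; off <- 0
  emit <- function(cells) {
    ix <<- ix + 1L
    acc[[ix]] <<- f(cells, off)
    off <<- off + ncol(cells)
  }
  if (kind == "homogeneity") {
    ncol <- ncol %||% (if (inherits(hypothesis, "hypothesis_spec")) hypothesis$ncol else 2L)
    homog_chunks(margins, ncol, emit, max_chunk)
  } else {
    k <- if (kind == "hwe") 3L else {
      if (inherits(hypothesis, "hypothesis_spec")) {
        nrow <- nrow %||% hypothesis$nrow; ncol <- ncol %||% hypothesis$ncol
      }
      nrow * ncol
    }
    composition_chunks(n, k, emit, max_chunk)
  }
  invisible(acc)
}

# stream compositions of n into k parts, lex order, prefix rows prepended
composition_chunks <- function(n, k, emit, max_chunk, prefix = integer(0)) {
  if (k == 1L || n_compositions(n, k) <= max_chunk) {
    x <- compositions(n, k)
    if (length(prefix)) {
      x <- rbind(matrix(prefix, length(prefix), ncol(x)), x, deparse.level = 0)
    }
    emit(x)
    return(invisible())
  }
  for (j in 0:n) {
    composition_chunks(n - j, k - 1L, emit, max_chunk, c(prefix, j))
  }
}

# stream the Cartesian product of per-row composition sets, row 1 slowest
homog_chunks <- function(margins, c, emit, max_chunk, prefix = NULL) {
  nt <- prod(n_compositions(margins, c))
  if (nt <= max_chunk || length(margins) == 1L) {
    rest <- table_space("homogeneity", margins = c(0L, margins), ncol = c,
                        max_tables = Inf)$cells
    # drop the dummy all-zero leading row used to satisfy the l >= 2 check
    rest <- rest[-seq_len(c), , drop = FALSE]
    if (!is.null(prefix)) {
      rest <- rbind(matrix(prefix, length(prefix), ncol(rest)), rest,
                    deparse.level = 0)
    }
    emit(rest)
    return(invisible())
  }
  first <- compositions(margins[1L], c)
  for (j in seq_len(ncol(first))) {
    homog_chunks(margins[-1L], c, emit, max_chunk,
                 prefix = c(prefix, first[, j]))
  }
}
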