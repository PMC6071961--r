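# All-tables index scans: every significance index evaluated for every
# table of an enumerated sample space, sharing one pass over the space.

scan_index_choices <- c("exact", "lrt", "chisq", "fisher", "barnard",
                        "evalue_asym", "evalue")

default_scan_indices <- function(hyp) {
  out <- c("exact", "lrt", "chisq", "evalue_asym")
  if (hyp$kind == "homogeneity" && hyp$nrow == 2L && hyp$ncol == 2L) {
    out <- c(out, "fisher", "barnard")
  }
  if (hyp$kind == "hwe") out <- c(out, "barnard")
  out
}

#' Evaluate every significance index over a whole sample space
#'
#' Enumerates the sample space once, precomputes the null distribution,
#' and returns one row per table with the requested indices.  Available
#' indices: `"exact"` (exact LRT p-value), `"lrt"` (asymptotic LRT
#' p-value), `"chisq"` (Pearson), `"fisher"` (2 x 2 homogeneity only),
#' `"barnard"` (2 x 2 homogeneity and hwe only), `"evalue_asym"`
#' (asymptotic FBST e-value) and `"evalue"` (Monte Carlo FBST e-value,
#' the only stochastic column; requires `seed`).  The default is every
#' deterministic index applicable to the hypothesis.
#'
#' @inheritParams table_space
#' @param indices character vector of index names.
#' @param k Monte Carlo sample size per table for `"evalue"`.
#' @param seed master seed; sub-seeds are drawn per table for `"evalue"`.
#' @param barnard_grid grid size for the Barnard maximisation.
#' @return a data.frame with the flattened cell counts, `log_lambda`, and
#'   one column per requested index (`p_exact`, `p_lrt`, `p_chisq`,
#'   `p_fisher`, `p_barnard`, `evalue_asym`, `evalue`).
#' @examples
#' index_scan("homogeneity", margins = c(1, 1), ncol = 2,
#'            indices = c("exact", "lrt"))
#' @export
index_scan <- function(hypothesis, margins = NULL, n = NULL,
                       nrow = NULL, ncol = NULL, indices = NULL,
                       k = 1e4, seed = NULL, barnard_grid = 1001L,
                       max_tables = 2e6) {
  hyp <- space_hyp(hypothesis, margins, nrow, ncol)
  indices <- if (is.null(indices)) default_scan_indices(hyp) else
    match.arg(indices, scan_index_choices, several.ok = TRUE)
  if ("fisher" %in% indices &&
      !(hyp$kind == "homogeneity" && hyp$nrow == 2L && hyp$ncol == 2L)) {
    stop("the Fisher index is supported for 2 x 2 homogeneity only")
  }
  if ("barnard" %in% indices &&
      !(hyp$kind == "hwe" ||
        (hyp$kind == "homogeneity" && hyp$nrow == 2L && hyp$ncol == 2L))) {
    stop("the Barnard index is supported for 2 x 2 homogeneity and hwe only")
  }
  if ("evalue" %in% indices && is.null(seed)) {
    stop("the Monte Carlo e-value needs an explicit seed")
  }
  if (hyp$kind == "homogeneity" && any(margins == 0)) {
    stop("index scan undefined: zero row margin")
  }
  nd <- null_distribution(hyp, margins = margins, n = n,
                          max_tables = max_tables)
  N <- nd$n_tables
  cells <- t(nd$cells)
  colnames(cells) <- cell_names(hyp)
  out <- data.frame(table = seq_len(N), cells, log_lambda = nd$log_lambda)
  for (ind in indices) {
    out[[scan_col(ind)]] <- switch(ind,
      exact = exact_pvalues_all(nd),
      lrt = lrt_pvalue_from_log_lambda(nd$log_lambda, hyp$df_freq),
      chisq = stats::pchisq(
        chisq_stat_space(nd$cells, hyp, margins = margins, n = n),
        df = hyp$df_freq, lower.tail = FALSE),
      evalue_asym = lrt_pvalue_from_log_lambda(nd$log_lambda, hyp$df_bayes),
      fisher = apply(nd$cells, 2, function(x) {
        stats::fisher.test(matrix(x, 2L, 2L, byrow = TRUE))$p.value
      }),
      barnard = barnard_all(nd, grid_n = barnard_grid),
      evalue = {
        seeds <- sub_seeds(seed, N)
        vapply(seq_len(N), function(i) {
          obsx <- if (hyp$kind == "hwe") nd$cells[, i] else
            matrix(nd$cells[, i], hyp$nrow, hyp$ncol, byrow = TRUE)
          fbst_evalue(obsx, hyp, k = k, seed = seeds[i])$evalue
        }, 0.0)
      })
  }
  attr(out, "hypothesis") <- hyp
  out
}

scan_col <- function(ind) {
  c(exact = "p_exact", lrt = "p_lrt", chisq = "p_chisq",
    fisher = "p_fisher", barnard = "p_barnard",
    evalue_asym = "evalue_asym", evalue = "evalue")[[ind]]
}

cell_names <- function(hyp) {
  if (hyp$kind == "hwe") return(c("x1", "x2", "x3"))
  as.vector(t(outer(seq_len(hyp$nrow), seq_len(hyp$ncol),
                    function(i, j) paste0("x", i, j))))
}

#' Catalogue of the bundled scan scenarios
#'
#' Ten preset small-sample scenarios covering the three hypotheses at
#' several table dimensions and sample sizes.
#'
#' @return a data.frame with columns `setting`, `hypothesis`, `dim`,
#'   `sizes`, `n_tables`.
#' @export
scan_scenarios <- function() {
  data.frame(
    setting = 1:10,
    hypothesis = c(rep("homogeneity", 4), rep("independence", 4),
                   rep("hwe", 2)),
    dim = c("2x2", "2x2", "2x3", "3x3", "2x2", "2x3", "3x3", "3x3", "-", "-"),
    sizes = c("30,30", "100,100", "30,30", "15,15,15",
              "30", "30", "15", "25", "30", "100"),
    n_tables = c(31^2, 101^2, 496^2, 136^3,
                 n_compositions(30, 4), n_compositions(30, 6),
                 n_compositions(15, 9), n_compositions(25, 9),
                 496, 5151),
    stringsAsFactors = FALSE
  )
}

#' Run one of the bundled scan scenarios
#'
#' Resolves a `setting` row of [scan_scenarios()] and runs [index_scan()]
#' on it, optionally writing the result as CSV.  Scenarios whose space
#' exceeds `max_tables` (the largest 3 x 3 spaces) are refused with a
#' pointer to the streaming API, which can evaluate single observed
#' tables in those spaces.
#'
#' @param setting integer 1 to 10.
#' @param out optional CSV path.
#' @param ... passed on to [index_scan()].
#' @inheritParams index_scan
#' @return the scan data.frame, invisibly when `out` is given.
#' @export
scenario_scan <- function(setting, out = NULL, max_tables = 6e6, ...) {
  sc <- scan_scenarios()
  if (!setting %in% sc$setting) stop("unknown scenario setting: ", setting)
  row <- sc[sc$setting == setting, ]
  sizes <- as.integer(strsplit(row$sizes, ",")[[1]])
  res <- switch(row$hypothesis,
    homogeneity = {
      d <- as.integer(strsplit(row$dim, "x")[[1]])
      index_scan("homogeneity", margins = sizes, ncol = d[2L],
                 max_tables = max_tables, ...)
    },
    independence = {
      d <- as.integer(strsplit(row$dim, "x")[[1]])
      index_scan("independence", n = sizes, nrow = d[1L], ncol = d[2L],
                 max_tables = max_tables, ...)
    },
    hwe = index_scan("hwe", n = sizes, max_tables = max_tables, ...)
  )
  if (!is.null(out)) {
    utils::write.csv(format(res, digits = 12, trim = TRUE), out,
                     row.names = FALSE, quote = FALSE)
    return(invisible(res))
  }
  res
}
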