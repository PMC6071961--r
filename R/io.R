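# Reading count inputs from files or inline strings.

#' Read a contingency table or genotype triple
#'
#' Accepts a path to a CSV/TSV file of integers (one table row per line)
#' or an inline string in the same format (rows separated by newlines or
#' semicolons).  With `hypothesis = "hwe"` a single line of three
#' comma-separated integers is read as the AA, Aa, aa genotype counts.
#' Parse failures name the offending row and column.
#'
#' @param source file path or inline string.
#' @param hypothesis hypothesis kind; decides whether a table or a
#'   genotype triple is expected.
#' @return a [contingency_table()] or [genotype_counts()] object.
#' @examples
#' read_counts("5,5\n5,5")
#' read_counts("1,2,1", hypothesis = "hwe")
#' @export
read_counts <- function(source, hypothesis = "homogeneity") {
  kind <- if (inherits(hypothesis, "hypothesis_spec")) hypothesis$kind else
    match.arg(hypothesis, c("homogeneity", "independence", "hwe"))
  lines <- if (length(source) == 1L && !grepl("[\n;]", source) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "[\n;]"))
  }
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no rows found in input")
  rows <- lapply(seq_along(lines), function(i) {
    fields <- trimws(strsplit(lines[i], "[,\t]")[[1]])
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("cannot parse cell at row ", i, " column ", which(is.na(vals))[1L],
           ": '", fields[which(is.na(vals))[1L]], "'")
    }
    vals
  })
  if (length(unique(lengths(rows))) != 1L) {
    stop("ragged rows: every row must have the same number of cells")
  }
  m <- do.call(rbind, rows)
  if (kind == "hwe") {
    if (!identical(dim(m), c(1L, 3L))) {
      stop("genotype input must be one line of three counts (AA, Aa, aa)")
    }
    genotype_counts(m[1L, ])
  } else {
    contingency_table(m)
  }
}

#' Write a contingency table or genotype triple as CSV text
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x))` recovers `x`.
#'
#' @param x a [contingency_table()] or [genotype_counts()].
#' @param path optional file path; when `NULL` the CSV text is returned.
#' @return the CSV text, invisibly when written to `path`.
#' @export
write_counts <- function(x, path = NULL) {
  txt <- if (inherits(x, "genotype_counts")) {
    paste(x$x, collapse = ",")
  } else {
    ct <- contingency_table(x)
    paste(apply(ct$counts, 1, paste, collapse = ","), collapse = "\n")
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
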