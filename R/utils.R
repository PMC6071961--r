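# Internal numeric helpers shared across the package.

# log(sum(exp(x))) without overflow; -Inf for empty input
logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# x * log(x / m) with the 0 log 0 = 0 convention; shapes of x preserved,
# m recycled column-wise for matrices (i.e. along cells of each table)
xlx <- function(x, m) {
  x * log(ifelse(x > 0, x / m, 1))
}

# a * log(t) with 0 * log(0) = 0 (the a = 0 case short-circuits t = 0)
plog <- function(a, t) {
  ifelse(a > 0, a * log(t), 0)
}

# t^p with the 0^0 = 1 convention, vectorised over both arguments
pow0 <- function(t, p) {
  ifelse(p == 0, 1, t^p)
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL runs the code with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic per-unit sub-seeds derived from one master seed
sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
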