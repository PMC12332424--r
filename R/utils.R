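# Internal helpers shared across tracks.

# Recognised ocean-basin labels (North Atlantic, Guinea, Brazil, Angola,
# Cape, Cape Verde, West European, Vema Fracture Zone, Puerto Rico Trench).
BASIN_LEVELS <- c("NAB", "GUB", "BB", "AB", "CB", "CVB", "WEB", "VFZ", "PRT")

MARKER_LEVELS <- c("COI", "16S")

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Euclidean projection of a nonnegative-orthant vector onto the probability
# simplex (Duchi et al. sort-based algorithm). Used to keep ancestry rows
# on the simplex after each optimizer sweep.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Derive a stream of distinct 32-bit seeds from one master seed.
derive_seeds <- function(seed, n) {
  withr_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(withr_seed)) assign(".Random.seed", withr_seed, envir = globalenv())
  s
}

# Adjusted Rand index between two label vectors; used throughout the test
# suite and by the examples to score recovery of planted structure.
#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two clusterings of the same specimens,
#' corrected for chance; 1 means identical partitions (up to label names),
#' 0 is the expectation under independent random labels.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maxidx <- (sum_i + sum_j) / 2
  if (maxidx == expected) return(1)
  (sum_ij - expected) / (maxidx - expected)
}
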