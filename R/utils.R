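#' @importFrom rlang abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

# Derive B reproducible sub-stream seeds (< 2^31) from one master seed, so any
# single replicate can be regenerated in isolation.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items (for
#' example a detected module partition against the planted blocks of
#' [simulate_traits()]): 1 for identical partitions, about 0 for independent
#' ones. Computed from the pair-counting contingency table
#' (Hubert-Arabie correction).
#'
#' @param a,b Vectors of group labels of equal length (any type; matched as
#'   factors). Named vectors are aligned by name when both are fully named.
#' @return A single number, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b)) &&
      all(nzchar(names(a))) && setequal(names(a), names(b))) {
    b <- b[names(a)]
  }
  if (length(a) != length(b)) abort("partitions must label the same items")
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial (all-one or all-singleton)
  (sij - expected) / denom
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}
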