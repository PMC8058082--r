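#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded sections do not
#' perturb the global random number stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`%s` must be a single finite number", name)
  if (x < lower || x > upper)
    stop_("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_scalar_number(x, name, lower = min)
  if (x != as.integer(x)) stop_("`%s` must be an integer count", name)
  invisible(as.integer(x))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same subjects:
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels (any type coercible to factor),
#'   equal length.
#' @return A single number, at most 1.
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == max_index, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}
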