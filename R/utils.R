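#' @keywords internal
"_PACKAGE"

# Relative tolerance used when counting null draws "at least as extreme" as
# the observed statistic.  Permutation draws that re-create the observed set
# can differ from the observed value by floating-point summation order only;
# without a tolerance such ties would be miscounted.
.tie_eps <- 1e-9

#' Derive a reproducible sub-stream seed
#'
#' All stochastic operations derive their own seed from the run seed plus a
#' string tag, so results do not depend on the order in which operations are
#' called. The result always fits a 32-bit integer.
#'
#' @param seed integer run seed.
#' @param tag character tag naming the operation (and, where needed, the
#'   unit of work within it).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147480009 # large prime < 2^31
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  as.integer((abs(seed) %% m * 69069 + h) %% m)
}

# column means and sample SDs of a numeric matrix, sd = 0 for 1-row input
.col_mean_sd <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  if (n < 2L) {
    s <- rep(0, ncol(x))
  } else {
    s <- sqrt(pmax(colSums(x * x) - n * m * m, 0) / (n - 1))
  }
  list(mean = m, sd = s)
}

#' Empirical permutation p-value
#'
#' Counts null draws at least as extreme as the observed statistic. For
#' two-sided tests extremity is distance from the null mean. Sampled nulls
#' use the add-one rule p = (count + 1) / (n + 1), which never returns 0;
#' exhaustive nulls use the exact count over all enumerated draws.
#'
#' @param observed observed statistic (scalar).
#' @param null numeric vector of null statistics.
#' @param sided `"two"` (distance from null mean) or `"upper"`.
#' @param exhaustive logical; exact counting without the add-one rule.
#' @return empirical p-value in (0, 1].
#' @export
empirical_p <- function(observed, null, sided = c("two", "upper"),
                        exhaustive = FALSE) {
  sided <- match.arg(sided)
  stopifnot(length(null) >= 1L, is.finite(observed))
  if (sided == "two") {
    ctr <- mean(null)
    d_obs <- abs(observed - ctr)
    d_null <- abs(null - ctr)
  } else {
    d_obs <- observed
    d_null <- null
  }
  tol <- .tie_eps * (1 + abs(d_obs))
  count <- sum(d_null >= d_obs - tol)
  if (exhaustive) count / length(null) else (count + 1) / (length(null) + 1)
}

#' Permutation test result
#'
#' Container for an observed statistic, its permutation null and the
#' empirical p-value.
#'
#' @param statistic name of the statistic.
#' @param observed observed value.
#' @param null numeric vector of null values.
#' @param empirical_p empirical p-value.
#' @param n_perm number of permutations (equals `length(null)` unless
#'   exhaustive).
#' @param seed RNG seed used for the null (NA for exhaustive nulls).
#' @param sided sidedness of the test.
#' @param exhaustive whether the null enumerates all draws.
#' @return an object of class `permutation_result`.
#' @export
permutation_result <- function(statistic, observed, null, empirical_p,
                               n_perm, seed = NA_integer_,
                               sided = "two", exhaustive = FALSE) {
  structure(
    list(statistic = statistic, observed = observed, null = null,
         empirical_p = empirical_p, n_perm = n_perm, seed = seed,
         sided = sided, exhaustive = exhaustive),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: %s = %.4g, p = %.4g (%s, %s, n_perm = %d)\n",
    x$statistic, x$observed, x$empirical_p, x$sided,
    if (x$exhaustive) "exhaustive" else "sampled", x$n_perm))
  invisible(x)
}
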