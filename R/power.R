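#' Simulated power of the exact test for a difference in proportions
#'
#' Monte-Carlo power of the two-sided Freeman-Halton exact test (here the
#' 2x2 special case, i.e. Fisher's exact test) to detect an absolute
#' difference `delta` in category proportions between two gene sets of
#' sizes `n1` and `n2`. Per replicate, in-category counts are drawn as
#' Binomial(`n1`, `p0`) and Binomial(`n2`, `p0 + delta`), the 2x2 table is
#' formed, and the exact test applied; power is the fraction of replicates
#' with p <= `alpha`.
#'
#' @param n1,n2 Annotated gene counts of the two sets being compared.
#' @param p0 Baseline in-category proportion of set 1.
#' @param delta Absolute difference in proportions (set 2 has `p0 + delta`);
#'   may be negative.
#' @param alpha Rejection level (default 0.05).
#' @param n_reps Monte-Carlo replicates (default 10000).
#' @param seed Optional integer seed.
#' @param tie_tol Tie tolerance passed to the exact-test kernel.
#' @return A `power_estimate`: list with `power`, `n_reps`, `mc_se` (the
#'   binomial Monte-Carlo standard error `sqrt(p(1-p)/n_reps)`), and
#'   `settings`.
#' @examples
#' simulate_power(200, 100, p0 = 0.2, delta = 0.2, n_reps = 200, seed = 1)
#' @export
simulate_power <- function(n1, n2, p0, delta, alpha = 0.05,
                           n_reps = 10000L, seed = NULL, tie_tol = 1e-7) {
  if (n1 < 1L || n2 < 1L) stop("n1 and n2 must be >= 1", call. = FALSE)
  if (p0 <= 0 || p0 >= 1 || p0 + delta <= 0 || p0 + delta >= 1) {
    stop("proportions must satisfy 0 < p0, p0 + delta < 1", call. = FALSE)
  }
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  x1 <- stats::rbinom(n_reps, n1, p0)
  x2 <- stats::rbinom(n_reps, n2, p0 + delta)
  lf <- lfactorial(0:(n1 + n2))
  reject <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    cells <- rbind(c(x1[i], x2[i]), c(n1 - x1[i], n2 - x2[i]))
    reject[i] <- .ffh_pvalue(cells, lf = lf, tie_tol = tie_tol)$p_value <= alpha
  }
  power <- mean(reject)
  structure(
    list(power = power,
         n_reps = as.integer(n_reps),
         mc_se = sqrt(power * (1 - power) / n_reps),
         settings = list(n1 = n1, n2 = n2, p0 = p0, delta = delta,
                         alpha = alpha, seed = seed)),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  s <- x$settings
  cat(sprintf(
    "Simulated power %.3f (MC se %.4f, %d reps) for n1=%d, n2=%d, p0=%.3f, delta=%+.3f, alpha=%.2f\n",
    x$power, x$mc_se, x$n_reps, s$n1, s$n2, s$p0, s$delta, s$alpha))
  invisible(x)
}

#' Minimum detectable difference on a grid
#'
#' Smallest candidate difference in proportions whose simulated power meets
#' the target. Candidates are evaluated in grid order (ascending), each with
#' its own simulation drawn from the seeded stream.
#'
#' @inheritParams simulate_power
#' @param target_power Power to reach (e.g. 0.8).
#' @param grid Ascending candidate `delta` values.
#' @return The smallest grid `delta` reaching `target_power`, or `NA_real_`
#'   if none does; the simulated power of every evaluated candidate is
#'   attached as attribute `"powers"`.
#' @examples
#' minimum_detectable_difference(500, 200, p0 = 0.2, target_power = 0.8,
#'                               n_reps = 200, seed = 1,
#'                               grid = c(0.05, 0.1, 0.2, 0.3))
#' @export
minimum_detectable_difference <- function(n1, n2, p0, alpha = 0.05,
                                          target_power = 0.8,
                                          n_reps = 2000L, seed = NULL,
                                          grid) {
  if (missing(grid) || length(grid) == 0L) {
    stop("grid of candidate deltas must be nonempty", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = FALSE)) {
    stop("grid must be sorted ascending", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  powers <- stats::setNames(rep(NA_real_, length(grid)), format(grid))
  for (i in seq_along(grid)) {
    powers[i] <- simulate_power(n1, n2, p0, grid[i], alpha = alpha,
                                n_reps = n_reps, seed = NULL)$power
    if (powers[i] >= target_power) {
      return(structure(grid[i], powers = powers[seq_len(i)]))
    }
  }
  structure(NA_real_, powers = powers)
}
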