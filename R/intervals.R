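#' Exact Clopper-Pearson binomial confidence interval
#'
#' Equal-tailed exact interval via the beta-quantile characterization:
#' `lower = qbeta((1-level)/2, x, n-x+1)` (0 when `x = 0`) and
#' `upper = qbeta(1-(1-level)/2, x+1, n-x)` (1 when `x = n`). This is the
#' interval the analysis plan reports alongside the response-rate estimates:
#' 6/30 responders give (0.077, 0.386) at 95%.
#'
#' @param successes Number of successes, `0 <= successes <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in `(0, 1)`; default 0.95.
#' @return An object of class `exact_ci`: list with `estimate`, `lower`,
#'   `upper`, `level`, `successes`, `n`.
#' @examples
#' clopper_pearson(6, 30)   # (0.077, 0.386)
#' clopper_pearson(27, 30)  # (0.735, 0.979)
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  .check_count(successes, "successes")
  .check_count(n, "n")
  if (n < 1) stop("'n' must be at least 1", call. = FALSE)
  if (successes > n)
    stop("'successes' must not exceed 'n'", call. = FALSE)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  a <- (1 - level) / 2
  lower <- if (successes == 0) 0
           else stats::qbeta(a, successes, n - successes + 1)
  upper <- if (successes == n) 1
           else stats::qbeta(1 - a, successes + 1, n - successes)
  structure(list(estimate = successes / n, lower = lower, upper = upper,
                 level = level, successes = successes, n = n),
            class = "exact_ci")
}

#' @export
print.exact_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %g%% exact CI (%.3f, %.3f)\n",
              x$successes, x$n, x$estimate, 100 * x$level, x$lower, x$upper))
  invisible(x)
}
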