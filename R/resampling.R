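#' Delete-one jackknife standard error
#'
#' Recomputes `estimator` n times, each time with one observation unit
#' removed, and returns the standard error
#' `sqrt((n - 1) / n * sum((theta_(i) - theta_bar)^2))`, where `theta_bar`
#' is the mean of the n leave-one-out estimates. For the entropy pipeline
#' the observation unit is the cell. Results are independent of evaluation
#' order.
#'
#' @param samples Observation units: a vector, or a matrix/data frame whose
#'   rows are units (rows are deleted one at a time).
#' @param estimator Function mapping a size-(n-1) subset of `samples` to a
#'   single numeric value.
#' @return A `jackknife_result`: list with `estimate_full` (estimator on the
#'   whole sample), `estimate_mean` (mean of leave-one-out estimates),
#'   `leave_one_out` (n values), `se` and `n`.
#' @export
#' @examples
#' jackknife(c(0, 1), mean)$se  # 0.5 = s/sqrt(n)
jackknife <- function(samples, estimator) {
  drop_unit <- if (is.matrix(samples) || is.data.frame(samples)) {
    n <- nrow(samples)
    function(i) samples[-i, , drop = FALSE]
  } else {
    n <- length(samples)
    function(i) samples[-i]
  }
  if (n < 2)
    stop("jackknife requires at least 2 observation units", call. = FALSE)
  loo <- vapply(seq_len(n), function(i) {
    val <- tryCatch(estimator(drop_unit(i)), error = function(e)
      stop(sprintf("estimator failed with unit %d deleted: %s",
                   i, conditionMessage(e)), call. = FALSE))
    as.numeric(val)
  }, numeric(1))
  theta_bar <- mean(loo)
  se <- sqrt((n - 1) / n * sum((loo - theta_bar)^2))
  structure(list(estimate_full = as.numeric(estimator(samples)),
                 estimate_mean = theta_bar,
                 leave_one_out = loo,
                 se = se,
                 n = n),
            class = "jackknife_result")
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf("jackknife: estimate %.6g +/- %.3g (n = %d)\n",
              x$estimate_full, x$se, x$n))
  invisible(x)
}
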