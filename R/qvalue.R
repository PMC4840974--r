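#' Estimate the null proportion pi0 from a P-value vector
#'
#' Storey-type estimator: pi0(lambda) = #\{p > lambda\} / (n (1 - lambda))
#' is computed on a grid of lambda values, smoothed by a cubic polynomial
#' fit in lambda, and the smoother is evaluated at the largest lambda.
#' The estimate is clamped into \[1/n, 1\]; the floor avoids q-values
#' collapsing to 0 when nearly all features carry signal.
#'
#' With fewer than 100 P-values the tail counts are too unstable for the
#' fit and the estimator falls back to pi0 = 1 (pure Benjamini-Hochberg).
#'
#' @param p Numeric vector of P-values in \[0, 1\] (`NA` ignored).
#' @param lambda_grid Strictly increasing grid in (0, 1); default
#'   0.05, 0.10, ..., 0.95.
#' @return A single number in (0, 1\].
#' @export
estimate_pi0 <- function(p, lambda_grid = seq(0.05, 0.95, by = 0.05)) {
  p <- p[!is.na(p)]
  if (any(p < 0 | p > 1)) stop("P-values must lie in [0, 1]")
  if (is.unsorted(lambda_grid, strictly = TRUE) ||
      any(lambda_grid <= 0 | lambda_grid >= 1))
    stop("`lambda_grid` must be strictly increasing within (0, 1)")
  n <- length(p)
  if (n < 100L) return(1)
  pi0_lambda <- vapply(lambda_grid,
                       function(l) sum(p > l) / (n * (1 - l)), numeric(1))
  fit <- stats::lm(pi0_lambda ~ poly(lambda_grid, 3))
  pi0 <- stats::predict(fit,
                        newdata = data.frame(lambda_grid = max(lambda_grid)))
  min(max(unname(pi0), 1 / n), 1)
}

#' Convert P-values to q-values (FDR)
#'
#' Step-up q-values: on the P-sorted order, q_(i) = min over j >= i of
#' pi0 * n * p_(j) / j, mapped back to the input order. With `pi0 = 1`
#' this is exactly the Benjamini-Hochberg adjusted P-value; with the
#' estimated pi0 < 1 the q-values are uniformly smaller. `NA` P-values
#' (degenerate features) receive `NA` q-values and do not count towards
#' n.
#'
#' @param p Numeric vector of P-values in \[0, 1\].
#' @param pi0 Either `"auto"` (estimate via [estimate_pi0()]) or a fixed
#'   number in (0, 1\].
#' @return A list of class `"qvalue_result"` with elements `q_values`
#'   (aligned to `p`) and `pi0`.
#' @examples
#' qvalues(c(0.01, 0.02, 0.03, 0.04), pi0 = 1)$q_values
#' @export
qvalues <- function(p, pi0 = "auto") {
  if (!length(p))
    return(structure(list(q_values = numeric(0), pi0 = 1),
                     class = "qvalue_result"))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("P-values must lie in [0, 1]")
  pi0_hat <- if (identical(pi0, "auto")) estimate_pi0(p[ok]) else {
    if (!is.numeric(pi0) || length(pi0) != 1L || pi0 <= 0 || pi0 > 1)
      stop("`pi0` must be \"auto\" or a single number in (0, 1]")
    pi0
  }
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  n <- length(pv)
  o <- order(pv)
  qs <- pmin(1, rev(cummin(rev(pi0_hat * n * pv[o] / seq_len(n)))))
  qq <- q[ok]; qq[o] <- qs; q[ok] <- qq
  structure(list(q_values = q, pi0 = pi0_hat), class = "qvalue_result")
}
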