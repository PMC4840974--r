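#' Fit an empirical-Bayes variance prior across features
#'
#' Method-of-moments fit of the scaled inverse-chi-square prior used by
#' moderated t-statistics: the log sample variances are assumed to follow
#' log(s0^2) plus a scaled log-chi-square with `d0` prior degrees of
#' freedom. Writing e_j = log(s2_j) - digamma(df/2) + log(df/2), the fit
#' solves trigamma(d0/2) = var(e) - trigamma(df/2) for `d0` by monotone
#' root-finding (`d0 = Inf` when the right-hand side is non-positive, i.e.
#' the variances are no more dispersed than pure chi-square sampling
#' noise), and then sets
#' s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2)).
#'
#' @param s2 Positive numeric vector of per-feature sample variances
#'   (non-positive or missing entries are excluded with a warning).
#' @param df Residual degrees of freedom each variance was computed with.
#' @return An object of class `"variance_prior"`: list with `d0` (prior
#'   df, possibly `Inf`) and `s0_squared`.
#' @references Smyth (2004), Stat. Appl. Genet. Mol. Biol. 3, Article 3
#'   (the moderated t framework this prior feeds).
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(is.numeric(df), length(df) == 1L, df > 0)
  drop <- is.na(s2) | s2 <= 0
  if (any(drop)) {
    warning(sum(drop), " non-positive or missing variances excluded from prior fit")
    s2 <- s2[!drop]
  }
  if (!length(s2)) stop("no positive variances left to fit the prior")
  if (length(s2) < 10L)
    warning("fewer than 10 variances; prior fit will be unstable")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ev <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(ev) || ev <= 0) {
    d0 <- Inf
    s0 <- exp(mean(e))
  } else {
    # trigamma is strictly decreasing on (0, Inf); bracket and solve
    root <- tryCatch(
      stats::uniroot(function(x) trigamma(x) - ev,
                     lower = 1e-8, upper = 1e8, tol = 1e-10)$root,
      error = function(err) NA_real_)
    if (is.na(root)) {
      warning("prior degrees-of-freedom root-finding failed; using d0 = Inf")
      d0 <- Inf
      s0 <- exp(mean(e))
    } else {
      d0 <- 2 * root
      s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  }
  structure(list(d0 = d0, s0_squared = s0), class = "variance_prior")
}

#' @export
print.variance_prior <- function(x, ...) {
  cat("variance_prior: d0 =", format(x$d0), " s0^2 =", format(x$s0_squared), "\n")
  invisible(x)
}

# Posterior (squeezed) variances: (d0 s0^2 + df s2) / (d0 + df).
# d0 = Inf collapses every variance to s0^2; d0 = 0 leaves s2 untouched.
squeeze_var <- function(s2, df, prior) {
  if (is.infinite(prior$d0)) return(rep(prior$s0_squared, length(s2)))
  if (prior$d0 == 0) return(s2)
  (prior$d0 * prior$s0_squared + df * s2) / (prior$d0 + df)
}

# Moderated two-sample t over the rows of `x` (group 1 minus group 0).
# The pooled within-group variance of each row is squeezed towards the
# empirical-Bayes prior fitted across all rows; the t statistic gains
# d0 extra degrees of freedom. Returns per-row statistic, p, and the
# prior used. `prior` can be supplied to override the fit (e.g. d0 = 0
# recovers the ordinary t-test).
row_moderated_t <- function(x, group, prior = NULL) {
  mom <- row_group_moments(x, group)
  n0 <- mom$n0; n1 <- mom$n1
  df <- n0 + n1 - 2
  ok <- n0 >= 2 & n1 >= 2
  s2 <- ifelse(ok & df > 0, (mom$ss0 + mom$ss1) / df, NA_real_)
  if (is.null(prior)) {
    full <- df == max(df[ok], na.rm = TRUE) & !is.na(s2) & s2 > 0
    prior <- if (sum(full) >= 10L) {
      fit_variance_prior(s2[full], df = max(df[ok], na.rm = TRUE))
    } else {
      structure(list(d0 = 0, s0_squared = NA_real_), class = "variance_prior")
    }
  }
  s2_post <- squeeze_var(s2, df, prior)
  se <- sqrt(s2_post * (1 / n0 + 1 / n1))
  diff <- mom$mean1 - mom$mean0
  stat <- p <- rep(NA_real_, length(diff))
  use <- ok & !is.na(se) & se > 0
  df_tot <- prior$d0 + df
  stat[use] <- diff[use] / se[use]
  p[use] <- if (is.infinite(prior$d0)) {
    2 * stats::pnorm(-abs(stat[use]))
  } else {
    2 * stats::pt(-abs(stat[use]), df = df_tot[use])
  }
  flat <- ok & !is.na(se) & se == 0 & diff == 0
  stat[flat] <- 0
  p[flat] <- 1
  list(statistic = stat, p_value = p, mean_diff = diff, prior = prior,
       df_total = df_tot)
}
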