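# Row-wise two-group summary statistics with per-entry missingness.
#
# All DV tests run over thousands of features, so the per-feature moments
# are computed in one pass of matrix arithmetic rather than per-row loops.
# Missing entries contribute neither to counts nor to sums.

row_group_moments <- function(x, group) {
  stopifnot(is.matrix(x), length(group) == ncol(x))
  miss <- is.na(x)
  x0 <- x
  x0[miss] <- 0
  out <- list()
  for (gv in c(0L, 1L)) {
    idx <- group == gv
    xm <- x0[, idx, drop = FALSE]
    mm <- miss[, idx, drop = FALSE]
    n <- rowSums(!mm)
    s <- rowSums(xm)
    mean <- ifelse(n > 0, s / n, NA_real_)
    dev <- xm - mean          # recycles mean down each column
    dev[mm] <- 0
    ss <- rowSums(dev * dev)
    var <- ifelse(n > 1, ss / (n - 1), NA_real_)
    key <- as.character(gv)
    out[[paste0("n", key)]] <- n
    out[[paste0("mean", key)]] <- mean
    out[[paste0("var", key)]] <- var
    out[[paste0("ss", key)]] <- ss
  }
  out
}

# Two-group Bartlett statistic per row. Returns statistic, p_value and a
# degenerate flag. Rows with < 3 values in either group, or zero variance
# in one or both groups, yield NA (flagged): a zero-variance group makes
# the statistic infinite and its P-value meaningless.
row_bartlett <- function(mom) {
  n0 <- mom$n0; n1 <- mom$n1
  v0 <- mom$var0; v1 <- mom$var1
  N <- n0 + n1
  ok <- n0 >= 3 & n1 >= 3 & !is.na(v0) & !is.na(v1)
  degen <- ok & (v0 <= 0 | v1 <= 0)
  usable <- ok & !degen
  stat <- p <- rep(NA_real_, length(n0))
  if (any(usable)) {
    n0u <- n0[usable]; n1u <- n1[usable]; Nu <- N[usable]
    v0u <- v0[usable]; v1u <- v1[usable]
    sp2 <- ((n0u - 1) * v0u + (n1u - 1) * v1u) / (Nu - 2)
    num <- (Nu - 2) * log(sp2) - (n0u - 1) * log(v0u) - (n1u - 1) * log(v1u)
    corr <- 1 + (1 / (n0u - 1) + 1 / (n1u - 1) - 1 / (Nu - 2)) / 3
    s <- pmax(num / corr, 0)
    stat[usable] <- s
    p[usable] <- stats::pchisq(s, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p, degenerate = degen)
}

# Two-sample t per row (group 1 minus group 0), Welch or pooled df.
row_t <- function(mom, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  n0 <- mom$n0; n1 <- mom$n1
  v0 <- mom$var0; v1 <- mom$var1
  diff <- mom$mean1 - mom$mean0
  ok <- n0 >= 2 & n1 >= 2 & !is.na(v0) & !is.na(v1)
  stat <- p <- df <- rep(NA_real_, length(n0))
  if (variant == "welch") {
    se2 <- v0 / n0 + v1 / n1
    dfw <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  } else {
    sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
    se2 <- sp2 * (1 / n0 + 1 / n1)
    dfw <- n0 + n1 - 2
  }
  pos <- ok & se2 > 0
  stat[pos] <- diff[pos] / sqrt(se2[pos])
  df[pos] <- dfw[pos]
  p[pos] <- 2 * stats::pt(-abs(stat[pos]), df = dfw[pos])
  # both groups constant: equal means give a well-defined null result,
  # unequal means an infinite statistic -> missing (flagged upstream)
  flat <- ok & se2 == 0
  stat[flat & diff == 0] <- 0
  p[flat & diff == 0] <- 1
  df[flat & diff == 0] <- n0[flat & diff == 0] + n1[flat & diff == 0] - 2
  list(statistic = stat, p_value = p, df = df)
}

# Joint 2-df score test for a group effect on mean and on variance, per
# row, on the working (M-value) matrix. Model: y = mu + beta*x + eps,
# Var(eps) = sigma^2 * exp(gamma * x), x in {0,1}; H0: beta = gamma = 0.
#
# The mean score reduces to T_beta = (n0 n1 / N) (ybar1 - ybar0)^2 /
# sigma2_hat. The variance score is the group contrast of the squared
# residuals d_i = (y_i - ybar)^2: T_gamma = (n0 n1 / N) (dbar1 -
# dbar0)^2 / v, where v is the variance of d. Under `information =
# "expected"` v is the Gaussian value 2 sigma2_hat^2 (the textbook
# expected-information score test); under the default `"robust"` v is
# the empirical variance of d (Koenker-type studentization), which keeps
# the test calibrated under non-Gaussian data and makes it insensitive
# to a handful of extreme outliers. T = T_beta + T_gamma ~ chi-square
# with 2 df.
row_jdmdv <- function(x, group, information = c("robust", "expected")) {
  information <- match.arg(information)
  miss <- is.na(x)
  x0 <- x
  x0[miss] <- 0
  nr <- rowSums(!miss)
  ybar <- rowSums(x0) / nr
  r <- x0 - ybar
  r[miss] <- 0
  d <- r * r
  N <- nr
  idx1 <- group == 1L
  n1 <- rowSums(!miss[, idx1, drop = FALSE])
  n0 <- N - n1
  sigma2 <- rowSums(d) / N
  d1bar <- rowSums(d[, idx1, drop = FALSE]) / n1
  d0bar <- (rowSums(d) - rowSums(d[, idx1, drop = FALSE])) / n0
  y1bar <- rowSums(x0[, idx1, drop = FALSE]) / n1
  y0bar <- (rowSums(x0) - rowSums(x0[, idx1, drop = FALSE])) / n0
  w <- n0 * n1 / N
  t_mean <- w * (y1bar - y0bar)^2 / sigma2
  v <- if (information == "expected") {
    2 * sigma2^2
  } else {
    dev <- d - (rowSums(d) / N)
    dev[miss] <- 0
    rowSums(dev * dev) / N
  }
  num_var <- w * (d1bar - d0bar)^2
  t_var <- ifelse(v > 0, num_var / v, ifelse(num_var == 0, 0, NA_real_))
  ok <- n0 >= 3 & n1 >= 3 & sigma2 > 0
  stat <- ifelse(ok, t_mean + t_var, NA_real_)
  p <- stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(statistic = stat, p_value = p, stat_mean = t_mean, stat_var = t_var,
       mean_diff = y1bar - y0bar)
}

# Nested Gaussian location-scale fits per row (closed-form MLEs):
#   M0 common mean / common variance, M1 group means / common variance,
#   M2 group means / group variances.
# LRT_mean = 2(l1 - l0) ~ chi2(1); LRT_var = 2(l2 - l1) ~ chi2(1).
# The log-likelihood of a Gaussian fit with MLE variance v on n points is
# -n/2 (log(2 pi v) + 1), so both LRTs reduce to log-variance ratios.
row_gamlss <- function(mom) {
  n0 <- mom$n0; n1 <- mom$n1
  N <- n0 + n1
  ss_within <- mom$ss0 + mom$ss1
  # total SS around the grand mean = within SS + between-group SS
  gmean <- (n0 * mom$mean0 + n1 * mom$mean1) / N
  ss_total <- ss_within + n0 * (mom$mean0 - gmean)^2 + n1 * (mom$mean1 - gmean)^2
  v0 <- mom$ss0 / n0      # MLE variances
  v1 <- mom$ss1 / n1
  ok <- n0 >= 3 & n1 >= 3 & v0 > 0 & v1 > 0
  lrt_mean <- lrt_var <- rep(NA_real_, length(n0))
  lrt_mean[ok] <- pmax(0, N[ok] * log(ss_total[ok] / ss_within[ok]))
  lrt_var[ok] <- pmax(0, N[ok] * log(ss_within[ok] / N[ok]) -
                         n0[ok] * log(v0[ok]) - n1[ok] * log(v1[ok]))
  list(lrt_mean = lrt_mean,
       lrt_var = lrt_var,
       p_mean = stats::pchisq(lrt_mean, df = 1, lower.tail = FALSE),
       p_var = stats::pchisq(lrt_var, df = 1, lower.tail = FALSE))
}
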