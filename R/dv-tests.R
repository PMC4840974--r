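#' Two-group Bartlett test of equal variances
#'
#' Closed form for k = 2 groups: with pooled variance s_p^2 and group
#' variances s_i^2,
#' T = \[(N-2) ln s_p^2 - sum (n_i - 1) ln s_i^2\] /
#'     \[1 + (sum 1/(n_i - 1) - 1/(N-2)) / 3\],
#' referred to the chi-square distribution with 1 degree of freedom.
#' Bartlett's test is the variance-significance engine of iEVORA; it is
#' powerful for differential variance but, being a normal-theory test, is
#' sensitive to heavy tails and single outliers.
#'
#' @param x0,x1 Numeric vectors (reference and disease group); `NA`
#'   dropped; each needs >= 3 finite values.
#' @return List with `statistic`, `p_value`, and `degenerate` (`TRUE` when
#'   at least one group has zero variance, in which case both statistic
#'   and P-value are `NA`).
#' @examples
#' bartlett_test(c(1, 2, 3, 4, 5), c(2, 4, 6, 8, 10))
#' @export
bartlett_test <- function(x0, x1) {
  x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
  if (length(x0) < 3L || length(x1) < 3L)
    stop("each group needs at least 3 non-missing values")
  x <- matrix(c(x0, x1), nrow = 1)
  res <- row_bartlett(row_group_moments(
    x, c(rep(0L, length(x0)), rep(1L, length(x1)))))
  list(statistic = res$statistic[1], p_value = res$p_value[1],
       degenerate = res$degenerate[1])
}

#' Two-sample t-test (Welch or pooled)
#'
#' Statistic for group 1 minus group 0; positive values mean
#' hypermethylation of the disease group. Used to re-rank
#' Bartlett-significant sites in iEVORA and to measure validation-set
#' progression in the PPV framework.
#'
#' @param x0,x1 Numeric vectors (reference, disease); `NA` dropped; each
#'   needs >= 2 finite values.
#' @param variant `"welch"` (Welch-Satterthwaite df, default) or
#'   `"pooled"`.
#' @return List with `statistic`, `p_value`, `df`. Both groups constant
#'   and equal gives statistic 0, p 1; zero variance with unequal means
#'   gives `NA` (degenerate).
#' @export
two_sample_t <- function(x0, x1, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
  if (length(x0) < 2L || length(x1) < 2L)
    stop("each group needs at least 2 non-missing values")
  x <- matrix(c(x0, x1), nrow = 1)
  res <- row_t(row_group_moments(
    x, c(rep(0L, length(x0)), rep(1L, length(x1)))), variant)
  list(statistic = res$statistic[1], p_value = res$p_value[1], df = res$df[1])
}

# ---- result-table plumbing ------------------------------------------------

dv_algorithms <- c("BT", "iEVORA", "DiffVar", "JDMDV", "GAMLSS", "TTEST")

# Assemble a dv_result table: attach q-values, direction, significance and
# ranks. `rank_p` is the P-value vector the ranking rule sorts on;
# `rank_within_significant` restricts ranks to the selected set (iEVORA,
# GAMLSS). Ties are broken by input feature order, so results are
# deterministic.
make_dv_result <- function(feature_ids, statistic, p_value, mean_diff,
                           algorithm, fdr, rank_p = p_value,
                           significant = NULL,
                           rank_within_significant = FALSE,
                           extra = NULL, pi0 = "auto") {
  qres <- qvalues(p_value, pi0 = pi0)
  q <- qres$q_values
  if (is.null(significant)) significant <- !is.na(q) & q < fdr
  direction <- ifelse(is.na(mean_diff) | mean_diff == 0, NA_character_,
                      ifelse(mean_diff > 0, "hyper", "hypo"))
  rank <- rep(NA_integer_, length(p_value))
  rankable <- if (rank_within_significant) significant & !is.na(rank_p)
              else !is.na(rank_p)
  if (any(rankable)) {
    ord <- order(rank_p[rankable], seq_len(sum(rankable)))
    rank[which(rankable)[ord]] <- seq_len(sum(rankable))
  }
  df <- data.frame(feature_id = feature_ids, statistic = statistic,
                   p_value = p_value, q_value = q, direction = direction,
                   significant = significant, rank = rank,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) df <- cbind(df, as.data.frame(extra))
  structure(df, class = c("dv_result", "data.frame"),
            algorithm = algorithm, fdr = fdr, pi0 = qres$pi0)
}

#' @export
print.dv_result <- function(x, ...) {
  cat("dv_result:", attr(x, "algorithm"), "-", nrow(x), "features,",
      sum(x$significant, na.rm = TRUE), "significant at FDR <",
      attr(x, "fdr"), "(pi0 =", format(attr(x, "pi0"), digits = 3), ")\n")
  utils::head(as.data.frame(x)[order(x$rank, na.last = TRUE), ], 6) |> print()
  invisible(x)
}

#' Write / read a DV result table as TSV
#'
#' @param result A `dv_result` from one of the `run_*` functions.
#' @param path Output path. Provenance (algorithm, FDR threshold, pi0)
#'   is written as `#`-prefixed comment lines.
#' @return `write_dv_result` invisibly returns `result`;
#'   `read_dv_result` returns the table (a `dv_result`).
#' @export
write_dv_result <- function(result, path) {
  stopifnot(inherits(result, "dv_result"))
  hdr <- c(paste0("# algorithm=", attr(result, "algorithm")),
           paste0("# fdr=", attr(result, "fdr")),
           paste0("# pi0=", format(attr(result, "pi0"), digits = 10)))
  df <- as.data.frame(result)
  body <- c(paste(colnames(df), collapse = "\t"),
            do.call(paste, c(lapply(df, function(col) {
              if (is.numeric(col)) ifelse(is.na(col), "NA", sprintf("%.10g", col))
              else ifelse(is.na(col), "NA", as.character(col))
            }), sep = "\t")))
  write_atomically(c(hdr, body), path)
  invisible(result)
}

#' @rdname write_dv_result
#' @export
read_dv_result <- function(path) {
  hdr <- character(0)
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(hit)) sub(paste0("^# ", key, "="), "", hit[1]) else default
  }
  structure(df, class = c("dv_result", "data.frame"),
            algorithm = meta("algorithm", NA),
            fdr = as.numeric(meta("fdr", NA)),
            pi0 = as.numeric(meta("pi0", NA)))
}

# ---- the six algorithms ---------------------------------------------------

#' Bartlett's test over all features (BT)
#'
#' Per-feature two-group Bartlett test on beta values; P-values are
#' converted to q-values and features ranked by ascending Bartlett
#' P-value. Degenerate features (zero within-group variance or < 3
#' values in a group) get missing rows and are excluded from the FDR
#' estimation.
#'
#' @param ds A [methylation_dataset()].
#' @param fdr FDR (q-value) significance threshold, default 0.05.
#' @return A `dv_result` table.
#' @export
run_bt <- function(ds, fdr = 0.05) {
  stopifnot(inherits(ds, "methylation_dataset"))
  mom <- row_group_moments(ds$values, ds$group)
  bt <- row_bartlett(mom)
  make_dv_result(ds$feature_ids, bt$statistic, bt$p_value,
                 mom$mean1 - mom$mean0, "BT", fdr)
}

#' iEVORA: Bartlett significance with differential-mean re-ranking
#'
#' Two-stage DV feature selection: (1) per-feature Bartlett tests on beta
#' values are converted to q-values and features with q below `bt_fdr`
#' are selected; (2) the selected features are re-ranked by ascending
#' t-test P-value, so that among significantly differentially variable
#' sites those with larger mean methylation shifts rise to the top and
#' sites driven by one or two outliers sink. Significance is thus decided
#' at the level of variance, ranking at the level of means. The selected
#' set is identical to [run_bt()]'s at the same threshold; only the
#' ordering differs.
#'
#' @inheritParams run_bt
#' @param bt_fdr FDR threshold applied to the Bartlett q-values.
#' @param t_variant t-test flavour for re-ranking; Welch by default
#'   (differentially variable sites have unequal variances by
#'   construction).
#' @return A `dv_result`: `statistic`/`p_value`/`q_value` are the
#'   Bartlett quantities, `t_stat`/`t_p` the re-ranking t quantities;
#'   `rank` covers only the selected features. An empty selected set is a
#'   valid result with all ranks `NA`.
#' @export
run_ievora <- function(ds, bt_fdr = 0.05, t_variant = c("welch", "pooled")) {
  stopifnot(inherits(ds, "methylation_dataset"))
  t_variant <- match.arg(t_variant)
  mom <- row_group_moments(ds$values, ds$group)
  bt <- row_bartlett(mom)
  tt <- row_t(mom, t_variant)
  make_dv_result(ds$feature_ids, bt$statistic, bt$p_value,
                 mom$mean1 - mom$mean0, "iEVORA", bt_fdr,
                 rank_p = tt$p_value, rank_within_significant = TRUE,
                 extra = list(t_stat = tt$statistic, t_p = tt$p_value))
}

#' DiffVar-type empirical-Bayes Levene test
#'
#' Works on M-values: per feature the absolute (or squared) deviations of
#' each sample from its own group mean are computed, and the two groups'
#' deviations are compared with a moderated two-sample t-test whose
#' per-feature variances are squeezed towards an empirical-Bayes prior
#' fitted across all features ([fit_variance_prior()]). Because a few
#' outliers inflate the deviation variance as much as the deviation mean,
#' this test is robust to — and correspondingly insensitive to —
#' outlier-driven (type-2) differential variability.
#'
#' @inheritParams run_bt
#' @param deviation `"absolute"` (default; more outlier-robust) or
#'   `"squared"` deviations from the group mean.
#' @param clip_epsilon Beta clipping for the M-value transform.
#' @param prior Optional `variance_prior` override (e.g. `d0 = 0` for the
#'   ordinary Levene t).
#' @return A `dv_result`; `direction` reflects the M-value mean
#'   difference of the underlying feature.
#' @export
run_diffvar <- function(ds, fdr = 0.05, deviation = c("absolute", "squared"),
                        clip_epsilon = 0.001, prior = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  deviation <- match.arg(deviation)
  m <- m_values(ds, clip_epsilon)
  mom <- row_group_moments(m, ds$group)
  ctr <- ifelse(outer(rep(1, nrow(m)), ds$group) == 1, mom$mean1, mom$mean0)
  z <- m - ctr
  z <- if (deviation == "absolute") abs(z) else z * z
  res <- row_moderated_t(z, ds$group, prior = prior)
  make_dv_result(ds$feature_ids, res$statistic, res$p_value,
                 mom$mean1 - mom$mean0, "DiffVar", fdr,
                 extra = list(z_diff = res$mean_diff))
}

#' Joint mean/variance score test (J-DMDV style)
#'
#' Works on M-values: per feature a 2-df score test of no group effect on
#' the mean and no group effect on the variance in the heteroscedastic
#' regression y = mu + beta x + eps, Var(eps) = sigma^2 exp(gamma x).
#' The default studentizes the variance score by the empirical variance
#' of the squared residuals (a Koenker-type robust score test), which
#' keeps the type-1 error controlled for non-Gaussian methylation data
#' and deliberately discounts outlier-driven variance signal;
#' `information = "expected"` uses the Gaussian expected information
#' instead.
#'
#' @inheritParams run_diffvar
#' @param information `"robust"` (default) or `"expected"`.
#' @return A `dv_result` with the chi-square(2) statistic; extras
#'   `stat_mean` and `stat_var` give the two 1-df components.
#' @export
run_jdmdv <- function(ds, fdr = 0.05, clip_epsilon = 0.001,
                      information = c("robust", "expected")) {
  stopifnot(inherits(ds, "methylation_dataset"))
  information <- match.arg(information)
  m <- m_values(ds, clip_epsilon)
  res <- row_jdmdv(m, ds$group, information)
  make_dv_result(ds$feature_ids, res$statistic, res$p_value, res$mean_diff,
                 "JDMDV", fdr,
                 extra = list(stat_mean = res$stat_mean,
                              stat_var = res$stat_var))
}

#' Nested Gaussian location-scale likelihood-ratio test (GAMLSS style)
#'
#' Works on M-values: three nested Gaussian fits per feature — common
#' mean/common variance, group means/common variance, group means/group
#' variances — yield two 1-df likelihood-ratio tests: `p_mean` (does the
#' phenotype shift the mean?) and `p_dv` (does the variance add signal
#' over the mean?). Each P-value set is converted to q-values separately;
#' a feature is significant if either q-value is below `fdr`, and the
#' selected features are ranked by ascending DV P-value. No
#' variance-only-versus-null comparison is made.
#'
#' @inheritParams run_diffvar
#' @return A `dv_result`: `statistic`/`p_value`/`q_value` are the DV
#'   (variance) quantities; extras `lrt_mean`, `p_mean`, `q_mean`.
#' @export
run_gamlss_ls <- function(ds, fdr = 0.05, clip_epsilon = 0.001) {
  stopifnot(inherits(ds, "methylation_dataset"))
  m <- m_values(ds, clip_epsilon)
  mom <- row_group_moments(m, ds$group)
  g <- row_gamlss(mom)
  q_mean <- qvalues(g$p_mean)$q_values
  q_dv <- qvalues(g$p_var)$q_values
  sig <- (!is.na(q_mean) & q_mean < fdr) | (!is.na(q_dv) & q_dv < fdr)
  make_dv_result(ds$feature_ids, g$lrt_var, g$p_var,
                 mom$mean1 - mom$mean0, "GAMLSS", fdr,
                 significant = sig, rank_within_significant = TRUE,
                 extra = list(lrt_mean = g$lrt_mean, p_mean = g$p_mean,
                              q_mean = q_mean))
}

#' Moderated t-test baseline (differential means)
#'
#' Per-feature moderated two-sample t on beta values: the differential
#' *mean* methylation baseline against which the DV algorithms are
#' compared. Uses the same empirical-Bayes variance squeezing as
#' [run_diffvar()], applied directly to the beta values.
#'
#' @inheritParams run_bt
#' @param prior Optional `variance_prior` override.
#' @return A `dv_result` ranked by ascending P-value.
#' @export
run_ttest_dmc <- function(ds, fdr = 0.05, prior = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  res <- row_moderated_t(ds$values, ds$group, prior = prior)
  make_dv_result(ds$feature_ids, res$statistic, res$p_value, res$mean_diff,
                 "TTEST", fdr)
}

#' Run one DV algorithm by name
#'
#' Dispatch helper used by the command-line interface and the benchmark.
#'
#' @param ds A [methylation_dataset()].
#' @param algorithm One of `"bt"`, `"ievora"`, `"diffvar"`, `"jdmdv"`,
#'   `"gamlss"`, `"ttest"` (case-insensitive).
#' @param fdr FDR threshold.
#' @param ... Passed to the specific `run_*` function.
#' @return A `dv_result`.
#' @export
run_dv_test <- function(ds, algorithm, fdr = 0.05, ...) {
  switch(tolower(algorithm),
         bt = run_bt(ds, fdr),
         ievora = run_ievora(ds, bt_fdr = fdr, ...),
         diffvar = run_diffvar(ds, fdr, ...),
         jdmdv = run_jdmdv(ds, fdr, ...),
         gamlss = run_gamlss_ls(ds, fdr, ...),
         ttest = run_ttest_dmc(ds, fdr, ...),
         stop("unknown algorithm: ", algorithm))
}
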