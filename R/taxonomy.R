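#' Classify a DV site into the type-1a / type-1b / type-2 taxonomy
#'
#' Decision rules applied to Bartlett-significant sites: a site is not a
#' DVC at all if its Bartlett q-value is at or above the FDR threshold;
#' otherwise it is type-2 if the t-test P-value is not significant
#' (t_p > t_alpha, i.e. differential variance with no detectable mean
#' shift — outlier-driven), type-1a if the t-test P-value is more
#' significant (strictly smaller) than the Bartlett P-value
#' (mean-dominated DV), and type-1b otherwise (variance-dominated DV
#' with a real mean shift). Boundary conventions: t_p exactly equal to
#' t_alpha counts as significant (type-1); t_p exactly equal to bt_p
#' falls to type-1b.
#'
#' @param bt_p,bt_q Bartlett P-value and q-value.
#' @param t_p t-test P-value. All three vectorized.
#' @param fdr FDR threshold on `bt_q` (default 0.05).
#' @param t_alpha t-test significance level (default 0.05).
#' @return Factor with levels `not_dvc`, `type1a`, `type1b`, `type2`.
#' @export
classify_dv_type <- function(bt_p, bt_q, t_p, fdr = 0.05, t_alpha = 0.05) {
  n <- max(length(bt_p), length(bt_q), length(t_p))
  bt_p <- rep_len(bt_p, n); bt_q <- rep_len(bt_q, n); t_p <- rep_len(t_p, n)
  if (any(c(bt_p, bt_q, t_p) < 0 | c(bt_p, bt_q, t_p) > 1, na.rm = TRUE))
    stop("all P- and q-values must lie in [0, 1]")
  out <- rep(NA_character_, n)
  known <- !is.na(bt_q)
  out[known & bt_q >= fdr] <- "not_dvc"
  dvc <- known & bt_q < fdr & !is.na(t_p)
  out[dvc & t_p > t_alpha] <- "type2"
  out[dvc & t_p <= t_alpha & t_p < bt_p] <- "type1a"
  out[dvc & t_p <= t_alpha & t_p >= bt_p] <- "type1b"
  factor(out, levels = c("not_dvc", "type1a", "type1b", "type2"))
}

#' Classify all features of an iEVORA/BT result table
#'
#' Applies [classify_dv_type()] to a `dv_result` that carries both
#' Bartlett and t-test columns (i.e. from [run_ievora()]).
#'
#' @param result A `dv_result` with columns `p_value`, `q_value`, `t_p`.
#' @param fdr,t_alpha Thresholds, see [classify_dv_type()].
#' @return A data.frame with feature_id, bt_p, bt_q, t_p and `dv_type`.
#' @export
classify_dv_results <- function(result, fdr = attr(result, "fdr"),
                                t_alpha = 0.05) {
  stopifnot(inherits(result, "dv_result"))
  if (is.null(result$t_p))
    stop("result table has no t-test column; run run_ievora() first")
  data.frame(feature_id = result$feature_id,
             bt_p = result$p_value, bt_q = result$q_value,
             t_p = result$t_p,
             dv_type = classify_dv_type(result$p_value, result$q_value,
                                        result$t_p, fdr, t_alpha),
             stringsAsFactors = FALSE)
}

#' Relative fractions of DV types among called DVCs
#'
#' @param calls Factor/character vector of taxonomy calls (from
#'   [classify_dv_type()]) or a data.frame with a `dv_type` column.
#' @return List with `counts` (named, over type1a/type1b/type2),
#'   `fractions` (summing to 1; all `NA` when no DVCs were called) and
#'   `n_dvc`.
#' @export
taxonomy_summary <- function(calls) {
  if (is.data.frame(calls)) calls <- calls$dv_type
  if (!length(calls)) stop("empty call list")
  lv <- c("type1a", "type1b", "type2")
  calls <- factor(as.character(calls[!is.na(calls)]),
                  levels = c("not_dvc", lv))
  counts <- table(calls)[lv]
  n_dvc <- sum(counts)
  fractions <- if (n_dvc > 0) as.numeric(counts) / n_dvc
               else rep(NA_real_, 3L)
  names(fractions) <- lv
  list(counts = stats::setNames(as.integer(counts), lv),
       fractions = fractions, n_dvc = as.integer(n_dvc))
}
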