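#' Sensitivity and true FDR of one DV run against simulation truth
#'
#' The five benchmark measures for a single simulated dataset: overall
#' sensitivity (fraction of true DVCs called significant), per-type
#' sensitivities, and the true FDR (fraction of called features that are
#' ground-truth null) at the estimated-FDR threshold the result was run
#' with. FDR rather than FPR is reported because the FDR is what
#' determines the confidence that a given call is real (FDR = 1 - PPV).
#' An empty call set has true FDR 0 by convention, so that runs remain
#' averageable.
#'
#' @param result A `dv_result` (its `significant` column defines the
#'   call set; for GAMLSS this already encodes the either-q rule).
#' @param truth A `simulated_dataset` (or its `truth` factor aligned to
#'   the result's features).
#' @return A one-row data.frame: algorithm, n_significant,
#'   sensitivity_overall, sensitivity_type1a/_1b/_2, true_fdr.
#' @export
simulation_metrics <- function(result, truth) {
  stopifnot(inherits(result, "dv_result"))
  if (inherits(truth, "simulated_dataset")) {
    if (!identical(truth$dataset$feature_ids, result$feature_id))
      stop("result and truth feature sets do not match")
    truth <- truth$truth
  }
  truth <- factor(as.character(truth),
                  levels = c("null", "type1a", "type1b", "type2"))
  if (length(truth) != nrow(result))
    stop("truth labels and result rows differ in length")
  sig <- !is.na(result$significant) & result$significant
  sens <- function(type) {
    n <- sum(truth == type)
    if (n == 0) NA_real_ else sum(sig & truth == type) / n
  }
  n_sig <- sum(sig)
  true_pos <- sum(sig & truth != "null")
  n_true <- sum(truth != "null")
  data.frame(algorithm = attr(result, "algorithm"),
             n_significant = n_sig,
             sensitivity_overall = if (n_true) true_pos / n_true else NA_real_,
             sensitivity_type1a = sens("type1a"),
             sensitivity_type1b = sens("type1b"),
             sensitivity_type2 = sens("type2"),
             true_fdr = if (n_sig) sum(sig & truth == "null") / n_sig else 0,
             stringsAsFactors = FALSE)
}

#' Monte-Carlo benchmark of DV algorithms on simulated data
#'
#' Repeats [simulate_dataset()] with seeds `base_seed`, `base_seed + 1`,
#' ..., runs every requested algorithm on each dataset, and collects the
#' five performance measures per run. Identical `base_seed` gives
#' bit-reproducible results.
#'
#' @param config A [sim_config()] describing the study conditions.
#' @param algorithms Character vector of algorithm names understood by
#'   [run_dv_test()].
#' @param n_runs Number of Monte-Carlo runs.
#' @param base_seed First seed.
#' @param fdr FDR threshold passed to every algorithm.
#' @param ... Extra arguments passed on to [run_dv_test()].
#' @return A list of class `"dv_benchmark"`: `per_run` (data.frame of
#'   per-run measures with `run` and `seed` columns) and `summary`
#'   (mean and sd of each measure per algorithm).
#' @export
run_benchmark <- function(config = sim_config(),
                          algorithms = c("bt", "ievora", "diffvar",
                                         "jdmdv", "gamlss"),
                          n_runs = 100, base_seed = 1, fdr = 0.05, ...) {
  stopifnot(n_runs >= 1)
  rows <- vector("list", n_runs * length(algorithms))
  k <- 0L
  for (r in seq_len(n_runs)) {
    seed <- base_seed + r - 1L
    sim <- simulate_dataset(config, seed = seed)
    for (alg in algorithms) {
      k <- k + 1L
      row <- tryCatch(
        cbind(run = r, seed = seed,
              simulation_metrics(run_dv_test(sim$dataset, alg, fdr, ...), sim)),
        error = function(err) {
          warning("run ", r, ", algorithm ", alg, " failed: ",
                  conditionMessage(err))
          NULL
        })
      rows[[k]] <- row
    }
  }
  per_run <- do.call(rbind, rows)
  measures <- c("sensitivity_overall", "sensitivity_type1a",
                "sensitivity_type1b", "sensitivity_type2", "true_fdr")
  summ <- do.call(rbind, lapply(split(per_run, per_run$algorithm), function(d) {
    means <- colMeans(d[measures], na.rm = TRUE)
    sds <- vapply(d[measures], stats::sd, numeric(1), na.rm = TRUE)
    data.frame(algorithm = d$algorithm[1], n_runs = nrow(d),
               measure = measures, mean = unname(means), sd = unname(sds),
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(per_run = per_run, summary = summ, config = config,
                 fdr = fdr),
            class = "dv_benchmark")
}

#' @export
print.dv_benchmark <- function(x, ...) {
  cat("dv_benchmark:", length(unique(x$per_run$algorithm)), "algorithms x",
      max(x$per_run$run), "runs, FDR <", x$fdr, "\n")
  wide <- stats::reshape(x$summary[c("algorithm", "measure", "mean")],
                         idvar = "algorithm", timevar = "measure",
                         direction = "wide")
  colnames(wide) <- sub("^mean\\.", "", colnames(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a benchmark summary to TSV
#'
#' One row per algorithm x measure with mean and sd, plus `#` provenance
#' lines.
#'
#' @param bench A `dv_benchmark`.
#' @param path Output path.
#' @param header Optional extra provenance lines.
#' @return Invisibly, `bench`.
#' @export
write_benchmark <- function(bench, path, header = NULL) {
  stopifnot(inherits(bench, "dv_benchmark"))
  s <- bench$summary
  lines <- c(paste0("# ", c(header,
                            paste0("fdr=", bench$fdr),
                            paste0("n_runs=", max(bench$per_run$run)))),
             "algorithm\tmeasure\tmean\tsd",
             paste(s$algorithm, s$measure, sprintf("%.10g", s$mean),
                   sprintf("%.10g", s$sd), sep = "\t"))
  write_atomically(lines, path)
  invisible(bench)
}

#' Progression PPV of a ranked discovery list in a validation dataset
#'
#' For the top `top_k` ranked discovery features (optionally restricted
#' to one discovery direction), computes a per-feature two-sample
#' validation t-statistic (group 1 vs group 0, beta values) and reports
#' the fraction whose t-statistic exceeds `t_threshold` in the discovery
#' direction (t > 1.96 for hyper, t < -1.96 for hypo; for
#' `direction = "both"` each feature is checked against its own
#' discovery direction). No multiple-testing correction is applied to
#' the validation t-statistics: at this stage controlling the false
#' negative rate matters more, and the same criterion is applied to
#' every algorithm being compared.
#'
#' @param discovery A ranked `dv_result` from the discovery dataset.
#' @param validation A [methylation_dataset()] with both group labels.
#' @param top_k How many top-ranked features to evaluate.
#' @param direction `"hyper"`, `"hypo"`, or `"both"`.
#' @param t_threshold Validation t threshold (default 1.96, i.e.
#'   P < 0.05).
#' @param t_variant t-test flavour for the validation statistics.
#' @return A list of class `"ppv_report"`: `ppv`, `n_evaluated`,
#'   `top_k`, `direction`, `t_threshold` and a per-feature data.frame
#'   `features` (feature_id, discovery rank/direction, validation t,
#'   validated flag).
#' @export
progression_ppv <- function(discovery, validation, top_k = 500,
                            direction = c("hyper", "hypo", "both"),
                            t_threshold = 1.96,
                            t_variant = c("welch", "pooled")) {
  stopifnot(inherits(discovery, "dv_result"),
            inherits(validation, "methylation_dataset"))
  direction <- match.arg(direction)
  t_variant <- match.arg(t_variant)
  ranked <- discovery[!is.na(discovery$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  if (direction != "both")
    ranked <- ranked[!is.na(ranked$direction) & ranked$direction == direction, ,
                     drop = FALSE]
  if (!nrow(ranked)) {
    warning("empty ranked set; PPV undefined")
    return(structure(list(ppv = NA_real_, n_evaluated = 0L, top_k = top_k,
                          direction = direction, t_threshold = t_threshold,
                          features = NULL), class = "ppv_report"))
  }
  if (top_k > nrow(ranked)) {
    warning("top_k (", top_k, ") exceeds ranked set size (", nrow(ranked),
            "); using all ranked features")
    top_k <- nrow(ranked)
  }
  top <- ranked[seq_len(top_k), , drop = FALSE]
  present <- top$feature_id %in% validation$feature_ids
  if (any(!present))
    message(sum(!present), " top-ranked features absent from validation matrix; excluded")
  top <- top[present, , drop = FALSE]
  if (!nrow(top))
    return(structure(list(ppv = NA_real_, n_evaluated = 0L, top_k = top_k,
                          direction = direction, t_threshold = t_threshold,
                          features = NULL), class = "ppv_report"))
  sub <- validation$values[match(top$feature_id, validation$feature_ids), ,
                           drop = FALSE]
  tt <- row_t(row_group_moments(sub, validation$group), t_variant)
  want <- if (direction == "both") top$direction else
    rep(direction, nrow(top))
  validated <- ifelse(want == "hyper", tt$statistic > t_threshold,
                      tt$statistic < -t_threshold)
  validated[is.na(validated)] <- FALSE
  structure(list(ppv = mean(validated), n_evaluated = nrow(top),
                 top_k = top_k, direction = direction,
                 t_threshold = t_threshold,
                 features = data.frame(feature_id = top$feature_id,
                                       rank = top$rank,
                                       discovery_direction = top$direction,
                                       t_validation = tt$statistic,
                                       validated = validated,
                                       stringsAsFactors = FALSE)),
            class = "ppv_report")
}

#' @export
print.ppv_report <- function(x, ...) {
  cat("ppv_report: PPV =", format(x$ppv, digits = 3), "over",
      x$n_evaluated, "features (direction", x$direction, ", |t| >",
      x$t_threshold, ")\n")
  invisible(x)
}
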