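#' Simulation configuration for the beta-mixture DV generator
#'
#' Encodes the two-phenotype beta-mixture design used throughout the
#' benchmark: a matrix of CpGs whose null distribution is Beta(a1, b1)
#' (default shape 10, 90: mean beta 0.1, sd ~0.03, i.e. a typically
#' unmethylated CpG), with a subset of truly differentially variable
#' CpGs whose altered disease samples are drawn from Beta(a2, b2)
#' (default 6, 4: mean 0.6, sd ~0.15), an average methylation gain of
#' ~0.5. The true DVCs split into three types by how many of the
#' disease samples are altered: type-1a (all), type-1b
#' (`n_altered_type1b`, default 20 of 50), type-2 (`n_altered_type2`,
#' default 3 — pure outlier-driven differential variance).
#'
#' @param n_features Total CpGs (default 6000).
#' @param n_samples_per_group Samples per phenotype (default 50).
#' @param n_true_per_type True DVCs of each type (default 200; the
#'   remaining features are null).
#' @param a1,b1 Null beta shape parameters (default 10, 90).
#' @param a2,b2 Altered beta shape parameters (default 6, 4).
#' @param n_altered_type1b,n_altered_type2 Altered disease samples per
#'   type-1b / type-2 feature (defaults 20 and 3).
#' @param direction `"hyper"` (default) simulates methylation gains;
#'   `"hypo"` mirrors the design (altered draws are 1 - Beta(a2, b2)),
#'   for testing direction handling. The two are statistically
#'   symmetric.
#' @param seed Optional integer seed; may also be supplied at
#'   [simulate_dataset()] time.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_features = 6000, n_samples_per_group = 50,
                       n_true_per_type = 200, a1 = 10, b1 = 90,
                       a2 = 6, b2 = 4, n_altered_type1b = 20,
                       n_altered_type2 = 3,
                       direction = c("hyper", "hypo"), seed = NULL) {
  direction <- match.arg(direction)
  cfg <- list(n_features = as.integer(n_features),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_true_per_type = as.integer(n_true_per_type),
              a1 = a1, b1 = b1, a2 = a2, b2 = b2,
              n_altered_type1b = as.integer(n_altered_type1b),
              n_altered_type2 = as.integer(n_altered_type2),
              direction = direction, seed = seed)
  if (any(c(cfg$a1, cfg$b1, cfg$a2, cfg$b2) <= 0))
    stop("beta shape parameters must be positive")
  if (3L * cfg$n_true_per_type > cfg$n_features)
    stop("3 * n_true_per_type must not exceed n_features")
  if (!(cfg$n_altered_type2 <= cfg$n_altered_type1b &&
        cfg$n_altered_type1b <= cfg$n_samples_per_group))
    stop("need n_altered_type2 <= n_altered_type1b <= n_samples_per_group")
  if (cfg$n_samples_per_group < 3L)
    stop("need at least 3 samples per group")
  structure(cfg, class = "sim_config")
}

#' Theoretical mean and standard deviation of a beta distribution
#'
#' mean = a/(a+b), sd = sqrt(ab / ((a+b)^2 (a+b+1))). With the default
#' generator shapes: Beta(10, 90) has mean 0.1 and sd ~0.03; Beta(6, 4)
#' has mean 0.6 and sd ~0.15.
#'
#' @param a,b Positive shape parameters.
#' @return Named numeric vector `c(mean =, sd =)`.
#' @examples
#' theoretical_moments(10, 90)
#' @export
theoretical_moments <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(a <= 0) || any(b <= 0))
    stop("shape parameters must be positive")
  c(mean = a / (a + b),
    sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
}

#' Generate a synthetic methylation dataset with ground-truth DV labels
#'
#' Draws the matrix described by a [sim_config()]: all normal-group
#' values and all null features come from Beta(a1, b1); for each true DV
#' feature a type-dependent subset of the disease samples is drawn from
#' Beta(a2, b2) instead (all samples for type-1a, `n_altered_type1b`
#' for type-1b, `n_altered_type2` for type-2). Altered-sample subsets
#' are redrawn independently for every feature. Truth labels are
#' assigned deterministically by feature index (first the type-1a block,
#' then 1b, then 2, then nulls), so two datasets generated from configs
#' that agree on the counts share their truth labels — the basis of the
#' two-stage discovery/validation design.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling all randomness through one
#'   generator stream; overrides `config$seed`. Identical seeds give
#'   bit-identical datasets.
#' @return A list of class `"simulated_dataset"`: `dataset` (a
#'   [methylation_dataset()], disease group = 1), `truth` (factor with
#'   levels null/type1a/type1b/type2 per feature), `altered_samples`
#'   (list of disease-sample indices drawn from the altered
#'   distribution, per feature), and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ns <- config$n_samples_per_group
  nf <- config$n_features
  nt <- config$n_true_per_type
  truth <- factor(rep(c("type1a", "type1b", "type2", "null"),
                      c(nt, nt, nt, nf - 3L * nt)),
                  levels = c("null", "type1a", "type1b", "type2"))
  # start from an all-null matrix, then overwrite altered disease cells
  values <- matrix(stats::rbeta(nf * 2L * ns, config$a1, config$b1),
                   nrow = nf, ncol = 2L * ns)
  group <- rep(c(0L, 1L), each = ns)
  disease_cols <- which(group == 1L)
  n_altered <- c(type1a = ns, type1b = config$n_altered_type1b,
                 type2 = config$n_altered_type2)
  altered_samples <- vector("list", nf)
  for (i in seq_len(3L * nt)) {
    k <- n_altered[[as.character(truth[i])]]
    pick <- if (k == ns) seq_len(ns) else sort(sample.int(ns, k))
    values[i, disease_cols[pick]] <- stats::rbeta(k, config$a2, config$b2)
    altered_samples[[i]] <- pick
  }
  # hypomethylation mirrors the whole design: unmethylated and methylated
  # CpGs are symmetric under beta -> 1 - beta
  if (config$direction == "hypo") values <- 1 - values
  ids <- sprintf("cg%06d", seq_len(nf))
  ds <- methylation_dataset(values, group, feature_ids = ids,
                            sample_ids = c(sprintf("N%03d", seq_len(ns)),
                                           sprintf("D%03d", seq_len(ns))))
  structure(list(dataset = ds, truth = truth,
                 altered_samples = altered_samples, config = config),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat("simulated_dataset:", x$config$n_features, "features x",
      2L * x$config$n_samples_per_group, "samples\n")
  print(table(x$truth))
  invisible(x)
}

#' Write the ground-truth labels of a simulated dataset to TSV
#'
#' Columns: feature_id, label, n_altered (number of disease samples drawn
#' from the altered distribution; 0 for null features).
#'
#' @param sim A `simulated_dataset`.
#' @param path Output path.
#' @param header Optional `#`-prefixed provenance lines.
#' @return Invisibly, `sim`.
#' @export
write_truth <- function(sim, path, header = NULL) {
  stopifnot(inherits(sim, "simulated_dataset"))
  n_alt <- vapply(sim$altered_samples,
                  function(a) if (is.null(a)) 0L else length(a), integer(1))
  lines <- c(if (length(header)) paste0("# ", header),
             "feature_id\tlabel\tn_altered",
             paste(sim$dataset$feature_ids, as.character(sim$truth), n_alt,
                   sep = "\t"))
  write_atomically(lines, path)
  invisible(sim)
}
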