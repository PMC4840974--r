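#' Construct a methylation dataset
#'
#' Bundles a beta-value matrix (features x samples) with a binary phenotype
#' vector into a validated container used by all DV tests. Beta values are
#' DNAm fractions and must lie in \[0, 1\]; missing entries (`NA`) are
#' allowed and are dropped per feature per group by the tests.
#'
#' @param values Numeric matrix of beta values, features in rows, samples in
#'   columns. `dimnames` supply feature and sample IDs unless given
#'   explicitly.
#' @param group Integer/numeric vector of 0/1 phenotype labels, one per
#'   sample. 0 is the reference (normal) phenotype, 1 the disease/at-risk
#'   phenotype; all hyper/hypo direction calls are group 1 relative to
#'   group 0.
#' @param feature_ids,sample_ids Optional character vectors of unique IDs;
#'   default to the matrix `dimnames`.
#' @return An object of class `"methylation_dataset"`: a list with elements
#'   `values`, `group`, `feature_ids`, `sample_ids`.
#' @examples
#' beta <- matrix(runif(20, 0.05, 0.15), 4, 5,
#'                dimnames = list(paste0("cg", 1:4), paste0("s", 1:5)))
#' ds <- methylation_dataset(beta, group = c(0, 0, 0, 1, 1))
#' ds
#' @export
methylation_dataset <- function(values, group, feature_ids = rownames(values),
                                sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)")
  if (is.null(feature_ids))
    feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids))
    sample_ids <- paste0("s", seq_len(ncol(values)))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values))
    stop("feature_ids length does not match number of rows")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length does not match number of columns")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs: ",
         paste(unique(feature_ids[duplicated(feature_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  group <- as.integer(group)
  if (length(group) != ncol(values))
    stop("`group` length (", length(group), ") does not match number of samples (",
         ncol(values), ")")
  if (!all(group %in% c(0L, 1L)))
    stop("`group` must contain only 0 (reference) and 1 (disease) labels")
  if (length(unique(group)) < 2L)
    stop("both group labels (0 and 1) must be present")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    stop("beta values outside [0,1]: first offender feature '",
         feature_ids[ij[1]], "', sample '", sample_ids[ij[2]], "' (value ",
         format(values[bad[1]]), ")")
  }
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, group = group,
                 feature_ids = feature_ids, sample_ids = sample_ids),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat("methylation_dataset:", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  cat("  group 0 (reference):", sum(x$group == 0L),
      " group 1 (disease):", sum(x$group == 1L), "\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat("  missing entries:", nmiss, "\n")
  invisible(x)
}

#' @export
dim.methylation_dataset <- function(x) dim(x$values)

#' Convert beta values to M-values
#'
#' The M-value is the logit2 transform M = log2(beta / (1 - beta)), the
#' variance-stabilized scale on which the Levene-type, joint score and
#' location-scale DV tests operate. Beta values are clipped into
#' \[`clip_epsilon`, 1 - `clip_epsilon`\] first so that saturated probes
#' (beta of exactly 0 or 1) map to finite M-values.
#'
#' @param beta Numeric vector/matrix of beta values in \[0, 1\]; `NA`
#'   allowed.
#' @param clip_epsilon Clipping bound in (0, 0.5); the default 0.001 limits
#'   M-values to about +/- 9.97.
#' @return Object of the same shape with finite M-values (`NA` preserved).
#' @seealso [m_to_beta()] for the inverse.
#' @examples
#' beta_to_m(c(0.5, 0.8, 0.1))
#' @export
beta_to_m <- function(beta, clip_epsilon = 0.001) {
  if (!is.numeric(clip_epsilon) || length(clip_epsilon) != 1L ||
      clip_epsilon <= 0 || clip_epsilon >= 0.5)
    stop("`clip_epsilon` must be a single number in (0, 0.5)")
  if (any(!is.na(beta) & (beta < 0 | beta > 1)))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, clip_epsilon), 1 - clip_epsilon)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' Inverse logit2: beta = 2^M / (1 + 2^M). Exact inverse of [beta_to_m()]
#' for beta inside the clipped range; saturates smoothly towards 0/1 for
#' large |M|.
#'
#' @param m Numeric vector/matrix of M-values.
#' @return Beta values in (0, 1) of the same shape.
#' @examples
#' m_to_beta(beta_to_m(0.3))
#' @export
m_to_beta <- function(m) {
  # plogis is 1/(1+exp(-x)); exact tails, avoids 2^m overflow
  stats::plogis(m * log(2))
}

#' Extract the M-value matrix of a dataset
#'
#' @param ds A [methylation_dataset()].
#' @param clip_epsilon Passed to [beta_to_m()].
#' @return Numeric matrix of M-values with the dataset's dimnames.
#' @export
m_values <- function(ds, clip_epsilon = 0.001) {
  stopifnot(inherits(ds, "methylation_dataset"))
  beta_to_m(ds$values, clip_epsilon)
}

#' Read a beta matrix and phenotype file into a dataset
#'
#' The matrix file is tab-separated with a header row of sample IDs and a
#' first column of feature IDs; `NA` is the missing token. The phenotype
#' file is two-column tab-separated (sample_id, group) with group in
#' \{0, 1\}; it may list samples in any order and is reconciled to the
#' matrix column order. Every matrix sample must appear in the phenotype
#' file.
#'
#' @param matrix_path,phenotype_path Paths to the two TSV files.
#' @param clip_epsilon Retained on the dataset for downstream M-value
#'   conversion (not applied at load time).
#' @return A [methylation_dataset()].
#' @seealso [write_dataset()]
#' @export
load_dataset <- function(matrix_path, phenotype_path, clip_epsilon = 0.001) {
  for (p in c(matrix_path, phenotype_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", comment.char = "#",
                           quote = "")
  if (ncol(tab) < 2L) stop("matrix file has no sample columns: ", matrix_path)
  feature_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw) & !(raw %in% c("NA", "", "na", "NaN")))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(raw))
    stop("non-numeric cell '", raw[bad[1]], "' at feature '",
         feature_ids[ij[1]], "', sample '", sample_ids[ij[2]], "' in ",
         matrix_path)
  }
  ph <- utils::read.table(phenotype_path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "#",
                          colClasses = c("character", "integer"),
                          col.names = c("sample_id", "group"))
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample IDs in phenotype file: ", phenotype_path)
  missing_ph <- setdiff(sample_ids, ph$sample_id)
  if (length(missing_ph))
    stop("samples missing from phenotype file: ",
         paste(missing_ph, collapse = ", "))
  group <- ph$group[match(sample_ids, ph$sample_id)]
  methylation_dataset(num, group, feature_ids = feature_ids,
                      sample_ids = sample_ids)
}

#' Write a dataset to matrix + phenotype TSV files
#'
#' Inverse of [load_dataset()]: values are written with full precision
#' (format `%.17g`) so that a write/load round trip is bit-exact for finite
#' entries and preserves missingness (`NA`).
#'
#' @param ds A [methylation_dataset()].
#' @param matrix_path,phenotype_path Output paths.
#' @param header Optional character vector of provenance comment lines
#'   (written prefixed with `#`).
#' @return Invisibly, `ds`.
#' @export
write_dataset <- function(ds, matrix_path, phenotype_path, header = NULL) {
  stopifnot(inherits(ds, "methylation_dataset"))
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  lines <- c(
    if (length(header)) paste0("# ", header),
    paste(c("feature_id", ds$sample_ids), collapse = "\t"),
    vapply(seq_len(nrow(ds$values)), function(i)
      paste(c(ds$feature_ids[i], fmt(ds$values[i, ])), collapse = "\t"),
      character(1)))
  write_atomically(lines, matrix_path)
  ph <- c(if (length(header)) paste0("# ", header),
          "sample_id\tgroup",
          paste(ds$sample_ids, ds$group, sep = "\t"))
  write_atomically(ph, phenotype_path)
  invisible(ds)
}

# Write lines via a temp file in the destination directory, then rename.
write_atomically <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}
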