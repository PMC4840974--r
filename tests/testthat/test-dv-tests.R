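test_that("bartlett_test matches the independent reference on random instances", {
  set.seed(10)
  for (i in 1:200) {
    n0 <- sample(3:30, 1); n1 <- sample(3:30, 1)
    x0 <- rnorm(n0, sd = runif(1, 0.2, 3))
    x1 <- rnorm(n1, sd = runif(1, 0.2, 3))
    mine <- bartlett_test(x0, x1)
    ref <- stats::bartlett.test(list(x0, x1))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("bartlett_test basic properties and degeneracies", {
  x <- c(1, 2, 3, 4, 5)
  same <- bartlett_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- bartlett_test(x, 2 * x)
  b <- bartlett_test(10 * x, 20 * x)     # scale invariance
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_gte(a$statistic, 0)
  # zero variance in one or both groups is degenerate, not an error
  d <- bartlett_test(rep(1, 5), x)
  expect_true(d$degenerate)
  expect_true(is.na(d$p_value))
  expect_true(bartlett_test(rep(1, 5), rep(2, 4))$degenerate)
  expect_error(bartlett_test(c(1, 2), x), "at least 3")
})

test_that("two_sample_t matches t.test for both variants and is antisymmetric", {
  set.seed(12)
  for (i in 1:200) {
    n0 <- sample(2:25, 1); n1 <- sample(2:25, 1)
    x0 <- rnorm(n0); x1 <- rnorm(n1, 0.3)
    w <- two_sample_t(x0, x1, "welch")
    ref <- stats::t.test(x1, x0)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-8)
    p <- two_sample_t(x0, x1, "pooled")
    refp <- stats::t.test(x1, x0, var.equal = TRUE)
    expect_equal(p$statistic, unname(refp$statistic), tolerance = 1e-10)
    expect_equal(p$p_value, refp$p.value, tolerance = 1e-10)
  }
  x0 <- c(0.1, 0.1, 0.1, 0.1, 0.2); x1 <- c(0.1, 0.6, 0.1, 0.1, 0.1)
  fl <- two_sample_t(x1, x0)
  fw <- two_sample_t(x0, x1)
  expect_equal(fl$statistic, -fw$statistic)   # antisymmetry
  expect_equal(fl$p_value, fw$p_value)
  expect_gt(fw$statistic, 0)                  # mean(x1) > mean(x0)
  id <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  # both groups constant and equal -> 0/1; constant but unequal -> NA
  expect_equal(two_sample_t(c(1, 1, 1), c(1, 1))$p_value, 1)
  expect_true(is.na(two_sample_t(c(1, 1, 1), c(2, 2))$statistic))
})

test_that("variance prior recovers simulated (d0, s0^2) and handles limits", {
  set.seed(20)
  d0 <- 4; s02 <- 1; df <- 30; nf <- 50000
  sg2 <- s02 * d0 / rchisq(nf, d0)          # true variances from the prior
  s2 <- sg2 * rchisq(nf, df) / df           # sample variances given truth
  fit <- fit_variance_prior(s2, df)
  expect_equal(fit$d0, d0, tolerance = 0.10)
  expect_equal(fit$s0_squared, s02, tolerance = 0.05)
  # all variances identical -> no excess dispersion -> d0 infinite; the
  # d0 = Inf scale estimate carries the chi-square log-bias correction
  flat <- fit_variance_prior(rep(2.5, 100), df = 10)
  expect_identical(flat$d0, Inf)
  expect_equal(flat$s0_squared, exp(log(2.5) - digamma(5) + log(5)),
               tolerance = 1e-9)
  # under-dispersed input also takes the d0 = Inf branch
  set.seed(21)
  tight <- fit_variance_prior(exp(rnorm(1000, 0, 0.001)), df = 5)
  expect_identical(tight$d0, Inf)
  expect_warning(fit_variance_prior(c(-1, rep(1.5, 50)), df = 10),
                 "non-positive")
  expect_error(suppressWarnings(fit_variance_prior(c(-1, 0), df = 10)),
               "no positive")
})

test_that("variance prior agrees with limma's empirical-Bayes squeeze", {
  skip_if_not_installed("limma")
  set.seed(22)
  df <- 40
  s2 <- (2 * 3 / rchisq(5000, 3)) * rchisq(5000, df) / df
  fit <- fit_variance_prior(s2, df)
  ref <- limma::squeezeVar(s2, df = df)
  expect_equal(fit$d0, ref$df.prior, tolerance = 0.05)
  expect_equal(fit$s0_squared, ref$var.prior, tolerance = 0.05)
})

test_that("run_bt ranks by Bartlett P and is stable under feature permutation", {
  ds <- null_beta_dataset(n_features = 40, n_per_group = 15, seed = 30)
  # inflate group-1 variance of one feature 100-fold (on the beta scale)
  i <- 7
  v <- ds$values
  g1 <- ds$group == 1
  v[i, g1] <- pmin(pmax(0.1 + (v[i, g1] - 0.1) * 10, 0), 1)
  ds2 <- methylation_dataset(v, ds$group, ds$feature_ids, ds$sample_ids)
  res <- run_bt(ds2)
  expect_equal(res$feature_id[which(res$rank == 1)], ds$feature_ids[i])
  expect_equal(res$rank[order(res$p_value)], seq_len(nrow(res)))
  # permuting features permutes rows but not per-feature values
  perm <- sample(nrow(v))
  resp <- run_bt(methylation_dataset(v[perm, ], ds$group,
                                     ds$feature_ids[perm], ds$sample_ids))
  m <- match(res$feature_id, resp$feature_id)
  expect_equal(resp$statistic[m], res$statistic)
  expect_equal(resp$p_value[m], res$p_value)
  expect_equal(resp$q_value[m], res$q_value)
})

test_that("iEVORA selects exactly the BT set and re-ranks by mean shift", {
  set.seed(31)
  sim <- simulate_dataset(small_sim_config(), seed = 31)
  bt <- run_bt(sim$dataset)
  iev <- run_ievora(sim$dataset)
  expect_identical(iev$significant, bt$significant)   # same selected set
  expect_identical(iev$p_value, bt$p_value)
  # ranks cover exactly the selected features, 1..k
  sel <- which(iev$significant)
  expect_setequal(iev$rank[sel], seq_along(sel))
  expect_true(all(is.na(iev$rank[-sel])))
  # among significant features, rank order follows ascending t P-value
  o <- sel[order(iev$rank[sel])]
  expect_true(all(diff(iev$t_p[o]) >= 0))
  # type-1a features (full-group shift) outrank type-2 (3 outliers)
  r1a <- iev$rank[sim$truth == "type1a"]
  r2 <- iev$rank[sim$truth == "type2"]
  expect_lt(median(r1a, na.rm = TRUE), median(r2, na.rm = TRUE))
  expect_gt(mean(rank(iev$t_p)[sim$truth == "type2"] >
                   max(rank(iev$t_p)[sim$truth == "type1a"])), 0.9)
})

test_that("iEVORA on a pure null dataset returns a valid empty ranking", {
  ds <- null_beta_dataset(n_features = 300, n_per_group = 20, seed = 32)
  res <- run_ievora(ds)
  expect_s3_class(res, "dv_result")
  expect_equal(sum(res$significant), 0)
  expect_true(all(is.na(res$rank)))
})

test_that("DiffVar reduces to the ordinary Levene t at d0 = 0 and handles flat rows", {
  ds <- null_beta_dataset(n_features = 60, n_per_group = 12, seed = 33)
  plain <- structure(list(d0 = 0, s0_squared = NA_real_),
                     class = "variance_prior")
  res0 <- run_diffvar(ds, prior = plain)
  # ordinary t on the absolute deviations, computed independently
  m <- m_values(ds)
  i <- 17
  z0 <- abs(m[i, ds$group == 0] - mean(m[i, ds$group == 0]))
  z1 <- abs(m[i, ds$group == 1] - mean(m[i, ds$group == 1]))
  ref <- stats::t.test(z1, z0, var.equal = TRUE)
  expect_equal(res0$statistic[i], unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res0$p_value[i], ref$p.value, tolerance = 1e-10)
  # identical values in both groups -> all deviations equal -> t = 0, p = 1
  v <- ds$values
  v[5, ] <- rep(c(0.1, 0.12, 0.14), length.out = ncol(v))
  v[5, ds$group == 1] <- v[5, ds$group == 0]
  ds5 <- methylation_dataset(v, ds$group, ds$feature_ids, ds$sample_ids)
  r5 <- run_diffvar(ds5, prior = plain)
  expect_equal(r5$statistic[5], 0)
  expect_equal(r5$p_value[5], 1)
})

test_that("joint score test: location invariance and quadratic decomposition", {
  set.seed(34)
  ds <- null_beta_dataset(n_features = 80, n_per_group = 25, seed = 34)
  res <- run_jdmdv(ds)
  # shifting all beta values on the M scale leaves the statistic unchanged
  m2 <- m_values(ds) + 1.3
  ds_shift <- methylation_dataset(m_to_beta(m2), ds$group,
                                  ds$feature_ids, ds$sample_ids)
  res_shift <- run_jdmdv(ds_shift)
  expect_equal(res_shift$statistic, res$statistic, tolerance = 1e-6)
  # the 2-df statistic dominates its variance-only component
  expect_true(all(res$statistic >= res$stat_var - 1e-12, na.rm = TRUE))
  expect_true(all(res$statistic >= res$stat_mean - 1e-12, na.rm = TRUE))
  # a pure mean shift loads on the mean component
  v <- ds$values
  v[1, ds$group == 1] <- pmin(v[1, ds$group == 1] + 0.15, 1)
  rs <- run_jdmdv(methylation_dataset(v, ds$group, ds$feature_ids,
                                      ds$sample_ids))
  expect_gt(rs$stat_mean[1], rs$stat_var[1])
})

test_that("location-scale LRTs are nonnegative, nested, and separate mean from variance", {
  set.seed(35)
  sim <- simulate_dataset(small_sim_config(), seed = 35)
  res <- run_gamlss_ls(sim$dataset)
  # nesting: each LRT is a likelihood gain, so >= 0
  expect_true(all(res$statistic >= 0, na.rm = TRUE))
  expect_true(all(res$lrt_mean >= 0, na.rm = TRUE))
  # identical group values -> both LRTs exactly 0
  v <- sim$dataset$values
  v[3, sim$dataset$group == 1] <- v[3, sim$dataset$group == 0]
  r3 <- run_gamlss_ls(methylation_dataset(v, sim$dataset$group,
                                          sim$dataset$feature_ids,
                                          sim$dataset$sample_ids))
  expect_equal(r3$lrt_mean[3], 0)
  expect_equal(r3$statistic[3], 0)
  # full-group shift (type-1a): mean P-value far below the DV P-value
  p1a <- res[sim$truth == "type1a", ]
  expect_lt(median(log(p1a$p_mean)), median(log(p1a$p_value)))
  # selection uses the either-q rule
  expect_identical(res$significant,
                   (!is.na(res$q_mean) & res$q_mean < 0.05) |
                   (!is.na(res$q_value) & res$q_value < 0.05))
})

test_that("moderated t baseline: sign matches direction, flags null data", {
  set.seed(36)
  runs <- vapply(1:8, function(s) {
    ds <- null_beta_dataset(n_features = 800, n_per_group = 25, seed = 100 + s)
    sum(run_ttest_dmc(ds)$significant)
  }, numeric(1))
  expect_true(mean(runs == 0) >= 0.75)
  sim <- simulate_dataset(small_sim_config(), seed = 37)
  res <- run_ttest_dmc(sim$dataset)
  ok <- !is.na(res$direction)
  expect_identical(res$direction[ok],
                   ifelse(res$statistic[ok] > 0, "hyper", "hypo"))
  # type-2 features (3 outliers of 50) escape the mean test but not BT
  bt <- run_bt(sim$dataset)
  t2 <- sim$truth == "type2"
  expect_lt(sum(res$significant[t2]), 0.2 * sum(t2))
  expect_gt(sum(bt$significant[t2]), 0.8 * sum(t2))
})

test_that("null P-values are uniform for the robust tests, inflated for BT on heavy tails", {
  ds <- permuted_gaussian_dataset(n_features = 5000, seed = 40)
  expect_gt(ks.test(run_diffvar(ds)$p_value, "punif")$p.value, 0.01)
  expect_gt(ks.test(run_jdmdv(ds)$p_value, "punif")$p.value, 0.01)
  g <- run_gamlss_ls(ds)
  expect_gt(ks.test(g$p_value, "punif")$p.value, 0.01)
  expect_gt(ks.test(g$p_mean, "punif")$p.value, 0.01)
  # BT anti-conservative on t3-tailed data: median null P well below 0.5
  set.seed(41)
  mt <- matrix(rt(5000 * 100, df = 3) * 0.1 - 3, 5000, 100)
  ds_t3 <- methylation_dataset(m_to_beta(mt), ds$group,
                               ds$feature_ids, ds$sample_ids)
  expect_lt(median(run_bt(ds_t3)$p_value, na.rm = TRUE), 0.5)
})

test_that("result tables serialize to TSV and back", {
  sim <- simulate_dataset(small_sim_config(), seed = 42)
  res <- run_ievora(sim$dataset)
  path <- tempfile(fileext = ".tsv")
  write_dv_result(res, path)
  back <- read_dv_result(path)
  expect_equal(attr(back, "algorithm"), "iEVORA")
  expect_equal(back$feature_id, res$feature_id)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-9)
  expect_equal(back$rank, res$rank)
})
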