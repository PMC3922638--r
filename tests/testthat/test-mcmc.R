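# MCMC engine: configuration, likelihood bookkeeping, trace selection,
# diagnostics, reproducibility.

test_that("invalid configurations fail before sampling", {
  expect_error(mcmc_config(n_iters = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(n_iters = 0), "configuration error")
  expect_error(mcmc_config(sigma = -1), "configuration error")
})

test_that("complete-data log-likelihood decomposes and reduces correctly", {
  # no reads: the likelihood part is exactly zero
  data0 <- flat_data(2, depth = 0)
  tree0 <- manual_tree(parent = c(0L, 1L), eta = c(0.4, 0.6), z = c(2L, 2L))
  parts0 <- complete_data_log_likelihood(tree0, data0, parts = TRUE)
  expect_equal(parts0$data_loglik, 0)
  lw <- clonetree:::all_node_log_weights(tree0)
  expect_equal(parts0$assignment_logprior, 2 * lw[2])
  # single node, single SNV: equals snv_log_likelihood plus log omega
  df <- tibble::tibble(id = "s", sample = "S1", variant_reads = 30,
                       total_reads = 100, copy_number = 2,
                       zygosity = "heterozygous")
  data1 <- snv_data(df)
  tree1 <- manual_tree(0L, eta = 1, z = 1L, nu = 0.7)
  parts1 <- complete_data_log_likelihood(tree1, data1, parts = TRUE)
  g <- default_genotype_config(2, "heterozygous")
  expect_equal(parts1$data_loglik, snv_log_likelihood(30, 100, g, 1))
  expect_equal(parts1$assignment_logprior, log(0.7))
})

test_that("splitting nearby clusters can beat the merged chain", {
  # two groups of SNVs at population frequencies 0.45 and 0.40 with depth
  # 10,000: a tree putting them in separate nodes scores a higher data
  # likelihood than merging them into one node
  set.seed(20)
  sc <- sim_scenario(c(0.45, 0.40), snvs_per_node = 5, depth = 10000,
                     name = "close")
  sim <- simulate_reads(sc, seed = 77)
  data <- snv_data(sim$counts)
  truth <- sim$truth$node[match(data$snv_ids, sim$truth$id)]
  split_tree <- manual_tree(parent = c(0L, 1L, 2L),
                            eta = c(0.55, 0.05, 0.40),
                            z = 1L + truth, single_clone = TRUE)
  merged_tree <- manual_tree(parent = c(0L, 1L),
                             eta = c(0.575, 0.425),
                             z = rep(2L, 10), single_clone = TRUE)
  ll_split <- complete_data_log_likelihood(split_tree, data,
                                           parts = TRUE)$data_loglik
  ll_merged <- complete_data_log_likelihood(merged_tree, data,
                                            parts = TRUE)$data_loglik
  expect_gt(ll_split, ll_merged)
})

test_that("best_tree returns the argmax snapshot with earliest tie-break", {
  fit <- fake_fit(z_list = list(1L, 1L, 1L),
                  parent_list = list(0L, 0L, 0L),
                  ids = "s1", cdllh = c(-5, -1, -3))
  expect_equal(best_tree(fit)$cdllh, -1)
  fit2 <- fake_fit(z_list = list(1L, 1L), parent_list = list(0L, 0L),
                   ids = "s1", cdllh = c(-2, -2))
  expect_identical(which.max(fit2$cdllh), 1L)
  # monotone likelihood sequence: last snapshot wins
  fit3 <- fake_fit(z_list = list(1L, 1L, 1L), parent_list = list(0L, 0L, 0L),
                   ids = "s1", cdllh = c(-3, -2, -1))
  expect_equal(best_tree(fit3)$cdllh, -1)
})

test_that("a single SNV yields a single occupied node", {
  set.seed(22)
  df <- tibble::tibble(id = "only", sample = "S1", variant_reads = 300,
                       total_reads = 1000, copy_number = 2,
                       zygosity = "heterozygous")
  fit <- infer_clone_tree(df, n_iters = 150, burn_in = 30, mh_iters = 150,
                          seed = 5)
  occupied <- vapply(fit$snapshots, function(sn) length(unique(sn$z)),
                     integer(1))
  expect_true(all(occupied == 1))
})

test_that("runs are reproducible given the seed", {
  sc <- sim_scenario(c(0.7, 0.25), snvs_per_node = 3, depth = 800,
                     name = "repro")
  sim <- simulate_reads(sc, seed = 55)
  f1 <- infer_clone_tree(sim$counts, n_iters = 80, burn_in = 20,
                         mh_iters = 100, seed = 77)
  f2 <- infer_clone_tree(sim$counts, n_iters = 80, burn_in = 20,
                         mh_iters = 100, seed = 77)
  expect_identical(f1$cdllh, f2$cdllh)
  expect_identical(best_tree(f1)$z, best_tree(f2)$z)
})

test_that("trace diagnostics behave like an autocorrelation function", {
  set.seed(24)
  # white noise: lag-0 is 1 and higher lags are small
  x <- stats::rnorm(800)
  acf_tbl <- trace_diagnostics(x, max_lag = 40)
  expect_equal(acf_tbl$autocorrelation[1], 1)
  band <- 3 / sqrt(length(x))
  expect_gte(mean(abs(acf_tbl$autocorrelation[-1]) < band), 0.95)
  # AR(1) with coefficient 0.9
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), n = 6000))
  acf_ar <- trace_diagnostics(ar, max_lag = 5)
  expect_lt(abs(acf_ar$autocorrelation[2] - 0.9), 0.05)
  # constant trace: undefined beyond lag 0
  const <- trace_diagnostics(rep(2.5, 50), max_lag = 5)
  expect_equal(const$autocorrelation[1], 1)
  expect_true(all(is.na(const$autocorrelation[-1])))
  expect_error(trace_diagnostics(1:5), "at least 10")
})

test_that("recorded snapshots satisfy the weight invariants", {
  set.seed(26)
  sc <- sim_scenario(c(0.8, 0.3), snvs_per_node = 3, depth = 1000,
                     name = "inv")
  sim <- simulate_reads(sc, seed = 61)
  fit <- infer_clone_tree(sim$counts, n_iters = 100, burn_in = 20,
                          mh_iters = 150, seed = 9)
  for (sn in fit$snapshots) {
    expect_lt(max(abs(sn$phi[1, ] - 1)), 1e-9)
    for (v in seq_along(sn$parent)) {
      ch <- which(sn$parent == v)
      if (length(ch) > 0) {
        expect_true(all(sn$phi[v, ] -
                          colSums(sn$phi[ch, , drop = FALSE]) >= -1e-9))
      }
    }
  }
})

test_that("tidy and glance summarize a fit", {
  set.seed(28)
  sc <- sim_scenario(c(0.6), snvs_per_node = 3, depth = 500, name = "g")
  sim <- simulate_reads(sc, seed = 71)
  fit <- infer_clone_tree(sim$counts, n_iters = 60, burn_in = 10,
                          mh_iters = 100, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(names(td), c("id", "sample", "variant_reads",
                               "total_reads", "vaf", "phi_mean",
                               "best_tree_node"))
  expect_equal(nrow(td), 3)
  expect_true(all(td$phi_mean >= 0 & td$phi_mean <= 1))
  gl <- glance(fit)
  expect_equal(gl$n_snvs, 3)
  expect_equal(gl$n_draws, 50)
  expect_s3_class(autoplot(fit), "ggplot")
})
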