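# Full posterior sampling: each Gibbs sweep resamples SNV assignments,
# sticks and hyperparameters, culls empty branches, then updates the
# per-sample auxiliary weights by Metropolis-Hastings.

#' MCMC configuration
#'
#' @param n_iters Total Gibbs sweeps (default 5000).
#' @param burn_in Sweeps discarded before recording (default 100).
#' @param mh_iters Inner Metropolis-Hastings iterations per sweep for the
#'   auxiliary weights (default 5000).
#' @param sigma Dirichlet proposal concentration (default 100).
#' @param seed Optional integer seed; the run is reproducible given the seed.
#' @param ranges Hyperparameter ranges, see [default_hyper_ranges()].
#' @param single_clone Assume a single founding clone (the root may have only
#'   one child lineage), the model's default; disable for multicentral
#'   tumors.
#' @param verbose Print the complete-data log-likelihood every 100 sweeps.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iters = 5000, burn_in = 100, mh_iters = 5000,
                        sigma = 100, seed = NULL,
                        ranges = default_hyper_ranges(),
                        single_clone = TRUE, verbose = FALSE) {
  if (burn_in >= n_iters) {
    stop("configuration error: `burn_in` must be < `n_iters`.", call. = FALSE)
  }
  if (n_iters < 1 || mh_iters < 1 || sigma <= 0) {
    stop("configuration error: invalid iteration counts or sigma.", call. = FALSE)
  }
  structure(list(n_iters = as.integer(n_iters), burn_in = as.integer(burn_in),
                 mh_iters = as.integer(mh_iters), sigma = sigma, seed = seed,
                 ranges = ranges, single_clone = isTRUE(single_clone),
                 verbose = isTRUE(verbose)),
            class = "mcmc_config")
}

#' Complete-data log-likelihood of a tree state
#'
#' Sum over SNVs and samples of the genotype-marginalized read-count
#' log-likelihood at each SNV's node frequency, plus the log stick-breaking
#' weight `log omega` of each SNV's assigned node (the assignment prior
#' term). Set `parts = TRUE` to get the decomposition.
#'
#' @param tree A `clone_tree` carrying current assignments and weights.
#' @param data An [snv_data()] object.
#' @param parts Return a list with `data_loglik` and `assignment_logprior`?
#' @return Numeric scalar, or a list when `parts = TRUE`.
#' @export
complete_data_log_likelihood <- function(tree, data, parts = FALSE) {
  ga <- genotype_arrays(data)
  phi <- phi_from_eta_matrix(tree, eta_matrix(tree))
  ll_mat <- snv_loglik_matrix_cpp(phi, as.integer(tree$z), data$b, data$d,
                                  lchoose(data$d, data$b),
                                  ga$mu_r, ga$mu_v, ga$log_w)
  data_ll <- sum(ll_mat)
  lw <- all_node_log_weights(tree)
  prior_ll <- sum(lw[tree$z])
  if (parts) {
    list(total = data_ll + prior_ll, data_loglik = data_ll,
         assignment_logprior = prior_ll)
  } else {
    data_ll + prior_ll
  }
}

snapshot_tree <- function(tree, data, cdll) {
  list(
    z = tree$z,
    parent = vapply(tree$nodes, function(n) n$parent, integer(1)),
    phi = phi_from_eta_matrix(tree, eta_matrix(tree)),
    hypers = tree$hypers,
    cdllh = cdll$total,
    data_loglik = cdll$data_loglik
  )
}

#' Run the MCMC sampler
#'
#' Executes `n_iters` Gibbs sweeps (assignments, sticks and hyperparameters,
#' culling, then the global Metropolis-Hastings weight move), discards the
#' burn-in, and records one tree snapshot per retained sweep. Deterministic
#' given `config$seed`.
#'
#' @param data An [snv_data()] object (or a data frame accepted by
#'   [snv_data()]).
#' @param config An [mcmc_config()].
#' @return A `clone_tree_fit` object: the trace of snapshots, per-snapshot
#'   complete-data log-likelihoods, and the input data and configuration.
#' @export
run_mcmc <- function(data, config = mcmc_config()) {
  if (is.data.frame(data)) data <- snv_data(data)
  stopifnot(inherits(data, "snv_data"), inherits(config, "mcmc_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- n_snvs(data)
  S <- n_samples(data)
  # all SNVs start at the root with the full unit weight there; the first
  # sweeps peel clusters off into children (the root frequency is pinned at
  # 1 per sample, so SNVs below clonal frequency escape immediately and the
  # likelihood barrier keeps them from returning)
  tree <- new_clone_tree(S, N, ranges = config$ranges,
                         single_clone = config$single_clone)

  keep <- config$n_iters - config$burn_in
  snapshots <- vector("list", keep)
  cdllh <- numeric(keep)
  accept <- numeric(keep)
  hyper_trace <- matrix(NA_real_, keep, 3,
                        dimnames = list(NULL, c("alpha0", "gamma", "lambda")))
  # first sweep: update SNVs in decreasing allele-fraction order, so
  # high-frequency clusters claim auxiliary weight while the root still
  # holds it (clusters escape the root from the top down and nest naturally)
  vaf_order <- order(rowMeans(data$b / pmax(data$d, 1)), decreasing = TRUE)
  for (it in seq_len(config$n_iters)) {
    ord <- if (it == 1) vaf_order else NULL
    tree <- gibbs_fresh_scan(tree, data, order = ord)
    tree <- gibbs_assignments(tree, data, order = ord)
    tree <- subtree_relocations(tree)
    if (config$single_clone) tree <- root_parent_moves(tree, data)
    tree <- gibbs_sticks_and_hypers(tree)
    tree <- cull_tree(tree)
    tree <- multisample_mh_step(tree, data, config$sigma, config$mh_iters)
    if (it > config$burn_in) {
      k <- it - config$burn_in
      cdll <- complete_data_log_likelihood(tree, data, parts = TRUE)
      snapshots[[k]] <- snapshot_tree(tree, data, cdll)
      cdllh[k] <- cdll$total
      accept[k] <- attr(tree, "accept_rate")
      hyper_trace[k, ] <- unlist(tree$hypers)
    }
    if (config$verbose && it %% 100 == 0) {
      cdll_now <- complete_data_log_likelihood(tree, data)
      message(sprintf("iteration %d: complete-data log-likelihood %.2f",
                      it, cdll_now))
    }
  }
  structure(
    list(snapshots = snapshots, cdllh = cdllh, accept_rate = accept,
         hyper_trace = tibble::as_tibble(hyper_trace),
         data = data, config = config, final_tree = tree),
    class = "clone_tree_fit"
  )
}

#' Infer a subclonal lineage tree from SNV read counts
#'
#' Data-frame-first front end to [run_mcmc()]: takes one row per
#' (SNV, sample) with variant and total read counts, builds the dataset, and
#' samples the posterior over lineage trees.
#'
#' @param df Data frame accepted by [snv_data()], or an `snv_data` object.
#' @param n_iters,burn_in,mh_iters,sigma,seed,ranges,single_clone,verbose See
#'   [mcmc_config()].
#' @param error_rate Sequencer error rate for default genotype configs.
#' @param n_restarts Independent chains started from different random
#'   initializations (seeds `seed`, `seed + 1`, ...); the run with the
#'   highest complete-data log-likelihood is returned, the standard remedy
#'   for chains caught in a poor local mode.
#' @return A `clone_tree_fit`; see [tidy.clone_tree_fit()],
#'   [glance.clone_tree_fit()], [best_tree()], [partial_order()].
#' @export
infer_clone_tree <- function(df, n_iters = 5000, burn_in = 100,
                             mh_iters = 5000, sigma = 100, seed = NULL,
                             ranges = default_hyper_ranges(),
                             single_clone = TRUE, error_rate = 0.001,
                             n_restarts = 1, verbose = FALSE) {
  data <- if (inherits(df, "snv_data")) df else snv_data(df, error_rate)
  seeds <- if (is.null(seed)) rep(list(NULL), n_restarts) else
    as.list(seed + seq_len(n_restarts) - 1L)
  fits <- lapply(seeds, function(s) {
    run_mcmc(data, mcmc_config(n_iters, burn_in, mh_iters, sigma, s,
                               ranges, single_clone, verbose))
  })
  fits[[which.max(vapply(fits, function(f) max(f$cdllh), numeric(1)))]]
}

#' @export
print.clone_tree_fit <- function(x, ...) {
  cat("<clone_tree_fit>", length(x$snapshots), "posterior samples,",
      n_snvs(x$data), "SNVs,", n_samples(x$data), "sample(s)\n")
  cat("best complete-data log-likelihood:", format(max(x$cdllh)), "\n")
  invisible(x)
}

#' Best posterior tree snapshot
#'
#' The recorded snapshot with the highest complete-data log-likelihood; ties
#' are broken by the earliest iteration.
#'
#' @param fit A `clone_tree_fit`.
#' @return A snapshot: list with `z` (assignments), `parent` (node parents),
#'   `phi` (node frequencies per sample), `hypers`, and the log-likelihoods.
#' @export
best_tree <- function(fit) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  if (length(fit$snapshots) == 0) stop("empty trace.", call. = FALSE)
  fit$snapshots[[which.max(fit$cdllh)]]
}

#' Posterior mean SNV population frequencies
#'
#' @param fit A `clone_tree_fit`.
#' @return Matrix (SNVs x samples) of posterior means of each SNV's node
#'   frequency.
#' @export
posterior_mean_phi <- function(fit) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  acc <- matrix(0, n_snvs(fit$data), n_samples(fit$data),
                dimnames = dimnames(fit$data$b))
  for (sn in fit$snapshots) {
    acc <- acc + sn$phi[sn$z, , drop = FALSE]
  }
  acc / length(fit$snapshots)
}

#' Likelihood-trace diagnostics
#'
#' Normalized autocorrelation of the complete-data log-likelihood trace at
#' lags `0..max_lag` (lag 0 is exactly 1), plus a one-row summary. For a
#' constant trace the autocorrelation is undefined beyond lag 0 and reported
#' as `NA`.
#'
#' @param fit A `clone_tree_fit` (or a numeric log-likelihood trace).
#' @param max_lag Largest lag; defaults to `min(n - 1, 50)`.
#' @return Tibble with columns `lag` and `autocorrelation`; summary in
#'   attribute `"summary"`.
#' @export
trace_diagnostics <- function(fit, max_lag = NULL) {
  x <- if (inherits(fit, "clone_tree_fit")) fit$cdllh else as.numeric(fit)
  n <- length(x)
  if (n < 10) stop("need at least 10 post-burn-in samples.", call. = FALSE)
  if (is.null(max_lag)) max_lag <- min(n - 1L, 50L)
  if (stats::var(x) == 0) {
    ac <- c(1, rep(NA_real_, max_lag))
  } else {
    ac <- as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                                demean = TRUE)$acf)
  }
  out <- tibble::tibble(lag = 0:max_lag, autocorrelation = ac)
  attr(out, "summary") <- tibble::tibble(
    n = n, mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x)
  )
  out
}
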