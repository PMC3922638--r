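# Synthetic read-count generator emulating targeted deep sequencing of
# clustered somatic SNVs.

#' Define a simulation scenario
#'
#' A scenario is a set of SNV clusters (tree nodes) with per-sample
#' population frequencies, a number of SNVs per cluster, and a mean read
#' depth. When `parent` is supplied the frequencies must respect the clonal
#' constraint (each node's frequency at least the sum of its children's, per
#' sample, with an implicit wildtype root at frequency 1); when `parent` is
#' `NULL` the clusters are free-floating frequency groups.
#'
#' @param phi Cluster frequencies: vector (one sample) or clusters-x-samples
#'   matrix.
#' @param parent Optional parent index per cluster (0 = child of the
#'   wildtype root).
#' @param snvs_per_node Integer (recycled) or one per cluster; with
#'   `snv_count = "poisson"`, the mean of a Poisson truncated at 1.
#' @param depth Mean read depth; per-SNV depths are Poisson around it.
#' @param error_rate Sequencer error rate (`mu_r = 1 - error_rate`).
#' @param snv_count `"fixed"` (default) or `"poisson"`.
#' @param seed Optional seed stored with the scenario.
#' @param name Optional scenario label.
#' @return A `sim_scenario` object.
#' @export
sim_scenario <- function(phi, parent = NULL, snvs_per_node = 9,
                         depth = 10000, error_rate = 0.001,
                         snv_count = c("fixed", "poisson"), seed = NULL,
                         name = "scenario") {
  phi <- if (is.null(dim(phi))) matrix(phi, ncol = 1) else as.matrix(phi)
  snv_count <- match.arg(snv_count)
  if (any(phi < 0 | phi > 1)) {
    stop("scenario error: frequencies must lie in [0, 1].", call. = FALSE)
  }
  K <- nrow(phi)
  if (!is.null(parent)) {
    parent <- as.integer(parent)
    stopifnot(length(parent) == K, sum(parent == 0L) >= 1)
    for (t in seq_len(ncol(phi))) {
      child_sum <- numeric(K + 1)
      for (v in seq_len(K)) {
        idx <- if (parent[v] == 0L) K + 1 else parent[v]
        child_sum[idx] <- child_sum[idx] + phi[v, t]
      }
      node_f <- c(phi[, t], 1)
      if (any(child_sum > node_f + 1e-9)) {
        stop("scenario error: frequencies violate the clonal constraint.",
             call. = FALSE)
      }
    }
  }
  structure(
    list(phi = phi, parent = parent,
         snvs_per_node = rep_len(snvs_per_node, K), depth = depth,
         error_rate = error_rate, snv_count = snv_count, seed = seed,
         name = name),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>", x$name, "-", nrow(x$phi), "clusters,",
      ncol(x$phi), "sample(s), depth", x$depth, "\n")
  invisible(x)
}

#' Simulate heterozygous SNV read counts from a scenario
#'
#' For each SNV at frequency `phi`, depth `d ~ Poisson(depth)` and variant
#' reads `b ~ Binomial(d, 1 - ((1 - phi) mu_r + phi * 0.5))` -- the
#' heterozygous, normal-copy-number observation model, so the expected
#' variant allele fraction is about `phi / 2`.
#'
#' @param scenario A [sim_scenario()].
#' @param seed Optional seed (overrides the scenario's).
#' @return List with `counts` (tibble ready for [snv_data()]) and `truth`
#'   (tibble: `id`, `node`, `sample`, `phi`).
#' @export
simulate_reads <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) set.seed(seed)
  K <- nrow(scenario$phi)
  S <- ncol(scenario$phi)
  n_per <- if (scenario$snv_count == "poisson") {
    pmax(1L, stats::rpois(K, scenario$snvs_per_node))
  } else {
    as.integer(scenario$snvs_per_node)
  }
  node_of <- rep(seq_len(K), n_per)
  N <- length(node_of)
  ids <- sprintf("snv%02d_c%d", seq_len(N), node_of)
  mu_r <- 1 - scenario$error_rate
  rows <- list()
  for (t in seq_len(S)) {
    d <- stats::rpois(N, scenario$depth)
    d <- pmax(d, 1L)
    phi_i <- scenario$phi[node_of, t]
    p_var <- 1 - ref_allele_prob(phi_i, mu_r, 0.5)
    b <- stats::rbinom(N, d, p_var)
    rows[[t]] <- tibble::tibble(
      id = ids, sample = paste0("S", t), variant_reads = b, total_reads = d,
      copy_number = 2L, zygosity = "heterozygous"
    )
  }
  truth <- tibble::tibble(
    id = rep(ids, S),
    node = rep(node_of, S),
    sample = rep(paste0("S", seq_len(S)), each = N),
    phi = as.vector(scenario$phi[node_of, , drop = FALSE])
  )
  list(counts = dplyr::bind_rows(rows), truth = truth, scenario = scenario)
}

#' Preset simulation scenarios
#'
#' * `flat6` -- six frequency clusters `{1.0, 0.85, 0.6, 0.35, 0.2, 0.08}`,
#'   nine SNVs each, one sample, depth 10,000; `flat6_d1000` and
#'   `flat6_d200` are the same design at depths 1,000 and 200.
#' * `chain5` -- a five-node chain `0.9 -> 0.75 -> 0.55 -> 0.4 -> 0.25`,
#'   five SNVs per node, one sample, depth 10,000 (only consistent with a
#'   chain by the sum rule).
#' * `crossing2` -- two samples, a branching tree whose two branches swap
#'   frequency order between samples (exercises the crossing rule).
#'
#' @param seed Optional seed stored in every scenario.
#' @return Named list of [sim_scenario()] objects.
#' @export
preset_scenarios <- function(seed = NULL) {
  flat <- c(1.0, 0.85, 0.6, 0.35, 0.2, 0.08)
  list(
    flat6 = sim_scenario(flat, snvs_per_node = 9, depth = 10000,
                         seed = seed, name = "flat6"),
    flat6_d1000 = sim_scenario(flat, snvs_per_node = 9, depth = 1000,
                               seed = seed, name = "flat6_d1000"),
    flat6_d200 = sim_scenario(flat, snvs_per_node = 9, depth = 200,
                              seed = seed, name = "flat6_d200"),
    chain5 = sim_scenario(c(0.9, 0.75, 0.55, 0.4, 0.25),
                          parent = c(0L, 1L, 2L, 3L, 4L),
                          snvs_per_node = 5, depth = 10000,
                          seed = seed, name = "chain5"),
    crossing2 = sim_scenario(
      rbind(c(0.9, 0.9), c(0.4, 0.2), c(0.2, 0.4)),
      parent = c(0L, 1L, 1L), snvs_per_node = 5, depth = 10000,
      seed = seed, name = "crossing2"
    )
  )
}
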