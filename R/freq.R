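# Constrained sampling of SNV population frequencies via auxiliary weights.
#
# Any nonnegative weights eta summing to 1 over nodes induce frequencies
# phi_v = eta_v + sum of descendant eta, which automatically satisfy the
# infinite-sites (clonal) constraint phi_parent >= sum of children's phi.

#' Draw auxiliary weights and frequencies from the constrained prior
#'
#' Breadth-first generative scheme: the root starts with the full unit mass;
#' visiting each node, every child draws `eta ~ Uniform(0, eta_parent)` and
#' the parent is decremented, so the weights always sum to one per sample.
#' Frequencies follow by subtree sums.
#'
#' @param tree A `clone_tree`.
#' @return The tree with fresh `eta` per node and sample; the implied
#'   frequencies are available via [phi_from_eta()].
#' @export
draw_frequencies <- function(tree) {
  S <- tree$n_samples
  for (v in seq_along(tree$nodes)) tree$nodes[[v]]$eta <- numeric(S)
  tree$nodes[[1]]$eta <- rep(1, S)
  queue <- 1L
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in tree$nodes[[v]]$children) {
      eta_w <- stats::runif(S) * tree$nodes[[v]]$eta
      tree$nodes[[w]]$eta <- eta_w
      tree$nodes[[v]]$eta <- tree$nodes[[v]]$eta - eta_w
      queue <- c(queue, w)
    }
  }
  tree
}

#' Population frequencies from auxiliary weights
#'
#' `phi_v = eta_v + sum over descendants of eta`, equivalently
#' `phi_v = eta_v + sum over children of phi`. When the weights sum to one,
#' the root frequency is one.
#'
#' @param tree A `clone_tree`.
#' @param eta Optional weights: a vector (single sample) or a nodes-x-samples
#'   matrix. Defaults to the weights stored in the tree.
#' @return Matrix of frequencies (nodes x samples), or a vector if `eta` was
#'   a vector.
#' @export
phi_from_eta <- function(tree, eta = NULL) {
  drop_dim <- FALSE
  if (is.null(eta)) {
    eta <- eta_matrix(tree)
  } else if (is.null(dim(eta))) {
    if (length(eta) != length(tree$nodes)) {
      stop("missing node weight: `eta` must have one entry per node.",
           call. = FALSE)
    }
    eta <- matrix(eta, ncol = 1)
    drop_dim <- TRUE
  }
  if (nrow(eta) != length(tree$nodes)) {
    stop("missing node weight: `eta` must have one row per node.", call. = FALSE)
  }
  phi <- phi_from_eta_matrix(tree, eta)
  if (drop_dim) drop(phi) else phi
}

#' Log-density of the sequential-uniform weight prior
#'
#' Exact density of the [draw_frequencies()] scheme at a given weight
#' vector: each child's draw contributes `1 / available parent mass`, where
#' the available mass when child `i` draws is the parent's final weight plus
#' the weights of the children not yet drawn.
#'
#' @param tree A `clone_tree`.
#' @param eta Weight vector over nodes (one sample).
#' @return Log-density (up to nothing -- it is exact).
#' @export
eta_prior_log_density <- function(tree, eta) {
  ld <- 0
  for (v in seq_along(tree$nodes)) {
    ch <- tree$nodes[[v]]$children
    if (length(ch) == 0) next
    avail <- eta[v] + sum(eta[ch])
    for (w in ch) {
      if (avail <= 0) return(-Inf)
      ld <- ld - log(avail)
      avail <- avail - eta[w]
    }
  }
  ld
}

# assemble the flat arrays the C++ kernel needs
mh_inputs <- function(tree, data) {
  K <- length(tree$nodes)
  parent <- vapply(tree$nodes, function(n) n$parent, integer(1))
  children <- lapply(tree$nodes, function(n) as.integer(n$children))
  ord <- rev(preorder_indices(tree))
  ga <- genotype_arrays(data)
  lch <- lchoose(data$d, data$b)
  list(parent = parent, children = children, order = as.integer(ord),
       ga = ga, lch = lch)
}

#' Metropolis-Hastings update of the auxiliary weights (all samples)
#'
#' Runs `n_iters` iterations of a Markov chain on the per-sample weight
#' simplices whose stationary distribution is the product over SNVs of the
#' genotype-marginalized binomial likelihood (evaluated at each SNV's node
#' frequency) times the sequential-uniform prior. The proposal is an
#' asymmetric Dirichlet centred on the current weights,
#' `Dirichlet(sigma * eta + floor)`; per-sample proposals are made jointly
#' and accepted or rejected in one global move on the product of per-sample
#' posteriors. With a single sample this is the plain per-sample update.
#'
#' @param tree A `clone_tree` with current assignments.
#' @param data An [snv_data()] object.
#' @param sigma Dirichlet proposal concentration (default 100).
#' @param n_iters Chain length (default 5000).
#' @param floor Pseudo-count floor keeping the proposal proper.
#' @param thin If positive, record every `thin`-th state.
#' @return The tree with updated weights. Attributes: `accept_rate`, and
#'   `eta_trace` (list of matrices, one per sample) when `thin > 0`.
#' @export
multisample_mh_step <- function(tree, data, sigma = 100, n_iters = 5000,
                                floor = 1e-4, thin = 0) {
  stopifnot(n_iters >= 1, sigma > 0)
  inp <- mh_inputs(tree, data)
  res <- mh_weights_cpp(
    eta_matrix(tree), inp$parent, inp$children, inp$order,
    as.integer(tree$z), data$b, data$d, inp$lch,
    inp$ga$mu_r, inp$ga$mu_v, inp$ga$log_w,
    sigma, floor, as.integer(n_iters), as.integer(thin)
  )
  for (v in seq_along(tree$nodes)) tree$nodes[[v]]$eta <- res$eta[v, ]
  attr(tree, "accept_rate") <- res$accept_rate
  if (thin > 0) {
    K <- length(tree$nodes)
    attr(tree, "eta_trace") <- lapply(seq_len(tree$n_samples), function(t) {
      res$trace[, (t - 1) * K + seq_len(K), drop = FALSE]
    })
  }
  tree
}

#' Metropolis-Hastings update of one sample's auxiliary weights
#'
#' Single-sample form of [multisample_mh_step()]: updates the weights of
#' `sample_index` only, holding other samples fixed.
#'
#' @inheritParams multisample_mh_step
#' @param sample_index Which sample to update.
#' @return Named weight vector over nodes for that sample; attributes
#'   `accept_rate` and, when `thin > 0`, `trace` (iterations x nodes matrix).
#' @export
mh_update_weights <- function(tree, data, sample_index = 1L, sigma = 100,
                              n_iters = 5000, floor = 1e-4, thin = 0) {
  sub <- data
  sub$b <- data$b[, sample_index, drop = FALSE]
  sub$d <- data$d[, sample_index, drop = FALSE]
  sub$sample_labels <- data$sample_labels[sample_index]
  sub_tree <- tree
  sub_tree$n_samples <- 1L
  for (v in seq_along(tree$nodes)) {
    sub_tree$nodes[[v]]$eta <- tree$nodes[[v]]$eta[sample_index]
  }
  out <- multisample_mh_step(sub_tree, sub, sigma = sigma, n_iters = n_iters,
                             floor = floor, thin = thin)
  eta <- vapply(out$nodes, function(n) n$eta, numeric(1))
  names(eta) <- paste0("node", seq_along(eta))
  attr(eta, "accept_rate") <- attr(out, "accept_rate")
  if (thin > 0) attr(eta, "trace") <- attr(out, "eta_trace")[[1]]
  eta
}
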