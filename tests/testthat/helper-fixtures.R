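# Shared fixtures and independent oracles, built in code.

# genotype config whose likelihood is flat in phi (mu_r == mu_v): the
# read-count probability does not depend on the population frequency, so
# samplers fall back to their priors
flat_genotype <- function() genotype_config(0.5, "flat", 0.5)

# a dataset of n SNVs carrying no frequency information
flat_data <- function(n = 6, n_samples = 1, depth = 0) {
  df <- tidyr::expand_grid(id = sprintf("s%02d", seq_len(n)),
                           sample = paste0("S", seq_len(n_samples)))
  df$variant_reads <- 0
  df$total_reads <- depth
  df$genotype <- rep(list(flat_genotype()), nrow(df))
  snv_data(df)
}

# build a clone tree by hand: parent[1] must be 0 (root); eta is a
# nodes x samples matrix (or vector); sticks set to fixed mid values
manual_tree <- function(parent, eta, z = integer(0), nu = 0.5, psi = 0.5,
                        hypers = list(alpha0 = 1, gamma = 1, lambda = 1),
                        single_clone = FALSE) {
  eta <- if (is.null(dim(eta))) matrix(eta, ncol = 1) else eta
  S <- ncol(eta)
  tree <- new_clone_tree(n_samples = S, n_snvs = 0,
                         hypers = hypers, single_clone = single_clone)
  tree$nodes[[1]]$nu <- nu
  tree$nodes[[1]]$eta <- eta[1, ]
  for (v in seq_along(parent)[-1]) {
    node <- list(parent = as.integer(parent[v]), children = integer(0),
                 nu = nu, psi = psi, eta = eta[v, ])
    tree$nodes[[v]] <- node
    tree$nodes[[parent[v]]]$children <-
      c(tree$nodes[[parent[v]]]$children, v)
  }
  tree$z <- as.integer(z)
  tree
}

# fabricate a clone_tree_fit from explicit snapshots (for consensus tests)
fake_fit <- function(z_list, parent_list, ids, phi_list = NULL,
                     cdllh = NULL) {
  n <- length(z_list)
  if (is.null(phi_list)) {
    phi_list <- lapply(parent_list, function(p) {
      matrix(0.5, length(p), 1)
    })
  }
  if (is.null(cdllh)) cdllh <- rep(0, n)
  snaps <- lapply(seq_len(n), function(k) {
    list(z = as.integer(z_list[[k]]), parent = as.integer(parent_list[[k]]),
         phi = phi_list[[k]],
         hypers = list(alpha0 = 1, gamma = 1, lambda = 1),
         cdllh = cdllh[k], data_loglik = cdllh[k])
  })
  df <- tibble::tibble(id = ids, sample = "S1", variant_reads = 1,
                       total_reads = 2)
  structure(
    list(snapshots = snaps, cdllh = cdllh,
         accept_rate = rep(0.3, n),
         hyper_trace = tibble::tibble(alpha0 = rep(1, n), gamma = 1,
                                      lambda = 1),
         data = snv_data(df),
         config = mcmc_config(n_iters = n + 1, burn_in = 1, mh_iters = 10,
                              seed = 1),
         final_tree = NULL),
    class = "clone_tree_fit"
  )
}

# Monte-Carlo oracle for the genotype-marginalized likelihood: sample
# pi ~ Dirichlet(delta), G ~ Categorical(pi), average the binomial likelihood
mc_marginal_likelihood <- function(b, d, config, phi, n_draws = 1e6) {
  G <- length(config$delta)
  gam <- matrix(stats::rgamma(n_draws * G, shape = rep(config$delta,
                                                       each = n_draws)),
                n_draws, G)
  pi <- gam / rowSums(gam)
  g <- max.col(log(pi) - log(-log(matrix(stats::runif(n_draws * G),
                                         n_draws, G))))
  p_ref <- (1 - phi) * config$mu_r + phi * config$mu_v[g]
  lik <- stats::dbinom(b, d, 1 - p_ref)
  list(mean = mean(lik), se = stats::sd(lik) / sqrt(n_draws))
}

# random frequency triple with A >= max(B, C), per sample
random_triples <- function(n, n_samples = 1) {
  lapply(seq_len(n), function(k) {
    t(vapply(seq_len(n_samples), function(t) {
      bc <- stats::runif(2)
      a <- stats::runif(1, max(bc), 1)
      c(a, bc)
    }, numeric(3)))
  })
}

# does a parent vector encode the labelled chain 1 -> 2 -> ... -> k?
is_chain_parent <- function(parent) {
  identical(as.integer(parent), c(0L, seq_len(length(parent) - 1L)))
}
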