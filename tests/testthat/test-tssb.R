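# Tree-structured stick-breaking prior: weights, forward sampling, Gibbs
# kernels, culling.

test_that("node weights follow the interleaved stick-breaking formula", {
  # root with nu ~ 1 takes all mass
  t1 <- manual_tree(parent = 0L, eta = 1, nu = 1 - 1e-12)
  expect_equal(node_weight(t1, 1), 1, tolerance = 1e-9)
  # omega_root = nu_root for any nu
  t2 <- manual_tree(parent = 0L, eta = 1, nu = 0.37)
  expect_equal(node_weight(t2, 1), 0.37)
  # hand evaluation: nu_root = 0.5, single child with psi = 1, nu = 0.5
  t3 <- manual_tree(parent = c(0L, 1L), eta = c(0.5, 0.5), nu = 0.5,
                    psi = 1 - 1e-12)
  expect_equal(node_weight(t3, 1), 0.5)
  expect_equal(node_weight(t3, 2), 0.25, tolerance = 1e-9)
})

test_that("instantiated weights plus residual mass equal one", {
  set.seed(3)
  for (k in 1:20) {
    tree <- new_clone_tree(1, 0, hypers = list(alpha0 = runif(1, 0.5, 10),
                                               gamma = runif(1, 0.5, 4),
                                               lambda = runif(1, 0.3, 1)))
    for (d in 1:15) {
      res <- clonetree:::find_node(tree, runif(1))
      tree <- res$tree
    }
    lw <- clonetree:::all_node_log_weights(tree)
    residual <- 1 - clonetree:::covered_mass(tree)
    expect_lt(abs(sum(exp(lw)) + residual - 1), 1e-10)
    # per-node recursion agrees with the path formula
    for (v in seq_along(tree$nodes)) {
      expect_equal(node_weight(tree, v), exp(lw[v]), tolerance = 1e-12)
    }
  }
})

test_that("forward sampling is reproducible and collapses as alpha0 -> 0", {
  set.seed(5)
  draws <- forward_sample_tree(40, alpha0 = 1e-9, gamma = 1, lambda = 1)
  expect_true(all(draws == 1L))
  set.seed(9)
  a <- forward_sample_tree(30, alpha0 = 3, gamma = 1, lambda = 0.8)
  set.seed(9)
  b <- forward_sample_tree(30, alpha0 = 3, gamma = 1, lambda = 0.8)
  expect_identical(as.integer(a), as.integer(b))
})

test_that("occupied-node count grows with alpha0", {
  set.seed(13)
  mean_k <- function(alpha0) {
    mean(replicate(150, {
      length(unique(forward_sample_tree(50, alpha0, gamma = 1, lambda = 1)))
    }))
  }
  expect_gt(mean_k(50), mean_k(1))
})

test_that("alpha(j) decreases with depth for lambda < 1, giving shallower trees", {
  set.seed(17)
  depth_of <- function(lambda) {
    mean(replicate(120, {
      draws <- forward_sample_tree(30, alpha0 = 10, gamma = 1,
                                   lambda = lambda)
      mean(lengths(attr(draws, "paths")))
    }))
  }
  expect_gt(depth_of(1), depth_of(0.25))
})

test_that("culling removes empty branches and conserves weight", {
  # single occupied root stays put
  t0 <- manual_tree(0L, eta = 1, z = 1L)
  expect_identical(cull_tree(t0)$z, 1L)
  # chain root - A - B with B empty: B removed, its weight returns to A
  t1 <- manual_tree(parent = c(0L, 1L, 2L), eta = c(0.2, 0.3, 0.5),
                    z = c(1L, 2L))
  culled <- cull_tree(t1)
  expect_length(culled$nodes, 2)
  expect_equal(culled$nodes[[2]]$eta, 0.8)
  eta_sum <- sum(vapply(culled$nodes, function(n) n$eta, numeric(1)))
  expect_equal(eta_sum, 1, tolerance = 1e-12)
  # a whole empty subtree is returned to the nearest kept ancestor
  t2 <- manual_tree(parent = c(0L, 1L, 2L, 2L), eta = c(0.4, 0.2, 0.3, 0.1),
                    z = c(1L, 2L))
  culled2 <- cull_tree(t2)
  expect_length(culled2$nodes, 2)
  expect_equal(culled2$nodes[[2]]$eta, 0.6)
})

test_that("stick resampling respects occupancy and ranges", {
  set.seed(23)
  tree <- manual_tree(parent = c(0L, 1L), eta = c(0.5, 0.5),
                      z = rep(2L, 8))
  # node 1 has all data beneath it and none at it: nu posterior shifts low
  nus <- replicate(400, gibbs_sticks_and_hypers(tree,
                                                n_hyper_steps = 0)$nodes[[1]]$nu)
  prior_mean <- 1 / (1 + tree$hypers$alpha0)
  expect_lt(mean(nus), prior_mean)
  # hyperparameters stay inside their configured ranges
  tree$ranges <- default_hyper_ranges()
  for (k in 1:50) {
    tree <- gibbs_sticks_and_hypers(tree, n_hyper_steps = 2)
    hy <- tree$hypers
    expect_true(hy$alpha0 >= 1 && hy$alpha0 <= 50)
    expect_true(hy$gamma >= 1 && hy$gamma <= 8)
    expect_true(hy$lambda >= 0.25 && hy$lambda <= 1)
  }
})

test_that("with no data the stationary nu_root is its Beta(1, alpha0) prior", {
  set.seed(29)
  tree <- new_clone_tree(1, 0, hypers = list(alpha0 = 2, gamma = 1,
                                             lambda = 1))
  nus <- replicate(2000, {
    tree <<- gibbs_sticks_and_hypers(tree, n_hyper_steps = 0)
    tree$nodes[[1]]$nu
  })
  ks <- stats::ks.test(nus, stats::rbeta(5000, 1, 2))
  expect_gt(ks$p.value, 0.01)
})

test_that("the Gibbs kernel with flat likelihood recovers the prior", {
  # assignments + sticks + culling on data carrying no frequency
  # information must leave the cluster-count distribution of the prior
  # unchanged (prior-equivalence oracle)
  set.seed(31)
  n <- 12
  data <- flat_data(n)
  hypers <- list(alpha0 = 4, gamma = 1.5, lambda = 1)
  tree <- new_clone_tree(1, n, hypers = hypers)
  n_sweeps <- 4000
  thin <- 5
  counts <- integer(n_sweeps %/% thin)
  for (s in seq_len(n_sweeps)) {
    tree <- gibbs_assignments(tree, data)
    tree <- gibbs_sticks_and_hypers(tree, n_hyper_steps = 0)
    tree <- cull_tree(tree)
    if (s %% thin == 0) counts[s %/% thin] <- length(unique(tree$z))
  }
  fwd <- replicate(length(counts), {
    length(unique(forward_sample_tree(n, hypers$alpha0, hypers$gamma,
                                      hypers$lambda)))
  })
  ks <- suppressWarnings(stats::ks.test(counts, fwd))
  expect_gt(ks$p.value, 0.01)
})

test_that("assignment sampling finds well-separated clusters", {
  set.seed(37)
  sc <- sim_scenario(c(0.9, 0.1), snvs_per_node = 5, depth = 10000,
                     name = "sep")
  sim <- simulate_reads(sc, seed = 101)
  fit <- infer_clone_tree(sim$counts, n_iters = 120, burn_in = 20,
                          mh_iters = 200, seed = 3)
  truth <- sim$truth$node[match(fit$data$snv_ids, sim$truth$id)]
  # no node may mix SNVs from the two frequency groups (within-group
  # splits into adjacent nodes are legitimate posterior states)
  pure <- vapply(fit$snapshots, function(sn) {
    !any(tapply(truth, sn$z, function(tt) length(unique(tt))) > 1)
  }, logical(1))
  expect_gt(mean(pure), 0.95)
})

test_that("flat-likelihood assignments match the stick weights", {
  # with one SNV and frozen sticks, the assignment distribution over a
  # fixed two-node tree follows omega (chi-square against the weights)
  set.seed(41)
  data <- flat_data(1)
  tree <- manual_tree(parent = c(0L, 1L), eta = c(0.6, 0.4), z = 1L,
                      nu = 0.45, psi = 0.9)
  lw <- clonetree:::all_node_log_weights(tree)
  hits <- integer(2)
  n_sweeps <- 4000
  for (s in seq_len(n_sweeps)) {
    tree2 <- gibbs_assignments(tree, data)
    z <- tree2$z[1]
    if (z <= 2) hits[z] <- hits[z] + 1
  }
  w <- exp(lw)
  # conditional on landing in one of the two instantiated nodes
  p <- w / sum(w)
  test <- stats::chisq.test(hits, p = p)
  expect_gt(test$p.value, 0.01)
})
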