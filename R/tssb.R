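# Tree-structured stick-breaking (TSSB) prior over lineage trees.
#
# A tree is a plain list:
#   $nodes  list of nodes; node = list(parent, children, nu, psi, eta)
#           parent: integer (0 for root); children: integer vector in sibling
#           order; nu, psi: stick variables in (0,1) (psi is the stick for the
#           node's own position among its parent's children, NA at the root);
#           eta: per-sample auxiliary weight vector (length S, sums to 1 over
#           nodes).
#   $z      integer vector of SNV -> node assignments (may be length 0)
#   $hypers list(alpha0, gamma, lambda)
#   $ranges list(alpha0 = c(lo,hi), gamma = c(lo,hi), lambda = c(lo,hi))
#   $n_samples
# Node 1 is always the root.

MAX_DEPTH <- 30L
MAX_WIDTH <- 60L

#' Default hyperparameter ranges for the tree prior
#'
#' The hull of the simulation grid used to calibrate the prior:
#' `alpha0` in \[1, 50\], `gamma` in \[1, 8\], `lambda` in \[0.25, 1\].
#' Uniform priors over these ranges are integrated over during sampling.
#'
#' @return Named list of length-2 numeric ranges.
#' @export
default_hyper_ranges <- function() {
  list(alpha0 = c(1, 50), gamma = c(1, 8), lambda = c(0.25, 1))
}

# depth-dependent concentration alpha(j) = lambda^j * alpha0 (root depth 0)
alpha_at_depth <- function(hypers, depth) hypers$lambda^depth * hypers$alpha0

# keep stick draws strictly inside (0, 1) so Beta densities stay finite
rbeta_stick <- function(a, b) {
  min(max(stats::rbeta(1, a, b), 1e-10), 1 - 1e-10)
}

new_node <- function(parent, n_samples, nu, psi = NA_real_) {
  list(parent = as.integer(parent), children = integer(0),
       nu = nu, psi = psi, eta = numeric(n_samples))
}

#' Create a one-node lineage tree
#'
#' @param n_samples Number of tumor samples.
#' @param n_snvs Number of SNVs (all initially assigned to the root).
#' @param hypers Named list with `alpha0`, `gamma`, `lambda`; defaults drawn
#'   uniformly from `ranges`.
#' @param ranges Hyperparameter ranges, see [default_hyper_ranges()].
#' @param single_clone Enforce a single founding clone: the root (the
#'   normal-cell ancestor) may have at most one child lineage, its branch
#'   stick treated as 1. The pure stick-breaking prior has no such
#'   constraint (default `FALSE`); tumor inference enables it.
#' @return A `clone_tree` list structure.
#' @export
new_clone_tree <- function(n_samples = 1L, n_snvs = 0L, hypers = NULL,
                           ranges = default_hyper_ranges(),
                           single_clone = FALSE) {
  if (is.null(hypers)) {
    # start at the parsimony corner (few nodes, few siblings): new-node
    # stopping probabilities are then large in the first sweeps, which is
    # when clusters must claim their frequencies; the Metropolis updates
    # explore the full ranges afterwards
    hypers <- list(alpha0 = ranges$alpha0[1], gamma = ranges$gamma[1],
                   lambda = ranges$lambda[2])
  }
  root <- new_node(0L, n_samples, nu = rbeta_stick(1, alpha_at_depth(hypers, 0)))
  root$eta <- rep(1, n_samples)
  structure(
    list(nodes = list(root), z = rep(1L, n_snvs), hypers = hypers,
         ranges = ranges, n_samples = as.integer(n_samples),
         single_clone = isTRUE(single_clone)),
    class = "clone_tree"
  )
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree>", length(x$nodes), "node(s),", length(x$z), "SNV(s),",
      x$n_samples, "sample(s)\n")
  invisible(x)
}

node_depth <- function(tree, v) {
  d <- 0L
  while (tree$nodes[[v]]$parent != 0L) {
    v <- tree$nodes[[v]]$parent
    d <- d + 1L
  }
  d
}

# index sequence epsilon from root to v (integer() for the root)
node_path <- function(tree, v) {
  path <- integer(0)
  while (tree$nodes[[v]]$parent != 0L) {
    p <- tree$nodes[[v]]$parent
    path <- c(match(v, tree$nodes[[p]]$children), path)
    v <- p
  }
  path
}

# depth-first (preorder) comparison of two epsilon paths: a node precedes its
# descendants, and child i precedes child i+1. Returns -1, 0, or 1.
path_cmp <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0) {
    for (k in seq_len(n)) {
      if (a[k] < b[k]) return(-1L)
      if (a[k] > b[k]) return(1L)
    }
  }
  sign(length(a) - length(b))
}

# nodes listed with children after parents (root first)
preorder_indices <- function(tree) {
  out <- integer(0)
  stack <- 1L
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    ch <- tree$nodes[[v]]$children
    if (length(ch) > 0) stack <- c(stack, rev(ch))
  }
  out
}

subtree_indices <- function(tree, v) {
  out <- v
  stack <- tree$nodes[[v]]$children
  while (length(stack) > 0) {
    w <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, w)
    stack <- c(stack, tree$nodes[[w]]$children)
  }
  out
}

#' Stick-breaking weight of a node
#'
#' The prior mass the interleaved stick-breaking construction assigns to a
#' node: `omega = nu * prod over path edges of (psi_i * prod_{j<i} (1-psi_j))
#' * prod over proper ancestors of (1 - nu)`. The root's weight is its own
#' `nu`. Weights over the infinite tree sum to one, so instantiated nodes sum
#' to at most one.
#'
#' @param tree A `clone_tree`.
#' @param v Node index.
#' @return The probability `omega_v`.
#' @export
node_weight <- function(tree, v) exp(node_log_weight(tree, v))

node_log_weight <- function(tree, v) {
  single <- isTRUE(tree$single_clone)
  lw <- log(tree$nodes[[v]]$nu)
  while (tree$nodes[[v]]$parent != 0L) {
    p <- tree$nodes[[v]]$parent
    if (!(single && p == 1L)) {
      sibs <- tree$nodes[[p]]$children
      pos <- match(v, sibs)
      lw <- lw + log(tree$nodes[[v]]$psi)
      if (pos > 1) {
        for (j in seq_len(pos - 1)) {
          lw <- lw + log1p(-tree$nodes[[sibs[j]]]$psi)
        }
      }
    }
    lw <- lw + log1p(-tree$nodes[[p]]$nu)
    v <- p
  }
  lw
}

all_node_log_weights <- function(tree) {
  K <- length(tree$nodes)
  single <- isTRUE(tree$single_clone)
  lw <- numeric(K)
  # carry[v]: log mass reaching v's subtree region
  carry <- numeric(K)
  for (v in preorder_indices(tree)) {
    node <- tree$nodes[[v]]
    lw[v] <- carry[v] + log(node$nu)
    rest <- carry[v] + log1p(-node$nu)
    if (single && v == 1L) {
      # the root's single child takes the whole descendant region
      if (length(node$children) > 0) carry[node$children[1]] <- rest
    } else {
      acc <- 0
      for (w in node$children) {
        carry[w] <- rest + acc + log(tree$nodes[[w]]$psi)
        acc <- acc + log1p(-tree$nodes[[w]]$psi)
      }
    }
  }
  lw
}

# mass covered by the instantiated part of the tree; 1 - residual
covered_mass <- function(tree, v = 1L) {
  node <- tree$nodes[[v]]
  if (isTRUE(tree$single_clone) && v == 1L) {
    acc_children <- if (length(node$children) > 0) {
      covered_mass(tree, node$children[1])
    } else {
      0
    }
    return(node$nu + (1 - node$nu) * acc_children)
  }
  acc_children <- 0
  remaining <- 1
  for (w in node$children) {
    psi <- tree$nodes[[w]]$psi
    acc_children <- acc_children + remaining * psi * covered_mass(tree, w)
    remaining <- remaining * (1 - psi)
  }
  node$nu + (1 - node$nu) * acc_children
}

# instantiate the next child of `parent`, drawing its sticks from the prior.
# With `with_eta` the new node immediately takes Uniform(0, eta_parent)
# auxiliary weight from its parent; transient nodes created during slice
# search are instantiated without weight and only receive a (tentative) draw
# when they are evaluated as candidates, so the search does not bleed the
# parent's weight.
instantiate_child <- function(tree, parent, with_eta = TRUE) {
  hy <- tree$hypers
  depth <- node_depth(tree, parent) + 1L
  child <- new_node(parent, tree$n_samples,
                    nu = rbeta_stick(1, alpha_at_depth(hy, depth)),
                    psi = rbeta_stick(1, hy$gamma))
  if (with_eta) {
    eta_p <- tree$nodes[[parent]]$eta
    eta_c <- stats::runif(tree$n_samples) * eta_p
    child$eta <- eta_c
    tree$nodes[[parent]]$eta <- eta_p - eta_c
  }
  tree$nodes[[length(tree$nodes) + 1L]] <- child
  idx <- length(tree$nodes)
  tree$nodes[[parent]]$children <- c(tree$nodes[[parent]]$children, idx)
  list(tree = tree, node = idx)
}

# map u in [0,1) to a node by inverting the stick representation, lazily
# instantiating sticks as needed (retrospective sampling)
find_node <- function(tree, u) {
  v <- 1L
  depth <- 0L
  repeat {
    nu <- tree$nodes[[v]]$nu
    if (u < nu || depth >= MAX_DEPTH) {
      return(list(tree = tree, node = v))
    }
    u <- (u - nu) / (1 - nu)
    if (isTRUE(tree$single_clone) && v == 1L) {
      if (length(tree$nodes[[1L]]$children) == 0) {
        res <- instantiate_child(tree, 1L, with_eta = FALSE)
        tree <- res$tree
      }
      v <- tree$nodes[[1L]]$children[1]
    } else {
      i <- 1L
      repeat {
        if (i > length(tree$nodes[[v]]$children)) {
          res <- instantiate_child(tree, v, with_eta = FALSE)
          tree <- res$tree
        }
        w <- tree$nodes[[v]]$children[i]
        psi <- tree$nodes[[w]]$psi
        if (u < psi || i >= MAX_WIDTH) {
          u <- min(u / psi, 1 - 1e-12)
          v <- w
          break
        }
        u <- (u - psi) / (1 - psi)
        i <- i + 1L
      }
    }
    depth <- depth + 1L
  }
}

#' Forward-sample node assignments from the tree prior
#'
#' Draws `n_draws` assignments from the tree-structured stick-breaking prior
#' with sticks `nu ~ Beta(1, lambda^depth * alpha0)` and
#' `psi ~ Beta(1, gamma)`, instantiating nodes lazily. Serves as the prior
#' oracle for the Gibbs kernels.
#'
#' @param n_draws Number of draws.
#' @param alpha0,gamma,lambda Hyperparameters of the prior.
#' @return Integer vector of node indices (with the generated tree attached
#'   as attribute `"tree"`; index paths as attribute `"paths"`).
#' @export
forward_sample_tree <- function(n_draws, alpha0 = 5, gamma = 1, lambda = 1) {
  tree <- new_clone_tree(
    n_samples = 1L, n_snvs = 0L,
    hypers = list(alpha0 = alpha0, gamma = gamma, lambda = lambda)
  )
  draws <- integer(n_draws)
  for (k in seq_len(n_draws)) {
    res <- find_node(tree, stats::runif(1))
    tree <- res$tree
    draws[k] <- res$node
  }
  attr(draws, "tree") <- tree
  attr(draws, "paths") <- lapply(draws, function(v) node_path(tree, v))
  draws
}

# ---- Gibbs updates ---------------------------------------------------------

# log-likelihood of SNV i (all samples) when assigned to node v
snv_ll_at_node <- function(tree, data, ga, i, v) {
  phi_v <- phi_from_eta_matrix(tree, eta_matrix(tree))[v, , drop = FALSE]
  snv_ll_profile_cpp(data$b[i, ], data$d[i, ],
                     lchoose(data$d[i, ], data$b[i, ]),
                     ga$mu_r[i], ga$mu_v[[i]], ga$log_w[[i]], phi_v)[1]
}

snv_ll_point <- function(b, d, mu_r, mu_v, log_w, phi) {
  p_var <- 1 - pmin(pmax((1 - phi) * mu_r + phi * mu_v, 1e-10), 1 - 1e-10)
  terms <- log_w + stats::dbinom(b, d, p_var, log = TRUE)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

eta_matrix <- function(tree) {
  # nodes x samples, robust to S == 1
  t(matrix(unlist(lapply(tree$nodes, function(n) n$eta)),
           nrow = tree$n_samples))
}

phi_from_eta_matrix <- function(tree, eta) {
  phi <- eta
  for (v in rev(preorder_indices(tree))) {
    for (w in tree$nodes[[v]]$children) phi[v, ] <- phi[v, ] + phi[w, ]
  }
  phi
}

#' Resample SNV-to-node assignments (Gibbs step)
#'
#' Each SNV is reassigned to node `v` with conditional probability
#' proportional to `omega_v * prod_t L(i, t, phi_v^t)`, using
#' slice-retrospective sampling: candidates are drawn proportional to the
#' stick weights by inverting the stick representation and accepted against a likelihood slice,
#' shrinking the interval by depth-first path order. New nodes may be
#' instantiated (sticks from the prior, auxiliary weight split uniformly from
#' the parent); unoccupied leaf paths are culled afterwards.
#'
#' @param tree A `clone_tree` with valid per-sample weights.
#' @param data An [snv_data()] object.
#' @param order Order in which SNVs are updated; defaults to a random
#'   permutation.
#' @return The tree with updated assignments.
#' @export
gibbs_assignments <- function(tree, data, order = NULL) {
  if (length(tree$z) == 0) return(tree)
  ga <- genotype_arrays(data)
  if (is.null(order)) order <- sample(seq_along(tree$z))
  for (i in order) {
    old <- tree$z[i]
    old_path <- node_path(tree, old)
    ll_cur <- snv_ll_at_node(tree, data, ga, i, old)
    log_u <- ll_cur + log(stats::runif(1))
    u_min <- 0
    u_max <- 1
    repeat {
      u <- stats::runif(1, u_min, u_max)
      res <- find_node(tree, u)
      tree <- res$tree
      v <- res$node
      # a fresh (weightless, unoccupied) candidate gets a tentative weight
      # drawn Uniform(0, eta_parent); it is committed (parent decremented)
      # only on acceptance
      fresh <- v != 1L && sum(tree$nodes[[v]]$eta) == 0 && !any(tree$z == v)
      if (fresh) {
        p <- tree$nodes[[v]]$parent
        tree$nodes[[v]]$eta <- stats::runif(tree$n_samples) *
          tree$nodes[[p]]$eta
      }
      ll <- snv_ll_at_node(tree, data, ga, i, v)
      if (ll > log_u) {
        if (fresh) {
          p <- tree$nodes[[v]]$parent
          tree$nodes[[p]]$eta <- tree$nodes[[p]]$eta - tree$nodes[[v]]$eta
        }
        tree$z[i] <- v
        break
      }
      if (fresh) tree$nodes[[v]]$eta <- numeric(tree$n_samples)
      if (u_max - u_min < 1e-9) {
        tree$z[i] <- old
        break
      }
      cmp <- path_cmp(node_path(tree, v), old_path)
      if (cmp < 0) u_min <- u else if (cmp > 0) u_max <- u
    }
    # cull unoccupied candidates right away: they would otherwise hold
    # auxiliary weight hostage for the rest of the sweep
    tree <- cull_tree(tree)
  }
  tree
}

# stick-breaking bookkeeping for the candidate scan: for every node, its log
# weight, and the log prior mass of its next (uninstantiated) child
node_weight_table <- function(tree) {
  K <- length(tree$nodes)
  single <- isTRUE(tree$single_clone)
  lw <- numeric(K)
  fresh_base <- numeric(K) # log mass reaching the next-child region of v
  carry <- numeric(K)
  for (v in preorder_indices(tree)) {
    node <- tree$nodes[[v]]
    lw[v] <- carry[v] + log(node$nu)
    rest <- carry[v] + log1p(-node$nu)
    if (single && v == 1L) {
      if (length(node$children) > 0) {
        carry[node$children[1]] <- rest
        fresh_base[v] <- -Inf
      } else {
        fresh_base[v] <- rest
      }
    } else {
      acc <- 0
      for (w in node$children) {
        carry[w] <- rest + acc + log(tree$nodes[[w]]$psi)
        acc <- acc + log1p(-tree$nodes[[w]]$psi)
      }
      fresh_base[v] <- rest + acc
    }
  }
  list(log_w = lw, fresh_base = fresh_base)
}

# like instantiate_child() but with given sticks and committed weight
commit_child <- function(tree, parent, nu, psi, eta) {
  child <- new_node(parent, tree$n_samples, nu = nu, psi = psi)
  child$eta <- eta
  tree$nodes[[parent]]$eta <- tree$nodes[[parent]]$eta - eta
  tree$nodes[[length(tree$nodes) + 1L]] <- child
  idx <- length(tree$nodes)
  tree$nodes[[parent]]$children <- c(tree$nodes[[parent]]$children, idx)
  list(tree = tree, node = idx)
}

#' Auxiliary-candidate Gibbs scan over SNV assignments
#'
#' Complementary assignment move: each SNV picks among all instantiated
#' nodes plus one fresh candidate child per node (sticks drawn from the
#' prior, tentative weight `Uniform(0, eta_parent)`), with probability
#' proportional to the stick-breaking weight times the read-count
#' likelihood. Fresh candidates are committed to the tree only when
#' selected, so rejected proposals leave no trace. This move crosses the
#' low-probability valleys that single-candidate slice updates cannot (a
#' high-frequency cluster trapped at the root escapes as soon as one
#' tentative weight lands near its frequency).
#'
#' @param tree A `clone_tree`.
#' @param data An [snv_data()] object.
#' @param order SNV update order (default: random permutation).
#' @param n_fresh Number of auxiliary fresh candidates per node; the
#'   next-child prior mass is split evenly among them.
#' @return The updated tree.
#' @export
gibbs_fresh_scan <- function(tree, data, order = NULL, n_fresh = 3L) {
  if (length(tree$z) == 0) return(tree)
  ga <- genotype_arrays(data)
  S <- tree$n_samples
  if (is.null(order)) order <- sample(seq_along(tree$z))
  lch <- lchoose(data$d, data$b)
  for (i in order) {
    K <- length(tree$nodes)
    tab <- node_weight_table(tree)
    phi <- phi_from_eta_matrix(tree, eta_matrix(tree))
    hy <- tree$hypers
    n_cand <- K * (1L + n_fresh)
    # fresh candidates: sticks from the prior, tentative weights from the
    # would-be parent (all drawn in a batch)
    depths1 <- vapply(seq_len(K), node_depth, integer(1), tree = tree) + 1L
    nu_f <- pmin(pmax(stats::rbeta(K * n_fresh, 1,
                                   alpha_at_depth(hy, rep(depths1,
                                                          each = n_fresh))),
                      1e-10), 1 - 1e-10)
    psi_f <- pmin(pmax(stats::rbeta(K * n_fresh, 1, hy$gamma), 1e-10),
                  1 - 1e-10)
    u_f <- matrix(stats::runif(K * n_fresh * S), K * n_fresh, S)
    eta_parent <- t(vapply(seq_len(K), function(v) tree$nodes[[v]]$eta,
                           numeric(S)))
    if (S == 1) eta_parent <- matrix(eta_parent, ncol = 1)
    eta_f <- u_f * eta_parent[rep(seq_len(K), each = n_fresh), , drop = FALSE]
    cand_phi <- rbind(phi, eta_f)
    ll_all <- snv_ll_profile_cpp(data$b[i, ], data$d[i, ], lch[i, ],
                                 ga$mu_r[i], ga$mu_v[[i]], ga$log_w[[i]],
                                 cand_phi)
    logp <- numeric(n_cand)
    logp[seq_len(K)] <- tab$log_w + ll_all[seq_len(K)]
    idx_f <- K + seq_len(K * n_fresh)
    logp[idx_f] <- tab$fresh_base[rep(seq_len(K), each = n_fresh)] -
      log(n_fresh) + log(psi_f) + log(nu_f) + ll_all[idx_f]
    fresh <- lapply(seq_len(K * n_fresh), function(k) {
      list(parent = (k - 1L) %/% n_fresh + 1L, nu = nu_f[k], psi = psi_f[k],
           eta = eta_f[k, ])
    })
    # Gumbel-max categorical draw on the log scale
    pick <- which.max(logp - log(-log(stats::runif(n_cand))))
    if (pick <= K) {
      tree$z[i] <- pick
    } else {
      cand <- fresh[[pick - K]]
      res <- commit_child(tree, cand$parent, cand$nu, cand$psi, cand$eta)
      tree <- res$tree
      tree$z[i] <- res$node
    }
  }
  cull_tree(tree)
}

# joint log prior of the current tree state: assignment stick weights,
# auxiliary-weight density, and stick densities (nu depends on depth)
tree_log_prior <- function(tree) {
  lw <- all_node_log_weights(tree)
  sc <- if (length(tree$z) > 0) sum(lw[tree$z]) else 0
  eta <- eta_matrix(tree)
  for (t in seq_len(tree$n_samples)) {
    sc <- sc + eta_prior_log_density(tree, eta[, t])
  }
  sc + nu_stick_loglik(tree, tree$hypers$alpha0, tree$hypers$lambda) +
    psi_stick_loglik(tree, tree$hypers$gamma)
}

#' Subtree relocation Metropolis move
#'
#' Detaches a random subtree and reattaches it under another node that holds
#' enough auxiliary weight, transferring the subtree's weight out of the new
#' parent's own weight and back into the old parent's. Every node frequency
#' -- and hence the read-count likelihood -- is unchanged, so the move is
#' accepted on the prior ratio alone. This is what lets the chain move
#' between branching and chain placements of clusters whose frequencies
#' admit both.
#'
#' @param tree A `clone_tree`.
#' @param n_moves Number of attempted relocations.
#' @return The updated tree.
#' @export
subtree_relocations <- function(tree, n_moves = length(tree$nodes)) {
  K <- length(tree$nodes)
  if (K < 3) return(tree)
  for (rep in seq_len(n_moves)) {
    w <- if (K == 2) 2L else sample(2:K, 1)
    sub <- subtree_indices(tree, w)
    p <- tree$nodes[[w]]$parent
    pool <- setdiff(seq_len(K), c(sub, p))
    if (isTRUE(tree$single_clone)) pool <- setdiff(pool, 1L)
    if (length(pool) == 0) next
    q <- if (length(pool) == 1) pool else sample(pool, 1)
    eta <- eta_matrix(tree)
    m <- colSums(eta[sub, , drop = FALSE])
    if (any(tree$nodes[[q]]$eta < m)) next
    # depth guard: the relocated subtree must stay within bounds
    sub_depth <- max(vapply(sub, node_depth, integer(1), tree = tree)) -
      node_depth(tree, w)
    if (node_depth(tree, q) + 1L + sub_depth > MAX_DEPTH) next
    old_score <- tree_log_prior(tree)
    cand <- tree
    cand$nodes[[p]]$children <- setdiff(cand$nodes[[p]]$children, w)
    cand$nodes[[p]]$eta <- cand$nodes[[p]]$eta + m
    cand$nodes[[q]]$eta <- cand$nodes[[q]]$eta - m
    cand$nodes[[q]]$children <- c(cand$nodes[[q]]$children, w)
    cand$nodes[[w]]$parent <- q
    new_score <- tree_log_prior(cand)
    # proposal is symmetric: same node count, same subtree, same pool size
    if (is.finite(new_score) &&
        log(stats::runif(1)) < new_score - old_score) {
      tree <- cand
    }
  }
  tree
}

#' Parent-insertion / deletion Metropolis moves at the root
#'
#' Under the single-founding-clone assumption the root has one child, and no
#' ordinary assignment move can ever create a lineage *above* the current
#' founding clone -- a high-frequency SNV caught inside a fused founding
#' cluster would stay trapped forever. This reversible move pair fixes that:
#' *insert* proposes a new node between the root and its unique child,
#' taking `Uniform(0, eta_root)` weight and one SNV; *delete* removes such a
#' single-SNV, single-child node, returning its weight to the root and
#' relocating its SNV. Acceptance uses the exact Metropolis-Hastings ratio
#' (joint prior, the moved SNV's likelihood, and both proposal densities).
#'
#' @param tree A `clone_tree` with `single_clone = TRUE`.
#' @param data An [snv_data()] object.
#' @param n_attempts Number of proposals per call.
#' @return The updated tree.
#' @export
root_parent_moves <- function(tree, data, n_attempts = 2L) {
  if (!isTRUE(tree$single_clone) || length(tree$z) == 0) return(tree)
  ga <- genotype_arrays(data)
  for (rep in seq_len(n_attempts)) {
    K <- length(tree$nodes)
    do_insert <- stats::runif(1) < 0.5
    if (do_insert) {
      if (length(tree$nodes[[1]]$children) != 1) next
      top <- tree$nodes[[1]]$children[1]
      i <- sample.int(length(tree$z), 1)
      v_old <- tree$z[i]
      eta_root <- tree$nodes[[1]]$eta
      if (any(eta_root <= 0)) next
      eta_w <- stats::runif(tree$n_samples) * eta_root
      nu_w <- rbeta_stick(1, alpha_at_depth(tree$hypers, 1))
      cand <- tree
      w <- K + 1L
      node_w <- new_node(1L, tree$n_samples, nu = nu_w, psi = 0.5)
      node_w$eta <- eta_w
      node_w$children <- top
      cand$nodes[[w]] <- node_w
      cand$nodes[[1]]$children <- w
      cand$nodes[[1]]$eta <- eta_root - eta_w
      cand$nodes[[top]]$parent <- w
      cand$z[i] <- w
      ll_old <- snv_ll_at_node(tree, data, ga, i, v_old)
      ll_new <- snv_ll_at_node(cand, data, ga, i, w)
      lq_fwd <- -log(length(tree$z)) - sum(log(eta_root)) +
        stats::dbeta(nu_w, 1, alpha_at_depth(tree$hypers, 1), log = TRUE)
      lq_rev <- -log(K) # destination choice among the K surviving nodes
      log_ratio <- tree_log_prior(cand) - tree_log_prior(tree) +
        ll_new - ll_old + lq_rev - lq_fwd
      if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
        tree <- cull_tree(cand)
      }
    } else {
      if (length(tree$nodes[[1]]$children) != 1) next
      w <- tree$nodes[[1]]$children[1]
      at_w <- which(tree$z == w)
      if (length(at_w) != 1 || length(tree$nodes[[w]]$children) != 1) next
      i <- at_w
      dest_pool <- setdiff(seq_len(K), w)
      v_new <- if (length(dest_pool) == 1) dest_pool else
        sample(dest_pool, 1)
      eta_w <- tree$nodes[[w]]$eta
      cand <- tree
      top <- tree$nodes[[w]]$children[1]
      cand$nodes[[1]]$children <- top
      cand$nodes[[top]]$parent <- 1L
      cand$nodes[[1]]$eta <- cand$nodes[[1]]$eta + eta_w
      cand$z[i] <- v_new
      # drop w and renumber
      keepers <- setdiff(seq_len(K), w)
      remap <- integer(K)
      remap[keepers] <- seq_along(keepers)
      cand$nodes <- lapply(cand$nodes[keepers], function(nd) {
        nd$parent <- if (nd$parent == 0L) 0L else remap[nd$parent]
        nd$children <- remap[setdiff(nd$children, w)]
        nd
      })
      cand$z <- remap[cand$z]
      ll_old <- snv_ll_at_node(tree, data, ga, i, w)
      ll_new <- snv_ll_at_node(cand, data, ga, i, cand$z[i])
      eta_root_after <- cand$nodes[[1]]$eta
      lq_fwd <- -log(K - 1)
      lq_rev <- -log(length(tree$z)) - sum(log(eta_root_after)) +
        stats::dbeta(tree$nodes[[w]]$nu, 1,
                     alpha_at_depth(tree$hypers, 1), log = TRUE)
      log_ratio <- tree_log_prior(cand) - tree_log_prior(tree) +
        ll_new - ll_old + lq_rev - lq_fwd
      if (is.finite(log_ratio) && log(stats::runif(1)) < log_ratio) {
        tree <- cand
      }
    }
  }
  tree
}

# occupancy counts: n_v (SNVs at node), s_v (SNVs in subtree incl. node)
occupancy <- function(tree) {
  K <- length(tree$nodes)
  n_v <- tabulate(tree$z, nbins = K)
  s_v <- n_v
  for (v in rev(preorder_indices(tree))) {
    for (w in tree$nodes[[v]]$children) s_v[v] <- s_v[v] + s_v[w]
  }
  list(n = n_v, s = s_v)
}

#' Resample stick lengths and stick-breaking hyperparameters (Gibbs step)
#'
#' Sticks get conjugate Beta updates from occupancy counts:
#' `nu_v ~ Beta(1 + n_v, alpha(depth) + n_descendants)` and each child stick
#' `psi_i ~ Beta(1 + s_i, gamma + sum_{j>i} s_j)` where `s` counts SNVs in a
#' child's subtree. Hyperparameters `alpha0`, `gamma`, `lambda` are updated
#' by Metropolis steps under uniform priors on their configured ranges.
#'
#' @param tree A `clone_tree` with current assignments.
#' @param n_hyper_steps Metropolis proposals per hyperparameter.
#' @return The updated tree.
#' @export
gibbs_sticks_and_hypers <- function(tree, n_hyper_steps = 5L) {
  occ <- occupancy(tree)
  hy <- tree$hypers
  for (v in seq_along(tree$nodes)) {
    depth <- node_depth(tree, v)
    n_desc <- occ$s[v] - occ$n[v]
    tree$nodes[[v]]$nu <- rbeta_stick(1 + occ$n[v],
                                      alpha_at_depth(hy, depth) + n_desc)
    ch <- tree$nodes[[v]]$children
    if (length(ch) > 0) {
      s_ch <- occ$s[ch]
      for (k in seq_along(ch)) {
        later <- if (k < length(ch)) sum(s_ch[(k + 1):length(ch)]) else 0
        tree$nodes[[ch[k]]]$psi <- rbeta_stick(1 + s_ch[k], hy$gamma + later)
      }
    }
  }
  tree <- update_hypers(tree, n_hyper_steps)
  tree
}

# log p(sticks | alpha0, lambda) and log p(psi sticks | gamma)
nu_stick_loglik <- function(tree, alpha0, lambda) {
  sum(vapply(seq_along(tree$nodes), function(v) {
    a <- lambda^node_depth(tree, v) * alpha0
    stats::dbeta(tree$nodes[[v]]$nu, 1, a, log = TRUE)
  }, numeric(1)))
}

psi_stick_loglik <- function(tree, gamma) {
  psis <- vapply(tree$nodes, function(n) n$psi, numeric(1))
  if (isTRUE(tree$single_clone)) {
    parents <- vapply(tree$nodes, function(n) n$parent, integer(1))
    psis[parents == 1L] <- NA_real_
  }
  psis <- psis[!is.na(psis)]
  if (length(psis) == 0) return(0)
  sum(stats::dbeta(psis, 1, gamma, log = TRUE))
}

update_hypers <- function(tree, n_steps = 5L) {
  rg <- tree$ranges
  hy <- tree$hypers
  for (s in seq_len(n_steps)) {
    # alpha0 and lambda (nu sticks), independent uniform proposals
    for (nm in c("alpha0", "lambda")) {
      prop <- hy
      prop[[nm]] <- stats::runif(1, rg[[nm]][1], rg[[nm]][2])
      log_r <- nu_stick_loglik(tree, prop$alpha0, prop$lambda) -
        nu_stick_loglik(tree, hy$alpha0, hy$lambda)
      if (is.finite(log_r) && log(stats::runif(1)) < log_r) hy <- prop
    }
    prop_gamma <- stats::runif(1, rg$gamma[1], rg$gamma[2])
    log_r <- psi_stick_loglik(tree, prop_gamma) - psi_stick_loglik(tree, hy$gamma)
    if (is.finite(log_r) && log(stats::runif(1)) < log_r) hy$gamma <- prop_gamma
  }
  tree$hypers <- hy
  tree
}

#' Remove unoccupied leaf branches
#'
#' Drops every node that holds no SNV and has no occupied descendant (the
#' root always stays). The auxiliary weight of a removed branch is returned
#' to its retained parent so the weights still sum to one per sample.
#'
#' @param tree A `clone_tree`.
#' @return The culled tree (node indices are renumbered).
#' @export
cull_tree <- function(tree) {
  K <- length(tree$nodes)
  occ <- occupancy(tree)
  keep <- occ$s > 0
  keep[1] <- TRUE
  if (all(keep)) return(tree)
  # return eta of removed subtrees to the nearest kept ancestor
  eta <- eta_matrix(tree)
  for (v in preorder_indices(tree)) {
    if (!keep[v]) next
    for (w in tree$nodes[[v]]$children) {
      if (!keep[w]) {
        sub <- subtree_indices(tree, w)
        extra <- colSums(eta[sub, , drop = FALSE])
        tree$nodes[[v]]$eta <- tree$nodes[[v]]$eta + extra
      }
    }
  }
  new_idx <- cumsum(keep)
  new_idx[!keep] <- NA_integer_
  nodes <- vector("list", sum(keep))
  for (v in which(keep)) {
    node <- tree$nodes[[v]]
    node$parent <- if (node$parent == 0L) 0L else new_idx[node$parent]
    node$children <- new_idx[node$children[keep[node$children]]]
    nodes[[new_idx[v]]] <- node
  }
  tree$nodes <- nodes
  tree$z <- new_idx[tree$z]
  tree
}
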