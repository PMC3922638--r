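# Posterior consensus summaries: co-clustering, correlation clustering,
# parent-edge frequencies, and the partial order plot emitted as DOT.

#' Co-clustering matrix from a posterior trace
#'
#' `C[i, j]` is the number of posterior samples in which SNVs `i` and `j`
#' share a node minus the number in which they do not; the diagonal equals
#' the number of samples.
#'
#' @param fit A `clone_tree_fit`.
#' @return Symmetric integer matrix with SNV ids as dimnames (class
#'   `cocluster_matrix`).
#' @export
coclustering_matrix <- function(fit) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  if (length(fit$snapshots) == 0) stop("empty trace.", call. = FALSE)
  ids <- fit$data$snv_ids
  N <- length(ids)
  together <- matrix(0L, N, N)
  for (sn in fit$snapshots) {
    together <- together + outer(sn$z, sn$z, "==")
  }
  M <- length(fit$snapshots)
  C <- 2L * together - M
  dimnames(C) <- list(ids, ids)
  class(C) <- c("cocluster_matrix", class(C))
  C
}

correlation_objective <- function(C, labels) {
  same <- outer(labels, labels, "==")
  sum(C[upper.tri(C)][same[upper.tri(same)]])
}

#' Correlation clustering of a signed co-clustering matrix
#'
#' Partitions SNVs to maximize the sum of `C[i, j]` over within-cluster
#' pairs (equivalently, agreement within minus disagreement across).
#' Correlation clustering is NP-hard; this uses greedy agglomeration plus
#' single-move local search with random restarts, ties broken toward the
#' lowest SNV index.
#'
#' @param C Symmetric matrix (e.g. from [coclustering_matrix()]).
#' @param n_restarts Random restarts of the local search.
#' @return Integer cluster labels (named by SNV id when `C` has dimnames),
#'   with the objective value in attribute `"objective"`.
#' @export
correlation_cluster <- function(C, n_restarts = 10) {
  C <- unclass(as.matrix(C))
  N <- nrow(C)
  diag(C) <- 0
  local_search <- function(labels) {
    repeat {
      improved <- FALSE
      for (i in seq_len(N)) {
        # gain of moving i into each existing cluster, vs a new singleton (0)
        ks <- sort(unique(labels))
        gains <- vapply(ks, function(k) {
          sum(C[i, labels == k & seq_len(N) != i])
        }, numeric(1))
        cur <- gains[match(labels[i], ks)]
        best_gain <- max(gains)
        if (max(best_gain, 0) > cur + 1e-9) {
          labels[i] <- if (best_gain > 0) {
            ks[which.max(gains)]
          } else {
            max(labels) + 1L
          }
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    labels
  }
  greedy_start <- function(order) {
    labels <- integer(N)
    labels[order[1]] <- 1L
    next_label <- 2L
    for (i in order[-1]) {
      assigned <- which(labels > 0)
      gains <- vapply(seq_len(next_label - 1), function(k) {
        sum(C[i, assigned[labels[assigned] == k]])
      }, numeric(1))
      if (length(gains) > 0 && max(gains) > 0) {
        labels[i] <- which.max(gains)
      } else {
        labels[i] <- next_label
        next_label <- next_label + 1L
      }
    }
    labels
  }
  best_labels <- NULL
  best_obj <- -Inf
  orders <- c(list(seq_len(N)),
              lapply(seq_len(max(0, n_restarts - 1)), function(k) sample(N)))
  for (ord in orders) {
    labels <- local_search(greedy_start(ord))
    obj <- correlation_objective(C, labels)
    if (obj > best_obj) {
      best_obj <- obj
      best_labels <- labels
    }
  }
  # canonical labels: clusters numbered by their lowest member index
  canon <- match(best_labels, unique(best_labels[order(seq_len(N))]))
  names(canon) <- rownames(C)
  attr(canon, "objective") <- best_obj
  canon
}

# exhaustive partition maximizer, used as a test oracle for small N
brute_force_partition <- function(C) {
  C <- unclass(as.matrix(C))
  N <- nrow(C)
  diag(C) <- 0
  best <- NULL
  best_obj <- -Inf
  labels <- integer(N)
  recurse <- function(i, labels, n_used) {
    if (i > N) {
      obj <- correlation_objective(C, labels)
      if (obj > best_obj) {
        best_obj <<- obj
        best <<- labels
      }
      return(invisible())
    }
    for (k in seq_len(n_used + 1)) {
      labels[i] <- k
      recurse(i + 1, labels, max(n_used, k))
    }
  }
  recurse(1L, labels, 0L)
  attr(best, "objective") <- best_obj
  best
}

#' Posterior parent-edge frequencies between SNVs
#'
#' For each ordered SNV pair (P, Q), the fraction of posterior samples in
#' which the node where P first appears is the parent of the node where Q
#' first appears. SNVs sharing a node contribute no edge between each other.
#'
#' @param fit A `clone_tree_fit`.
#' @return Tibble with columns `parent`, `child`, `weight` (only pairs with
#'   positive weight).
#' @export
edge_frequencies <- function(fit) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  if (length(fit$snapshots) == 0) stop("empty trace.", call. = FALSE)
  ids <- fit$data$snv_ids
  N <- length(ids)
  counts <- matrix(0, N, N, dimnames = list(ids, ids))
  for (sn in fit$snapshots) {
    parent_node_of_snv <- sn$parent[sn$z]
    is_parent <- outer(sn$z, parent_node_of_snv, "==")
    diag(is_parent) <- FALSE
    counts <- counts + is_parent
  }
  w <- counts / length(fit$snapshots)
  idx <- which(w > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    parent = ids[idx[, 1]], child = ids[idx[, 2]], weight = w[idx]
  )
  dplyr::arrange(out, .data$parent, .data$child)
}

#' Partial order summary of the posterior over trees
#'
#' Combines [edge_frequencies()] (edge weight = posterior probability that
#' one SNV's lineage directly parents another's) with
#' [correlation_cluster()] labels from the co-clustering matrix.
#'
#' @param fit A `clone_tree_fit`.
#' @param n_restarts Restarts for the correlation clustering.
#' @return A `partial_order` object: list with `nodes` (tibble: `id`,
#'   `cluster`) and `edges` (tibble: `parent`, `child`, `weight`).
#' @export
partial_order <- function(fit, n_restarts = 10) {
  C <- coclustering_matrix(fit)
  labels <- correlation_cluster(C, n_restarts)
  structure(
    list(
      nodes = tibble::tibble(id = fit$data$snv_ids,
                             cluster = as.integer(labels)),
      edges = edge_frequencies(fit)
    ),
    class = "partial_order"
  )
}

#' @export
print.partial_order <- function(x, ...) {
  cat("<partial_order>", nrow(x$nodes), "SNVs,", nrow(x$edges), "edges\n")
  print(x$edges)
  invisible(x)
}

#' Write a partial order as Graphviz DOT text
#'
#' Emits a deterministic DOT digraph: nodes sorted by SNV id with border
#' color by cluster, edges above `edge_threshold` with pen width
#' proportional to weight. Layout is delegated to any DOT renderer.
#'
#' @param po A [partial_order()] object (or a list with `nodes`/`edges`
#'   tibbles of the same shape).
#' @param edge_threshold Drop edges with weight below this (default 0.1).
#' @param path Optional file to write to.
#' @return The DOT text, invisibly when `path` is given.
#' @export
write_dot <- function(po, edge_threshold = 0.1, path = NULL) {
  palette <- c("red", "blue", "forestgreen", "orange", "purple", "brown",
               "deeppink", "cadetblue")
  nodes <- po$nodes[order(po$nodes$id), , drop = FALSE]
  lines <- c("digraph partial_order {", "  rankdir=TB;")
  for (i in seq_len(nrow(nodes))) {
    col <- palette[(nodes$cluster[i] - 1) %% length(palette) + 1]
    lines <- c(lines, sprintf("  \"%s\" [color=%s];", nodes$id[i], col))
  }
  edges <- po$edges[po$edges$weight >= edge_threshold, , drop = FALSE]
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [penwidth=%.3f, weight=%.3f];",
      edges$parent[i], edges$child[i], 0.5 + 4 * edges$weight[i],
      edges$weight[i]
    ))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# canonical string for the occupied-node structure of one snapshot: empty
# nodes are contracted onto their nearest occupied ancestor (or the implicit
# root), each node prints its sorted SNV cluster ids and its children's
# signatures in sorted order
structure_signature <- function(sn, ids) {
  occupied <- sort(unique(sn$z))
  nearest_occ <- function(v) {
    v <- sn$parent[v]
    while (v != 0L && !(v %in% occupied)) v <- sn$parent[v]
    v
  }
  kids <- lapply(occupied, function(v) integer(0))
  names(kids) <- occupied
  top <- integer(0)
  for (v in occupied) {
    p <- nearest_occ(v)
    if (p == 0L) top <- c(top, v) else {
      kids[[as.character(p)]] <- c(kids[[as.character(p)]], v)
    }
  }
  sig <- function(v) {
    own <- paste(sort(ids[sn$z == v]), collapse = ",")
    ch <- vapply(kids[[as.character(v)]], sig, character(1))
    paste0("(", own, if (length(ch) > 0) paste0("->[",
      paste(sort(ch), collapse = ";"), "]"), ")")
  }
  paste(sort(vapply(top, sig, character(1))), collapse = "+")
}

#' Posterior distribution over occupied-tree structures
#'
#' Tallies, across posterior samples, the canonical structure of the
#' occupied nodes (clusters of SNVs and their ancestry; unoccupied
#' pass-through nodes are contracted).
#'
#' @param fit A `clone_tree_fit`.
#' @return Tibble with columns `structure` and `probability`, sorted by
#'   decreasing probability. The modal tree is the first row.
#' @export
posterior_structures <- function(fit) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  sigs <- vapply(fit$snapshots, structure_signature, character(1),
                 ids = fit$data$snv_ids)
  tab <- sort(table(sigs), decreasing = TRUE)
  tibble::tibble(structure = names(tab),
                 probability = as.numeric(tab) / length(sigs))
}

# cumulative lineage genotypes (one character key per node) of one snapshot
snapshot_genotypes <- function(sn, ids) {
  K <- length(sn$parent)
  sets <- vector("list", K)
  at_node <- split(seq_along(sn$z), factor(sn$z, levels = seq_len(K)))
  # parents precede children in snapshot node numbering only after culling;
  # walk in an order where parents come first
  order <- integer(0)
  queue <- which(sn$parent == 0L)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    queue <- c(queue, which(sn$parent == v))
  }
  for (v in order) {
    own <- ids[at_node[[v]]]
    inherited <- if (sn$parent[v] == 0L) character(0) else sets[[sn$parent[v]]]
    sets[[v]] <- sort(unique(c(inherited, own)))
  }
  sets
}

#' Posterior probability of a lineage genotype
#'
#' Fraction of posterior samples containing a node whose cumulative genotype
#' (the union of SNVs first appearing along its ancestral path, including its
#' own) is exactly the query set.
#'
#' @param fit A `clone_tree_fit`.
#' @param snvs Character vector of SNV ids defining the genotype.
#' @return Probability in `[0, 1]`.
#' @export
genotype_posterior <- function(fit, snvs) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  query <- sort(unique(as.character(snvs)))
  hits <- vapply(fit$snapshots, function(sn) {
    sets <- snapshot_genotypes(sn, fit$data$snv_ids)
    any(vapply(sets, function(s) identical(s, query), logical(1)))
  }, logical(1))
  mean(hits)
}

#' All lineage genotypes and their posterior probabilities
#'
#' @param fit A `clone_tree_fit`.
#' @return Tibble with columns `genotype` (comma-joined sorted SNV ids) and
#'   `probability`, sorted by decreasing probability. Empty genotypes (nodes
#'   holding no SNVs on their path) are dropped.
#' @export
lineage_genotypes <- function(fit) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  tally <- new.env(parent = emptyenv())
  for (sn in fit$snapshots) {
    sets <- snapshot_genotypes(sn, fit$data$snv_ids)
    keys <- unique(vapply(sets, paste, character(1), collapse = ","))
    keys <- keys[keys != ""]
    for (k in keys) {
      assign(k, (if (exists(k, tally)) get(k, tally) else 0) + 1, tally)
    }
  }
  keys <- ls(tally)
  out <- tibble::tibble(
    genotype = keys,
    probability = unname(vapply(keys, get, numeric(1), envir = tally)) /
      length(fit$snapshots)
  )
  dplyr::arrange(out, dplyr::desc(.data$probability))
}
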