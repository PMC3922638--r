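#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy per-SNV posterior summary of a fit
#'
#' @param x A `clone_tree_fit`.
#' @param ... Unused.
#' @return Tibble with one row per (SNV, sample): observed counts, allele
#'   fraction `vaf`, posterior-mean population frequency `phi_mean`, and the
#'   SNV's node in the best tree.
#' @export
tidy.clone_tree_fit <- function(x, ...) {
  phi <- posterior_mean_phi(x)
  bt <- best_tree(x)
  out <- tidy_counts(x$data)
  out$phi_mean <- phi[cbind(match(out$id, x$data$snv_ids),
                            match(out$sample, x$data$sample_labels))]
  out$best_tree_node <- bt$z[match(out$id, x$data$snv_ids)]
  out
}

#' One-row summary of a fit
#'
#' @param x A `clone_tree_fit`.
#' @param ... Unused.
#' @return Tibble with counts of SNVs, samples and posterior draws, the best
#'   complete-data log-likelihood, the number of occupied nodes in the best
#'   tree, and the mean Metropolis-Hastings acceptance rate.
#' @export
glance.clone_tree_fit <- function(x, ...) {
  bt <- best_tree(x)
  tibble::tibble(
    n_snvs = n_snvs(x$data),
    n_samples = n_samples(x$data),
    n_draws = length(x$snapshots),
    best_cdllh = max(x$cdllh),
    best_n_nodes = sum(tabulate(bt$z, nbins = length(bt$parent)) > 0),
    mean_accept_rate = mean(x$accept_rate)
  )
}

#' Tidy the edges of a partial order
#'
#' @param x A `partial_order`.
#' @param ... Unused.
#' @return The edge tibble joined with the parent's and child's cluster
#'   labels.
#' @export
tidy.partial_order <- function(x, ...) {
  edges <- x$edges
  edges$parent_cluster <- x$nodes$cluster[match(edges$parent, x$nodes$id)]
  edges$child_cluster <- x$nodes$cluster[match(edges$child, x$nodes$id)]
  edges
}

#' Likelihood-trace plot of a fit
#'
#' @param object A `clone_tree_fit`.
#' @param ... Unused.
#' @return A ggplot: complete-data log-likelihood against recorded sweep.
#' @export
autoplot.clone_tree_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$cdllh),
                       cdllh = object$cdllh)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cdllh)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "recorded sweep",
                  y = "complete-data log-likelihood") +
    ggplot2::theme_minimal()
}

#' Plot a partial order graph
#'
#' Simple layered drawing: SNVs are placed on vertical levels by their
#' longest incoming path among retained edges; edge width is the posterior
#' parenthood probability and node color the consensus cluster.
#'
#' @param po A [partial_order()] object.
#' @param edge_threshold Drop edges below this weight before layout.
#' @return A ggplot.
#' @export
plot_partial_order <- function(po, edge_threshold = 0.1) {
  nodes <- po$nodes
  edges <- po$edges[po$edges$weight >= edge_threshold, , drop = FALSE]
  # level = longest path from a source, computed by relaxation
  level <- stats::setNames(rep(0L, nrow(nodes)), nodes$id)
  for (pass in seq_len(nrow(nodes))) {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]
      q <- edges$child[k]
      if (level[q] < level[p] + 1L) {
        level[q] <- level[p] + 1L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  nodes$level <- level[nodes$id]
  nodes <- dplyr::group_by(nodes, .data$level)
  nodes <- dplyr::mutate(nodes, x = seq_along(.data$id) -
                           (dplyr::n() + 1) / 2)
  nodes <- dplyr::ungroup(nodes)
  seg <- dplyr::left_join(
    edges,
    dplyr::select(nodes, parent = "id", x0 = "x", y0 = "level"),
    by = "parent"
  )
  seg <- dplyr::left_join(
    seg, dplyr::select(nodes, child = "id", x1 = "x", y1 = "level"),
    by = "child"
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = -.data$y0, xend = .data$x1,
                   yend = -.data$y1, linewidth = .data$weight),
      color = "grey50"
    ) +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = -.data$level, label = .data$id,
                   color = factor(.data$cluster))
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), limits = c(0, 1)) +
    ggplot2::labs(color = "cluster", linewidth = "P(parent)") +
    ggplot2::theme_void()
}
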