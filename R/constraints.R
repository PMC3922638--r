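# Topological constraint rules on SNV population frequencies under the
# infinite sites assumption, and a brute-force enumerator of consistent
# rooted trees.

#' Classify a frequency triplet under the topological constraint rules
#'
#' Given per-sample population frequencies of three SNVs (A, B, C) with A
#' asserted ancestral to both B and C:
#' * **sum rule** -- if in any sample `f_B + f_C > f_A`, B and C cannot be
#'   sibling branches, so the phylogeny must be a chain;
#' * **crossing rule** -- if `f_B > f_C` in one sample and `f_C > f_B` in
#'   another, neither can be ancestral to the other, so the phylogeny must
#'   branch.
#' Both rules firing means no tree is consistent; neither means the data are
#' ambiguous. A mock ancestor A with frequency 1 (the wildtype state) is
#' allowed.
#'
#' @param freqs Numeric vector `c(f_A, f_B, f_C)` for one sample, or a
#'   matrix / data frame with one row per sample and columns A, B, C.
#' @param tol Nonnegative slack for noisy frequency estimates (default 0,
#'   exact frequencies).
#' @return A one-row tibble (class `triplet_verdict`) with columns `verdict`
#'   (one of `"chain_only"`, `"branching_only"`, `"ambiguous"`,
#'   `"inconsistent"`) and `witness` (which rule fired, in which samples).
#' @export
#' @examples
#' classify_triplet(c(0.8, 0.6, 0.4)) # chain_only by the sum rule
#' classify_triplet(rbind(c(0.8, 0.4, 0.2), c(0.8, 0.2, 0.4))) # branching_only
classify_triplet <- function(freqs, tol = 0) {
  f <- if (is.null(dim(freqs))) matrix(freqs, nrow = 1) else as.matrix(freqs)
  if (ncol(f) != 3) stop("`freqs` must have three columns (A, B, C).", call. = FALSE)
  if (any(f < 0 | f > 1)) stop("frequencies must lie in [0, 1].", call. = FALSE)
  verdict_row <- function(verdict, witness) {
    tibble::new_tibble(
      tibble::tibble(verdict = verdict, witness = witness),
      class = "triplet_verdict"
    )
  }
  anc_bad <- which(f[, 1] < pmax(f[, 2], f[, 3]) - tol)
  if (length(anc_bad) > 0) {
    return(verdict_row("inconsistent",
                       paste0("ancestry violated in sample(s) ",
                              paste(anc_bad, collapse = ","))))
  }
  sum_hits <- which(f[, 2] + f[, 3] > f[, 1] + tol)
  b_gt_c <- which(f[, 2] > f[, 3] + tol)
  c_gt_b <- which(f[, 3] > f[, 2] + tol)
  crossing <- length(b_gt_c) > 0 && length(c_gt_b) > 0
  sum_fired <- length(sum_hits) > 0
  if (sum_fired && crossing) {
    verdict_row("inconsistent",
                paste0("sum rule in sample(s) ",
                       paste(sum_hits, collapse = ","),
                       "; crossing rule in samples ",
                       b_gt_c[1], " vs ", c_gt_b[1]))
  } else if (sum_fired) {
    verdict_row("chain_only",
                paste0("sum rule in sample(s) ",
                       paste(sum_hits, collapse = ",")))
  } else if (crossing) {
    verdict_row("branching_only",
                paste0("crossing rule in samples ", b_gt_c[1], " vs ",
                       c_gt_b[1]))
  } else {
    verdict_row("ambiguous", "no rule fired")
  }
}

# all rooted labeled trees on k nodes as parent vectors (root's parent = 0)
all_rooted_trees <- function(k, root = NULL) {
  roots <- if (is.null(root)) seq_len(k) else root
  out <- list()
  for (r in roots) {
    others <- setdiff(seq_len(k), r)
    if (length(others) == 0) {
      out[[length(out) + 1]] <- structure(0L, names = NULL)
      next
    }
    grid <- as.matrix(expand.grid(rep(list(seq_len(k)), length(others))))
    for (g in seq_len(nrow(grid))) {
      parent <- integer(k)
      parent[others] <- grid[g, ]
      if (any(parent[others] == others)) next
      # acyclicity: every node must reach the root
      ok <- TRUE
      for (v in others) {
        u <- v
        steps <- 0
        while (u != r) {
          u <- parent[u]
          steps <- steps + 1
          if (steps > k) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) out[[length(out) + 1]] <- parent
    }
  }
  out
}

#' Enumerate rooted trees consistent with SNV frequencies
#'
#' Brute force over all rooted labeled trees on `k` SNVs, keeping those in
#' which, in every sample, each node's frequency is at least the sum of its
#' children's (the infinite sites constraint). With `mock_root = TRUE` an
#' extra wildtype ancestor at frequency 1 is added and forests hanging under
#' it are covered (the multicentral case).
#'
#' @param freqs Frequencies: vector of length `k` (one sample) or matrix
#'   with one row per sample and one column per SNV.
#' @param tol Nonnegative slack.
#' @param root Optional index of the SNV forced to be the root.
#' @param mock_root Attach all trees under a wildtype ancestor with
#'   frequency 1 instead of forcing one SNV as root.
#' @return List of parent vectors (0 marks the root; with `mock_root`, 0
#'   marks the mock ancestor, so several SNVs may have parent 0).
#' @export
enumerate_consistent_trees <- function(freqs, tol = 0, root = NULL,
                                       mock_root = FALSE) {
  f <- if (is.null(dim(freqs))) matrix(freqs, nrow = 1) else as.matrix(freqs)
  k <- ncol(f)
  if (k > 8) stop("enumeration limited to k <= 8 SNVs.", call. = FALSE)
  if (k == 0) return(list())
  consistent <- function(parent, fmat) {
    for (t in seq_len(nrow(fmat))) {
      child_sum <- numeric(k + 1) # slot k+1 for the (mock) root parent 0
      for (v in seq_len(k)) {
        p <- parent[v]
        idx <- if (p == 0) k + 1 else p
        child_sum[idx] <- child_sum[idx] + fmat[t, v]
      }
      node_f <- c(fmat[t, ], 1) # mock/implicit root has frequency 1
      if (any(child_sum > node_f + tol)) return(FALSE)
      # every child individually below its parent
      for (v in seq_len(k)) {
        p <- parent[v]
        pf <- if (p == 0) 1 else fmat[t, p]
        if (fmat[t, v] > pf + tol) return(FALSE)
      }
    }
    TRUE
  }
  if (mock_root) {
    # forests on k labeled nodes = parent in {0, other nodes}, acyclic
    others <- seq_len(k)
    grid <- as.matrix(expand.grid(rep(list(0:k), k)))
    trees <- list()
    for (g in seq_len(nrow(grid))) {
      parent <- as.integer(grid[g, ])
      if (any(parent == others)) next
      ok <- TRUE
      for (v in others) {
        u <- v
        steps <- 0
        while (u != 0) {
          u <- parent[u]
          steps <- steps + 1
          if (steps > k) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) trees[[length(trees) + 1]] <- parent
    }
  } else {
    trees <- all_rooted_trees(k, root)
  }
  Filter(function(p) consistent(p, f), trees)
}
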