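# Reading SNV count tables and writing run artifacts.

strip_thousands <- function(x) as.numeric(gsub(",", "", as.character(x)))

#' Read an SNV read-count table
#'
#' UTF-8 TSV with a header; one row per (SNV, sample). Required columns:
#' `id`, `variant_reads`, `total_reads`; optional: `sample` (default a
#' single sample `"S1"`), `gene`, `copy_number` (default 2), `zygosity`
#' (default `"heterozygous"`). Thousands separators in counts are accepted
#' (`"12,085"` reads as 12085).
#'
#' @param path Path to the TSV file.
#' @param error_rate Sequencer error rate for the genotype configurations.
#' @return An [snv_data()] object.
#' @export
read_snv_table <- function(path, error_rate = 0.001) {
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                    progress = FALSE),
    error = function(e) stop("format error reading '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0 || !all(c("id", "variant_reads", "total_reads") %in% names(df))) {
    stop("format error: need a non-empty TSV with columns id, variant_reads, ",
         "total_reads.", call. = FALSE)
  }
  df$variant_reads <- strip_thousands(df$variant_reads)
  df$total_reads <- strip_thousands(df$total_reads)
  if (!"sample" %in% names(df)) df$sample <- "S1"
  if ("copy_number" %in% names(df)) {
    df$copy_number <- as.integer(strip_thousands(df$copy_number))
  }
  snv_data(df, error_rate = error_rate)
}

best_tree_to_list <- function(fit) {
  bt <- best_tree(fit)
  ids <- fit$data$snv_ids
  sets <- snapshot_genotypes(bt, ids)
  K <- length(bt$parent)
  list(
    samples = fit$data$sample_labels,
    complete_data_log_likelihood = bt$cdllh,
    data_log_likelihood = bt$data_loglik,
    hypers = bt$hypers,
    nodes = lapply(seq_len(K), function(v) {
      list(
        node = v,
        parent = bt$parent[v],
        snvs = ids[bt$z == v],
        genotype = sets[[v]],
        phi = as.numeric(bt$phi[v, ])
      )
    }),
    assignments = stats::setNames(as.list(bt$z), ids)
  )
}

#' Write the standard result files of a run
#'
#' Writes into `outdir`: `best_tree.json` (structure, per-node genotypes and
#' frequencies), `partial_order.dot`, `coclustering.tsv`,
#' `likelihood_trace.tsv`, and `config.yaml` (an echo of the run
#' configuration).
#'
#' @param fit A `clone_tree_fit`.
#' @param outdir Output directory (created if missing).
#' @param edge_threshold Edge threshold for the DOT output.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit, outdir, edge_threshold = 0.1) {
  stopifnot(inherits(fit, "clone_tree_fit"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("best_tree.json", "partial_order.dot",
                               "coclustering.tsv", "likelihood_trace.tsv",
                               "config.yaml"))
  jsonlite::write_json(best_tree_to_list(fit), paths[1], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  po <- partial_order(fit)
  write_dot(po, edge_threshold = edge_threshold, path = paths[2])
  C <- coclustering_matrix(fit)
  utils::write.table(as.data.frame(unclass(C)), paths[3], sep = "\t",
                     quote = FALSE, col.names = NA)
  readr::write_tsv(
    tibble::tibble(iteration = seq_along(fit$cdllh),
                   complete_data_log_likelihood = fit$cdllh),
    paths[4]
  )
  cfg <- fit$config
  cfg$ranges <- lapply(cfg$ranges, as.numeric)
  yaml::write_yaml(unclass(cfg), paths[5])
  invisible(paths)
}

#' Reload a best-tree JSON written by [write_results()]
#'
#' @param path Path to `best_tree.json`.
#' @return A snapshot-like list with `z`, `parent`, `phi`, `hypers`, and the
#'   log-likelihoods, matching [best_tree()] output.
#' @export
read_best_tree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  K <- length(x$nodes)
  parent <- vapply(x$nodes, function(n) as.integer(n$parent), integer(1))
  phi <- do.call(rbind, lapply(x$nodes, function(n) as.numeric(n$phi)))
  z <- as.integer(unlist(x$assignments))
  names(z) <- names(x$assignments)
  list(
    z = unname(z), parent = parent, phi = phi,
    hypers = lapply(x$hypers, as.numeric),
    cdllh = as.numeric(x$complete_data_log_likelihood),
    data_loglik = as.numeric(x$data_log_likelihood)
  )
}
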