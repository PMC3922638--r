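#' Assemble an SNV read-count dataset
#'
#' Takes one row per (SNV, sample) and pivots into the rectangular dataset
#' the sampler consumes: every SNV must be observed in every sample. Genotype
#' configurations are built from `copy_number` / `zygosity` columns via
#' [default_genotype_config()] unless a list-column `genotype` of
#' [genotype_config()] objects is supplied.
#'
#' @param df Data frame with columns `id`, `sample`, `variant_reads`,
#'   `total_reads`, and either `copy_number` + `zygosity` or a `genotype`
#'   list-column. Extra columns are ignored.
#' @param error_rate Sequencer error rate used when building default
#'   genotype configurations.
#' @return An object of class `snv_data`: read-count matrices `b` and `d`
#'   (SNVs x samples), `snv_ids`, `sample_labels` and per-SNV `genotypes`.
#' @export
#' @examples
#' df <- tibble::tibble(
#'   id = c("s1", "s2"), sample = "t1",
#'   variant_reads = c(50, 10), total_reads = c(100, 100),
#'   copy_number = 2, zygosity = "heterozygous"
#' )
#' snv_data(df)
snv_data <- function(df, error_rate = 0.001) {
  df <- tibble::as_tibble(df)
  required <- c("id", "sample", "variant_reads", "total_reads")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty SNV table.", call. = FALSE)
  ids <- unique(df$id)
  samples <- unique(df$sample)
  key <- paste(df$id, df$sample, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (SNV, sample) rows.", call. = FALSE)
  }
  full <- expand.grid(id = ids, sample = samples, stringsAsFactors = FALSE)
  miss <- setdiff(paste(full$id, full$sample, sep = "\r"), key)
  if (length(miss) > 0) {
    cell <- strsplit(miss[1], "\r", fixed = TRUE)[[1]]
    stop("missing cell for SNV '", cell[1], "' in sample '", cell[2], "'.",
         call. = FALSE)
  }
  b <- matrix(NA_real_, length(ids), length(samples),
              dimnames = list(ids, samples))
  d <- b
  b[cbind(match(df$id, ids), match(df$sample, samples))] <- df$variant_reads
  d[cbind(match(df$id, ids), match(df$sample, samples))] <- df$total_reads
  if (any(b < 0) || any(d < 0)) {
    stop("read counts must be non-negative.", call. = FALSE)
  }
  if (any(b > d)) {
    bad <- which(b > d, arr.ind = TRUE)[1, ]
    stop("validation error: b > d for SNV '", ids[bad[1]], "' in sample '",
         samples[bad[2]], "'.", call. = FALSE)
  }
  first <- df[!duplicated(df$id), , drop = FALSE]
  first <- first[match(ids, first$id), , drop = FALSE]
  genotypes <- if ("genotype" %in% names(df)) {
    gl <- first$genotype
    stopifnot(all(vapply(gl, inherits, logical(1), "genotype_config")))
    gl
  } else {
    cn <- if ("copy_number" %in% names(df)) {
      as.integer(first$copy_number)
    } else {
      rep(2L, length(ids))
    }
    zy <- if ("zygosity" %in% names(df)) {
      as.character(first$zygosity)
    } else {
      rep("heterozygous", length(ids))
    }
    purrr::map2(cn, zy, default_genotype_config, error_rate = error_rate)
  }
  structure(
    list(b = b, d = d, snv_ids = ids, sample_labels = as.character(samples),
         genotypes = genotypes),
    class = "snv_data"
  )
}

#' @export
print.snv_data <- function(x, ...) {
  cat("<snv_data>", n_snvs(x), "SNVs x", n_samples(x), "sample(s)\n")
  print(utils::head(tidy_counts(x), 10))
  invisible(x)
}

#' Number of SNVs / samples in an `snv_data` object
#' @param data An `snv_data` object.
#' @return Integer.
#' @export
n_snvs <- function(data) nrow(data$b)

#' @rdname n_snvs
#' @export
n_samples <- function(data) ncol(data$b)

#' Long-format view of an `snv_data` object
#'
#' @param data An `snv_data` object.
#' @return Tibble with one row per (SNV, sample): counts and allele
#'   frequency `vaf = variant_reads / total_reads`.
#' @export
tidy_counts <- function(data) {
  stopifnot(inherits(data, "snv_data"))
  tibble::tibble(
    id = rep(data$snv_ids, times = n_samples(data)),
    sample = rep(data$sample_labels, each = n_snvs(data)),
    variant_reads = as.vector(data$b),
    total_reads = as.vector(data$d),
    vaf = as.vector(data$b / data$d)
  )
}

# internal: flatten per-SNV genotype configs for the C++ likelihood kernels
genotype_arrays <- function(data) {
  list(
    mu_r = vapply(data$genotypes, function(g) g$mu_r, numeric(1)),
    mu_v = lapply(data$genotypes, function(g) g$mu_v),
    log_w = lapply(data$genotypes, function(g) log(mixture_weights(g)))
  )
}
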