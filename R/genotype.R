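#' Genotype configuration for one SNV
#'
#' Describes how reads sample alleles at one SNV locus: the probability
#' `mu_r` of drawing a reference allele from cells *without* the variant
#' (1 minus the sequencer error rate), and, for cells *with* the variant, a
#' set of candidate genotypes `g` (e.g. `AB`, `B`, `BB`), each with its own
#' reference-allele sampling probability `mu_v[g]` and a Dirichlet
#' pseudo-count `delta[g]`. The genotype is never observed; the likelihood
#' marginalizes over it with weights `delta / sum(delta)`.
#'
#' @param mu_r Probability of sampling a reference allele from the reference
#'   (non-variant) population, in `[0, 1]`.
#' @param states Character vector of genotype labels.
#' @param mu_v Numeric vector, same length as `states`: probability of
#'   sampling a reference allele from the variant population under each
#'   genotype.
#' @param delta Positive pseudo-counts of the Dirichlet prior over genotype
#'   states. Defaults to 1 per state (uniform).
#' @return An object of class `genotype_config`.
#' @export
#' @examples
#' genotype_config(0.999, "AB", 0.5)
genotype_config <- function(mu_r, states, mu_v, delta = rep(1, length(states))) {
  if (!is.numeric(mu_r) || length(mu_r) != 1L || mu_r < 0 || mu_r > 1) {
    stop("`mu_r` must be a single probability in [0, 1].", call. = FALSE)
  }
  if (length(states) < 1L) {
    stop("at least one genotype state is required.", call. = FALSE)
  }
  if (length(mu_v) != length(states) || length(delta) != length(states)) {
    stop("`states`, `mu_v` and `delta` must have the same length.", call. = FALSE)
  }
  if (any(mu_v < 0 | mu_v > 1)) {
    stop("all `mu_v` must lie in [0, 1].", call. = FALSE)
  }
  if (any(!is.finite(delta) | delta <= 0)) {
    stop("invalid pseudo-count: all `delta` must be > 0.", call. = FALSE)
  }
  structure(
    list(mu_r = mu_r, states = as.character(states),
         mu_v = as.numeric(mu_v), delta = as.numeric(delta)),
    class = "genotype_config"
  )
}

#' @export
print.genotype_config <- function(x, ...) {
  cat("<genotype_config> mu_r =", format(x$mu_r), "\n")
  print(tibble::tibble(state = x$states, mu_v = x$mu_v, delta = x$delta))
  invisible(x)
}

#' Marginal genotype mixture weights
#'
#' The Dirichlet-compound-multinomial with a single draw reduces to the
#' normalized pseudo-counts: the prior probability that the variant
#' population carries genotype `g` is `delta_g / sum(delta)`.
#'
#' @param config A [genotype_config()].
#' @return Numeric vector of probabilities over the genotype states,
#'   summing to 1.
#' @export
mixture_weights <- function(config) {
  stopifnot(inherits(config, "genotype_config"))
  config$delta / sum(config$delta)
}

#' Reference-allele sampling probability at frequency phi
#'
#' A sample in which a fraction `phi` of cells carry the variant yields a
#' reference read with probability `(1 - phi) * mu_r + phi * mu_v_g`. The
#' result is clamped away from 0 and 1 so log-likelihoods stay finite.
#'
#' @param phi SNV population frequency in `[0, 1]` (fraction of cells
#'   carrying the variant). Vectorized.
#' @param mu_r,mu_v_g Reference-allele sampling probabilities for the
#'   reference and variant populations.
#' @param eps Clamp width; probabilities are kept in `(eps, 1 - eps)`.
#' @return Probability of a reference read.
#' @export
#' @examples
#' ref_allele_prob(0.972, 0.999, 0.5) # expected variant fraction ~ 0.486
ref_allele_prob <- function(phi, mu_r, mu_v_g, eps = 1e-10) {
  if (any(phi < 0 | phi > 1) || any(mu_r < 0 | mu_r > 1) ||
      any(mu_v_g < 0 | mu_v_g > 1)) {
    stop("`phi`, `mu_r` and `mu_v_g` must lie in [0, 1].", call. = FALSE)
  }
  p <- (1 - phi) * mu_r + phi * mu_v_g
  pmin(pmax(p, eps), 1 - eps)
}

#' Genotype-marginalized binomial log-likelihood of one SNV
#'
#' Log-probability of observing `b` variant reads out of `d` at population
#' frequency `phi`, marginalizing the variant-population genotype under its
#' Dirichlet prior:
#' `log sum_g w_g Binomial(b; d, 1 - ref_allele_prob(phi, mu_r, mu_v_g))`
#' with `w = mixture_weights(config)`. Computed with log-sum-exp.
#'
#' @param b,d Variant read count and total depth (scalars).
#' @param config A [genotype_config()].
#' @param phi Population frequency in `[0, 1]`. Vectorized.
#' @return Log-likelihood, same length as `phi`.
#' @export
snv_log_likelihood <- function(b, d, config, phi) {
  stopifnot(inherits(config, "genotype_config"))
  if (b > d) stop("invalid observation: b > d.", call. = FALSE)
  if (any(phi < 0 | phi > 1)) stop("`phi` must lie in [0, 1].", call. = FALSE)
  lw <- log(mixture_weights(config))
  ll <- vapply(phi, function(f) {
    p_var <- 1 - ref_allele_prob(f, config$mu_r, config$mu_v)
    terms <- lw + stats::dbinom(b, d, p_var, log = TRUE)
    m <- max(terms)
    m + log(sum(exp(terms - m)))
  }, numeric(1))
  ll
}

#' Default genotype configuration from copy number and zygosity
#'
#' Builds the genotype states a variant population can take at a locus of
#' the given copy number. For known zygosity a single state is used; for
#' unknown zygosity all numbers of variant copies `k = 1..copy_number` are
#' enumerated, each with reference-allele probability
#' `(1 - k / copy_number)` adjusted for sequencer error, plus uniform
#' pseudo-counts.
#'
#' @param copy_number Positive integer copy number of the locus.
#' @param zygosity One of `"heterozygous"`, `"hemizygous"`, `"homozygous"`,
#'   `"unknown"`.
#' @param error_rate Sequencer error rate; `mu_r = 1 - error_rate`.
#' @return A [genotype_config()].
#' @export
#' @examples
#' default_genotype_config(2, "heterozygous")
default_genotype_config <- function(copy_number, zygosity = "heterozygous",
                                    error_rate = 0.001) {
  if (copy_number < 1) stop("`copy_number` must be >= 1.", call. = FALSE)
  mu_r <- 1 - error_rate
  # a population with k of n copies variant samples a reference allele with
  # probability (n-k)/n, shrunk into (error_rate, 1-error_rate) at the edges
  mu_k <- function(k, n) {
    p <- (n - k) / n
    min(max(p, error_rate), 1 - error_rate)
  }
  switch(zygosity,
    heterozygous = {
      if (copy_number < 2) {
        stop("heterozygous requires copy number >= 2.", call. = FALSE)
      }
      genotype_config(mu_r, "AB", mu_k(1, copy_number))
    },
    hemizygous = genotype_config(mu_r, "B", mu_k(1, 1)),
    homozygous = genotype_config(
      mu_r, strrep("B", copy_number), mu_k(copy_number, copy_number)
    ),
    unknown = {
      k <- seq_len(copy_number)
      labels <- paste0(strrep("A", copy_number - k), strrep("B", k))
      genotype_config(mu_r, labels, vapply(k, mu_k, numeric(1), n = copy_number))
    },
    stop("unsupported zygosity label: ", zygosity, call. = FALSE)
  )
}
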