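#' Analysis configuration
#'
#' Bundles every tunable parameter of the pipeline with its default. All
#' thresholds are proportions in (0, 1); counts are positive integers.
#'
#' @param rare_freq_threshold Overall band-frequency ceiling below which a
#'   marker can qualify as rare (strict inequality). Default 0.10.
#' @param rare_popfrac_threshold Ceiling on the fraction of populations
#'   carrying the band (strict inequality). Default 0.20.
#' @param target_P Target proportion of among-population diversity that the
#'   selected populations must represent. Default 0.999.
#' @param n_permutations Permutation replicates for AMOVA significance tests.
#'   Default 1023.
#' @param n_bootstrap Marker-bootstrap replicates for the F_ST confidence
#'   interval. Default 1000.
#' @param rng_seed Integer seed used for permutations and bootstraps.
#' @param dixon_theta_max Upper bound of the uniform prior on the true
#'   haplotype number. Default 100.
#' @param proportion_decimals Decimals used when reporting regional
#'   proportions. Default 2.
#' @param missing_token Token in input files denoting a missing marker call;
#'   missing calls are dropped from that population's frequency denominator.
#' @param dw_normalize If TRUE (default) the frequency down-weighted rarity
#'   score is divided by the population sample size.
#' @param nei_correction If TRUE apply the small-sample n/(n-1) factor to
#'   per-marker diversity terms. Default FALSE (plain phenotypic estimator).
#' @param truncate_negative_variance If TRUE negative AMOVA variance
#'   components are set to zero before computing fixation indices. Default
#'   FALSE (components reported as-is, with a warning).
#' @param regression_through_origin If TRUE the loss-probability regressions
#'   are fitted without intercept. Default FALSE.
#' @param psa_method "capture" (default) assigns each rare allele to the
#'   region maximizing the one-population capture probability;
#'   "carrier_fraction" uses the fraction of the region's populations that
#'   carry it.
#' @param use_rounded_proportions If TRUE apportionment uses the reported
#'   (rounded) PSA proportions instead of the exact ones. Default FALSE.
#' @param prioritize_weights Named numeric vector of bonus weights added to
#'   the composite score: `vulnerability` (stable/acceptable), `protected`,
#'   `large_area`, `large_size`. Default all 0 (ranking on genetics alone).
#'
#' @return A list of class `rguc_config`.
#' @export
#' @examples
#' cfg <- rguc_config(n_permutations = 199)
#' cfg$rare_freq_threshold
rguc_config <- function(rare_freq_threshold = 0.10,
                        rare_popfrac_threshold = 0.20,
                        target_P = 0.999,
                        n_permutations = 1023L,
                        n_bootstrap = 1000L,
                        rng_seed = 1L,
                        dixon_theta_max = 100L,
                        proportion_decimals = 2L,
                        missing_token = "NA",
                        dw_normalize = TRUE,
                        nei_correction = FALSE,
                        truncate_negative_variance = FALSE,
                        regression_through_origin = FALSE,
                        psa_method = c("capture", "carrier_fraction"),
                        use_rounded_proportions = FALSE,
                        prioritize_weights = c(vulnerability = 0, protected = 0,
                                               large_area = 0, large_size = 0)) {
  psa_method <- match.arg(psa_method)
  stopifnot(rare_freq_threshold > 0, rare_freq_threshold < 1,
            rare_popfrac_threshold > 0, rare_popfrac_threshold < 1,
            target_P > 0, target_P < 1,
            n_permutations >= 0, n_bootstrap >= 0, dixon_theta_max >= 1)
  cfg <- list(rare_freq_threshold = rare_freq_threshold,
              rare_popfrac_threshold = rare_popfrac_threshold,
              target_P = target_P,
              n_permutations = as.integer(n_permutations),
              n_bootstrap = as.integer(n_bootstrap),
              rng_seed = as.integer(rng_seed),
              dixon_theta_max = as.integer(dixon_theta_max),
              proportion_decimals = as.integer(proportion_decimals),
              missing_token = missing_token,
              dw_normalize = isTRUE(dw_normalize),
              nei_correction = isTRUE(nei_correction),
              truncate_negative_variance = isTRUE(truncate_negative_variance),
              regression_through_origin = isTRUE(regression_through_origin),
              psa_method = psa_method,
              use_rounded_proportions = isTRUE(use_rounded_proportions),
              prioritize_weights = prioritize_weights)
  class(cfg) <- "rguc_config"
  cfg
}

#' Read an analysis configuration from a YAML file
#'
#' Keys missing from the file keep their [rguc_config()] defaults; unknown
#' keys are an error so typos do not pass silently.
#'
#' @param path Path to a YAML file.
#' @return A `rguc_config` list.
#' @export
read_rguc_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(rguc_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(known, collapse = ", "))
  if (!is.null(raw$prioritize_weights))
    raw$prioritize_weights <- unlist(raw$prioritize_weights)
  do.call(rguc_config, raw)
}

#' @export
print.rguc_config <- function(x, ...) {
  cat("rguc analysis configuration\n")
  for (k in setdiff(names(x), "prioritize_weights"))
    cat(sprintf("  %-28s %s\n", k, format(x[[k]])))
  w <- x$prioritize_weights
  cat(sprintf("  %-28s %s\n", "prioritize_weights",
              paste(names(w), w, sep = "=", collapse = " ")))
  invisible(x)
}
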