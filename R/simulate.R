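#' Specification for a synthetic dominant-marker dataset
#'
#' Defines the shape and structure of a simulated study: populations,
#' individuals, markers, a region partition, the F-model differentiation
#' parameter, and optional injected rare bands with known truth. Defaults
#' mirror a 17-population, 3-region, ~360-individual, ~1100-marker design
#' with moderate differentiation.
#'
#' @param n_populations Number of populations.
#' @param n_individuals Individuals per population (scalar or vector).
#' @param n_markers Number of background markers.
#' @param F Differentiation parameter of the Balding-Nichols F-model,
#'   in \[0, 1); under the model this is the quantity AMOVA's F_ST
#'   estimates, so parameter recovery is directly checkable.
#' @param regions Optional named character vector population -> region; by
#'   default populations are split into `n_regions` contiguous blocks.
#' @param n_regions Number of regions for the default partition.
#' @param rare_injections Optional data.frame with columns `p` (target
#'   within-carrier frequency, inside the rare band) and `n_carriers`
#'   (number of carrier populations); each row adds one extra marker whose
#'   frequency is `p` in `n_carriers` randomly chosen populations
#'   (optionally constrained to `region`) and 0 elsewhere.
#' @param seed Integer RNG seed; same seed, same dataset.
#' @return List of class `sim_spec`.
#' @export
sim_spec <- function(n_populations = 17L, n_individuals = 21L,
                     n_markers = 1100L, F = 0.29,
                     regions = NULL, n_regions = 3L,
                     rare_injections = NULL, seed = 1L) {
  stopifnot(n_populations >= 1, all(n_individuals >= 1), n_markers >= 1,
            F >= 0, F < 1)
  if (length(n_individuals) == 1L)
    n_individuals <- rep(n_individuals, n_populations)
  stopifnot(length(n_individuals) == n_populations)
  pops <- paste0("P", seq_len(n_populations))
  if (is.null(regions)) {
    blocks <- sort(rep_len(seq_len(n_regions), n_populations))
    regions <- stats::setNames(paste0("R", blocks), pops)
  }
  if (!is.null(rare_injections)) {
    stopifnot(all(c("p", "n_carriers") %in% names(rare_injections)),
              all(rare_injections$p > 0), all(rare_injections$p < 1),
              all(rare_injections$n_carriers >= 1),
              all(rare_injections$n_carriers <= n_populations))
  }
  structure(list(n_populations = as.integer(n_populations),
                 n_individuals = as.integer(n_individuals),
                 n_markers = as.integer(n_markers),
                 F = F, regions = regions,
                 rare_injections = rare_injections,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Simulate a dominant-marker matrix under the F-model
#'
#' Each background marker gets an ancestral band frequency
#' `pi ~ Uniform(0.05, 0.95)`; each population's frequency is drawn from
#' `Beta(pi (1-F)/F, (1-pi)(1-F)/F)` (Balding-Nichols), collapsing to `pi`
#' exactly when `F = 0`; individuals are Bernoulli draws. Injected rare
#' markers overwrite the frequency to the target `p` in the chosen carrier
#' populations and 0 elsewhere. The truth record lists, for every injected
#' marker, the carriers and both the target and the realized frequencies.
#'
#' @param spec A [sim_spec()].
#' @return List with `matrix` (a [marker_matrix()]), `regions` (named
#'   character vector), and `truth` (data.frame over injected markers:
#'   `marker`, `target_p`, `carrier_pops`, `realized_overall_freq`,
#'   `realized_carrier_pops`).
#' @export
#' @examples
#' sim <- simulate_marker_matrix(sim_spec(n_populations = 3, n_individuals = 6,
#'                                        n_markers = 20, F = 0.2, seed = 42))
#' sim$matrix
simulate_marker_matrix <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  pops <- names(spec$regions)
  n_ind <- spec$n_individuals
  pop_vec <- rep(pops, n_ind)
  n_total <- sum(n_ind)
  pi0 <- stats::runif(spec$n_markers, 0.05, 0.95)
  if (spec$F == 0) {
    pf <- matrix(pi0, nrow = spec$n_populations, ncol = spec$n_markers,
                 byrow = TRUE)
  } else {
    a <- pi0 * (1 - spec$F) / spec$F
    b <- (1 - pi0) * (1 - spec$F) / spec$F
    pf <- matrix(stats::rbeta(spec$n_populations * spec$n_markers,
                              rep(a, each = spec$n_populations),
                              rep(b, each = spec$n_populations)),
                 nrow = spec$n_populations)
  }
  rownames(pf) <- pops
  inj <- spec$rare_injections
  n_inj <- if (is.null(inj)) 0L else nrow(inj)
  carriers_list <- vector("list", n_inj)
  if (n_inj > 0L) {
    inj_pf <- matrix(0, nrow = spec$n_populations, ncol = n_inj,
                     dimnames = list(pops, NULL))
    for (r in seq_len(n_inj)) {
      cand <- pops
      if (!is.null(inj$region) && !is.na(inj$region[r]))
        cand <- pops[spec$regions[pops] == inj$region[r]]
      carriers <- sample(cand, inj$n_carriers[r])
      inj_pf[carriers, r] <- inj$p[r]
      carriers_list[[r]] <- sort(carriers)
    }
    pf <- cbind(pf, inj_pf)
  }
  n_markers_all <- ncol(pf)
  marker_ids <- c(paste0("m", seq_len(spec$n_markers)),
                  if (n_inj) paste0("rare", seq_len(n_inj)))
  prob <- pf[pop_vec, , drop = FALSE]
  vals <- matrix(stats::rbinom(n_total * n_markers_all, 1, prob),
                 nrow = n_total)
  ind_ids <- paste0(pop_vec, "_i", unlist(lapply(n_ind, seq_len)))
  m <- marker_matrix(vals, pop_vec, individual_ids = ind_ids,
                     marker_ids = marker_ids)
  truth <- NULL
  if (n_inj > 0L) {
    bf <- band_frequencies(m)
    idx <- spec$n_markers + seq_len(n_inj)
    truth <- data.frame(marker = marker_ids[idx],
                        target_p = inj$p,
                        n_carriers_target = inj$n_carriers,
                        realized_overall_freq = unname(bf$overall[idx]),
                        stringsAsFactors = FALSE)
    truth$carrier_pops <- carriers_list
    truth$realized_carrier_pops <- lapply(idx, function(j)
      rownames(bf$carriers_per_pop)[bf$carriers_per_pop[, j] > 0])
  }
  list(matrix = m, regions = spec$regions, truth = truth)
}

#' Simulate a haplotype sample from a known pool
#'
#' Draws `n` sequences from a multinomial pool of haplotype frequencies and
#' reports how many distinct haplotypes were observed.
#'
#' @param pool_freqs Haplotype frequencies, summing to 1.
#' @param n Sample size.
#' @param seed Integer RNG seed.
#' @return A [haplotype_sample()] restricted to the observed haplotypes.
#' @export
simulate_haplotype_sample <- function(pool_freqs, n, seed = 1L) {
  stopifnot(abs(sum(pool_freqs) - 1) < 1e-8, n >= 1)
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n, pool_freqs))
  obs <- counts[counts > 0]
  haplotype_sample(n, length(obs), obs)
}
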