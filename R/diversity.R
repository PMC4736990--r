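#' Band frequencies per population and overall
#'
#' Frequencies are carrier counts over non-missing calls; a population with
#' no valid call for a marker gets `NaN` there.
#'
#' @param x A [marker_matrix()].
#' @return A list with `per_pop` (populations x markers matrix of band
#'   frequencies), `overall` (named vector over markers, pooled over all
#'   individuals), `carriers_per_pop` (integer counts) and `n_valid_per_pop`.
#' @export
band_frequencies <- function(x) {
  pop <- pop_of(x)
  pops <- populations(x)
  v <- unclass(x)
  carriers <- t(vapply(pops, function(p) colSums(v[pop == p, , drop = FALSE], na.rm = TRUE),
                       numeric(ncol(v))))
  nvalid <- t(vapply(pops, function(p) colSums(!is.na(v[pop == p, , drop = FALSE])),
                     numeric(ncol(v))))
  dimnames(carriers) <- dimnames(nvalid) <- list(pops, colnames(v))
  list(per_pop = carriers / nvalid,
       overall = colSums(v, na.rm = TRUE) / colSums(!is.na(v)),
       carriers_per_pop = carriers,
       n_valid_per_pop = nvalid)
}

#' Nei's gene diversity of a population from band phenotypes
#'
#' Per marker the term is `1 - f^2 - (1 - f)^2` with `f` the band frequency
#' in the population; the reported value is the mean of this term over the
#' markers polymorphic in the full dataset. Frequencies are used on the
#' phenotypic (band) scale -- no Hardy-Weinberg square-root transform -- and
#' by default no small-sample correction is applied
#' (`nei_correction = TRUE` multiplies each term by n/(n-1)).
#'
#' @param x A [marker_matrix()].
#' @param population Population code; if `NULL`, a named vector over all
#'   populations is returned.
#' @param nei_correction Apply the n/(n-1) small-sample factor.
#' @return Diversity in [0, 1], or a named vector of them.
#' @export
nei_diversity <- function(x, population = NULL, nei_correction = FALSE) {
  if (is.null(population)) {
    out <- vapply(populations(x), function(p)
      nei_diversity(x, p, nei_correction = nei_correction), numeric(1))
    return(out)
  }
  pop <- pop_of(x)
  if (!population %in% pop) stop("unknown population: ", population)
  sub <- unclass(x)[pop == population, , drop = FALSE]
  if (nrow(sub) < 2L)
    stop("population '", population,
         "' has a single individual; exclude it from diversity estimation")
  poly <- is_polymorphic(x)
  if (!any(poly)) stop("no polymorphic marker in the dataset")
  f <- colSums(sub[, poly, drop = FALSE], na.rm = TRUE) /
    colSums(!is.na(sub[, poly, drop = FALSE]))
  h <- 1 - f^2 - (1 - f)^2
  if (nei_correction) {
    n <- colSums(!is.na(sub[, poly, drop = FALSE]))
    h <- h * n / (n - 1)
  }
  mean(h, na.rm = TRUE)
}

#' Frequency down-weighted marker rarity (DW)
#'
#' For each marker carried anywhere in the dataset, the population's carrier
#' count is divided by the dataset-wide carrier count; the sum of these
#' ratios is the population's rarity score. Carrying bands that are globally
#' scarce contributes close to 1 per band, carrying ubiquitous bands
#' contributes little. By default the sum is divided by the population's
#' sample size (`normalize = FALSE` returns the raw sum).
#'
#' @param x A [marker_matrix()].
#' @param population Population code; `NULL` for a named vector over all.
#' @param normalize Divide by the population sample size (default TRUE).
#' @return Nonnegative rarity score(s).
#' @export
dw_rarity <- function(x, population = NULL, normalize = TRUE) {
  bf <- band_frequencies(x)
  total_carriers <- colSums(bf$carriers_per_pop)
  keep <- total_carriers > 0
  pops <- populations(x)
  raw <- rowSums(bf$carriers_per_pop[, keep, drop = FALSE] /
                   rep(total_carriers[keep], each = length(pops)))
  if (normalize) raw <- raw / as.vector(table(pop_of(x))[pops])
  out <- stats::setNames(raw, pops)
  if (is.null(population)) return(out)
  if (!population %in% pops) stop("unknown population: ", population)
  out[[population]]
}

#' Identify rare bands
#'
#' A marker is rare when its overall frequency (over all individuals) is
#' strictly below `rare_freq_threshold` and it is present in strictly fewer
#' than `rare_popfrac_threshold` of the populations. Markers absent
#' everywhere are never rare. For each rare band the frequency `p` is the
#' unweighted mean of its frequencies in the populations that carry it.
#'
#' @param x A [marker_matrix()].
#' @param config A [rguc_config()] providing the two thresholds.
#' @return A data.frame of class `rare_alleles`: one row per rare band with
#'   `marker`, `overall_freq`, `p` (mean carrier-population frequency),
#'   `n_carriers`, and a list-column `carrier_pops`.
#' @export
find_rare_alleles <- function(x, config = rguc_config()) {
  if (n_populations(x) < 2L) stop("rare-band identification needs >= 2 populations")
  bf <- band_frequencies(x)
  npop <- n_populations(x)
  present <- bf$carriers_per_pop > 0
  n_carriers <- colSums(present)
  sel <- bf$overall > 0 &
    bf$overall < config$rare_freq_threshold &
    n_carriers / npop < config$rare_popfrac_threshold
  idx <- which(sel)
  carrier_pops <- lapply(idx, function(j) rownames(present)[present[, j]])
  p <- vapply(idx, function(j) mean(bf$per_pop[present[, j], j]), numeric(1))
  out <- data.frame(marker = colnames(x)[idx],
                    overall_freq = unname(bf$overall[idx]),
                    p = unname(p),
                    n_carriers = unname(n_carriers[idx]),
                    stringsAsFactors = FALSE)
  out$carrier_pops <- carrier_pops
  class(out) <- c("rare_alleles", "data.frame")
  out
}

#' @export
print.rare_alleles <- function(x, ...) {
  cat(sprintf("rare_alleles: %d band(s)", nrow(x)))
  if (nrow(x))
    cat(sprintf(" (mean p = %.3f, carriers 1..%d)", mean(x$p), max(x$n_carriers)))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(x[c("marker", "overall_freq", "p", "n_carriers")], 10))
  invisible(x)
}

#' Count rare bands carried by a population
#'
#' @param rare A `rare_alleles` table from [find_rare_alleles()].
#' @param population Population code; `NULL` for a named vector over every
#'   population appearing in any carrier set.
#' @param all_populations Optional character vector fixing the populations
#'   (so populations carrying no rare band report 0).
#' @return Integer count(s).
#' @export
n_rare_per_population <- function(rare, population = NULL, all_populations = NULL) {
  pops <- all_populations %||% sort(unique(unlist(rare$carrier_pops)))
  counts <- stats::setNames(integer(length(pops)), pops)
  for (cp in rare$carrier_pops) counts[cp] <- counts[cp] + 1L
  if (is.null(population)) return(counts)
  if (!population %in% pops) stop("unknown population: ", population)
  counts[[population]]
}

#' Dice similarity and Nei-Li distance between two band profiles
#'
#' `dice = 2 * shared / (bands_a + bands_b)`; the Nei-Li genetic distance is
#' its complement. Undefined when both profiles carry no band at all.
#'
#' @param a,b Binary vectors over the same marker set.
#' @return Similarity in [0, 1].
#' @export
dice_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("profiles must cover the same marker set")
  ok <- !is.na(a) & !is.na(b)
  na_ <- sum(a[ok]); nb <- sum(b[ok])
  if (na_ + nb == 0) stop("Dice similarity undefined: both profiles are all-zero")
  2 * sum(a[ok] == 1 & b[ok] == 1) / (na_ + nb)
}

#' @rdname dice_similarity
#' @export
nei_li_distance <- function(a, b) 1 - dice_similarity(a, b)

#' Per-population diversity/rarity profiles
#'
#' Convenience table combining sample size, Nei diversity, DW rarity and the
#' rare-band count per population.
#'
#' @param x A [marker_matrix()].
#' @param config A [rguc_config()].
#' @param rare Optional precomputed [find_rare_alleles()] result.
#' @return data.frame with one row per population: `population`,
#'   `n_individuals`, `h_nei`, `dw`, `n_r`.
#' @export
population_profiles <- function(x, config = rguc_config(), rare = NULL) {
  pops <- populations(x)
  if (is.null(rare)) rare <- find_rare_alleles(x, config)
  data.frame(population = pops,
             n_individuals = as.vector(table(pop_of(x))[pops]),
             h_nei = unname(nei_diversity(x, nei_correction = config$nei_correction)),
             dw = unname(dw_rarity(x, normalize = config$dw_normalize)),
             n_r = unname(n_rare_per_population(rare, all_populations = pops)),
             stringsAsFactors = FALSE)
}
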