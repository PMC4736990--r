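#' Minimum number of populations representing a target share of diversity
#'
#' Solves `P = 1 - F_ST^n` for the smallest integer `n` such that sampling
#' `n` populations represents at least a proportion `P` of the
#' among-population genetic diversity; the real-valued solution
#' `ln(1 - P)/ln(F_ST)` is returned alongside as a diagnostic.
#' The ceiling (never plain rounding) is taken: conservation targets are
#' lower bounds.
#'
#' @param target_P Target proportion of among-population diversity, in (0,1).
#' @param fst Fixation index F_ST, in \[0, 1).
#' @return A list of class `sampling_requirement` with `target_P`, `fst`,
#'   `n_real` and `n_required`.
#' @export
#' @examples
#' populations_needed(0.999, 0.289)$n_required  # 6
populations_needed <- function(target_P, fst) {
  stopifnot(target_P > 0, target_P < 1)
  if (fst >= 1) stop("fst >= 1: the sampling equation has no solution")
  if (fst < 0) stop("fst must be nonnegative")
  if (fst == 0) {
    out <- list(target_P = target_P, fst = fst, n_real = 1, n_required = 1L,
                note = "fst = 0: a single population carries all diversity")
    class(out) <- "sampling_requirement"
    return(out)
  }
  n_real <- log(1 - target_P) / log(fst)
  out <- list(target_P = target_P, fst = fst, n_real = n_real,
              n_required = max(1L, as.integer(ceiling(n_real))))
  class(out) <- "sampling_requirement"
  out
}

#' @export
print.sampling_requirement <- function(x, ...) {
  cat(sprintf("Sampling requirement: n = %d populations (real-valued n = %.3f)\n",
              x$n_required, x$n_real))
  cat(sprintf("  to represent P = %.4g of among-population diversity at F_ST = %.4g\n",
              x$target_P, x$fst))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Loss probabilities of rare bands
#'
#' For a rare band of mean carrier-population frequency `p` occurring in `N`
#' populations, the probability that sampling misses it is
#' `L = (1 - p)^(2N)`. The observed loss `Lo` uses the band's actual carrier
#' count; the expected loss `Le = (1 - p)^2` is the single-population
#' reference (the scheme in which only one population is sampled), so
#' `Lo <= Le` with equality exactly for bands private to one population.
#'
#' @param rare A `rare_alleles` table from [find_rare_alleles()].
#' @return Data.frame of class `loss_probabilities` with per-band `p`,
#'   `n_carriers`, `Lo`, `Le`, `neg_log_lo`, `neg_log_le` (natural logs).
#' @export
loss_probabilities <- function(rare) {
  if (any(rare$p <= 0 | rare$p >= 1))
    stop("degenerate rare-band frequency (p = 0 or 1); check the rarity filter")
  if (any(rare$n_carriers < 1)) stop("rare band with no carrier population")
  lo <- (1 - rare$p)^(2 * rare$n_carriers)
  le <- (1 - rare$p)^2
  out <- data.frame(marker = rare$marker, p = rare$p,
                    n_carriers = rare$n_carriers,
                    Lo = lo, Le = le,
                    neg_log_lo = -log(lo), neg_log_le = -log(le),
                    stringsAsFactors = FALSE)
  class(out) <- c("loss_probabilities", "data.frame")
  out
}

#' Capture statistic R from loss regressions
#'
#' `-log Lo` and `-log Le` are regressed on the mean band frequency `p`
#' (ordinary least squares, with intercept by default); R is the ratio of
#' the expected to the observed slope and measures the proportion of rare
#' bands captured by sampling a single population. R is invariant to the
#' logarithm base and equals 1 exactly when every band is private to one
#' population.
#'
#' @param loss A [loss_probabilities()] table.
#' @param through_origin Fit the regressions without intercept.
#' @return List of class `capture_regression` with `slope_obs`, `slope_exp`,
#'   `R` and the two `lm` fits.
#' @export
capture_R <- function(loss, through_origin = FALSE) {
  if (nrow(loss) < 2L || length(unique(loss$p)) < 2L)
    stop("capture regression needs >= 2 rare bands with distinct frequencies")
  fo <- if (through_origin) neg_log_lo ~ p + 0 else neg_log_lo ~ p
  fe <- if (through_origin) neg_log_le ~ p + 0 else neg_log_le ~ p
  fit_o <- stats::lm(fo, data = loss)
  fit_e <- stats::lm(fe, data = loss)
  m_o <- unname(stats::coef(fit_o)[["p"]])
  m_e <- unname(stats::coef(fit_e)[["p"]])
  out <- list(slope_obs = m_o, slope_exp = m_e, R = m_e / m_o,
              fit_obs = fit_o, fit_exp = fit_e,
              through_origin = through_origin, n_alleles = nrow(loss))
  class(out) <- "capture_regression"
  out
}

#' @export
print.capture_regression <- function(x, ...) {
  cat(sprintf("Capture regression over %d rare bands%s\n", x$n_alleles,
              if (x$through_origin) " (through origin)" else ""))
  cat(sprintf("  slope(-log Le) = %.4f, slope(-log Lo) = %.4f\n",
              x$slope_exp, x$slope_obs))
  cat(sprintf("  R = %.3f (proportion of rare bands captured by sampling one population)\n",
              x$R))
  invisible(x)
}

#' Assign each rare band to its preferred sampling area
#'
#' The preferred sampling area (PSA) of a rare band is the region
#' maximizing the probability that one population drawn uniformly from the
#' region carries and yields the band:
#' `P_g = (1/K_g) * sum_j [1 - (1 - p_j)^(2 n_j)]` over the region's `K_g`
#' populations, with `p_j` the band frequency and `n_j` the sample size in
#' population `j`. With `method = "carrier_fraction"` the simpler score
#' `carriers in region / K_g` is used instead. Ties go to the region with
#' the higher mean band frequency, then to region label order.
#'
#' @param rare A `rare_alleles` table.
#' @param partition Named character vector population -> region.
#' @param freqs Result of [band_frequencies()] for the same matrix.
#' @param method `"capture"` (default) or `"carrier_fraction"`.
#' @param proportion_decimals Decimals for the reported proportions.
#' @return List of class `psa_assignment`: `region_of_allele` (named
#'   character), `counts` and `proportions` per region, `exclusive_counts`
#'   (bands whose carriers all lie in one region).
#' @export
assign_psa <- function(rare, partition, freqs,
                       method = c("capture", "carrier_fraction"),
                       proportion_decimals = 2L) {
  method <- match.arg(method)
  regions <- sort(unique(unname(partition)))
  pops <- names(partition)
  miss <- setdiff(unique(unlist(rare$carrier_pops)), pops)
  if (length(miss)) stop("carrier population(s) without region: ",
                         paste(miss, collapse = ", "))
  n_j <- rowSums(freqs$n_valid_per_pop) / ncol(freqs$n_valid_per_pop)  # mean valid n
  n_j <- round(n_j)
  score_one <- function(marker) {
    pj <- freqs$per_pop[pops, marker]
    pj[is.na(pj)] <- 0
    s <- vapply(regions, function(g) {
      j <- pops[partition[pops] == g]
      if (method == "capture")
        mean(1 - (1 - pj[j])^(2 * n_j[j]))
      else
        mean(pj[j] > 0)
    }, numeric(1))
    mf <- vapply(regions, function(g) {
      j <- pops[partition[pops] == g]
      mean(pj[j])
    }, numeric(1))
    # ties: higher mean frequency, then label order (regions already sorted)
    ord <- order(-s, -mf, regions)
    regions[ord[1]]
  }
  assigned <- vapply(rare$marker, score_one, character(1))
  counts <- stats::setNames(integer(length(regions)), regions)
  tb <- table(assigned)
  counts[names(tb)] <- as.integer(tb)
  exclusive <- vapply(regions, function(g) {
    sum(vapply(rare$carrier_pops, function(cp)
      all(partition[cp] == g), logical(1)))
  }, integer(1))
  out <- list(region_of_allele = assigned,
              counts = counts,
              proportions = counts / sum(counts),
              proportions_reported = round(counts / sum(counts), proportion_decimals),
              exclusive_counts = exclusive,
              method = method)
  class(out) <- "psa_assignment"
  out
}

#' @export
print.psa_assignment <- function(x, ...) {
  cat(sprintf("Preferred sampling areas (%s method), %d rare bands\n",
              x$method, sum(x$counts)))
  df <- data.frame(region = names(x$counts), n_bands = as.integer(x$counts),
                   proportion = round(x$proportions, 3),
                   exclusive = as.integer(x$exclusive_counts))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Largest-remainder apportionment of populations across regions
#'
#' Allocates `n_required` population slots to regions proportionally to the
#' given shares using Hamilton's largest-remainder method: each region first
#' receives the floor of its exact quota, then the remaining slots go to the
#' largest fractional remainders. Remainder ties are broken by region label
#' order.
#'
#' @param n_required Total number of populations to allocate.
#' @param proportions Named nonnegative vector summing to (approximately) 1.
#' @return Named integer vector summing to `n_required`.
#' @export
#' @examples
#' apportion(6, c(IP = 0.45, M = 0.34, CI = 0.21))  # 3, 2, 1
apportion <- function(n_required, proportions) {
  stopifnot(n_required >= 1, all(proportions >= 0))
  if (sum(proportions) <= 0) stop("all-zero proportions")
  q <- n_required * proportions / sum(proportions)
  alloc <- floor(q)
  left <- n_required - sum(alloc)
  if (left > 0) {
    ord <- order(-(q - alloc), names(q))
    take <- ord[seq_len(left)]
    alloc[take] <- alloc[take] + 1
  }
  stats::setNames(as.integer(alloc), names(proportions))
}

#' Rank populations within regions and select the conservation set
#'
#' Within each region, populations are ranked by a composite score: the mean
#' of min-max-normalized (within region) Nei diversity, DW rarity and
#' rare-band count, plus configurable bonus weights for favourable
#' qualitative attributes (stable vulnerability, protected status, large
#' occupation area, high population size). The top `allocation[region]`
#' populations are selected; afterwards a coverage pass greedily appends
#' "also recommended" populations until every endemic haplotype of the
#' region is represented.
#'
#' @param profiles Data.frame from [population_profiles()].
#' @param attributes Data.frame from [read_population_attributes()], or NULL.
#' @param allocation Named integer vector region -> slots (see [apportion()]).
#' @param partition Named character vector population -> region.
#' @param weights Named bonus weights (`vulnerability`, `protected`,
#'   `large_area`, `large_size`); default all zero.
#' @return List of class `rguc_selection`: per region a data.frame of ranked
#'   populations with scores and flags, plus `selected` and
#'   `also_recommended` character vectors.
#' @export
prioritize <- function(profiles, attributes, allocation, partition,
                       weights = c(vulnerability = 0, protected = 0,
                                   large_area = 0, large_size = 0)) {
  w <- c(vulnerability = 0, protected = 0, large_area = 0, large_size = 0)
  w[names(weights)] <- weights
  minmax <- function(v) {
    if (length(v) == 1L || diff(range(v)) == 0) return(rep(0.5, length(v)))
    (v - min(v)) / (max(v) - min(v))
  }
  regions <- list()
  selected <- character(0)
  also <- character(0)
  for (g in sort(unique(unname(partition)))) {
    pops_g <- names(partition)[partition == g]
    pr <- profiles[profiles$population %in% pops_g, , drop = FALSE]
    if (nrow(pr) == 0L) next
    score <- rowMeans(cbind(minmax(pr$h_nei), minmax(pr$dw), minmax(pr$n_r)))
    bonus <- numeric(nrow(pr))
    missing_attr <- character(0)
    if (!is.null(attributes)) {
      for (i in seq_len(nrow(pr))) {
        p <- pr$population[i]
        if (!p %in% rownames(attributes)) {
          missing_attr <- c(missing_attr, p)
          next
        }
        a <- attributes[p, ]
        bonus[i] <- w[["vulnerability"]] * (a$vulnerability == "stable") +
          w[["protected"]] * (a$legal_status == "protected") +
          w[["large_area"]] * (a$occupation_area == "large") +
          w[["large_size"]] * (a$population_size == "high")
      }
      if (length(missing_attr))
        warning("no attributes for population(s) ",
                paste(missing_attr, collapse = ", "),
                "; ranked on genetic metrics only")
    }
    total <- score + bonus
    # ties broken by raw diversity, then label order, so ranking is a total order
    ord <- order(-total, -pr$h_nei, pr$population)
    ranked <- data.frame(population = pr$population[ord],
                         score = total[ord], genetic_score = score[ord],
                         bonus = bonus[ord], stringsAsFactors = FALSE)
    k <- min(allocation[[g]] %||% 0L, nrow(ranked))
    sel_g <- ranked$population[seq_len(k)]
    ranked$selected <- ranked$population %in% sel_g
    ranked$also_recommended <- FALSE
    if (!is.null(attributes)) {
      covered <- unique(unlist(attributes[intersect(sel_g, rownames(attributes)),
                                          "haplotypes"]))
      endemics_g <- unique(unlist(attributes[intersect(pops_g, rownames(attributes)),
                                             "endemic_haplotypes"]))
      uncovered <- setdiff(endemics_g, covered)
      for (p in ranked$population) {
        if (!length(uncovered)) break
        if (p %in% sel_g) next
        hp <- if (p %in% rownames(attributes)) attributes[p, "haplotypes"][[1]] else character(0)
        if (length(intersect(hp, uncovered))) {
          ranked$also_recommended[ranked$population == p] <- TRUE
          also <- c(also, p)
          uncovered <- setdiff(uncovered, hp)
        }
      }
    }
    regions[[g]] <- ranked
    selected <- c(selected, sel_g)
  }
  structure(list(regions = regions, selected = selected,
                 also_recommended = also, allocation = allocation,
                 weights = w),
            class = "rguc_selection")
}

#' @export
print.rguc_selection <- function(x, ...) {
  cat("Population selection (", sum(unlist(x$allocation)), " slots: ",
      paste(names(x$allocation), x$allocation, sep = "=", collapse = ", "), ")\n",
      sep = "")
  for (g in names(x$regions)) {
    r <- x$regions[[g]]
    cat(sprintf("  %s: selected %s%s\n", g,
                paste(r$population[r$selected], collapse = ", "),
                if (any(r$also_recommended))
                  paste0("; also recommended (haplotype coverage): ",
                         paste(r$population[r$also_recommended], collapse = ", "))
                else ""))
  }
  invisible(x)
}
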