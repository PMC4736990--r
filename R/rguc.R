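#' Select relevant genetic units for conservation
#'
#' Runs the full prioritization analysis on a dominant-marker dataset:
#' per-population diversity/rarity profiles, AMOVA (one-level and, given a
#' region partition, hierarchical), rare-band identification, loss
#' probabilities and the capture statistic R, preferred-sampling-area
#' assignment, largest-remainder apportionment of the required number of
#' populations across regions, within-region prioritization, and (when a
#' haplotype sample is supplied) haplotype-sampling completeness.
#'
#' @param x A [marker_matrix()].
#' @param partition Named character vector population -> region.
#' @param attributes Optional qualitative attribute table from
#'   [read_population_attributes()].
#' @param haplotypes Optional [haplotype_sample()] (e.g. from
#'   [collapse_haplotypes()] or [simulate_haplotype_sample()]).
#' @param config A [rguc_config()].
#' @param fst Optional externally supplied F_ST for the sampling equation;
#'   by default the one-level AMOVA estimate is used.
#' @return Object of class `rguc`: a list with components `profiles`,
#'   `amova`, `amova_hier`, `rare`, `loss`, `capture`, `requirement`,
#'   `psa`, `allocation`, `selection`, `dixon`, `config`.
#' @export
#' @examples
#' sim <- simulate_marker_matrix(sim_spec(n_populations = 6, n_individuals = 8,
#'                                        n_markers = 120, F = 0.3, seed = 3))
#' cfg <- rguc_config(n_permutations = 49, n_bootstrap = 49)
#' fit <- rguc(sim$matrix, sim$regions, config = cfg)
#' print(fit)
rguc <- function(x, partition, attributes = NULL, haplotypes = NULL,
                 config = rguc_config(), fst = NULL) {
  partition <- validate_partition(x, partition)
  rare <- find_rare_alleles(x, config)
  profiles <- population_profiles(x, config, rare = rare)
  fit1 <- amova(x, config = config)
  fit2 <- if (length(unique(partition)) >= 2L)
    amova(x, partition = partition, config = config) else NULL
  if (is.null(fst)) fst <- unname(fit1$phi[["F_ST"]])
  requirement <- populations_needed(config$target_P, fst)
  loss <- NULL; capture <- NULL; psa <- NULL; allocation <- NULL
  if (nrow(rare) > 0L) {
    loss <- loss_probabilities(rare)
    if (length(unique(rare$p)) >= 2L)
      capture <- capture_R(loss, through_origin = config$regression_through_origin)
    psa <- assign_psa(rare, partition, band_frequencies(x),
                      method = config$psa_method,
                      proportion_decimals = config$proportion_decimals)
    props <- if (config$use_rounded_proportions) psa$proportions_reported
             else psa$proportions
    allocation <- apportion(requirement$n_required, props)
  } else {
    # no rare band: spread the requirement evenly across regions
    regions <- sort(unique(unname(partition)))
    allocation <- apportion(requirement$n_required,
                            stats::setNames(rep(1, length(regions)), regions))
  }
  selection <- prioritize(profiles, attributes, allocation, partition,
                          weights = config$prioritize_weights)
  dixon <- if (!is.null(haplotypes))
    dixon_completeness(haplotypes, theta_max = config$dixon_theta_max) else NULL
  structure(list(profiles = profiles, amova = fit1, amova_hier = fit2,
                 rare = rare, loss = loss, capture = capture,
                 requirement = requirement, psa = psa,
                 allocation = allocation, selection = selection,
                 dixon = dixon, partition = partition, config = config),
            class = "rguc")
}

#' @export
print.rguc <- function(x, ...) {
  cat("RGUC selection analysis\n")
  cat(sprintf("  %d populations in %d region(s); F_ST = %.3f\n",
              nrow(x$profiles), length(unique(x$partition)),
              x$amova$phi[["F_ST"]]))
  cat(sprintf("  populations required (P = %.4g): %d\n",
              x$config$target_P, x$requirement$n_required))
  cat(sprintf("  rare bands: %d", nrow(x$rare)))
  if (!is.null(x$capture)) cat(sprintf("; capture R = %.3f", x$capture$R))
  cat("\n")
  if (!is.null(x$allocation))
    cat("  allocation:",
        paste(names(x$allocation), x$allocation, sep = "=", collapse = ", "), "\n")
  cat("  selected:", paste(x$selection$selected, collapse = ", "), "\n")
  if (length(x$selection$also_recommended))
    cat("  also recommended (haplotype coverage):",
        paste(x$selection$also_recommended, collapse = ", "), "\n")
  if (!is.null(x$dixon))
    cat(sprintf("  haplotype completeness: posterior mean theta = %.3f, P(complete) = %.3f\n",
                x$dixon$posterior_mean, x$dixon$p_complete))
  invisible(x)
}

#' @export
summary.rguc <- function(object, ...) {
  print(object)
  cat("\nPer-population profiles:\n")
  pr <- object$profiles
  pr$region <- unname(object$partition[pr$population])
  pr$h_nei <- round(pr$h_nei, 3); pr$dw <- round(pr$dw, 3)
  print(pr[c("population", "region", "n_individuals", "h_nei", "dw", "n_r")],
        row.names = FALSE)
  cat("\n")
  print(object$amova)
  if (!is.null(object$amova_hier)) { cat("\n"); print(object$amova_hier) }
  if (!is.null(object$psa)) { cat("\n"); print(object$psa) }
  invisible(object)
}

#' Plot the loss-probability regressions of a fitted analysis
#'
#' Shows `-log Lo` and `-log Le` against the mean rare-band frequency with
#' their least-squares lines; the slope ratio is the capture statistic R.
#'
#' @param x A fitted `rguc` object with at least two rare bands.
#' @param ... Passed to [plot()].
#' @export
plot.rguc <- function(x, ...) {
  if (is.null(x$capture)) stop("no capture regression in this fit (too few rare bands)")
  l <- x$loss
  plot(l$p, l$neg_log_lo, pch = 1, xlab = "mean rare-band frequency p",
       ylab = "-log L", ...)
  graphics::points(l$p, l$neg_log_le, pch = 17)
  graphics::abline(x$capture$fit_obs, lty = 1)
  graphics::abline(x$capture$fit_exp, lty = 2)
  graphics::legend("topleft", pch = c(1, 17), lty = c(1, 2),
                   legend = c("observed (-log Lo)", "expected (-log Le)"),
                   bty = "n")
  graphics::mtext(sprintf("R = %.3f", x$capture$R), side = 3, adj = 1)
  invisible(x)
}

.amova_table <- function(a) {
  if (is.null(a)) return(NULL)
  df <- a$levels
  df$F_ST <- c(a$phi[["F_ST"]], rep(NA, nrow(df) - 1))
  df
}

#' Write a machine-readable report of a fitted analysis
#'
#' Emits `report.json` (all numbers at full precision, round-trippable with
#' [read_report()]) plus delimited tables `profiles.tsv`, `amova.tsv` and
#' `rare_alleles.tsv` into a directory.
#'
#' @param fit A fitted `rguc` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(fit, dir) {
  stopifnot(inherits(fit, "rguc"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create report directory: ", dir)
  cfg <- fit$config
  report <- list(
    config = cfg[c("rare_freq_threshold", "rare_popfrac_threshold", "target_P",
                   "n_permutations", "n_bootstrap", "rng_seed",
                   "dixon_theta_max", "psa_method")],
    profiles = fit$profiles,
    amova = list(
      one_level = fit$amova$levels,
      one_level_phi = as.list(fit$amova$phi),
      one_level_p = as.list(fit$amova$p_values),
      fst_ci = fit$amova$fst_ci,
      hierarchical = if (!is.null(fit$amova_hier)) fit$amova_hier$levels,
      hierarchical_phi = if (!is.null(fit$amova_hier)) as.list(fit$amova_hier$phi)),
    sampling = list(target_P = fit$requirement$target_P,
                    fst = fit$requirement$fst,
                    n_real = fit$requirement$n_real,
                    n_required = fit$requirement$n_required),
    rare = list(count = nrow(fit$rare),
                table = fit$rare[setdiff(names(fit$rare), "carrier_pops")],
                capture_R = if (!is.null(fit$capture)) fit$capture$R),
    psa = if (!is.null(fit$psa))
      list(counts = as.list(fit$psa$counts),
           proportions = as.list(fit$psa$proportions),
           exclusive = as.list(fit$psa$exclusive_counts)),
    allocation = as.list(fit$allocation),
    selection = list(selected = fit$selection$selected,
                     also_recommended = fit$selection$also_recommended),
    dixon = if (!is.null(fit$dixon))
      list(n = fit$dixon$n, k = fit$dixon$k,
           posterior_mean = fit$dixon$posterior_mean,
           p_complete = fit$dixon$p_complete))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(fit$profiles, file.path(dir, "profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  am <- .amova_table(fit$amova)
  if (!is.null(fit$amova_hier)) am <- rbind(am, .amova_table(fit$amova_hier))
  utils::write.table(am, file.path(dir, "amova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rare_flat <- fit$rare
  rare_flat$carrier_pops <- vapply(rare_flat$carrier_pops, paste,
                                   character(1), collapse = ",")
  utils::write.table(rare_flat, file.path(dir, "rare_alleles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_report
#' @param path Path to a `report.json` written by [write_report()].
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  if (!file.exists(path)) stop("report not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
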