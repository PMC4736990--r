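#' Pairwise squared distances between band profiles
#'
#' For binary phenotypes the squared Euclidean distance equals the number of
#' markers at which two individuals differ; markers missing in either
#' individual are skipped for that pair.
#'
#' @param x A [marker_matrix()] (or plain 0/1 matrix).
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
pairwise_sq_distance <- function(x) {
  v <- unclass(as.matrix(x))
  ones <- v; ones[is.na(ones)] <- 0
  zeros <- 1 - v; zeros[is.na(zeros)] <- 0
  d <- tcrossprod(ones, zeros)
  d <- d + t(d)
  dimnames(d) <- list(rownames(v), rownames(v))
  d
}

# sum over unordered within-group pairs of D, each group divided by its size
.ss_within_groups <- function(d, idx_list) {
  sum(vapply(idx_list, function(idx)
    sum(d[idx, idx]) / (2 * length(idx)), numeric(1)))
}

# variance components for one-level or hierarchical AMOVA given a distance
# matrix and population/group labels; labels are parallel to rows of d
.amova_components <- function(d, pop, group = NULL) {
  n_tot <- nrow(d)
  pops <- unique(pop)
  n_p <- vapply(pops, function(p) sum(pop == p), numeric(1))
  ss_total <- sum(d) / (2 * n_tot)
  ss_wp <- .ss_within_groups(d, lapply(pops, function(p) which(pop == p)))
  if (is.null(group) || length(unique(group)) < 2L) {
    ss_ap <- ss_total - ss_wp
    df <- c(length(pops) - 1, n_tot - length(pops))
    ms <- c(ss_ap, ss_wp) / df
    n0 <- (n_tot - sum(n_p^2) / n_tot) / (length(pops) - 1)
    s2_w <- ms[2]
    s2_a <- (ms[1] - s2_w) / n0
    return(list(source = c("Among populations", "Within populations"),
                df = df, ss = c(ss_ap, ss_wp), ms = ms,
                sigma2 = c(s2_a, s2_w), hierarchical = FALSE))
  }
  groups <- unique(group)
  grp_of_pop <- vapply(pops, function(p) group[match(p, pop)], character(1))
  n_g <- vapply(groups, function(g) sum(group == g), numeric(1))
  ss_wg <- .ss_within_groups(d, lapply(groups, function(g) which(group == g)))
  ss_ag <- ss_total - ss_wg
  ss_apwg <- ss_wg - ss_wp
  df <- c(length(groups) - 1, length(pops) - length(groups), n_tot - length(pops))
  ms <- ifelse(df > 0, c(ss_ag, ss_apwg, ss_wp) / df, 0)
  # expected-mean-square coefficients for unequal sample sizes
  sum_np2_by_g <- vapply(groups, function(g)
    sum(n_p[grp_of_pop == g]^2) / n_g[match(g, groups)], numeric(1))
  n1 <- (n_tot - sum(sum_np2_by_g)) / (length(pops) - length(groups))
  n2 <- (sum(sum_np2_by_g) - sum(n_p^2) / n_tot) / (length(groups) - 1)
  n3 <- (n_tot - sum(n_g^2) / n_tot) / (length(groups) - 1)
  s2_c <- ms[3]
  # groups coinciding with populations leave no among-populations-within-
  # groups stratum: its component is identically zero
  s2_b <- if (df[2] > 0) (ms[2] - s2_c) / n1 else 0
  s2_a <- (ms[1] - s2_c - n2 * s2_b) / n3
  list(source = c("Among groups", "Among populations within groups",
                  "Within populations"),
       df = df, ss = c(ss_ag, ss_apwg, ss_wp), ms = ms,
       sigma2 = c(s2_a, s2_b, s2_c), hierarchical = TRUE)
}

.phi_from_components <- function(sigma2, hierarchical) {
  tot <- sum(sigma2)
  if (hierarchical)
    c(F_CT = sigma2[1] / tot,
      F_SC = sigma2[2] / (sigma2[2] + sigma2[3]),
      F_ST = (sigma2[1] + sigma2[2]) / tot)
  else
    c(F_ST = sigma2[1] / tot)
}

#' Analysis of molecular variance on dominant marker phenotypes
#'
#' Partitions the squared-distance variation in band profiles among
#' populations (and, when a region partition is supplied, among regional
#' groups, among populations within groups, and within populations),
#' following the classical sums-of-squares decomposition of a pairwise
#' squared Euclidean distance matrix with expected-mean-square coefficients
#' for unequal sample sizes. Significance is assessed by permutation:
#' individuals are reassigned to populations (sizes preserved) for F_ST;
#' in the hierarchical design additionally individuals are permuted among
#' populations within groups for F_SC and whole populations among groups
#' for F_CT. A percentile bootstrap over marker columns gives the F_ST
#' confidence interval.
#'
#' @param x A [marker_matrix()].
#' @param partition Optional named character vector mapping population codes
#'   to region codes (see [read_region_partition()]); when given a
#'   three-component hierarchical analysis is performed.
#' @param config A [rguc_config()]; `n_permutations = 0` or
#'   `n_bootstrap = 0` skip the corresponding resampling.
#' @return Object of class `amova`: a list with `levels` (data.frame of
#'   source, df, SS, MS, variance component, percentage), `phi`
#'   (fixation indices), `p_values`, `fst_ci`, and `config` echo.
#' @export
#' @examples
#' set.seed(1)
#' m <- simulate_marker_matrix(sim_spec(n_populations = 4, n_individuals = 8,
#'                                      n_markers = 60, F = 0.2, seed = 7))$matrix
#' fit <- amova(m, config = rguc_config(n_permutations = 99, n_bootstrap = 99))
#' fit$phi[["F_ST"]]
amova <- function(x, partition = NULL, config = rguc_config()) {
  pop <- unname(pop_of(x))
  sizes <- table(pop)
  if (length(sizes) < 2L) stop("AMOVA needs >= 2 populations")
  if (any(sizes < 2L))
    stop("population(s) with a single individual: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; exclude them before AMOVA")
  group <- NULL
  if (!is.null(partition)) {
    partition <- validate_partition(x, partition)
    if (length(unique(partition)) < 2L) {
      warning("partition has a single region; fitting one-level AMOVA")
    } else {
      group <- unname(partition[pop])
      singles <- names(which(table(partition) == 1L))
      if (length(singles))
        warning("region(s) with a single population (F_SC degenerate there): ",
                paste(singles, collapse = ", "))
    }
  }
  d <- pairwise_sq_distance(x)
  comp <- .amova_components(d, pop, group)
  if (any(comp$sigma2 < 0)) {
    warning("negative variance component(s) reported as-is; set ",
            "truncate_negative_variance = TRUE to clamp at zero")
    if (config$truncate_negative_variance) comp$sigma2 <- pmax(comp$sigma2, 0)
  }
  phi <- .phi_from_components(comp$sigma2, comp$hierarchical)

  p_values <- NULL
  if (config$n_permutations > 0) {
    set.seed(config$rng_seed)
    nperm <- config$n_permutations
    if (!comp$hierarchical) {
      stat <- function(lbl) {
        cc <- .amova_components(d, lbl)
        .phi_from_components(cc$sigma2, FALSE)[["F_ST"]]
      }
      perm <- replicate(nperm, stat(sample(pop)))
      p_values <- c(F_ST = (sum(perm >= phi[["F_ST"]]) + 1) / (nperm + 1))
    } else {
      pops <- unique(pop)
      grp_of_pop <- stats::setNames(vapply(pops, function(p) group[match(p, pop)],
                                           character(1)), pops)
      # F_ST: individuals permuted among populations over the whole dataset
      perm_st <- replicate(nperm, {
        cc <- .amova_components(d, sample(pop), group)
        .phi_from_components(cc$sigma2, TRUE)[["F_ST"]]
      })
      # F_SC: individuals permuted among populations within their group
      perm_sc <- replicate(nperm, {
        lbl <- pop
        for (g in unique(group)) {
          i <- which(group == g)
          lbl[i] <- sample(lbl[i])
        }
        cc <- .amova_components(d, lbl, group)
        .phi_from_components(cc$sigma2, TRUE)[["F_SC"]]
      })
      # F_CT: whole populations permuted among groups (sizes in populations kept)
      perm_ct <- replicate(nperm, {
        g_perm <- stats::setNames(sample(unname(grp_of_pop)), names(grp_of_pop))
        cc <- .amova_components(d, pop, unname(g_perm[pop]))
        .phi_from_components(cc$sigma2, TRUE)[["F_CT"]]
      })
      p_values <- c(F_CT = (sum(perm_ct >= phi[["F_CT"]]) + 1) / (nperm + 1),
                    F_SC = (sum(perm_sc >= phi[["F_SC"]]) + 1) / (nperm + 1),
                    F_ST = (sum(perm_st >= phi[["F_ST"]]) + 1) / (nperm + 1))
    }
  }

  fst_ci <- NULL
  if (config$n_bootstrap > 0) {
    set.seed(config$rng_seed + 1L)
    boot <- replicate(config$n_bootstrap, {
      cols <- sample.int(ncol(x), replace = TRUE)
      db <- pairwise_sq_distance(unclass(x)[, cols, drop = FALSE])
      cc <- .amova_components(db, pop, group)
      .phi_from_components(cc$sigma2, comp$hierarchical)[["F_ST"]]
    })
    fst_ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }

  levels_df <- data.frame(source = comp$source, df = comp$df, SS = comp$ss,
                          MS = comp$ms, sigma2 = comp$sigma2,
                          percent = 100 * comp$sigma2 / sum(comp$sigma2),
                          stringsAsFactors = FALSE)
  structure(list(levels = levels_df, phi = phi, p_values = p_values,
                 fst_ci = fst_ci, hierarchical = comp$hierarchical,
                 n_individuals = nrow(x), n_markers = ncol(x),
                 config = config),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 4, ...) {
  cat(if (x$hierarchical) "Hierarchical AMOVA" else "One-level AMOVA",
      sprintf("(%d individuals, %d markers)\n", x$n_individuals, x$n_markers))
  df <- x$levels
  df$SS <- round(df$SS, digits); df$MS <- round(df$MS, digits)
  df$sigma2 <- round(df$sigma2, digits); df$percent <- round(df$percent, 2)
  print(df, row.names = FALSE)
  cat("Fixation indices:",
      paste(names(x$phi), round(x$phi, digits), sep = " = ", collapse = ", "), "\n")
  if (!is.null(x$p_values))
    cat("Permutation p:",
        paste(names(x$p_values), signif(x$p_values, 3), sep = " = ", collapse = ", "),
        sprintf(" (%d permutations)\n", x$config$n_permutations))
  if (!is.null(x$fst_ci))
    cat(sprintf("F_ST 95%% CI (marker bootstrap): %.3f-%.3f\n",
                x$fst_ci[1], x$fst_ci[2]))
  invisible(x)
}
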