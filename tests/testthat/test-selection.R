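test_that("the sampling equation gives the minimum integer population count", {
  req <- populations_needed(0.999, 0.289)
  expect_equal(req$n_required, 6L)
  expect_equal(req$n_real, log(0.001) / log(0.289))
  # closed-form case: 1 - 0.5^2 = 0.75 exactly
  expect_equal(populations_needed(0.75, 0.5)$n_required, 2L)
  # the defining inequalities of the minimal n
  expect_gte(1 - req$fst^req$n_required, req$target_P)
  expect_lt(1 - req$fst^(req$n_required - 1), req$target_P)
})

test_that("the real-valued n reconciles a differentiation inside the CI", {
  # diagnostic: n = 5.69 corresponds to F_ST ~ 0.297, not 0.289
  expect_equal(round(populations_needed(0.999, 0.297)$n_real, 2), 5.69)
})

test_that("populations_needed is monotone and handles edge cases", {
  grid_P <- c(0.9, 0.99, 0.999, 0.9999)
  ns <- sapply(grid_P, function(P) populations_needed(P, 0.3)$n_required)
  expect_true(all(diff(ns) >= 0))
  grid_f <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ns2 <- sapply(grid_f, function(f) populations_needed(0.999, f)$n_required)
  expect_true(all(diff(ns2) >= 0))
  expect_equal(populations_needed(0.999, 0)$n_required, 1L)
  expect_error(populations_needed(0.999, 1), "no solution")
})

test_that("loss probabilities follow L = (1 - p)^(2N) with Le the N = 1 reference", {
  rare <- structure(data.frame(marker = c("a", "b"), overall_freq = c(0.02, 0.03),
                               p = c(0.5, 0.1), n_carriers = c(1L, 3L)),
                    class = c("rare_alleles", "data.frame"))
  rare$carrier_pops <- list("P1", c("P1", "P2", "P3"))
  loss <- loss_probabilities(rare)
  expect_equal(loss$Lo, c(0.25, 0.9^6))
  expect_equal(loss$Le, c(0.25, 0.81))
  expect_equal(loss$Lo[2], 0.531441)
  # any band in >= 2 populations is safer than the single-population reference
  expect_true(all(loss$Lo[loss$n_carriers >= 2] < loss$Le[loss$n_carriers >= 2]))
  rare$p[1] <- 0
  expect_error(loss_probabilities(rare), "degenerate")
})

make_rare <- function(p, n_carriers) {
  out <- structure(data.frame(marker = paste0("r", seq_along(p)),
                              overall_freq = p / 5, p = p,
                              n_carriers = as.integer(n_carriers)),
                   class = c("rare_alleles", "data.frame"))
  out$carrier_pops <- lapply(n_carriers, function(n) paste0("P", seq_len(n)))
  out
}

test_that("capture R is 1 for private bands and matches an OLS oracle otherwise", {
  p <- c(0.02, 0.04, 0.06, 0.08)
  expect_equal(capture_R(loss_probabilities(make_rare(p, rep(1, 4))))$R, 1)
  # all bands in 2 populations, small p: slopes scale with 2N, so R near 1/2
  cap2 <- capture_R(loss_probabilities(make_rare(p, rep(2, 4))))
  expect_equal(cap2$R, 0.5, tolerance = 0.01)
  # mixed carriers: compare slopes with independent closed-form OLS
  loss <- loss_probabilities(make_rare(c(0.02, 0.05, 0.07, 0.09), c(1, 2, 3, 2)))
  ols_slope <- function(x, y) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  m_o <- ols_slope(loss$p, -log(loss$Lo))
  m_e <- ols_slope(loss$p, -log(loss$Le))
  cap <- capture_R(loss)
  expect_equal(cap$slope_obs, m_o)
  expect_equal(cap$slope_exp, m_e)
  expect_equal(cap$R, m_e / m_o)
  expect_true(cap$R > 0 && cap$R <= 1)
})

test_that("R is invariant to the logarithm base", {
  loss <- loss_probabilities(make_rare(c(0.02, 0.05, 0.08), c(2, 3, 1)))
  loss10 <- loss
  loss10$neg_log_lo <- -log10(loss$Lo)
  loss10$neg_log_le <- -log10(loss$Le)
  expect_equal(capture_R(loss)$R, capture_R(loss10)$R)
})

test_that("degenerate regressions are refused", {
  expect_error(capture_R(loss_probabilities(make_rare(c(0.05, 0.05), c(1, 2)))),
               "distinct")
})

test_that("preferred sampling areas follow the one-population capture probability", {
  # an allele private to one region must land there; an allele at equal
  # frequency in 1 of 2 IP populations and 1 of 4 M populations goes to the
  # smaller region (division by the number of the region's populations)
  pops <- paste0("P", 1:6)
  partition <- setNames(c("IP", "IP", "M", "M", "M", "M"), pops)
  pop_vec <- rep(pops, each = 3)
  vals <- matrix(0, 18, 2)
  vals[which(pop_vec == "P1")[1], 1] <- 1            # private to IP
  vals[which(pop_vec == "P1")[1], 2] <- 1            # 1 of 2 IP pops ...
  vals[which(pop_vec == "P3")[1], 2] <- 1            # ... and 1 of 4 M pops
  m <- marker_matrix(vals, pop_vec)
  rare <- structure(data.frame(marker = c("m1", "m2"),
                               overall_freq = c(1, 2) / 18,
                               p = c(1 / 3, 1 / 3), n_carriers = c(1L, 2L)),
                    class = c("rare_alleles", "data.frame"))
  rare$carrier_pops <- list("P1", c("P1", "P3"))
  psa <- assign_psa(rare, partition, band_frequencies(m))
  expect_equal(unname(psa$region_of_allele["m1"]), "IP")
  expect_equal(unname(psa$region_of_allele["m2"]), "IP")
  expect_equal(sum(psa$counts), nrow(rare))
})

test_that("PSA assignment equals brute-force evaluation of the capture score", {
  sim <- simulate_marker_matrix(sim_spec(n_populations = 6, n_individuals = 6,
                                         n_markers = 80, F = 0.2, n_regions = 3,
                                         seed = 31))
  m <- sim$matrix
  rare <- find_rare_alleles(m)
  expect_gt(nrow(rare), 0)
  bf <- band_frequencies(m)
  psa <- assign_psa(rare, sim$regions, bf)
  nj <- table(pop_of(m))
  for (r in seq_len(nrow(rare))) {
    best <- NA; best_s <- -Inf
    for (g in sort(unique(unname(sim$regions)))) {
      js <- names(sim$regions)[sim$regions == g]
      s <- 0
      for (j in js) {
        pj <- bf$per_pop[j, rare$marker[r]]
        s <- s + (1 - (1 - pj)^(2 * nj[[j]]))
      }
      s <- s / length(js)
      if (s > best_s + 1e-12) { best_s <- s; best <- g }
    }
    expect_equal(unname(psa$region_of_allele[rare$marker[r]]), best)
  }
  expect_equal(sum(psa$counts), nrow(rare))
})

test_that("largest-remainder apportionment conserves the total and matches search", {
  expect_equal(apportion(6, c(IP = 0.45, M = 0.34, CI = 0.21)),
               c(IP = 3L, M = 2L, CI = 1L))
  # exact tie broken by label order
  expect_equal(apportion(5, c(A = 0.5, B = 0.5)), c(A = 3L, B = 2L))
  expect_error(apportion(3, c(A = 0, B = 0)), "all-zero")
  # exhaustive oracle: minimal total absolute deviation from the quotas
  set.seed(17)
  for (rep in 1:8) {
    k <- sample(2:4, 1); n <- sample(1:10, 1)
    pr <- runif(k); pr <- pr / sum(pr); names(pr) <- LETTERS[1:k]
    alloc <- apportion(n, pr)
    expect_equal(sum(alloc), n)
    q <- n * pr
    # enumerate all integer allocations summing to n
    grid <- expand.grid(rep(list(0:n), k))
    grid <- grid[rowSums(grid) == n, , drop = FALSE]
    best <- min(apply(grid, 1, function(a) sum(abs(a - q))))
    expect_equal(sum(abs(alloc - q)), best, tolerance = 1e-9)
  }
})

test_that("prioritization ranks dominant populations first and covers endemics", {
  profiles <- data.frame(population = c("A1", "A2", "A3", "B1", "B2"),
                         n_individuals = 10,
                         h_nei = c(0.15, 0.08, 0.10, 0.12, 0.07),
                         dw = c(4.0, 1.5, 2.0, 3.0, 1.0),
                         n_r = c(40L, 10L, 20L, 30L, 5L))
  partition <- setNames(c("R1", "R1", "R1", "R2", "R2"), profiles$population)
  attr_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "population\toccupation_area\tpopulation_size\tvulnerability\tlegal_status\thaplotypes",
    "A1\tlarge\thigh\tstable\tprotected\tI",
    "A2\tsmall\treduced\tcritical\tunprotected\tI,*X",
    "A3\tlarge\thigh\tstable\tprotected\tI",
    "B1\tlarge\thigh\tstable\tprotected\tII",
    "B2\tsmall\treduced\tcritical\tunprotected\tII"), attr_path)
  att <- read_population_attributes(attr_path)
  sel <- prioritize(profiles, att, allocation = c(R1 = 1L, R2 = 1L), partition)
  # A1 dominates every genetic metric in R1, B1 in R2
  expect_equal(sel$regions$R1$population[1], "A1")
  expect_true("A1" %in% sel$selected && "B1" %in% sel$selected)
  expect_equal(length(sel$selected), 2)
  # the endemic haplotype X lives only in low-ranked A2: flagged for coverage
  expect_true("A2" %in% sel$also_recommended)
  expect_false("B2" %in% sel$also_recommended)
})

test_that("attribute bonuses shift the ranking only through the weights", {
  profiles <- data.frame(population = c("A1", "A2"), n_individuals = 10,
                         h_nei = c(0.10, 0.11), dw = c(2.0, 2.1), n_r = c(20L, 21L))
  partition <- setNames(c("R1", "R1"), profiles$population)
  attr_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "population\toccupation_area\tpopulation_size\tvulnerability\tlegal_status",
    "A1\tlarge\thigh\tstable\tprotected",
    "A2\tsmall\treduced\tcritical\tunprotected"), attr_path)
  att <- read_population_attributes(attr_path)
  sel0 <- prioritize(profiles, att, c(R1 = 1L), partition)
  expect_equal(sel0$selected, "A2")  # wins on genetics with zero weights
  selw <- prioritize(profiles, att, c(R1 = 1L), partition,
                     weights = c(vulnerability = 2, protected = 2,
                                 large_area = 2, large_size = 2))
  expect_equal(selw$selected, "A1")  # bonuses dominate
  # missing attributes: ranked on genetics with a warning
  expect_warning(selm <- prioritize(profiles, att[1, , drop = FALSE],
                                    c(R1 = 1L), partition),
                 "ranked on genetic metrics only")
  expect_equal(selm$selected, "A2")
})
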