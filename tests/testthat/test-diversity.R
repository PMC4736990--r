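test_that("band frequencies match a direct per-cell recount", {
  m <- marker_matrix(rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 0),
                           c(1, 0), c(1, 0)),
                     pop = c(rep("A", 4), "B", "B"),
                     marker_ids = c("m1", "m2"))
  bf <- band_frequencies(m)
  expect_equal(bf$per_pop["A", "m1"], 0.25)  # 1 carrier of 4
  expect_equal(unname(bf$overall["m2"]), 0)  # absent everywhere

  m <- random_matrix(3, 5, 12, seed = 11)
  bf <- band_frequencies(m)
  for (p in populations(m)) {
    sub <- unclass(m)[pop_of(m) == p, , drop = FALSE]
    for (j in seq_len(ncol(m))) {
      cnt <- 0; tot <- 0
      for (i in seq_len(nrow(sub))) {
        tot <- tot + 1
        if (sub[i, j] == 1) cnt <- cnt + 1
      }
      expect_equal(bf$per_pop[p, j], cnt / tot)
    }
  }
})

test_that("Nei diversity matches hand computation and edge behaviour", {
  # pop A monomorphic at every marker, B provides dataset polymorphism
  m <- marker_matrix(rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 0)),
                     pop = c("A", "A", "B", "B"))
  expect_equal(nei_diversity(m, "A"), 0)

  # a single polymorphic marker at f = 0.5 averaged alone gives 0.5
  m2 <- marker_matrix(cbind(c(1, 0, 1, 0)), pop = rep("A", 4))
  expect_equal(nei_diversity(m2, "A"), 0.5)

  # 5-individual toy over 4 markers: mean of 1 - f^2 - (1-f)^2 per marker
  vals <- rbind(c(1, 1, 0, 0),
                c(1, 0, 0, 1),
                c(0, 1, 0, 1),
                c(1, 1, 0, 1),
                c(0, 0, 1, 1))
  m3 <- marker_matrix(vals, pop = rep("A", 5))
  f <- c(3, 3, 1, 4) / 5
  expect_equal(nei_diversity(m3, "A"), mean(1 - f^2 - (1 - f)^2))

  expect_error(nei_diversity(marker_matrix(rbind(c(1, 0), c(0, 1), c(1, 1)),
                                           pop = c("A", "B", "B")), "A"),
               "single individual")
})

test_that("Nei diversity is invariant to column order and 0/1 relabelling", {
  m <- random_matrix(2, 8, 10, seed = 5)
  h0 <- nei_diversity(m, "P1")
  perm <- sample(ncol(m))
  m_perm <- marker_matrix(unclass(m)[, perm], pop = pop_of(m),
                          marker_ids = colnames(m)[perm])
  expect_equal(nei_diversity(m_perm, "P1"), h0)
  flip <- unclass(m); flip[, 3] <- 1 - flip[, 3]
  m_flip <- marker_matrix(flip, pop = pop_of(m))
  expect_equal(nei_diversity(m_flip, "P1"), h0)
})

test_that("DW rarity follows the count-ratio convention", {
  # single population: every ratio is 1, so dw = markers present / sample size
  m1 <- marker_matrix(rbind(c(1, 1, 0), c(1, 0, 0)), pop = c("A", "A"))
  expect_equal(unname(dw_rarity(m1, "A")), 2 / 2)
  # two populations with identical profiles score identically
  m2 <- marker_matrix(rbind(c(1, 0, 1), c(0, 1, 1), c(1, 0, 1), c(0, 1, 1)),
                      pop = c("A", "A", "B", "B"))
  dw <- dw_rarity(m2)
  expect_equal(unname(dw["A"]), unname(dw["B"]))
  # adding a private band strictly increases the carrier's dw
  base <- rbind(c(1, 0), c(1, 1), c(0, 1), c(1, 1), c(1, 0), c(0, 1))
  pops <- rep(c("A", "B", "C"), each = 2)
  with_priv <- cbind(base, c(1, 0, 0, 0, 0, 0))
  expect_gt(dw_rarity(marker_matrix(with_priv, pop = pops), "A") * 2,
            dw_rarity(marker_matrix(base, pop = pops), "A") * 2)
  # unnormalized variant is the raw ratio sum
  expect_equal(unname(dw_rarity(m1, "A", normalize = FALSE)), 2)
})

test_that("rare-band filter equals the brute-force double loop", {
  cfg <- rguc_config()
  any_rare <- FALSE
  for (seed in 1:6) {
    set.seed(seed + 100)
    freqs <- runif(20, 0, 0.30)
    m <- random_matrix(11, 4, 20, seed = seed, freqs = freqs)
    rare <- find_rare_alleles(m, cfg)
    any_rare <- any_rare || nrow(rare) > 0
    # brute force, marker by marker
    expected <- character(0)
    v <- unclass(m); pop <- pop_of(m)
    for (j in seq_len(ncol(v))) {
      overall <- mean(v[, j])
      carriers <- 0
      for (p in unique(pop)) if (any(v[pop == p, j] == 1)) carriers <- carriers + 1
      if (overall > 0 && overall < 0.10 && carriers / 11 < 0.20)
        expected <- c(expected, colnames(v)[j])
    }
    expect_setequal(rare$marker, expected)
    # p is the unweighted mean of carrier-population frequencies
    for (r in seq_len(nrow(rare))) {
      cp <- rare$carrier_pops[[r]]
      fr <- sapply(cp, function(p) mean(v[pop == p, rare$marker[r]]))
      expect_equal(rare$p[r], mean(fr))
    }
  }
  expect_true(any_rare)  # the property must have been exercised
})

test_that("rare-band criteria use strict inequalities on both thresholds", {
  # 17 populations of 3; marker A in 1 pop at overall 2/51 (~0.04): rare
  # marker B in 4 of 17 pops (4/17 > 0.20): excluded despite low frequency
  vals <- matrix(0, 51, 2)
  vals[1:2, 1] <- 1
  vals[c(1, 4, 7, 10), 2] <- 1
  m <- marker_matrix(vals, pop = rep(paste0("P", 1:17), each = 3))
  rare <- find_rare_alleles(m)
  expect_true("m1" %in% rare$marker)
  expect_false("m2" %in% rare$marker)
})

test_that("lowering the frequency threshold never adds rare bands", {
  set.seed(77)
  m <- random_matrix(11, 4, 30, seed = 77, freqs = runif(30, 0, 0.25))
  counts <- sapply(c(0.20, 0.12, 0.08, 0.04),
                   function(th) nrow(find_rare_alleles(m, rguc_config(rare_freq_threshold = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-population rare counts satisfy the double-counting identity", {
  set.seed(13)
  m <- random_matrix(11, 4, 40, seed = 13, freqs = runif(40, 0, 0.2))
  rare <- find_rare_alleles(m)
  expect_gt(nrow(rare), 0)
  counts <- n_rare_per_population(rare, all_populations = populations(m))
  expect_equal(sum(counts), sum(rare$n_carriers))
  # brute-force recount per population
  for (p in populations(m)) {
    expect_equal(unname(counts[p]),
                 sum(sapply(rare$carrier_pops, function(cp) p %in% cp)))
  }
  # a population carrying none reports 0
  expect_equal(unname(n_rare_per_population(rare[0, ],
                                            all_populations = "P1")["P1"]), 0L)
  expect_error(n_rare_per_population(rare, "nope", populations(m)), "unknown")
})

test_that("Dice similarity and Nei-Li distance behave on the stated cases", {
  expect_equal(dice_similarity(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(dice_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(dice_similarity(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_equal(nei_li_distance(c(1, 1, 0), c(1, 0, 1)), 0.5)
  expect_error(dice_similarity(c(0, 0), c(0, 0)), "all-zero")
  expect_error(dice_similarity(c(0, 0), c(0, 0, 1)), "same marker set")
})
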