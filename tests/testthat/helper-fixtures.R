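# Small fixtures built in code, shared across test files.

# hand-written 4-individual x 3-marker matrix over two populations
tiny_matrix <- function() {
  marker_matrix(rbind(a1 = c(1, 0, 1),
                      a2 = c(1, 1, 0),
                      b1 = c(0, 0, 1),
                      b2 = c(0, 1, 1)),
                pop = c("A", "A", "B", "B"),
                marker_ids = c("m1", "m2", "m3"))
}

# unstructured random binary matrix (every individual iid Bernoulli(0.5)
# unless freqs given per marker)
random_matrix <- function(n_pops, n_ind, n_markers, seed, freqs = NULL) {
  set.seed(seed)
  if (is.null(freqs)) freqs <- rep(0.5, n_markers)
  pops <- rep(paste0("P", seq_len(n_pops)), each = n_ind)
  vals <- matrix(rbinom(n_pops * n_ind * n_markers, 1,
                        rep(freqs, each = n_pops * n_ind)),
                 nrow = n_pops * n_ind)
  marker_matrix(vals, pops,
                individual_ids = paste0("i", seq_along(pops)))
}

# independent brute-force AMOVA oracle: literal sums-of-squares formulas
# evaluated with explicit loops, no shared code with the implementation
amova_oracle <- function(values, pop, group = NULL) {
  n <- nrow(values)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(values[i, ] != values[j, ])
  ss_pairs <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) if (i < j) s <- s + d[i, j]
    s
  }
  ss_total <- ss_pairs(seq_len(n)) / n
  pops <- unique(pop)
  ss_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    ss_wp <- ss_wp + ss_pairs(idx) / length(idx)
  }
  n_p <- sapply(pops, function(p) sum(pop == p))
  if (is.null(group)) {
    ss_ap <- ss_total - ss_wp
    df_a <- length(pops) - 1; df_w <- n - length(pops)
    n0 <- (n - sum(n_p^2) / n) / df_a
    s2_w <- ss_wp / df_w
    s2_a <- (ss_ap / df_a - s2_w) / n0
    return(list(ss = c(ss_ap, ss_wp), sigma2 = c(s2_a, s2_w),
                fst = s2_a / (s2_a + s2_w)))
  }
  groups <- unique(group)
  ss_wg <- 0
  for (g in groups) {
    idx <- which(group == g)
    ss_wg <- ss_wg + ss_pairs(idx) / length(idx)
  }
  ss_ag <- ss_total - ss_wg
  ss_apwg <- ss_wg - ss_wp
  df <- c(length(groups) - 1, length(pops) - length(groups), n - length(pops))
  ms <- c(ss_ag, ss_apwg, ss_wp) / df
  grp_of_pop <- sapply(pops, function(p) group[which(pop == p)[1]])
  n_g <- sapply(groups, function(g) sum(group == g))
  A <- sum(sapply(groups, function(g)
    sum(n_p[grp_of_pop == g]^2) / n_g[which(groups == g)]))
  n1 <- (n - A) / df[2]
  n2 <- (A - sum(n_p^2) / n) / df[1]
  n3 <- (n - sum(n_g^2) / n) / df[1]
  s2_c <- ms[3]
  s2_b <- (ms[2] - s2_c) / n1
  s2_a <- (ms[1] - s2_c - n2 * s2_b) / n3
  list(ss = c(ss_ag, ss_apwg, ss_wp), sigma2 = c(s2_a, s2_b, s2_c))
}

# exact Stirling number of the second kind by inclusion-exclusion,
# independent of the package's log-space recurrence
stirling2_exact <- function(n, k) {
  sum((-1)^(0:k) * choose(k, 0:k) * (k - 0:k)^n) / factorial(k)
}
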