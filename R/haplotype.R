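#' Collapse aligned sequences into haplotypes with indel coding
#'
#' Sequences must be aligned (equal length). Maximal gap runs longer than
#' one base are treated as single evolutionary events: each distinct run
#' (same start and end across sequences) becomes one presence/absence
#' character, and the nucleotide columns it covers are excluded from
#' comparison for sequences carrying the run. Single-base gaps stay in
#' place as a fifth character state. Haplotypes are groups of sequences
#' identical over nucleotides, fifth-state gaps and indel events.
#'
#' @param fasta Path to an aligned FASTA file, or a named character vector
#'   of equal-length sequences.
#' @param pop_of_sequence Optional named character vector mapping sequence
#'   ids to population codes, for the per-population haplotype table.
#' @param ambiguity How to treat IUPAC ambiguity codes: `"distinct"`
#'   (default, kept as their own states) or `"error"`.
#' @return List of class `haplotype_sample`: `n` sequences, `k` distinct
#'   haplotypes, `counts` per haplotype, `haplotype_of_sequence`,
#'   `pop_table` (population x haplotype counts, or NULL), and
#'   `coded_length` (characters after indel coding).
#' @export
collapse_haplotypes <- function(fasta, pop_of_sequence = NULL,
                                ambiguity = c("distinct", "error")) {
  ambiguity <- match.arg(ambiguity)
  if (length(fasta) == 1L && file.exists(fasta)) {
    dna <- ape::read.FASTA(fasta)
    seqs <- toupper(vapply(as.character(dna), paste, character(1), collapse = ""))
  } else {
    seqs <- toupper(fasta)
  }
  if (length(seqs) < 1L) stop("no sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  chars <- do.call(rbind, strsplit(seqs, ""))
  rownames(chars) <- names(seqs)
  if (ambiguity == "error" && any(!chars %in% c("A", "C", "G", "T", "-", "N")))
    stop("ambiguity code(s) in alignment: ",
         paste(unique(chars[!chars %in% c("A", "C", "G", "T", "-", "N")]),
               collapse = ", "))
  # maximal gap runs per sequence; runs of length > 1 become indel events
  events <- list()
  covered <- matrix(FALSE, nrow(chars), ncol(chars), dimnames = dimnames(chars))
  has_event <- list()
  for (i in seq_len(nrow(chars))) {
    r <- rle(chars[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths > 1L)
    ev <- character(0)
    for (j in long) {
      key <- paste0(starts[j], "-", ends[j])
      events[[key]] <- c(starts[j], ends[j])
      covered[i, starts[j]:ends[j]] <- TRUE
      ev <- c(ev, key)
    }
    has_event[[i]] <- ev
  }
  # coded representation: nucleotide columns with event-covered cells masked,
  # plus one presence/absence character per distinct indel event
  coded <- chars
  coded[covered] <- "."
  ev_keys <- names(events)
  ev_mat <- matrix("0", nrow(chars), length(ev_keys),
                   dimnames = list(rownames(chars), ev_keys))
  for (i in seq_len(nrow(chars))) ev_mat[i, has_event[[i]]] <- "1"
  full <- cbind(coded, ev_mat)
  key <- apply(full, 1, paste, collapse = "")
  hap_id <- match(key, unique(key))
  hap_labels <- paste0("H", seq_len(max(hap_id)))
  hap_of_seq <- stats::setNames(hap_labels[hap_id], rownames(chars))
  counts <- table(factor(hap_of_seq, levels = hap_labels))
  pop_table <- NULL
  if (!is.null(pop_of_sequence)) {
    miss <- setdiff(names(seqs), names(pop_of_sequence))
    if (length(miss)) stop("sequence(s) without population: ",
                           paste(miss, collapse = ", "))
    pop_table <- table(population = pop_of_sequence[names(seqs)],
                       haplotype = factor(hap_of_seq, levels = hap_labels))
  }
  structure(list(n = length(seqs), k = length(hap_labels),
                 counts = as.integer(counts),
                 haplotype_of_sequence = hap_of_seq,
                 pop_table = pop_table,
                 coded_length = ncol(full),
                 n_indel_events = length(ev_keys)),
            class = "haplotype_sample")
}

#' Coded differences between two aligned sequences
#'
#' Counts positions where both sequences have a comparable (non-masked)
#' state and differ; each multi-base gap run present in exactly one
#' sequence counts as a single step, matching the indel coding of
#' [collapse_haplotypes()].
#'
#' @param a,b Aligned sequences (character scalars, equal length).
#' @return Integer step count.
#' @export
coded_differences <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("sequences are not aligned")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  runs <- function(ch) {
    r <- rle(ch == "-")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    long <- which(r$values & r$lengths > 1L)
    list(keys = if (length(long)) paste0(starts[long], "-", ends[long]) else character(0),
         covered = unlist(mapply(function(s, e) s:e, starts[long], ends[long],
                                 SIMPLIFY = FALSE)))
  }
  ra <- runs(toupper(ca)); rb <- runs(toupper(cb))
  cov <- union(ra$covered, rb$covered)
  keep <- setdiff(seq_along(ca), cov)
  nuc_diff <- sum(toupper(ca[keep]) != toupper(cb[keep]))
  ev_diff <- length(setdiff(ra$keys, rb$keys)) + length(setdiff(rb$keys, ra$keys))
  # positions covered in one sequence by a long run but plain bases in the
  # other are represented by the event difference, not counted per base
  nuc_diff + ev_diff
}

#' @export
print.haplotype_sample <- function(x, ...) {
  cat(sprintf("haplotype_sample: n = %d sequences, k = %d haplotypes (counts: %s)\n",
              x$n, x$k, paste(x$counts, collapse = ", ")))
  if (!is.null(x$n_indel_events))
    cat(sprintf("  %d indel event(s) coded as single steps; coded length %d\n",
                x$n_indel_events, x$coded_length))
  invisible(x)
}

#' Construct a haplotype sample from counts
#'
#' @param n Number of sequences sampled.
#' @param k Number of distinct haplotypes observed.
#' @param counts Optional per-haplotype counts (k positive integers summing
#'   to n).
#' @return A `haplotype_sample`.
#' @export
haplotype_sample <- function(n, k, counts = NULL) {
  stopifnot(n >= 1, k >= 1, k <= n)
  if (!is.null(counts)) {
    stopifnot(length(counts) == k, all(counts >= 1), sum(counts) == n)
  }
  structure(list(n = as.integer(n), k = as.integer(k),
                 counts = if (is.null(counts)) NULL else as.integer(counts)),
            class = "haplotype_sample")
}

#' Log Stirling numbers of the second kind
#'
#' Computes `log S(n, k)` via the recurrence
#' `S(n, k) = k S(n-1, k) + S(n-1, k-1)` carried in log space
#' (log-sum-exp), numerically stable well beyond n = 100.
#'
#' @param n Number of items (positive integer).
#' @param k Number of nonempty groups, `1 <= k <= n`; may be a vector.
#' @return `log S(n, k)`, same length as `k`.
#' @export
#' @examples
#' exp(stirling2_log(4, 2))  # 7
stirling2_log <- function(n, k) {
  stopifnot(n >= 1, all(k >= 1))
  if (any(k > n)) stop("k > n: S(n, k) undefined (zero) above the diagonal")
  row <- .stirling2_log_row(n)
  row[k]
}

.stirling2_log_row <- function(n) {
  prev <- c(0, rep(-Inf, n - 1))
  if (n == 1L) return(prev)
  for (m in 2:n) {
    shifted <- c(-Inf, prev[seq_len(n - 1)])       # S(m-1, k-1)
    scaled <- log(seq_len(n)) + prev               # k * S(m-1, k)
    hi <- pmax(shifted, scaled)
    prev <- ifelse(is.finite(hi),
                   hi + log(exp(shifted - hi) + exp(scaled - hi)),
                   -Inf)
  }
  prev
}

#' Haplotype-sampling completeness via the Stirling distribution
#'
#' Under the model of `theta` equally frequent haplotypes, the probability
#' of observing exactly `k` distinct haplotypes among `n` sampled sequences
#' is `P(k | n, theta) = theta!/(theta-k)! * S(n,k) / theta^n`, where
#' `S(n,k)` is the Stirling number of the second kind. With a uniform prior
#' on `theta` over `{k, ..., theta_max}` this yields a posterior over the
#' true haplotype number; its mass at `theta = k` is the probability that
#' sampling is complete.
#'
#' @param sample A [haplotype_sample()] (fields `n`, `k`).
#' @param theta_max Upper bound of the uniform prior (default 100). The
#'   result is checked for insensitivity to this cap: if extending the
#'   support to `3 k` (when `theta_max < 3 k`) would move the posterior
#'   mean, a warning is raised.
#' @return Object of class `dixon_completeness`: `posterior` (named vector
#'   over theta), `posterior_mean`, `p_complete`, `n`, `k`.
#' @export
#' @examples
#' d <- dixon_completeness(haplotype_sample(61, 7))
#' round(d$posterior_mean, 3)  # 7.002
dixon_completeness <- function(sample, theta_max = 100L) {
  n <- sample$n; k <- sample$k
  stopifnot(n >= k, k >= 1, theta_max >= k)
  if (n == 1L && k == 1L)
    warning("n = k = 1: the likelihood is flat; the data carry no information")
  lS <- stirling2_log(n, k)
  thetas <- k:theta_max
  loglik <- lgamma(thetas + 1) - lgamma(thetas - k + 1) + lS - n * log(thetas)
  post <- exp(loglik - max(loglik))
  post <- post / sum(post)
  pm <- sum(post * thetas)
  # tail check: the cap must not bite
  tail_mass <- sum(post[thetas > max(3 * k, k + 5)])
  if (is.na(tail_mass)) tail_mass <- post[length(post)]
  if (post[length(post)] > 1e-6)
    warning("posterior mass at theta_max is non-negligible; increase theta_max")
  skew_note <- NULL
  if (!is.null(sample$counts) && length(sample$counts) > 1L) {
    cv <- stats::sd(sample$counts) / mean(sample$counts)
    if (cv > 1)
      skew_note <- "observed haplotype counts are highly skewed; the equal-frequency assumption is doubtful"
  }
  structure(list(posterior = stats::setNames(post, thetas),
                 posterior_mean = pm,
                 p_complete = post[[1]],
                 n = n, k = k, theta_max = as.integer(theta_max),
                 skew_note = skew_note),
            class = "dixon_completeness")
}

#' @export
print.dixon_completeness <- function(x, ...) {
  cat(sprintf("Haplotype-sampling completeness (n = %d sequences, k = %d haplotypes)\n",
              x$n, x$k))
  cat(sprintf("  posterior mean of true haplotype number: %.3f\n", x$posterior_mean))
  cat(sprintf("  P(all haplotypes sampled) = %.4f  (uniform prior on %d..%d)\n",
              x$p_complete, x$k, x$theta_max))
  if (!is.null(x$skew_note)) cat("  note:", x$skew_note, "\n")
  invisible(x)
}
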