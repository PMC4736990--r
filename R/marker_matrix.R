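#' Construct a dominant-marker matrix
#'
#' The central data container: a binary (0/1) individuals x markers matrix of
#' band presence/absence, with each individual assigned to exactly one
#' population. Missing calls may be encoded as `NA`; they are excluded from
#' frequency denominators, never imputed.
#'
#' @param values Numeric/integer matrix, rows = individuals, columns =
#'   markers; every non-missing cell must be 0 or 1.
#' @param pop Character vector (length `nrow(values)`) of population codes.
#' @param individual_ids Optional unique individual ids; defaults to the
#'   rownames of `values` or `ind1..indN`.
#' @param marker_ids Optional unique marker ids; defaults to the colnames of
#'   `values` or `m1..mM`.
#'
#' @return An object of class `marker_matrix`: the integer matrix with
#'   dimnames set and attribute `pop` (named character vector).
#' @export
#' @examples
#' m <- marker_matrix(rbind(c(1, 0, 1), c(1, 1, 0), c(0, 0, 1), c(0, 1, 1)),
#'                    pop = c("A", "A", "B", "B"))
#' n_populations(m)
marker_matrix <- function(values, pop, individual_ids = NULL, marker_ids = NULL) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty marker matrix")
  if (is.null(individual_ids))
    individual_ids <- rownames(values) %||% paste0("ind", seq_len(nrow(values)))
  if (is.null(marker_ids))
    marker_ids <- colnames(values) %||% paste0("m", seq_len(ncol(values)))
  if (anyDuplicated(individual_ids))
    stop("duplicate individual id(s): ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id(s): ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  if (length(pop) != nrow(values))
    stop("pop must have one entry per individual")
  bad <- which(!is.na(values) & values != 0 & values != 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary cell at individual '%s', marker '%s': %s",
                 individual_ids[bad[1, 1]], marker_ids[bad[1, 2]],
                 format(values[bad[1, , drop = FALSE]])))
  storage.mode(values) <- "integer"
  dimnames(values) <- list(individual_ids, marker_ids)
  structure(values, pop = stats::setNames(as.character(pop), individual_ids),
            class = c("marker_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname marker_matrix
#' @param x A `marker_matrix`.
#' @export
populations <- function(x) unique(unname(attr(x, "pop")))

#' @rdname marker_matrix
#' @export
n_populations <- function(x) length(populations(x))

#' @rdname marker_matrix
#' @export
pop_of <- function(x) attr(x, "pop")

#' Identify markers polymorphic in the whole dataset
#'
#' A marker is polymorphic when both band states are observed among the
#' non-missing calls.
#'
#' @param x A `marker_matrix`.
#' @return Logical vector over markers.
#' @export
is_polymorphic <- function(x) {
  f <- colMeans(unclass(x), na.rm = TRUE)
  f > 0 & f < 1
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d individuals x %d markers, %d populations (%d polymorphic markers)\n",
              nrow(x), ncol(x), n_populations(x), sum(is_polymorphic(x))))
  invisible(x)
}

#' Read a dominant-marker matrix from delimited text
#'
#' Expected layout (`orientation = "individuals_rows"`, the default): a
#' header row of marker ids; each data row starts with the individual id and
#' its population code, followed by 0/1 calls. With
#' `orientation = "markers_rows"` the file is transposed (rows = markers,
#' first column marker id; the header row holds individual ids and a second
#' header row holds population codes).
#'
#' @param path Path to the file.
#' @param sep Field delimiter; default tab.
#' @param orientation File orientation, see Details.
#' @param missing_token Token denoting a missing call (becomes `NA`).
#' @param quiet Suppress the summary message.
#' @return A [marker_matrix()].
#' @export
read_marker_matrix <- function(path, sep = "\t",
                               orientation = c("individuals_rows", "markers_rows"),
                               missing_token = "NA", quiet = FALSE) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("marker matrix file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) < 2L || ncol(raw) < 3L) stop("empty or malformed marker matrix: ", path)
  if (orientation == "individuals_rows") {
    marker_ids <- as.character(raw[1, -(1:2)])
    body <- raw[-1, , drop = FALSE]
    individual_ids <- body[[1]]
    pop <- body[[2]]
    cells <- as.matrix(body[, -(1:2), drop = FALSE])
  } else {
    individual_ids <- as.character(raw[1, -1])
    pop <- as.character(raw[2, -1])
    body <- raw[-(1:2), , drop = FALSE]
    marker_ids <- body[[1]]
    cells <- t(as.matrix(body[, -1, drop = FALSE]))
  }
  cells[cells == missing_token] <- NA
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which((is.na(num) & !is.na(cells)) |
                 (!is.na(num) & num != 0 & num != 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-binary value '%s' at individual '%s', marker '%s' in %s",
                 cells[bad[1, , drop = FALSE]], individual_ids[bad[1, 1]],
                 marker_ids[bad[1, 2]], path))
  m <- marker_matrix(num, pop, individual_ids = individual_ids, marker_ids = marker_ids)
  if (!quiet)
    message(sprintf("read %d individuals, %d populations, %d markers (%d polymorphic) from %s",
                    nrow(m), n_populations(m), ncol(m), sum(is_polymorphic(m)), path))
  m
}

#' Write a marker matrix to delimited text
#'
#' Inverse of [read_marker_matrix()] with `orientation = "individuals_rows"`.
#'
#' @param x A `marker_matrix`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @param missing_token Token written for `NA` cells.
#' @export
write_marker_matrix <- function(x, path, sep = "\t", missing_token = "NA") {
  cells <- matrix(as.character(unclass(x)), nrow = nrow(x))
  cells[is.na(cells)] <- missing_token
  header <- c("individual", "population", colnames(x))
  body <- cbind(rownames(x), unname(pop_of(x)), cells)
  utils::write.table(rbind(header, body), path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a population-to-region partition
#'
#' Two-column delimited file (header `population`, `region`). Every
#' population must appear exactly once.
#'
#' @param path Path to the file.
#' @param sep Field delimiter.
#' @return Named character vector: region code per population.
#' @export
read_region_partition <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("region partition file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character")
  if (ncol(tab) < 2L) stop("region partition needs columns population, region")
  if (anyDuplicated(tab[[1]]))
    stop("population listed twice in region partition: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  stats::setNames(tab[[2]], tab[[1]])
}

#' Check a region partition against a marker matrix
#'
#' @param x A `marker_matrix`.
#' @param partition Named character vector from [read_region_partition()].
#' @return The partition, restricted and ordered to the matrix populations.
#' @export
validate_partition <- function(x, partition) {
  pops <- populations(x)
  missing <- setdiff(pops, names(partition))
  if (length(missing))
    stop("population(s) without a region: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(partition), pops)
  if (length(extra))
    warning("region partition lists population(s) absent from the matrix: ",
            paste(extra, collapse = ", "))
  partition[pops]
}

.attr_levels <- list(
  occupation_area = c("small", "large"),
  population_size = c("reduced", "high"),
  vulnerability = c("stable", "declining", "critical"),
  legal_status = c("protected", "unprotected"))

# synonyms used in field tables for the three-level vulnerability scale
.vuln_synonyms <- c(stable = "stable", acceptable = "stable",
                    declining = "declining", moderate = "declining",
                    critical = "critical",
                    "critically declining" = "critical",
                    "critically-declining" = "critical")

#' Read qualitative population attributes
#'
#' One row per population with columns `population`, `occupation_area`
#' (small/large), `population_size` (reduced/high), `vulnerability`
#' (stable|acceptable / declining|moderate / critical|critically-declining),
#' `legal_status` (protected/unprotected) and an optional `haplotypes`
#' column: comma-separated haplotype labels, endemic ones prefixed with `*`.
#'
#' @param path Path to the file.
#' @param sep Field delimiter.
#' @param matrix_populations Optional character vector of population codes in
#'   the marker matrix; attributes for populations outside it raise a warning
#'   but are kept.
#' @return A data.frame (one row per population, rownames = population) with
#'   factor attribute columns and a list-column `haplotypes` of character
#'   vectors plus `endemic_haplotypes`.
#' @export
read_population_attributes <- function(path, sep = "\t", matrix_populations = NULL) {
  if (!file.exists(path)) stop("attribute file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("population", "occupation_area", "population_size",
            "vulnerability", "legal_status")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("attribute table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$population))
    stop("population listed twice in attribute table: ",
         paste(unique(tab$population[duplicated(tab$population)]), collapse = ", "))
  vul <- .vuln_synonyms[tolower(trimws(tab$vulnerability))]
  if (anyNA(vul))
    stop("unknown vulnerability level '",
         tab$vulnerability[which(is.na(vul))[1]], "'; allowed: ",
         paste(names(.vuln_synonyms), collapse = ", "))
  out <- data.frame(population = tab$population, stringsAsFactors = FALSE)
  for (col in c("occupation_area", "population_size", "legal_status")) {
    lv <- .attr_levels[[col]]
    val <- tolower(trimws(tab[[col]]))
    if (!all(val %in% lv))
      stop("unknown ", col, " level '", setdiff(val, lv)[1],
           "'; allowed: ", paste(lv, collapse = ", "))
    out[[col]] <- factor(val, levels = lv)
  }
  out$vulnerability <- factor(unname(vul), levels = .attr_levels$vulnerability)
  hap_raw <- if ("haplotypes" %in% names(tab)) tab$haplotypes else rep("", nrow(tab))
  hap_raw[is.na(hap_raw)] <- ""
  toks <- lapply(strsplit(hap_raw, "[,;]"), function(v) trimws(v[nzchar(trimws(v))]))
  out$haplotypes <- lapply(toks, function(v) sub("^\\*", "", v))
  out$endemic_haplotypes <- lapply(toks, function(v) sub("^\\*", "", v[startsWith(v, "*")]))
  rownames(out) <- out$population
  if (!is.null(matrix_populations)) {
    extra <- setdiff(out$population, matrix_populations)
    if (length(extra))
      warning("attributes given for population(s) absent from the matrix: ",
              paste(extra, collapse = ", "))
    absent <- setdiff(matrix_populations, out$population)
    if (length(absent))
      warning("no attributes for population(s): ", paste(absent, collapse = ", "))
  }
  out
}
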