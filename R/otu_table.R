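#' Construct an OTU count table
#'
#' An `otu_table` is the package's container for amplicon count data: an
#' integer matrix of sequencing reads with samples in rows and OTUs
#' (operational taxonomic units) in columns, plus an optional taxonomy
#' string per OTU. Sample and OTU identifiers must be unique; counts must
#' be nonnegative integers.
#'
#' @param counts Numeric matrix of nonnegative integer read counts, samples
#'   in rows and OTUs in columns, with row and column names. A data frame of
#'   counts (first column sample ids) is also accepted.
#' @param taxonomy Optional named character vector (or two-column data
#'   frame: otu id, taxonomy string) giving a ranked taxonomy string per OTU.
#' @return An object of class `otu_table`: the validated integer count
#'   matrix with a `taxonomy` attribute.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 7L), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2"))
#' )
#' tab <- otu_table(m)
#' richness(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (is.data.frame(counts)) {
    ids <- as.character(counts[[1L]])
    counts <- as.matrix(counts[, -1L, drop = FALSE])
    rownames(counts) <- ids
  }
  if (!is.matrix(counts)) abort("`counts` must be a matrix or data frame")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs sample ids as row names and OTU ids as column names")
  }
  if (anyDuplicated(rownames(counts))) {
    abort(sprintf(
      "duplicated sample id(s): %s",
      paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(counts))) {
    abort(sprintf(
      "duplicated OTU id(s): %s",
      paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", ")
    ))
  }
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "count for sample '%s', OTU '%s' is not a nonnegative integer (value: %s)",
      rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
      format(counts[bad[1L, , drop = FALSE]])
    ))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.data.frame(taxonomy)) {
      taxonomy <- setNames(as.character(taxonomy[[2L]]), as.character(taxonomy[[1L]]))
    }
    taxonomy <- taxonomy[intersect(names(taxonomy), colnames(counts))]
  }
  structure(counts, taxonomy = taxonomy, class = c("otu_table", "matrix", "array"))
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf(
    "<otu_table> %d samples x %d OTUs, %s reads total\n",
    nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ",")
  ))
  print(head(unclass(x)[, seq_len(min(ncol(x), 8L)), drop = FALSE], 6L))
  invisible(x)
}

#' @describeIn otu_table Long-format tibble (sample_id, otu_id, reads) view.
#' @param x An `otu_table`.
#' @param ... Unused.
#' @method as_tibble otu_table
#' @export
as_tibble.otu_table <- function(x, ...) {
  tibble(
    sample_id = rep(rownames(x), times = ncol(x)),
    otu_id = rep(colnames(x), each = nrow(x)),
    reads = as.integer(x)
  )
}

otu_counts <- function(table) {
  if (!inherits(table, "otu_table")) table <- otu_table(table)
  m <- unclass(table)
  attr(m, "taxonomy") <- NULL
  m
}

#' Read and write OTU count tables
#'
#' Tab-separated count tables with a header row and identifier first column.
#' Both orientations are supported: samples in rows (default) or OTUs in
#' rows (BIOM-style TSV; a leading `#OTU ID` header cell is recognised and
#' switches the orientation automatically). An optional taxonomy sidecar is
#' a two-column TSV `otu_id<TAB>taxonomy`.
#'
#' @param path Path to the tab-separated count table.
#' @param taxonomy_path Optional path to the taxonomy sidecar.
#' @param orientation `"samples_in_rows"` or `"otus_in_rows"`.
#' @return `read_otu_table()` returns an [otu_table]; `write_otu_table()`
#'   returns `path` invisibly.
#' @export
read_otu_table <- function(path, taxonomy_path = NULL,
                           orientation = c("samples_in_rows", "otus_in_rows")) {
  orientation <- match.arg(orientation)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#OTU ID")) orientation <- "otus_in_rows"
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- ids
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))), arr.ind = TRUE)
    cellr <- if (nrow(bad)) rownames(m)[bad[1, 1]] else ids[1]
    cellc <- if (nrow(bad)) colnames(m)[bad[1, 2]] else colnames(m)[1]
    abort(sprintf("non-numeric count at row '%s', column '%s' in %s", cellr, cellc, path))
  }
  if (orientation == "otus_in_rows") m <- t(m)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- read.delim(taxonomy_path, header = FALSE, stringsAsFactors = FALSE)
    taxonomy <- setNames(as.character(tx[[2L]]), as.character(tx[[1L]]))
  }
  otu_table(m, taxonomy = taxonomy)
}

#' @rdname read_otu_table
#' @param table An [otu_table] to write.
#' @export
write_otu_table <- function(table, path,
                            orientation = c("samples_in_rows", "otus_in_rows")) {
  orientation <- match.arg(orientation)
  m <- otu_counts(table)
  if (orientation == "otus_in_rows") {
    df <- data.frame(`#OTU ID` = colnames(m), t(m), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Zero out low-count cells and drop empty OTUs
#'
#' Sequencing and PCR artefacts show up as sporadic low counts; following
#' common amplicon practice, any cell with fewer than `min_reads` reads is
#' set to zero sample-by-sample, and OTUs whose counts become zero in every
#' sample are removed from the table.
#'
#' @param table An [otu_table].
#' @param min_reads Minimum reads for a cell to be kept (default 10).
#' @return A filtered [otu_table].
#' @export
filter_low_count <- function(table, min_reads = 10) {
  check_scalar_int(min_reads, "min_reads", min = 0)
  m <- otu_counts(table)
  m[m > 0L & m < min_reads] <- 0L
  keep <- colSums(m) > 0L
  otu_table(m[, keep, drop = FALSE], taxonomy = attr(table, "taxonomy"))
}

#' Rarefy samples to a common sequencing depth
#'
#' Each sample's reads are subsampled uniformly without replacement
#' (multivariate hypergeometric) down to `depth` reads, removing
#' depth-driven differences in observed richness before comparison.
#'
#' @param table An [otu_table]; every sample total must be at least `depth`.
#' @param depth Target reads per sample (>= 1).
#' @param seed Integer seed; the subsample is reproducible under it.
#' @return A rarefied [otu_table] whose sample totals all equal `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  check_scalar_int(depth, "depth", min = 1)
  check_scalar_int(seed, "seed")
  m <- otu_counts(table)
  tot <- rowSums(m)
  short <- which(tot < depth)
  if (length(short) > 0L) {
    abort(sprintf(
      "sample '%s' has only %d reads, fewer than depth %d",
      rownames(m)[short[1L]], tot[short[1L]], as.integer(depth)
    ))
  }
  set.seed(seed)
  out <- suppressWarnings(vegan::rrarefy(m, depth))
  storage.mode(out) <- "integer"
  otu_table(out, taxonomy = attr(table, "taxonomy"))
}

#' Per-sample OTU richness
#'
#' @param table An [otu_table].
#' @return A tibble with columns `sample_id` and `richness` (number of OTUs
#'   with at least one read in the sample).
#' @export
richness <- function(table) {
  m <- otu_counts(table)
  tibble(sample_id = rownames(m), richness = as.integer(rowSums(m > 0L)))
}

#' Partition OTUs between two compartments
#'
#' Classifies every OTU id occurring in either table (nonzero in at least
#' one sample) as specific to the first table, specific to the second, or
#' shared, and reports counts and percentages of the pooled total. With an
#' epiphyte table first and an endophyte table second this reproduces the
#' epiphyte-specific / endophyte-specific / shared split used to summarise
#' paired leaf-surface and leaf-interior communities.
#'
#' @param epi,endo Two [otu_table]s (or anything [otu_table] accepts).
#' @return A one-row tibble of class `partition_summary` with counts
#'   `n_epiphyte_specific`, `n_endophyte_specific`, `n_shared`, `n_total`
#'   and matching percentages rounded to two decimals.
#' @examples
#' partition_counts(596, 600, 195)
#' @export
partition_otus <- function(epi, endo) {
  pres <- function(tab) {
    m <- otu_counts(tab)
    colnames(m)[colSums(m) > 0L]
  }
  a <- pres(epi)
  b <- pres(endo)
  if (length(a) == 0L && length(b) == 0L) abort("no OTUs present in either table")
  shared <- intersect(a, b)
  partition_counts(length(setdiff(a, b)), length(setdiff(b, a)), length(shared))
}

#' @rdname partition_otus
#' @param n_epiphyte_specific,n_endophyte_specific,n_shared Nonnegative
#'   integer counts, e.g. taken from a published OTU summary.
#' @export
partition_counts <- function(n_epiphyte_specific, n_endophyte_specific, n_shared) {
  check_scalar_int(n_epiphyte_specific, "n_epiphyte_specific", min = 0)
  check_scalar_int(n_endophyte_specific, "n_endophyte_specific", min = 0)
  check_scalar_int(n_shared, "n_shared", min = 0)
  n_total <- n_epiphyte_specific + n_endophyte_specific + n_shared
  if (n_total == 0) abort("empty union: all partition counts are zero")
  out <- tibble(
    n_epiphyte_specific = as.integer(n_epiphyte_specific),
    n_endophyte_specific = as.integer(n_endophyte_specific),
    n_shared = as.integer(n_shared),
    n_total = as.integer(n_total),
    pct_epiphyte_specific = round(100 * n_epiphyte_specific / n_total, 2),
    pct_endophyte_specific = round(100 * n_endophyte_specific / n_total, 2),
    pct_shared = round(100 * n_shared / n_total, 2)
  )
  class(out) <- c("partition_summary", class(out))
  out
}
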