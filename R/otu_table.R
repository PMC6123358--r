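#' OTU tables as tibbles
#'
#' Throughout the package an OTU table is a tibble whose first column,
#' `otu_id`, holds unique OTU identifiers and whose remaining columns are
#' samples holding nonnegative counts (or, after [relative_abundance()],
#' per-sample proportions). This mirrors the on-disk TSV layout: OTUs as
#' rows, samples as columns. Count-only operations verify that every cell is
#' integral, so relative tables are rejected where counts are required.
#'
#' @param tbl An OTU table tibble.
#' @param counts If `TRUE`, additionally require integral cells.
#' @return `tbl`, invisibly, after validation.
#' @keywords internal
validate_otu_table <- function(tbl, counts = FALSE) {
  if (!is.data.frame(tbl) || names(tbl)[1] != "otu_id") {
    abort("an OTU table must be a data frame whose first column is 'otu_id'")
  }
  if (anyDuplicated(tbl$otu_id)) {
    abort("duplicate otu_id values in OTU table")
  }
  if (anyDuplicated(names(tbl))) {
    abort("duplicate sample ids in OTU table")
  }
  vals <- sample_columns(tbl)
  for (s in vals) {
    col <- tbl[[s]]
    if (!is.numeric(col)) abort(sprintf("sample column '%s' is not numeric", s))
    if (anyNA(col) || any(col < 0)) {
      bad <- which(is.na(col) | col < 0)[1]
      abort(sprintf("negative or missing count at otu '%s', sample '%s'",
                    tbl$otu_id[bad], s))
    }
    if (counts && any(col != trunc(col))) {
      bad <- which(col != trunc(col))[1]
      abort(sprintf("non-integer count at otu '%s', sample '%s' (got %s); this operation requires a count table",
                    tbl$otu_id[bad], s, format(col[bad])))
    }
  }
  invisible(tbl)
}

sample_columns <- function(tbl) setdiff(names(tbl), "otu_id")

#' Convert between tibble and matrix OTU-table forms
#'
#' `otu_matrix()` returns a samples-by-OTUs numeric matrix (rows are samples);
#' `as_otu_table()` converts such a matrix back to the tibble form.
#'
#' @param tbl An OTU table tibble (see [validate_otu_table()]).
#' @param m A samples-by-OTUs numeric matrix with dimnames.
#' @return A matrix, or an OTU table tibble.
#' @export
otu_matrix <- function(tbl) {
  validate_otu_table(tbl)
  m <- t(as.matrix(tbl[, sample_columns(tbl), drop = FALSE]))
  colnames(m) <- tbl$otu_id
  m
}

#' @rdname otu_matrix
#' @export
as_otu_table <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  out <- as_tibble(t(m), .name_repair = "minimal")
  tibble(otu_id = colnames(m)) |> dplyr::bind_cols(out)
}

#' Read and write OTU tables
#'
#' TSV with header `otu_id` followed by sample ids; cells are tab-separated
#' nonnegative integers, UTF-8, LF newlines. `read_otu_table()` and
#' [write_otu_table()] are mutual inverses on valid tables.
#'
#' @param path Path to a TSV file.
#' @return An OTU table tibble.
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("OTU table file not found: %s", path))
  tbl <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(tbl) < 1 || names(tbl)[1] != "otu_id") {
    abort(sprintf("%s: first column header must be 'otu_id'", path))
  }
  tbl$otu_id <- as.character(tbl$otu_id)
  tbl <- as_tibble(tbl)
  for (s in sample_columns(tbl)) {
    col <- tbl[[s]]
    if (is.character(col)) col <- suppressWarnings(as.numeric(col))
    if (is.logical(col) && nrow(tbl) == 0) col <- numeric(0)
    bad <- which(is.na(col) | col < 0 | col != trunc(col))
    if (length(bad)) {
      abort(sprintf("%s: invalid count at row '%s', column '%s'",
                    path, tbl$otu_id[bad[1]], s))
    }
    tbl[[s]] <- col
  }
  validate_otu_table(tbl, counts = TRUE)
  tbl
}

#' @param tbl An OTU table tibble.
#' @rdname read_otu_table
#' @export
write_otu_table <- function(tbl, path) {
  validate_otu_table(tbl)
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove low-total OTUs (singleton/doubleton filter)
#'
#' Drops every OTU whose count summed over all samples is at most
#' `max_total`. The default removes dataset-wide singletons and doubletons,
#' the usual guard against chimeric or artifactual amplicon OTUs. Totals are
#' pooled over the whole dataset, not per sample, and the sample set is
#' unchanged. Idempotent.
#'
#' @param tbl An OTU count table tibble.
#' @param max_total Drop OTUs with total count <= this (default 2).
#' @return The filtered OTU table.
#' @export
filter_low_count_otus <- function(tbl, max_total = 2) {
  stopifnot(max_total >= 0)
  validate_otu_table(tbl, counts = TRUE)
  totals <- rowSums(tbl[, sample_columns(tbl), drop = FALSE])
  tbl[totals > max_total, , drop = FALSE]
}

#' Samples too shallow for a rarefaction depth
#'
#' Lists samples whose total count falls below `depth`, so a caller can drop
#' them explicitly before [rarefy()] (which errors rather than silently
#' dropping samples).
#'
#' @inheritParams filter_low_count_otus
#' @param depth Target per-sample depth.
#' @return A tibble with columns `sample_id` and `total`.
#' @export
undersized_samples <- function(tbl, depth) {
  validate_otu_table(tbl, counts = TRUE)
  totals <- colSums(tbl[, sample_columns(tbl), drop = FALSE])
  tibble(sample_id = names(totals), total = unname(totals)) |>
    filter(.data$total < depth)
}

#' Rarefy (subsample without replacement) to a common depth
#'
#' Each sample is subsampled to exactly `depth` reads without replacement
#' (multivariate hypergeometric), equalizing sequencing depth before
#' richness comparison or ordination. Deterministic given `seed`.
#'
#' @inheritParams undersized_samples
#' @param seed Integer seed controlling the subsampling.
#' @return An OTU table tibble; every sample column sums to `depth`.
#' @export
rarefy <- function(tbl, depth, seed) {
  stopifnot(depth >= 1)
  validate_otu_table(tbl, counts = TRUE)
  short <- undersized_samples(tbl, depth)
  if (nrow(short) > 0) {
    abort(sprintf(
      "cannot rarefy to depth %d: sample(s) with fewer reads: %s (use undersized_samples() and drop them first)",
      depth, paste(short$sample_id, collapse = ", ")))
  }
  out <- tbl
  with_seed(seed, {
    for (s in sample_columns(tbl)) {
      counts <- tbl[[s]]
      total <- sum(counts)
      if (total == depth) next
      reads <- rep.int(seq_along(counts), counts)
      keep <- sample(reads, depth, replace = FALSE)
      out[[s]] <- as.numeric(tabulate(keep, nbins = length(counts)))
    }
  })
  out
}

#' Per-sample relative abundance
#'
#' Divides each sample column by its total; all-zero samples stay all-zero.
#' The result is a relative table (cells in \[0,1\], non-zero columns summing
#' to 1) and is rejected by operations requiring integer counts.
#'
#' @inheritParams filter_low_count_otus
#' @return An OTU table tibble of proportions.
#' @export
relative_abundance <- function(tbl) {
  validate_otu_table(tbl)
  out <- tbl
  for (s in sample_columns(tbl)) {
    total <- sum(tbl[[s]])
    if (total > 0) out[[s]] <- tbl[[s]] / total
  }
  out
}

#' Observed richness per sample
#'
#' Number of OTUs with count >= 1 in each sample.
#'
#' @inheritParams filter_low_count_otus
#' @return A tibble with columns `sample_id` and `richness`.
#' @export
observed_richness <- function(tbl) {
  validate_otu_table(tbl)
  vals <- sample_columns(tbl)
  tibble(
    sample_id = vals,
    richness = unname(vapply(vals, function(s) sum(tbl[[s]] >= 1), integer(1)))
  )
}
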