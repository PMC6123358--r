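#' Sample metadata
#'
#' Per-sample design labels for a culturomics experiment: `sample_id`,
#' `source` (one of `"rumen"`, `"plate"`, `"cohort"`), `medium` (`"defined"`,
#' `"undefined"`, or `"none"` for unplated samples), `dilution_exponent`
#' (integer d meaning a 10^-d decimal dilution; 0 is the original sample) and
#' `replicate`. Rumen and cohort samples carry `medium = "none"`; plate
#' samples carry a real medium and `dilution_exponent >= 1`.
#'
#' @param meta A metadata tibble.
#' @return `meta`, invisibly, after validation.
#' @keywords internal
validate_metadata <- function(meta) {
  need <- c("sample_id", "source", "medium", "dilution_exponent", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("metadata missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if (!all(meta$source %in% c("rumen", "plate", "cohort"))) {
    abort("metadata source must be one of rumen, plate, cohort")
  }
  if (!all(meta$medium %in% c("defined", "undefined", "none"))) {
    abort("metadata medium must be one of defined, undefined, none")
  }
  if (any(meta$dilution_exponent < 0 | meta$dilution_exponent > 6 |
            meta$dilution_exponent != trunc(meta$dilution_exponent))) {
    abort("dilution_exponent must be an integer in [0, 6]")
  }
  bad <- meta$source %in% c("rumen", "cohort") & meta$medium != "none"
  if (any(bad)) {
    abort(sprintf("rumen/cohort samples must have medium 'none': %s",
                  paste(meta$sample_id[bad], collapse = ", ")))
  }
  bad <- meta$source == "plate" &
    (!(meta$medium %in% c("defined", "undefined")) | meta$dilution_exponent < 1)
  if (any(bad)) {
    abort(sprintf("plate samples need a real medium and dilution_exponent >= 1: %s",
                  paste(meta$sample_id[bad], collapse = ", ")))
  }
  invisible(meta)
}

#' Read and write sample metadata
#'
#' TSV with columns `sample_id`, `source`, `medium`, `dilution_exponent`,
#' `replicate`.
#'
#' @param path Path to a TSV file.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  meta <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE) |>
    as_tibble()
  meta$sample_id <- as.character(meta$sample_id)
  validate_metadata(meta)
  meta
}

#' @param meta A metadata tibble.
#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  validate_metadata(meta)
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with columns `otu_id` and `lineage`, the latter a semicolon-delimited
#' ranked lineage (domain;phylum;class;order;family;genus\[;species\]).
#' Unassigned ranks may be left as empty strings.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `otu_id` and `lineage`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(sprintf("taxonomy file not found: %s", path))
  tax <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE) |>
    as_tibble()
  if (!all(c("otu_id", "lineage") %in% names(tax))) {
    abort("taxonomy must have columns otu_id and lineage")
  }
  if (anyDuplicated(tax$otu_id)) abort("duplicate otu_id in taxonomy")
  tax
}

#' Extract one rank from semicolon-delimited lineages
#'
#' @param lineage Character vector of lineages.
#' @param rank Rank position, 1 = domain ... 5 = family, 6 = genus.
#' @return Character vector; `NA` where the rank is absent or empty.
#' @export
lineage_rank <- function(lineage, rank = 5) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- vapply(parts, function(p) {
    if (length(p) >= rank && nzchar(trimws(p[rank]))) trimws(p[rank]) else NA_character_
  }, character(1))
  out
}
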