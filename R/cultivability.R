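#' OTUs detected in a set of samples
#'
#' Presence is a count of at least `min_count` in at least one of the named
#' samples. All set-theoretic accounting in the package is built on this
#' definition, applied to the non-rarefied, low-count-filtered table.
#'
#' @param tbl An OTU table tibble.
#' @param sample_ids Character vector of sample ids (must exist in `tbl`).
#' @param min_count Minimum count that counts as detection (default 1).
#' @return Character vector of detected OTU ids.
#' @export
detected_otus <- function(tbl, sample_ids, min_count = 1) {
  validate_otu_table(tbl)
  unknown <- setdiff(sample_ids, sample_columns(tbl))
  if (length(unknown)) {
    abort(sprintf("unknown sample id(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!length(sample_ids)) return(character(0))
  sub <- as.matrix(tbl[, sample_ids, drop = FALSE])
  tbl$otu_id[rowSums(sub >= min_count) > 0]
}

#' Partition OTUs across rumen and the two plated media
#'
#' The three detection groups are the rumen series (original sample plus its
#' dilutions), the defined-medium plates and the undefined-medium plates.
#' Their 2^3 membership patterns give seven disjoint regions whose union is
#' every detected OTU; derived unions give the cultivable (shared) set and
#' the plate-only set. Computed on the non-rarefied table, normally after
#' [filter_low_count_otus()].
#'
#' @param tbl An OTU table tibble covering all samples in `meta`.
#' @param meta Sample metadata (see [read_metadata()]); cohort samples are
#'   ignored here.
#' @param min_count Detection threshold passed to [detected_otus()].
#' @return A list of class `venn_partition` with the seven disjoint regions
#'   (`rumen_only`, `rumen_defined_only`, `rumen_undefined_only`,
#'   `rumen_both_media`, `both_media_only`, `defined_only`,
#'   `undefined_only`), the group detection sets (`rumen_all`, `defined_all`,
#'   `undefined_all`, `plates_all`) and the derived `shared` and `plate_only`
#'   sets.
#' @export
partition_otus <- function(tbl, meta, min_count = 1) {
  validate_metadata(meta)
  groups <- list(
    rumen = meta$sample_id[meta$source == "rumen"],
    defined = meta$sample_id[meta$source == "plate" & meta$medium == "defined"],
    undefined = meta$sample_id[meta$source == "plate" & meta$medium == "undefined"])
  empty <- names(groups)[lengths(groups) == 0]
  if (length(empty)) {
    abort(sprintf("no samples in group(s): %s", paste(empty, collapse = ", ")))
  }
  R <- detected_otus(tbl, groups$rumen, min_count)
  D <- detected_otus(tbl, groups$defined, min_count)
  U <- detected_otus(tbl, groups$undefined, min_count)
  plates <- union(D, U)
  structure(list(
    rumen_only = setdiff(R, plates),
    rumen_defined_only = setdiff(intersect(R, D), U),
    rumen_undefined_only = setdiff(intersect(R, U), D),
    rumen_both_media = intersect(R, intersect(D, U)),
    both_media_only = setdiff(intersect(D, U), R),
    defined_only = setdiff(D, union(R, U)),
    undefined_only = setdiff(U, union(R, D)),
    rumen_all = R, defined_all = D, undefined_all = U,
    plates_all = plates,
    shared = intersect(R, plates),
    plate_only = setdiff(plates, R)
  ), class = "venn_partition")
}

venn_regions <- c("rumen_only", "rumen_defined_only", "rumen_undefined_only",
                  "rumen_both_media", "both_media_only", "defined_only",
                  "undefined_only")

#' Cultivable fraction of the rumen community
#'
#' Fraction of OTUs detected in the rumen series that were also detected on
#' any plate: |shared| / |rumen|. The headline cultivability estimate of a
#' plating experiment; reported as a truncated whole percent by the report
#' layer (686 shared of 2881 detected reports as 23).
#'
#' @param p A [partition_otus()] result.
#' @return A fraction in \[0, 1\].
#' @export
cultivable_fraction <- function(p) {
  stopifnot(inherits(p, "venn_partition"))
  if (!length(p$rumen_all)) abort("no OTUs detected in the rumen group")
  length(p$shared) / length(p$rumen_all)
}

#' Richness gained by adding a second medium
#'
#' The proportional increase in cultured OTU richness from plating on the
#' `added` medium in addition to the other one: OTUs unique to the added
#' medium divided by the other medium's total. The denominator convention is
#' ambiguous in practice, so reports give the gain in both directions and
#' label the larger one "up to".
#'
#' @param p A [partition_otus()] result.
#' @param added Which medium is treated as the addition (`"defined"` or
#'   `"undefined"`).
#' @return A nonnegative proportion.
#' @export
medium_gain <- function(p, added = c("defined", "undefined")) {
  stopifnot(inherits(p, "venn_partition"))
  added <- match.arg(added)
  base <- if (added == "defined") p$undefined_all else p$defined_all
  add <- if (added == "defined") p$defined_all else p$undefined_all
  if (!length(base)) abort("the baseline medium detected no OTUs")
  length(setdiff(add, base)) / length(base)
}

#' Proportion of each rumen dilution's OTUs recovered on its matching plates
#'
#' For each plated dilution d and medium m: the OTUs detected on the (d, m)
#' plates that were also detected in the rumen sample diluted 10^-d, as a
#' proportion of that dilution's detected OTUs.
#'
#' @inheritParams partition_otus
#' @return A tibble with columns `dilution_exponent`, `medium`,
#'   `n_rumen_detected`, `n_shared`, `proportion`.
#' @export
shared_per_dilution <- function(tbl, meta, min_count = 1) {
  validate_metadata(meta)
  plate_meta <- meta |> filter(.data$source == "plate")
  if (!nrow(plate_meta)) abort("no plate samples in metadata")
  combos <- plate_meta |>
    dplyr::distinct(.data$dilution_exponent, .data$medium) |>
    arrange(.data$dilution_exponent, .data$medium)
  purrr::pmap_dfr(combos, function(dilution_exponent, medium) {
    d <- dilution_exponent
    rumen_id <- meta$sample_id[meta$source == "rumen" &
                                 meta$dilution_exponent == d]
    if (!length(rumen_id)) {
      abort(sprintf("no rumen sample at dilution exponent %d", d))
    }
    rumen_set <- detected_otus(tbl, rumen_id, min_count)
    plate_ids <- plate_meta$sample_id[plate_meta$dilution_exponent == d &
                                        plate_meta$medium == medium]
    plate_set <- detected_otus(tbl, plate_ids, min_count)
    n_shared <- length(intersect(rumen_set, plate_set))
    tibble(dilution_exponent = d, medium = medium,
           n_rumen_detected = length(rumen_set), n_shared = n_shared,
           proportion = if (length(rumen_set)) n_shared / length(rumen_set)
                        else NA_real_)
  })
}

#' Plate-only ("rare biosphere") OTUs
#'
#' OTUs that grew on the plates but were never detected in the original rumen
#' sample or any of its dilutions — the operational definition of cultured
#' members of the rare biosphere. Always satisfies
#' |rare| + |shared| = |plates|.
#'
#' @param p A [partition_otus()] result.
#' @return Character vector of OTU ids.
#' @export
rare_biosphere <- function(p) {
  stopifnot(inherits(p, "venn_partition"))
  p$plate_only
}

#' Survey a set of OTUs across a cohort of communities
#'
#' For each OTU, in how many cohort samples it is detected (count >= 1) and
#' the corresponding detection frequency. OTUs absent from the cohort table's
#' OTU list get frequency 0. Used to ask whether plate-only OTUs are
#' detectable in any of a larger panel of microbiomes.
#'
#' @param otus Character vector of OTU ids to survey.
#' @param cohort_tbl An OTU table tibble of cohort samples only.
#' @return A tibble with columns `otu_id`, `n_detected`, `frequency`.
#' @export
cohort_survey <- function(otus, cohort_tbl) {
  validate_otu_table(cohort_tbl)
  n_samples <- length(sample_columns(cohort_tbl))
  if (n_samples == 0) abort("cohort table has no samples")
  m <- as.matrix(cohort_tbl[, sample_columns(cohort_tbl), drop = FALSE])
  hits <- rowSums(m >= 1)
  names(hits) <- cohort_tbl$otu_id
  n_det <- ifelse(otus %in% names(hits), hits[otus], 0)
  tibble(otu_id = otus,
         n_detected = as.integer(unname(n_det)),
         frequency = as.numeric(n_det) / n_samples)
}

#' Cultured-richness gain of the undefined medium
#'
#' Compares plate richness between media within each dilution (mean observed
#' richness of undefined-medium plates over that of defined-medium plates at
#' the same dilution) and returns the geometric mean of those per-dilution
#' ratios over dilutions where both media grew anything. Pairing within
#' dilution controls the orders-of-magnitude richness range a
#' dilution-to-extinction series spans; a value near 2 reproduces the
#' "rumen fluid roughly doubles cultured richness" effect.
#'
#' @inheritParams partition_otus
#' @return A single positive number (NA if no dilution has growth on both
#'   media).
#' @export
plate_richness_ratio <- function(tbl, meta) {
  validate_metadata(meta)
  rich <- observed_richness(tbl) |> left_join(meta, by = "sample_id")
  pl <- rich |> filter(.data$source == "plate")
  agg <- pl |>
    group_by(.data$dilution_exponent, .data$medium) |>
    summarise(richness = mean(.data$richness), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "medium", values_from = "richness")
  if (!all(c("defined", "undefined") %in% names(agg))) {
    abort("both media are needed to compare richness")
  }
  ok <- !is.na(agg$defined) & !is.na(agg$undefined) &
    agg$defined > 0 & agg$undefined > 0
  if (!any(ok)) return(NA_real_)
  exp(mean(log(agg$undefined[ok] / agg$defined[ok])))
}
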