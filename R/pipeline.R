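#' Run the full culturomics analysis pipeline
#'
#' End-to-end orchestration: load (or simulate) the OTU table and metadata,
#' remove dataset-wide singletons/doubletons, partition OTUs across rumen and
#' media, compute the cultivable fraction, medium gains and per-dilution
#' shared proportions, identify the rare biosphere and survey it across the
#' cohort, run the phylogenetic-cohesion tests when distances are available,
#' rarefy for the ordination/richness branch (PCoA, two-way PERMANOVA on the
#' plate samples, paired richness tests), and compute the percentile-binned
#' abundance-cultivability correlation. Deterministic given (config, seed).
#'
#' Exactly one of `sim_params` or (`table`, `metadata`) must be supplied;
#' file paths are accepted in place of tibbles.
#'
#' @param table OTU table tibble or TSV path.
#' @param metadata Metadata tibble or TSV path.
#' @param taxonomy Optional taxonomy tibble or TSV path (enables per-family
#'   cohesion tests).
#' @param tree Optional `phylo` object or Newick path for patristic
#'   distances.
#' @param alignment Optional aligned-FASTA path for p-distances (used when no
#'   tree is given).
#' @param sim_params Optional [simulation_params()]; simulates the experiment
#'   instead of reading files (the simulated tree supplies distances).
#' @param rarefaction_depth Depth for the ordination/richness branch; default
#'   is the minimum total among rumen and plate samples.
#' @param max_total Low-count filter threshold (default 2: drop singletons
#'   and doubletons).
#' @param phylo_B,permanova_B Permutation counts (defaults 100 and 1000).
#' @param n_bins,r_threshold,alpha Percentile-correlation settings; rumen
#'   samples with fewer detected OTUs than `n_bins` are skipped and listed.
#' @param seed Master seed; each stage uses a named substream.
#' @param out_dir Optional output directory; writes `results.json`, TSV
#'   tables and a run log. Partial outputs are removed on failure.
#' @return A list of class `culturomics_results`.
#' @export
run_pipeline <- function(table = NULL, metadata = NULL, taxonomy = NULL,
                         tree = NULL, alignment = NULL, sim_params = NULL,
                         rarefaction_depth = NULL, max_total = 2,
                         phylo_B = 100, permanova_B = 1000, n_bins = 100,
                         r_threshold = 0.3, alpha = 0.05, seed = 1,
                         out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  if (is.null(sim_params) == is.null(table)) {
    abort("supply exactly one of sim_params or (table, metadata)")
  }

  truth <- NULL
  flagged <- character(0)
  stage("load", {
    if (!is.null(sim_params)) {
      bundle <- simulate_experiment(sim_params)
      table <- bundle$table
      metadata <- bundle$metadata
      truth <- bundle$truth
      flagged <- bundle$flagged
      if (is.null(tree)) tree <- bundle$truth$tree
    } else {
      if (is.character(table)) table <- read_otu_table(table)
      if (is.null(metadata)) abort("metadata is required with a table")
      if (is.character(metadata)) metadata <- read_metadata(metadata)
      validate_otu_table(table)
      validate_metadata(metadata)
    }
    if (!is.null(taxonomy) && is.character(taxonomy)) {
      taxonomy <- read_taxonomy(taxonomy)
    }
    missing_meta <- setdiff(sample_columns(table), metadata$sample_id)
    if (length(missing_meta)) {
      abort(sprintf("samples without metadata: %s",
                    paste(utils::head(missing_meta, 5), collapse = ", ")))
    }
    # zero-read samples (e.g. empty plates at extinction) are excluded from
    # the rarefied branch whether or not the simulator flagged them
    totals <- colSums(table[, sample_columns(table), drop = FALSE])
    flagged <- union(flagged, names(totals)[totals == 0])
  })

  filtered <- stage("filter", filter_low_count_otus(table, max_total))

  part <- stage("partition", partition_otus(filtered, metadata))
  fractions <- stage("fractions", list(
    cultivable_fraction = cultivable_fraction(part),
    medium_gain_defined_added = medium_gain(part, "defined"),
    medium_gain_undefined_added = medium_gain(part, "undefined")))
  shared <- stage("shared_per_dilution", shared_per_dilution(filtered, metadata))

  rare <- rare_biosphere(part)
  cohort_ids <- metadata$sample_id[metadata$source == "cohort"]
  survey <- NULL
  if (length(cohort_ids) && length(rare)) {
    survey <- stage("cohort_survey", cohort_survey(
      rare, filtered[, c("otu_id", cohort_ids), drop = FALSE]))
  }

  phylo <- stage("phylo_cohesion", {
    D <- NULL
    if (!is.null(tree)) {
      D <- patristic_distances(tree)
    } else if (!is.null(alignment)) {
      D <- pdistance_from_alignment(alignment)
    }
    if (is.null(D)) NULL else {
      # the null pool holds every detected OTU, cultured or not, so the
      # size-matched draw stays meaningful even when the cultured set
      # outnumbers the rumen-detected set
      pool <- intersect(union(part$rumen_all, part$plates_all), rownames(D))
      focal <- intersect(part$plates_all, rownames(D))
      overall <- phylo_permutation_test(
        focal, pool, D, B = phylo_B,
        subset_size = min(length(focal), length(pool)),
        seed = substream_seed(seed, "phylo"), group_label = "all_cultured")
      fam <- if (!is.null(taxonomy)) {
        family_cohesion_tests(focal, pool, taxonomy, D, B = phylo_B,
                              seed = substream_seed(seed, "phylo_family"))
      }
      list(overall = overall, families = fam)
    }
  })

  # ordination / richness branch on the rarefied rumen + plate samples
  exp_meta <- metadata |>
    filter(.data$source %in% c("rumen", "plate"),
           !.data$sample_id %in% flagged)
  exp_tbl <- filtered[, c("otu_id", exp_meta$sample_id), drop = FALSE]
  ord <- stage("ordination", {
    depth <- rarefaction_depth %||%
      min(colSums(exp_tbl[, sample_columns(exp_tbl), drop = FALSE]))
    rarefied <- rarefy(exp_tbl, depth, substream_seed(seed, "rarefy"))
    D_s <- suppressWarnings(euclidean_distances(rarefied))
    ordn <- pcoa(D_s)
    plate_meta <- exp_meta |> filter(.data$source == "plate")
    perma <- NULL
    if (nrow(plate_meta) >= 4 &&
          length(unique(plate_meta$medium)) >= 2 &&
          length(unique(plate_meta$dilution_exponent)) >= 2) {
      D_p <- D_s[plate_meta$sample_id, plate_meta$sample_id]
      perma <- permanova_two_way(
        D_p, plate_meta$medium, as.character(plate_meta$dilution_exponent),
        B = permanova_B, seed = substream_seed(seed, "permanova"),
        names = c("medium", "dilution"))
    }
    rich <- observed_richness(rarefied) |> left_join(exp_meta, by = "sample_id")
    list(depth = depth, pcoa = ordn, permanova = perma, richness = rich)
  })

  rich_tests <- stage("richness_tests", richness_tests(ord$richness))

  corr <- stage("percentile_correlation", {
    cultured_sets <- list(
      all_cultured = part$plates_all,
      defined_only = setdiff(part$defined_all, part$undefined_all),
      undefined_only = setdiff(part$undefined_all, part$defined_all),
      both_media = intersect(part$defined_all, part$undefined_all))
    suppressWarnings(cultivability_correlation(
      filtered, metadata, cultured_sets, n_bins = n_bins,
      r_threshold = r_threshold, alpha = alpha))
  })

  results <- structure(list(
    config = list(max_total = max_total, rarefaction_depth = ord$depth,
                  phylo_B = phylo_B, permanova_B = permanova_B,
                  n_bins = n_bins, r_threshold = r_threshold, alpha = alpha,
                  seed = seed, simulated = !is.null(sim_params)),
    partition = part,
    partition_sizes = tibble(
      region = c(venn_regions, "rumen_all", "plates_all", "shared", "plate_only"),
      n_otus = vapply(c(venn_regions, "rumen_all", "plates_all", "shared",
                        "plate_only"), function(r) length(part[[r]]), integer(1))),
    fractions = fractions,
    shared_per_dilution = shared,
    rare_biosphere = rare,
    cohort_survey = survey,
    phylo = phylo,
    pcoa = ord$pcoa,
    permanova = ord$permanova,
    richness = ord$richness,
    richness_tests = rich_tests,
    percentile_correlation = corr,
    flagged_samples = flagged,
    truth = truth
  ), class = "culturomics_results")

  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

# Paired richness comparisons: rumen vs each medium, paired by dilution
# (plate replicates averaged within a dilution), exact signed-rank; media
# against each other likewise; Kruskal-Wallis across the three groups;
# Holm adjustment across the paired comparisons.
richness_tests <- function(rich) {
  plate_mean <- rich |>
    filter(.data$source == "plate", .data$dilution_exponent >= 1) |>
    group_by(.data$medium, .data$dilution_exponent) |>
    summarise(richness = mean(.data$richness), .groups = "drop")
  rumen <- rich |>
    filter(.data$source == "rumen", .data$dilution_exponent >= 1) |>
    select("dilution_exponent", rumen = "richness")
  wide <- plate_mean |>
    tidyr::pivot_wider(names_from = "medium", values_from = "richness") |>
    dplyr::inner_join(rumen, by = "dilution_exponent") |>
    arrange(.data$dilution_exponent)
  # dilutions where one arm is entirely extinct (all plates empty) drop out
  # of the paired comparison
  pair_p <- function(a, b) {
    ok <- !is.na(wide[[a]]) & !is.na(wide[[b]])
    if (sum(ok) < 1) return(NULL)
    wilcoxon_signed_rank_exact(wide[[a]][ok], wide[[b]][ok])
  }
  comps <- list()
  if (all(c("rumen", "defined") %in% names(wide))) {
    comps[["rumen_vs_defined"]] <- pair_p("rumen", "defined")
  }
  if (all(c("rumen", "undefined") %in% names(wide))) {
    comps[["rumen_vs_undefined"]] <- pair_p("rumen", "undefined")
  }
  if (all(c("defined", "undefined") %in% names(wide))) {
    comps[["defined_vs_undefined"]] <- pair_p("defined", "undefined")
  }
  paired <- tibble(comparison = names(comps),
                   p_raw = unlist(comps, use.names = FALSE))
  paired$p_adjusted <- holm_bonferroni(paired$p_raw)
  groups <- list(
    rumen = rich$richness[rich$source == "rumen"],
    defined = rich$richness[rich$source == "plate" & rich$medium == "defined"],
    undefined = rich$richness[rich$source == "plate" & rich$medium == "undefined"])
  groups <- groups[lengths(groups) > 0]
  kw <- if (length(groups) >= 2) kruskal_wallis(groups) else NA_real_
  list(paired = paired, kruskal_wallis_p = kw)
}

#' Write a results bundle to disk
#'
#' Writes `results.json` (12 significant digits; raw fractions, never
#' formatted percents), TSV tables for the survey, richness, shared
#' proportions and PCoA coordinates, and `run_log.txt`. All outputs are
#' removed again if any write fails.
#'
#' @param results A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  stopifnot(inherits(results, "culturomics_results"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    abort(sprintf("pipeline stage 'write' failed: %s", conditionMessage(e)))
  }
  tryCatch({
    json <- results_as_json_list(results)
    path <- file.path(out_dir, "results.json")
    jsonlite::write_json(json, path, auto_unbox = TRUE, digits = 12,
                         null = "null", pretty = TRUE)
    written <- c(written, path)
    tsvs <- list(cohort_survey = results$cohort_survey,
                 shared_per_dilution = results$shared_per_dilution,
                 richness = results$richness,
                 pcoa_coordinates = results$pcoa$coordinates,
                 percentile_correlation = results$percentile_correlation)
    for (nm in names(tsvs)) {
      if (is.null(tsvs[[nm]])) next
      p <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(tsvs[[nm]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE, eol = "\n")
      written <- c(written, p)
    }
    log_path <- file.path(out_dir, "run_log.txt")
    writeLines(c(
      sprintf("rumencult %s | R %s", as.character(utils::packageVersion("rumencult")),
              paste(R.version$major, R.version$minor, sep = ".")),
      sprintf("seed: %d", results$config$seed),
      sprintf("config: %s", jsonlite::toJSON(results$config, auto_unbox = TRUE))
    ), log_path)
    written <- c(written, log_path)
  }, error = on_fail)
  invisible(out_dir)
}

results_as_json_list <- function(results) {
  part <- results$partition
  list(
    config = results$config,
    partition = stats::setNames(
      as.list(results$partition_sizes$n_otus), results$partition_sizes$region),
    fractions = results$fractions,
    shared_per_dilution = results$shared_per_dilution,
    rare_biosphere = list(n_otus = length(results$rare_biosphere),
                          otu_ids = results$rare_biosphere),
    cohort_survey = results$cohort_survey,
    phylo = if (!is.null(results$phylo)) {
      c(list(overall = unclass(results$phylo$overall)),
        if (!is.null(results$phylo$families)) list(
          families = lapply(results$phylo$families$results, unclass),
          skipped_families = results$phylo$families$skipped))
    },
    pcoa = list(coordinates = results$pcoa$coordinates,
                eigenvalues = results$pcoa$eigenvalues,
                proportion_explained = results$pcoa$proportion_explained),
    permanova = if (!is.null(results$permanova)) as.data.frame(results$permanova),
    richness_tests = results$richness_tests,
    percentile_correlation = results$percentile_correlation,
    flagged_samples = results$flagged_samples)
}

#' Human-readable summary of a pipeline run
#'
#' Headline quantities with report-layer percent formatting: whole percents
#' truncated, one-decimal percents rounded half-even (see [percent_value()]).
#'
#' @param results A [run_pipeline()] result.
#' @return A character vector of lines, invisibly; printed as a side effect.
#' @export
render_summary <- function(results) {
  stopifnot(inherits(results, "culturomics_results"))
  part <- results$partition
  fr <- results$fractions
  gains <- c(defined = fr$medium_gain_defined_added,
             undefined = fr$medium_gain_undefined_added)
  lines <- c(
    sprintf("cultivable: %d%% (%d of %d rumen OTUs found on plates)",
            percent_value(fr$cultivable_fraction),
            length(part$shared), length(part$rumen_all)),
    sprintf("medium gain: up to %d%% (adding %s medium; other direction %d%%)",
            percent_value(max(gains)), names(gains)[which.max(gains)],
            percent_value(min(gains))),
    sprintf("rare biosphere: %d OTUs (plate-only)", length(results$rare_biosphere)))
  if (!is.null(results$cohort_survey)) {
    lines <- c(lines, sprintf(
      "rare biosphere undetected in cohort: %d of %d OTUs",
      sum(results$cohort_survey$n_detected == 0), nrow(results$cohort_survey)))
  }
  if (!is.null(results$phylo)) {
    lines <- c(lines, sprintf(
      "phylo cohesion (all cultured): MPD %.4f at percentile %.1f, p(lesser)=%.4g",
      results$phylo$overall$observed_mean,
      results$phylo$overall$percentile_rank, results$phylo$overall$p_lesser))
  }
  pe <- results$pcoa$proportion_explained
  lines <- c(lines, sprintf("PCoA: axis 1 %.1f%%, axis 2 %.1f%% of variance",
                            100 * pe[1], 100 * pe[2]))
  if (!is.null(results$permanova)) {
    first <- results$permanova |>
      filter(.data$order == .data$order[1], !.data$term %in% c("Residual", "Total"))
    lines <- c(lines, sprintf(
      "PERMANOVA %s: R2=%.3f p=%.4g", first$term, first$variance_explained,
      first$p_value))
  }
  lines <- c(lines, sprintf("Kruskal-Wallis richness p = %.4g",
                            results$richness_tests$kruskal_wallis_p))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.culturomics_results <- function(x, ...) {
  cat("Culturomics pipeline results\n")
  render_summary(x)
  invisible(x)
}
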