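#' Simulation parameters for a dilution-to-extinction plating experiment
#'
#' Bundles the knobs of the synthetic culturomics experiment: a heavy-tailed
#' source community (log-normal abundances), a decimal dilution series
#' sequenced alongside the original sample, duplicate plating on a defined
#' and an undefined medium, and a cohort of additional animals. Cultivability
#' of each taxon is a logistic transform of a latent liability that evolves
#' as Brownian motion on the taxon phylogeny plus independent noise, so the
#' cultured set is phylogenetically cohesive by construction; the undefined
#' medium adds a constant log-odds boost. Cultivability is independent of
#' abundance by construction: any observed abundance-cultivability
#' correlation downstream emerges purely from Poisson founder sampling.
#'
#' @param n_taxa Number of taxa in the source community.
#' @param abundance_sigma Log-normal shape of true relative abundances.
#' @param inoculum_cells Expected cells in the plated aliquot of the
#'   undiluted sample.
#' @param dilution_exponents Integer vector of decimal dilution exponents d
#'   (the sample diluted 10^-d); the undiluted sample (d = 0) is always
#'   sequenced in addition.
#' @param media Character vector of plated media.
#' @param replicates Plates per (dilution, medium) combination.
#' @param read_depth Reads sequenced per sample.
#' @param cultivability_base Baseline culturing probability on the defined
#'   medium for a taxon with zero liability.
#' @param undefined_medium_log_odds_boost Log-odds added to cultivability on
#'   the undefined (rumen-fluid supplemented) medium.
#' @param phylo_signal_variance Variance of the Brownian liability accumulated
#'   root-to-tip (the tree is scaled to unit height).
#' @param independent_noise_variance Variance of the per-taxon independent
#'   liability noise.
#' @param growth_dispersion Log-normal sigma of the per-taxon colony growth
#'   factor applied on plates.
#' @param n_cohort_samples Number of additional cohort communities.
#' @param seed Master seed; every stage draws from a named substream of it.
#' @return A list of class `sim_params`.
#' @export
simulation_params <- function(n_taxa = 3000,
                              abundance_sigma = 2.5,
                              inoculum_cells = 1e7,
                              dilution_exponents = 1:6,
                              media = c("defined", "undefined"),
                              replicates = 2,
                              read_depth = 8078,
                              cultivability_base = 0.05,
                              undefined_medium_log_odds_boost = 1.2,
                              phylo_signal_variance = 1.0,
                              independent_noise_variance = 0.25,
                              growth_dispersion = 0.8,
                              n_cohort_samples = 38,
                              seed = 1) {
  stopifnot(n_taxa >= 2, abundance_sigma > 0, inoculum_cells > 0,
            all(dilution_exponents >= 1), replicates >= 1, read_depth >= 1,
            cultivability_base > 0, cultivability_base < 1,
            phylo_signal_variance >= 0, independent_noise_variance >= 0,
            growth_dispersion >= 0, n_cohort_samples >= 0)
  structure(
    list(n_taxa = n_taxa, abundance_sigma = abundance_sigma,
         inoculum_cells = inoculum_cells,
         dilution_exponents = sort(unique(as.integer(dilution_exponents))),
         media = media, replicates = replicates, read_depth = read_depth,
         cultivability_base = cultivability_base,
         undefined_medium_log_odds_boost = undefined_medium_log_odds_boost,
         phylo_signal_variance = phylo_signal_variance,
         independent_noise_variance = independent_noise_variance,
         growth_dispersion = growth_dispersion,
         n_cohort_samples = n_cohort_samples, seed = as.integer(seed)),
    class = "sim_params")
}

#' Simulate a Yule taxon phylogeny
#'
#' Pure-birth tree with `n_taxa` tips, rescaled to unit height, tips labelled
#' `otu_00001` onward. Reproducible given `seed`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An [ape::rphylo()] `phylo` object.
#' @export
simulate_tree <- function(n_taxa, seed) {
  if (n_taxa < 2) abort("a tree needs at least 2 taxa")
  tr <- with_seed(seed, ape::rphylo(n_taxa, birth = 1, death = 0))
  height <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / height
  tr$tip.label <- sprintf("otu_%05d", seq_len(n_taxa))
  tr
}

logit <- stats::qlogis
inv_logit <- stats::plogis

#' Simulate the ground truth of a culturomics experiment
#'
#' Draws the taxon tree, true relative abundances (normalized log-normal),
#' the Brownian-plus-noise cultivability liability, per-(taxon, medium)
#' culturing probabilities, and per-taxon colony growth factors.
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `synthetic_truth` with elements `tree`,
#'   `abundance` (named, sums to 1), `liability` (named), `cultivability`
#'   (taxa x media matrix of probabilities) and `growth_factor` (named).
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  tree <- simulate_tree(params$n_taxa, substream_seed(params$seed, "tree"))
  taxa <- tree$tip.label

  abundance <- with_seed(substream_seed(params$seed, "abundance"), {
    a <- stats::rlnorm(params$n_taxa, 0, params$abundance_sigma)
    a / sum(a)
  })
  names(abundance) <- taxa

  liability <- with_seed(substream_seed(params$seed, "liability"), {
    bm <- if (params$phylo_signal_variance > 0) {
      ape::rTraitCont(tree, model = "BM",
                      sigma = sqrt(params$phylo_signal_variance))
    } else {
      stats::setNames(rep(0, params$n_taxa), taxa)
    }
    noise <- stats::rnorm(params$n_taxa, 0,
                          sqrt(params$independent_noise_variance))
    bm[taxa] + noise
  })
  names(liability) <- taxa

  boost <- ifelse(params$media == "undefined",
                  params$undefined_medium_log_odds_boost, 0)
  cultivability <- vapply(seq_along(params$media), function(i) {
    inv_logit(logit(params$cultivability_base) + liability + boost[i])
  }, numeric(params$n_taxa))
  dimnames(cultivability) <- list(taxa, params$media)

  growth_factor <- with_seed(substream_seed(params$seed, "growth"), {
    stats::rlnorm(params$n_taxa, 0, params$growth_dispersion)
  })
  names(growth_factor) <- taxa

  structure(list(tree = tree, abundance = abundance, liability = liability,
                 cultivability = cultivability, growth_factor = growth_factor),
            class = "synthetic_truth")
}

# One sequenced sample: Poisson cells per taxon, multinomial reads over taxa
# with cells, or an all-zero flagged sample when no cell made it through.
sequence_community <- function(weights, read_depth) {
  if (sum(weights) <= 0) {
    list(reads = rep(0, length(weights)), flagged = TRUE)
  } else {
    list(reads = as.numeric(stats::rmultinom(1, read_depth, weights)),
         flagged = FALSE)
  }
}

#' Simulate the rumen dilution series and the cohort
#'
#' The original sample (d = 0) and each decimal dilution are sequenced: the
#' aliquot holds Poisson(inoculum_cells * 10^-d * abundance) cells per taxon
#' and reads are multinomial over the cells present. Cohort samples are
#' independent communities with fresh log-normal abundance vectors over the
#' same taxon set. A sample whose aliquot lost every cell is emitted all-zero
#' and flagged.
#'
#' @param truth A [simulate_truth()] object.
#' @param params The matching [simulation_params()].
#' @return A list with `table` (OTU table tibble), `metadata` and `flagged`
#'   (character vector of all-zero sample ids).
#' @export
simulate_rumen_and_cohort <- function(truth, params) {
  taxa <- names(truth$abundance)
  dils <- c(0L, params$dilution_exponents)
  flagged <- character(0)
  cols <- list()
  meta <- list()

  with_seed(substream_seed(params$seed, "rumen"), {
    for (d in dils) {
      cells <- stats::rpois(length(taxa),
                            params$inoculum_cells * 10^(-d) * truth$abundance)
      sq <- sequence_community(cells, params$read_depth)
      sid <- sprintf("rumen_d%d", d)
      cols[[sid]] <- sq$reads
      if (sq$flagged) flagged <- c(flagged, sid)
      meta[[sid]] <- tibble(sample_id = sid, source = "rumen", medium = "none",
                            dilution_exponent = d, replicate = 1L)
    }
  })

  if (params$n_cohort_samples > 0) {
    with_seed(substream_seed(params$seed, "cohort"), {
      for (k in seq_len(params$n_cohort_samples)) {
        ab <- stats::rlnorm(length(taxa), 0, params$abundance_sigma)
        ab <- ab / sum(ab)
        cells <- stats::rpois(length(taxa), params$inoculum_cells * ab)
        sq <- sequence_community(cells, params$read_depth)
        sid <- sprintf("cohort_%02d", k)
        cols[[sid]] <- sq$reads
        if (sq$flagged) flagged <- c(flagged, sid)
        meta[[sid]] <- tibble(sample_id = sid, source = "cohort",
                              medium = "none", dilution_exponent = 0L,
                              replicate = 1L)
      }
    })
  }

  list(table = tibble(otu_id = taxa) |> dplyr::bind_cols(as_tibble(cols)),
       metadata = bind_rows(meta), flagged = flagged)
}

#' Simulate duplicate plates on each medium at each dilution
#'
#' Each plate is founded by Poisson(inoculum_cells * 10^-d * abundance *
#' cultivability) colony founders per taxon; the scraped plate pool is
#' proportional to founders times the taxon growth factor, and reads are
#' multinomial at `read_depth`. Empty plates are emitted all-zero and
#' flagged.
#'
#' @inheritParams simulate_rumen_and_cohort
#' @return As [simulate_rumen_and_cohort()].
#' @export
simulate_plates <- function(truth, params) {
  taxa <- names(truth$abundance)
  flagged <- character(0)
  cols <- list()
  meta <- list()

  with_seed(substream_seed(params$seed, "plates"), {
    for (d in params$dilution_exponents) {
      for (m in params$media) {
        for (r in seq_len(params$replicates)) {
          lambda <- params$inoculum_cells * 10^(-d) * truth$abundance *
            truth$cultivability[, m]
          founders <- stats::rpois(length(taxa), lambda)
          pool <- founders * truth$growth_factor
          sq <- sequence_community(pool, params$read_depth)
          sid <- sprintf("plate_d%d_%s_r%d", d, m, r)
          cols[[sid]] <- sq$reads
          if (sq$flagged) flagged <- c(flagged, sid)
          meta[[sid]] <- tibble(sample_id = sid, source = "plate", medium = m,
                                dilution_exponent = d, replicate = r)
        }
      }
    }
  })

  list(table = tibble(otu_id = taxa) |> dplyr::bind_cols(as_tibble(cols)),
       metadata = bind_rows(meta), flagged = flagged)
}

#' Simulate a complete culturomics experiment
#'
#' Composes [simulate_truth()], [simulate_rumen_and_cohort()] and
#' [simulate_plates()] into one OTU table plus metadata. With the defaults
#' this yields 1 original + 6 dilutions + 24 plates (6 dilutions x 2 media x
#' duplicate) + 38 cohort samples = 69 sequenced samples. Byte-identical
#' given the same seed.
#'
#' @param params A [simulation_params()] object.
#' @return A list of class `experiment_bundle` with elements `truth`, `table`
#'   (OTU table tibble), `metadata` and `flagged`.
#' @export
simulate_experiment <- function(params = simulation_params()) {
  truth <- simulate_truth(params)
  rc <- simulate_rumen_and_cohort(truth, params)
  pl <- simulate_plates(truth, params)
  stopifnot(identical(rc$table$otu_id, pl$table$otu_id))
  table <- dplyr::bind_cols(rc$table,
                            pl$table[, sample_columns(pl$table), drop = FALSE])
  # samples ordered: rumen series, plates, cohort
  meta <- bind_rows(
    rc$metadata |> filter(.data$source == "rumen"),
    pl$metadata,
    rc$metadata |> filter(.data$source == "cohort"))
  table <- table[, c("otu_id", meta$sample_id)]
  validate_metadata(meta)
  structure(list(truth = truth, table = table, metadata = meta,
                 flagged = c(rc$flagged, pl$flagged), params = params),
            class = "experiment_bundle")
}

#' True cultivable fraction of the detected rumen community
#'
#' Among taxa detected in the bundle's rumen samples (original plus
#' dilutions), the fraction whose expected founder count on the least-dilute
#' plate under the most permissive medium is at least one colony, i.e. whose
#' cultivability clears the inoculum-scale detectability limit. Used to
#' validate that the pipeline's estimated cultivable fraction tracks the
#' simulated truth.
#'
#' @param bundle An [simulate_experiment()] bundle.
#' @return A fraction in \[0, 1\].
#' @export
true_cultivable_fraction <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  rumen_ids <- bundle$metadata$sample_id[bundle$metadata$source == "rumen"]
  detected <- detected_otus(bundle$table, rumen_ids)
  if (!length(detected)) abort("no taxa detected in rumen samples")
  d_min <- min(bundle$params$dilution_exponents)
  best_cult <- apply(bundle$truth$cultivability[detected, , drop = FALSE], 1, max)
  expected_founders <- bundle$params$inoculum_cells * 10^(-d_min) *
    bundle$truth$abundance[detected] * best_cult
  mean(expected_founders >= 1)
}

#' Write a simulated experiment to disk
#'
#' Writes `otu_table.tsv`, `metadata.tsv`, `tree.nwk` and `truth.json`
#' (abundance, liability, per-medium cultivability and growth factor keyed by
#' taxon) into `dir`.
#'
#' @param bundle An [simulate_experiment()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(bundle, dir) {
  stopifnot(inherits(bundle, "experiment_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(bundle$table, file.path(dir, "otu_table.tsv"))
  write_metadata(bundle$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(bundle$truth$tree, file.path(dir, "tree.nwk"))
  truth <- list(
    abundance = as.list(bundle$truth$abundance),
    liability = as.list(bundle$truth$liability),
    cultivability = apply(bundle$truth$cultivability, 2, as.list,
                          simplify = FALSE),
    growth_factor = as.list(bundle$truth$growth_factor),
    flagged_samples = bundle$flagged)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
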