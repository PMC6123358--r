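# Shared fixtures, all built in code.

make_otu_tbl <- function(m, otu_ids = NULL, sample_ids = NULL) {
  # m: OTUs x samples numeric matrix
  otu_ids <- otu_ids %||% sprintf("otu%02d", seq_len(nrow(m)))
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(ncol(m)))
  colnames(m) <- sample_ids
  dplyr::bind_cols(tibble::tibble(otu_id = otu_ids), tibble::as_tibble(m))
}

random_otu_tbl <- function(n_samples, n_otus, seed, lambda = 3) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), nrow = n_otus)
  make_otu_tbl(m)
}

# three-group presence/absence table realizing given membership sets, with
# metadata: one rumen sample, one plate per medium
membership_fixture <- function(rumen, defined, undefined) {
  otus <- sort(unique(c(rumen, defined, undefined)))
  tbl <- make_otu_tbl(
    cbind(as.numeric(otus %in% rumen),
          as.numeric(otus %in% defined),
          as.numeric(otus %in% undefined)),
    otu_ids = otus, sample_ids = c("rumen1", "plateD", "plateU"))
  meta <- tibble::tibble(
    sample_id = c("rumen1", "plateD", "plateU"),
    source = c("rumen", "plate", "plate"),
    medium = c("none", "defined", "undefined"),
    dilution_exponent = 1L,   # rumen aliquot at the plates' dilution
    replicate = 1L)
  list(table = tbl, metadata = meta)
}

# default-parameter bundles are expensive; cache per seed across tests
.bundle_cache <- new.env(parent = emptyenv())
cached_bundle <- function(seed, ...) {
  key <- paste(seed, ..., sep = "_")
  if (is.null(.bundle_cache[[key]])) {
    .bundle_cache[[key]] <- simulate_experiment(
      simulation_params(seed = seed, ...))
  }
  .bundle_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
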