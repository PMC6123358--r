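#' Pairwise p-distances from an aligned FASTA
#'
#' Distance between two aligned sequences is the proportion of mismatching
#' positions over comparable columns, where a column is comparable when both
#' sequences carry a non-gap, non-N character. Gap characters `-` and `.` and
#' the ambiguity code `N` are excluded pairwise.
#'
#' @param x Path to an aligned FASTA file, or a named character vector of
#'   equal-length sequences.
#' @return A symmetric distance matrix with OTU ids as dimnames.
#' @export
pdistance_from_alignment <- function(x) {
  seqs <- if (length(x) == 1 && file.exists(x)) read_fasta(x) else x
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    abort("alignment sequences must have unique ids")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort("sequences have unequal lengths; the input must be aligned")
  }
  n <- length(seqs)
  chars <- t(vapply(strsplit(toupper(seqs), ""), identity,
                    character(lens[1])))
  ok <- chars %in% c("A", "C", "G", "T")
  dim(ok) <- dim(chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp)) {
        abort(sprintf("no comparable columns between '%s' and '%s'",
                      names(seqs)[i], names(seqs)[j]))
      }
      d[i, j] <- d[j, i] <- sum(chars[i, comp] != chars[j, comp]) / sum(comp)
    }
  }
  d
}

read_fasta <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (!length(headers)) abort(sprintf("%s: not a FASTA file", path))
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)
  starts <- headers + 1
  ends <- c(headers[-1] - 1, length(lines))
  seqs <- vapply(seq_along(headers), function(k) {
    if (starts[k] > ends[k]) "" else
      paste(lines[starts[k]:ends[k]], collapse = "")
  }, character(1))
  stats::setNames(seqs, ids)
}

#' Patristic distance matrix from a tree
#'
#' Tip-to-tip distances as the sum of branch lengths on the connecting path.
#'
#' @param tree An [ape::read.tree()] `phylo` object, a Newick string, or a
#'   path to a Newick file.
#' @return A symmetric distance matrix with tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    abort("tree has missing branch lengths")
  }
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip labels")
  ape::cophenetic.phylo(tree)
}

#' Mean pairwise distance within a set
#'
#' Mean of d\[i, j\] over all unordered pairs of the given ids, each pair
#' counted once.
#'
#' @param ids Character vector of at least two ids present in `D`.
#' @param D A symmetric distance matrix with id dimnames.
#' @return A single number.
#' @export
mean_pairwise_distance <- function(ids, D) {
  ids <- unique(ids)
  if (length(ids) < 2) abort("mean pairwise distance needs at least 2 ids")
  unknown <- setdiff(ids, rownames(D))
  if (length(unknown)) {
    abort(sprintf("id(s) not in distance matrix: %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  sub <- D[ids, ids]
  mean(sub[lower.tri(sub)])
}

#' Phylogenetic-cohesion permutation test
#'
#' Compares the mean pairwise distance (MPD) of a focal OTU set (typically
#' the cultured OTUs) against a null distribution built from `B` random
#' subsets of the pool (typically all rumen OTUs), each drawn uniformly
#' without replacement at `subset_size`. A focal MPD low in that null
#' distribution indicates the focal set is phylogenetically clustered
#' ("cohesive"). Empirical p-values use the add-one estimator, so the
#' smallest attainable p is 1/(B+1), and ties count toward both tails.
#' The percentile rank of the observed MPD in the null is reported to match
#' the 10th/1st-percentile flagging convention.
#'
#' @param focal_ids Character vector of focal OTU ids (in `D`).
#' @param pool_ids Character vector of pool OTU ids to draw null subsets from.
#' @param D A symmetric distance matrix covering both sets.
#' @param B Number of permutations (default 100).
#' @param subset_size Size of each null subset; defaults to the focal set
#'   size (size-matched null).
#' @param seed Integer seed.
#' @param group_label Label carried into the result.
#' @return A list of class `phylo_permutation` with fields `group_label`,
#'   `observed_mean`, `null_means`, `p_lesser`, `p_greater`,
#'   `percentile_rank`, `subset_size`, `B`, `seed`.
#' @export
phylo_permutation_test <- function(focal_ids, pool_ids, D, B = 100,
                                   subset_size = length(unique(focal_ids)),
                                   seed = 1, group_label = "focal") {
  focal_ids <- unique(focal_ids)
  pool_ids <- unique(pool_ids)
  if (B < 1) abort("B must be >= 1")
  if (subset_size < 2) abort("subset_size must be >= 2")
  if (subset_size > length(pool_ids)) {
    abort("subset_size exceeds the pool size")
  }
  observed <- mean_pairwise_distance(focal_ids, D)
  null_means <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      mean_pairwise_distance(sample(pool_ids, subset_size), D)
    }, numeric(1))
  })
  structure(list(
    group_label = group_label,
    observed_mean = observed,
    null_means = null_means,
    p_lesser = (1 + sum(null_means <= observed)) / (B + 1),
    p_greater = (1 + sum(null_means >= observed)) / (B + 1),
    percentile_rank = 100 * sum(null_means < observed) / B,
    subset_size = subset_size, B = B, seed = seed
  ), class = "phylo_permutation")
}

#' @export
print.phylo_permutation <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic cohesion test [%s]\n  observed MPD %.4f at percentile %.1f of %d size-%d null subsets\n  p(lesser) = %.4g, p(greater) = %.4g\n",
    x$group_label, x$observed_mean, x$percentile_rank, x$B, x$subset_size,
    x$p_lesser, x$p_greater))
  invisible(x)
}

#' Per-family phylogenetic-cohesion tests
#'
#' Runs [phylo_permutation_test()] within each taxonomic family that has at
#' least `min_otus` members in both the focal set and the pool, restricting
#' the null pool to that family. Families below the threshold are skipped and
#' listed, never errored.
#'
#' @inheritParams phylo_permutation_test
#' @param taxonomy A tibble with columns `otu_id`, `lineage` (see
#'   [read_taxonomy()]); family is rank 5 of the lineage.
#' @param min_otus Minimum focal and pool members per family (default 10).
#' @return A list with `results` (list of `phylo_permutation`, labelled by
#'   family) and `skipped` (tibble of families failing the threshold with
#'   their focal/pool counts).
#' @export
family_cohesion_tests <- function(focal_ids, pool_ids, taxonomy, D, B = 100,
                                  min_otus = 10, seed = 1) {
  fam <- stats::setNames(lineage_rank(taxonomy$lineage, 5), taxonomy$otu_id)
  focal_fams <- fam[intersect(focal_ids, names(fam))]
  pool_fams <- fam[intersect(pool_ids, names(fam))]
  families <- sort(unique(stats::na.omit(c(focal_fams, pool_fams))))
  results <- list()
  skipped <- list()
  for (f in families) {
    focal_f <- names(focal_fams)[!is.na(focal_fams) & focal_fams == f]
    pool_f <- names(pool_fams)[!is.na(pool_fams) & pool_fams == f]
    if (length(focal_f) >= min_otus && length(pool_f) >= min_otus) {
      results[[f]] <- phylo_permutation_test(
        focal_f, pool_f, D, B = B, subset_size = length(focal_f),
        seed = substream_seed(seed, f), group_label = f)
    } else {
      skipped[[f]] <- tibble(family = f, n_focal = length(focal_f),
                             n_pool = length(pool_f))
    }
  }
  list(results = results,
       skipped = if (length(skipped)) bind_rows(skipped) else
         tibble(family = character(0), n_focal = integer(0),
                n_pool = integer(0)))
}
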