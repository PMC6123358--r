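#' Euclidean distances between samples
#'
#' Plain Euclidean distance on the count (or relative) vectors of each
#' sample. Meaningful for depth comparisons only on a table rarefied to a
#' common depth; a warning is issued when count totals differ.
#'
#' @param tbl An OTU table tibble.
#' @return A symmetric samples-by-samples distance matrix.
#' @export
euclidean_distances <- function(tbl) {
  validate_otu_table(tbl)
  m <- otu_matrix(tbl)
  totals <- rowSums(m)
  if (length(unique(round(totals, 6))) > 1) {
    warn("sample totals differ; consider rarefying to a common depth first")
  }
  as.matrix(stats::dist(m, method = "euclidean"))
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers -D^2/2 and eigendecomposes it; coordinates are eigenvectors
#' scaled by the square roots of the positive eigenvalues, ordered by
#' decreasing eigenvalue. Axis signs are fixed so the largest-magnitude
#' coordinate on each axis is positive. Proportion explained is per positive
#' eigenvalue. For a distance matrix computed from Euclidean row vectors the
#' embedding is an exact isometry.
#'
#' @param D A symmetric distance matrix with zero diagonal.
#' @return A list of class `rumen_pcoa` with `coordinates` (tibble:
#'   `sample_id` plus `Axis1..k`), `eigenvalues` and `proportion_explained`.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) abort("distance matrix is not symmetric")
  n <- nrow(D)
  ids <- rownames(D) %||% paste0("sample_", seq_len(n))
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1,
                                          eig = TRUE))
  pts <- fit$points
  k <- ncol(pts)
  for (a in seq_len(k)) {
    if (pts[which.max(abs(pts[, a])), a] < 0) pts[, a] <- -pts[, a]
  }
  eig <- fit$eig
  pos <- pmax(eig, 0)
  colnames(pts) <- paste0("Axis", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(tibble(sample_id = ids), as_tibble(pts)),
    eigenvalues = eig,
    proportion_explained = pos / sum(pos)
  ), class = "rumen_pcoa")
}

#' Two-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with two crossed factors,
#' sequential (Type I) sums of squares, pseudo-F of each term against the
#' residual, and p-values from free permutation of sample labels. Because
#' sequential SS depend on term order in unbalanced designs, the fit is
#' reported in both factor orders. Variance explained is SS / SS_total.
#' Backed by [vegan::adonis2()].
#'
#' @param D A symmetric samples-by-samples distance matrix whose dimnames
#'   match the factor order.
#' @param factor_a,factor_b Factor labels, one per sample, in `D`'s row
#'   order.
#' @param B Number of permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @param names Names for the two factors in the output.
#' @return A tibble of class `permanova_result` with columns `order`, `term`,
#'   `df`, `sum_of_squares`, `pseudo_F`, `variance_explained`, `p_value`,
#'   plus attributes `B` and `seed`.
#' @export
permanova_two_way <- function(D, factor_a, factor_b, B = 1000, seed = 1,
                              names = c("factor_a", "factor_b")) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(length(factor_a) == n, length(factor_b) == n)
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) {
    abort("each factor needs at least 2 levels")
  }
  mm <- stats::model.matrix(~ fa + fb)
  if (qr(mm)$rank < ncol(mm)) {
    abort(sprintf("factors '%s' and '%s' are aliased (confounded design)",
                  names[1], names[2]))
  }
  df <- stats::setNames(data.frame(fa, fb), names)
  fit_order <- function(terms, sub_seed) {
    dd <- stats::as.dist(D)  # adonis2 resolves the response in this frame
    form <- stats::as.formula(
      paste("dd ~", paste(terms, collapse = " + ")), env = environment())
    tab <- with_seed(sub_seed, vegan::adonis2(form, data = df,
                                              permutations = B, by = "terms"))
    tot <- tab$SumOfSqs[rownames(tab) == "Total"]
    tibble(order = paste(terms, collapse = "+"),
           term = rownames(tab),
           df = tab$Df,
           sum_of_squares = tab$SumOfSqs,
           pseudo_F = tab$F,
           variance_explained = tab$SumOfSqs / tot,
           p_value = tab$`Pr(>F)`)
  }
  out <- bind_rows(
    fit_order(names, substream_seed(seed, "permanova")),
    fit_order(rev(names), substream_seed(seed, "permanova")))
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("permanova_result", class(out))
  out
}

# Exact null distribution of the signed-rank statistic over all 2^n sign
# assignments, by generating-function convolution over doubled midranks
# (doubling keeps tied midranks integral).
signed_rank_null <- function(ranks2) {
  f <- c(1)
  for (w in ranks2) {
    g <- c(f, rep(0, w))
    g[(w + 1):(w + length(f))] <- g[(w + 1):(w + length(f))] + f
    f <- g
  }
  f / sum(f)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided p-value of the paired signed-rank statistic. Zero differences
#' are dropped. For n <= 25 remaining pairs the p-value is exact, computed
#' from the full null distribution over all 2^n sign assignments (midrank
#' ties handled exactly); larger n uses the tie-corrected normal
#' approximation. The two-sided p is twice the smaller tail, capped at 1,
#' with the observed statistic included in its tail. Six pairs with
#' same-signed differences give the smallest attainable exact p, 2/64 =
#' 0.03125.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return The two-sided p-value.
#' @export
wilcoxon_signed_rank_exact <- function(x, y) {
  stopifnot(length(x) == length(y), !anyNA(x), !anyNA(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all paired differences are zero; no test possible")
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  if (n <= 25) {
    ranks2 <- as.integer(round(2 * r))
    f <- signed_rank_null(ranks2)
    t2 <- as.integer(round(2 * t_obs))
    p_low <- sum(f[seq_len(t2 + 1)])          # P(T <= t_obs)
    p_high <- sum(f[(t2 + 1):length(f)])      # P(T >= t_obs)
    min(1, 2 * min(p_low, p_high))
  } else {
    suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  }
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided p-value of the rank-sum statistic of `x` against `y`. When the
#' combined sample size is at most 12 the p-value is exact, by enumerating
#' every assignment of the midranks to the two groups; larger samples use the
#' tie-corrected normal approximation.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum_exact <- function(x, y) {
  n <- length(x); m <- length(y)
  stopifnot(n >= 1, m >= 1)
  if (n + m <= 12) {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(n)])
    sums <- utils::combn(n + m, n, function(idx) sum(r[idx]))
    p_low <- mean(sums <= w_obs + 1e-9)
    p_high <- mean(sums >= w_obs - 1e-9)
    min(1, 2 * min(p_low, p_high))
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
  }
}

#' Kruskal-Wallis test across groups
#'
#' Midrank-tie-corrected H statistic with a chi-square p on k - 1 degrees of
#' freedom, via [stats::kruskal.test()]. A fully degenerate input (all values
#' identical) returns p = 1.
#'
#' @param groups A list of numeric vectors, each nonempty.
#' @return The p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2, all(lengths(groups) >= 1))
  vals <- unlist(groups)
  if (length(unique(vals)) == 1) return(1)
  stats::kruskal.test(groups)$p.value
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down familywise-error correction with monotonicity enforcement and
#' capping at 1, mapped back to input order; via [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
holm_bonferroni <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Percentile-binned abundance-cultivability correlation
#'
#' Ranks the OTUs detected in one rumen sample by relative abundance, splits
#' them into `n_bins` equal-count rank bins (stable order breaks abundance
#' ties), and correlates the mean relative abundance per bin with the number
#' of OTUs from a cultured subset falling in each bin (Pearson). A positive r
#' means more-abundant community members were cultured more often. Raw
#' p-values come from the t-distribution on `n_bins - 2` degrees of freedom;
#' adjusted p-values (Holm) and the significance rule |r| > `r_threshold` and
#' p_adjusted < `alpha` are applied across all cells of the call.
#'
#' @param tbl An OTU table tibble (counts or relative).
#' @param sample_id The rumen sample to bin.
#' @param cultured_sets Named list of OTU-id character vectors (e.g. all
#'   cultured, defined-only, undefined-only, both media). Ids not detected in
#'   the sample are ignored with a warning.
#' @param n_bins Number of equal-count rank bins (default 100); must not
#'   exceed the number of detected OTUs.
#' @param r_threshold,alpha Significance rule parameters.
#' @param adjust Apply Holm adjustment across the call's cells (default
#'   `TRUE`); the multi-dilution wrapper [cultivability_correlation()]
#'   adjusts globally instead.
#' @return A tibble with columns `subset`, `r`, `p_raw`, and (if `adjust`)
#'   `p_adjusted`, `significant`, plus `n_bins`, `n_detected`.
#' @export
percentile_cultivability_correlation <- function(tbl, sample_id, cultured_sets,
                                                 n_bins = 100,
                                                 r_threshold = 0.3,
                                                 alpha = 0.05,
                                                 adjust = TRUE) {
  validate_otu_table(tbl)
  if (!sample_id %in% sample_columns(tbl)) {
    abort(sprintf("unknown sample id '%s'", sample_id))
  }
  counts <- tbl[[sample_id]]
  detected <- which(counts >= 1 | (counts > 0 & counts < 1))
  if (!length(detected)) abort(sprintf("sample '%s' is empty", sample_id))
  if (n_bins > length(detected)) {
    abort(sprintf(
      "n_bins (%d) exceeds the %d detected OTUs in '%s'; lower n_bins explicitly",
      n_bins, length(detected), sample_id))
  }
  rel <- counts[detected] / sum(counts[detected])
  ids <- tbl$otu_id[detected]
  ord <- order(rel)                      # stable (radix) sort: ties keep row order
  bin <- ceiling(seq_along(ord) * n_bins / length(ord))
  bin_of <- stats::setNames(bin, ids[ord])
  x <- tapply(rel[ord], bin, mean)

  rows <- purrr::imap_dfr(cultured_sets, function(set, label) {
    missing_ids <- setdiff(set, ids)
    if (length(missing_ids)) {
      warn(sprintf("subset '%s': %d id(s) not detected in sample '%s' ignored",
                   label, length(missing_ids), sample_id))
    }
    present <- intersect(set, ids)
    y <- tabulate(bin_of[present], nbins = n_bins)
    if (stats::sd(y) == 0 || stats::sd(x) == 0) {
      tibble(subset = label, r = NA_real_, p_raw = NA_real_,
             n_bins = n_bins, n_detected = length(ids))
    } else {
      ct <- stats::cor.test(as.numeric(x), y, method = "pearson")
      tibble(subset = label, r = unname(ct$estimate), p_raw = ct$p.value,
             n_bins = n_bins, n_detected = length(ids))
    }
  })
  if (adjust) {
    rows$p_adjusted <- holm_bonferroni(rows$p_raw)
    rows$significant <- !is.na(rows$r) & abs(rows$r) > r_threshold &
      rows$p_adjusted < alpha
  }
  rows
}

#' Abundance-cultivability correlation across all rumen dilutions
#'
#' Applies [percentile_cultivability_correlation()] to the rumen sample at
#' each dilution and Holm-adjusts the p-values across all
#' (dilution x subset) cells of the run, as one multiple-testing family.
#'
#' Rumen samples with fewer detected OTUs than `n_bins` (e.g. near-extinct
#' high dilutions) cannot be binned at the requested resolution; they are
#' skipped with a warning and listed in the `skipped` attribute rather than
#' silently rebinned — lower `n_bins` explicitly to include them.
#'
#' @inheritParams percentile_cultivability_correlation
#' @param meta Sample metadata identifying rumen samples and their dilutions.
#' @return A tibble with columns `dilution_exponent`, `subset`, `r`, `p_raw`,
#'   `p_adjusted`, `significant`, `n_bins`, `n_detected`; skipped samples in
#'   `attr(, "skipped")`.
#' @export
cultivability_correlation <- function(tbl, meta, cultured_sets, n_bins = 100,
                                      r_threshold = 0.3, alpha = 0.05) {
  validate_metadata(meta)
  rumen <- meta |> filter(.data$source == "rumen") |>
    arrange(.data$dilution_exponent)
  skipped <- character(0)
  rows <- purrr::map2_dfr(rumen$sample_id, rumen$dilution_exponent,
    function(sid, d) {
      n_det <- sum(tbl[[sid]] > 0)
      if (n_det < n_bins) {
        warn(sprintf(
          "sample '%s' skipped: %d detected OTUs < n_bins = %d", sid, n_det,
          n_bins))
        skipped <<- c(skipped, sid)
        return(NULL)
      }
      res <- percentile_cultivability_correlation(
        tbl, sid, cultured_sets, n_bins = n_bins, r_threshold = r_threshold,
        alpha = alpha, adjust = FALSE)
      mutate(res, dilution_exponent = d, .before = 1)
    })
  if (nrow(rows)) {
    rows$p_adjusted <- holm_bonferroni(rows$p_raw)
    rows$significant <- !is.na(rows$r) & abs(rows$r) > r_threshold &
      rows$p_adjusted < alpha
  }
  attr(rows, "skipped") <- skipped
  rows
}
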