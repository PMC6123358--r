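# Brute-force oracles, independent of the package implementations
signed_rank_p_oracle <- function(x, y) {
  d <- (x - y)[(x - y) != 0]
  n <- length(d)
  r <- rank(abs(d))
  t_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- signs %*% r
  min(1, 2 * min(mean(stats <= t_obs + 1e-9), mean(stats >= t_obs - 1e-9)))
}

rank_sum_p_oracle <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(x)
  w_obs <- sum(r[seq_len(n)])
  sums <- apply(utils::combn(length(r), n), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(sums <= w_obs + 1e-9), mean(sums >= w_obs - 1e-9)))
}

test_that("euclidean distances match the textbook definition", {
  tbl <- make_otu_tbl(matrix(c(3, 4, 0, 0, 3, 4), nrow = 2),
                      sample_ids = c("a", "zero", "b"))
  D <- suppressWarnings(euclidean_distances(tbl))
  expect_equal(D["a", "zero"], 5)
  expect_equal(D["a", "b"], 0)

  rnd <- random_otu_tbl(6, 15, seed = 3)
  D2 <- suppressWarnings(euclidean_distances(rnd))
  m <- otu_matrix(rnd)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(D2[i, j], sqrt(sum((m[i, ] - m[j, ])^2)))
  }
  expect_warning(euclidean_distances(tbl), "rarefying")
})

test_that("PCoA embeds collinear points on one axis and duplicates together", {
  D <- as.matrix(stats::dist(c(0, 1, 3)))
  dimnames(D) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  ord <- pcoa(D)
  expect_equal(sum(ord$eigenvalues > 1e-9), 1)
  ax1 <- ord$coordinates$Axis1
  expect_equal(as.matrix(stats::dist(ax1)), unname(D), ignore_attr = TRUE)

  # duplicated samples receive identical coordinates
  tbl <- random_otu_tbl(4, 10, seed = 8)
  tbl$s05 <- tbl$s01
  ordd <- pcoa(suppressWarnings(euclidean_distances(tbl)))
  co <- as.matrix(ordd$coordinates[, -1])
  expect_lt(max(abs(co[1, ] - co[5, ])), 1e-6)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), "symmetric")
})

test_that("PCoA on Euclidean row vectors is an exact isometry", {
  rnd <- random_otu_tbl(10, 40, seed = 4, lambda = 6)
  D <- suppressWarnings(euclidean_distances(rnd))
  ord <- pcoa(D)
  co <- as.matrix(ord$coordinates[, -1])
  recon <- as.matrix(stats::dist(co))
  expect_lt(max(abs(recon - D)), 1e-8)
  expect_true(all(diff(ord$eigenvalues) <= 1e-9))
  pe <- ord$proportion_explained
  expect_equal(sum(pe), 1, tolerance = 1e-12)
})

test_that("PERMANOVA decomposes variance and flags aliased designs", {
  set.seed(10)
  a <- rep(c("x", "y"), each = 8)
  b <- rep(c("u", "v"), times = 8)
  m <- matrix(rnorm(16 * 5), 16)
  rownames(m) <- paste0("s", 1:16)
  D <- as.matrix(stats::dist(m))
  res <- permanova_two_way(D, a, b, B = 99, seed = 1)
  first <- res[res$order == res$order[1], ]
  ss <- first$sum_of_squares
  expect_equal(sum(ss[first$term != "Total"]), ss[first$term == "Total"],
               tolerance = 1e-6)
  expect_equal(sum(first$variance_explained[first$term != "Total"]), 1,
               tolerance = 1e-6)

  expect_error(permanova_two_way(D, a, a, B = 9, seed = 1), "aliased")
  expect_error(permanova_two_way(D, rep("x", 16), b, B = 9, seed = 1),
               "2 levels")
})

test_that("PERMANOVA detects separated clusters and ignores random labels", {
  p_a <- c(); p_b <- c()
  for (s in 1:10) {
    set.seed(s)
    m <- rbind(matrix(rnorm(10 * 4), 10), matrix(rnorm(10 * 4, mean = 6), 10))
    rownames(m) <- paste0("s", 1:20)
    D <- as.matrix(stats::dist(m))
    fa <- rep(c("c1", "c2"), each = 10)
    fb <- sample(rep(c("u", "v"), 10))
    res <- permanova_two_way(D, fa, fb, B = 1000, seed = s,
                             names = c("cluster", "noise"))
    first <- res[res$order == "cluster+noise", ]
    p_a <- c(p_a, first$p_value[first$term == "cluster"])
    p_b <- c(p_b, first$p_value[first$term == "noise"])
  }
  expect_gte(mean(p_a == 1 / 1001), 0.95)
  expect_gt(mean(p_b), 0.2)
  expect_lt(mean(p_b), 0.8)
})

test_that("exact signed-rank p-values match full enumeration and wilcox.test", {
  # six same-signed pairs: the minimal attainable two-sided exact p
  expect_equal(wilcoxon_signed_rank_exact(2:7, 1:6), 2 / 64)
  expect_equal(wilcoxon_signed_rank_exact(1, 2), 1)

  set.seed(40)
  for (n in 2:10) {
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(wilcoxon_signed_rank_exact(x, y), signed_rank_p_oracle(x, y),
                 info = paste("n =", n))
    expect_equal(wilcoxon_signed_rank_exact(x, y),
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 info = paste("wilcox.test n =", n))
  }
  # ties in |differences| are handled exactly (wilcox.test cannot)
  x <- c(5, 4, 7, 9); y <- c(3, 2, 5, 10)  # diffs 2, 2, 2, -1
  expect_equal(wilcoxon_signed_rank_exact(x, y), signed_rank_p_oracle(x, y))
  # zero differences are dropped
  expect_equal(wilcoxon_signed_rank_exact(c(1, 5), c(1, 2)),
               wilcoxon_signed_rank_exact(5, 2))
  expect_error(wilcoxon_signed_rank_exact(c(1, 2), c(1, 2)), "zero")
})

test_that("exact rank-sum p-values match enumeration and wilcox.test", {
  expect_equal(wilcoxon_rank_sum_exact(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum_exact(c(2, 2, 2), c(2, 2, 2)), 1)

  set.seed(41)
  for (k in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(wilcoxon_rank_sum_exact(x, y), rank_sum_p_oracle(x, y))
    expect_equal(wilcoxon_rank_sum_exact(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # tied data against the enumeration oracle
  x <- c(1, 2, 2, 3); y <- c(2, 3, 3)
  expect_equal(wilcoxon_rank_sum_exact(x, y), rank_sum_p_oracle(x, y))
})

test_that("Kruskal-Wallis wraps the chi-square test with degenerate guard", {
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1))), 1)

  set.seed(42)
  x <- rnorm(50); y <- rnorm(50, 0.4)
  expect_lt(abs(kruskal_wallis(list(x, y)) -
                  stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value),
            0.01)

  power <- mean(vapply(1:20, function(s) {
    set.seed(s)
    g <- list(rnorm(10), rnorm(10, 3), rnorm(10, 6))
    kruskal_wallis(g) < 0.01
  }, logical(1)))
  expect_gte(power, 0.95)
})

test_that("Holm-Bonferroni reproduces step-down hand computations", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(c(0.015625, 0.015625)), c(0.03125, 0.03125))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")

  set.seed(43)
  p <- runif(10)
  adj <- holm_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(adj[order(p)] == cummax(adj[order(p)])))
})

test_that("percentile correlation is positive for top-bin cultured sets and
           centered at zero for random ones", {
  set.seed(44)
  counts <- sort(rpois(200, 20) + 1)
  tbl <- make_otu_tbl(matrix(counts, ncol = 1), sample_ids = "rumen_d0")
  top_ids <- tbl$otu_id[order(tbl$rumen_d0, decreasing = TRUE)[1:10]]
  res <- percentile_cultivability_correlation(
    tbl, "rumen_d0", list(top = top_ids), n_bins = 20)
  expect_gt(res$r, 0)

  null_r <- vapply(1:200, function(s) {
    set.seed(s)
    ids <- sample(tbl$otu_id, 40)
    percentile_cultivability_correlation(
      tbl, "rumen_d0", list(u = ids), n_bins = 20, adjust = FALSE)$r
  }, numeric(1))
  expect_lt(abs(mean(null_r)), 0.1)

  expect_error(percentile_cultivability_correlation(
    tbl, "rumen_d0", list(top = top_ids), n_bins = 500), "n_bins")
  expect_warning(percentile_cultivability_correlation(
    tbl, "rumen_d0", list(x = c(top_ids, "ghost")), n_bins = 20), "ignored")
})

test_that("abundance dependence of cultivability weakens with dilution", {
  wins <- vapply(1:20, function(s) {
    b <- simulate_experiment(simulation_params(seed = s, n_cohort_samples = 0))
    tblf <- filter_low_count_otus(b$table)
    part <- partition_otus(tblf, b$metadata)
    sets <- list(all_cultured = part$plates_all)
    r_at <- function(sid) {
      nb <- min(30, sum(tblf[[sid]] > 0))
      suppressWarnings(percentile_cultivability_correlation(
        tblf, sid, sets, n_bins = nb, adjust = FALSE)$r)
    }
    r1 <- r_at("rumen_d1"); r5 <- r_at("rumen_d5")
    !is.na(r1) && !is.na(r5) && r1 > r5
  }, logical(1))
  expect_gte(sum(wins), 14)
})
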