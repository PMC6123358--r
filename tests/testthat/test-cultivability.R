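test_that("detection matches a brute-force scan", {
  tbl <- make_otu_tbl(matrix(c(0, 3), nrow = 2), otu_ids = c("otu1", "otu2"),
                      sample_ids = "s1")
  expect_equal(detected_otus(tbl, "s1"), "otu2")
  expect_length(detected_otus(tbl, "s1", min_count = 5), 0)
  expect_error(detected_otus(tbl, "nope"), "unknown sample")

  rnd <- random_otu_tbl(10, 40, seed = 2, lambda = 0.5)
  ids <- c("s02", "s05", "s09")
  brute <- rnd$otu_id[apply(as.matrix(rnd[, ids]) >= 2, 1, any)]
  expect_setequal(detected_otus(rnd, ids, min_count = 2), brute)
})

test_that("the Venn partition reproduces hand-computed set arithmetic", {
  fx <- membership_fixture(rumen = c("A", "B", "C"), defined = c("B", "D"),
                           undefined = c("B", "C", "E"))
  p <- partition_otus(fx$table, fx$metadata)
  expect_setequal(p$shared, c("B", "C"))
  expect_setequal(p$plate_only, c("D", "E"))
  expect_setequal(p$defined_only, "D")
  expect_setequal(p$undefined_only, "E")
  expect_setequal(p$rumen_both_media, "B")
  expect_setequal(p$rumen_undefined_only, "C")
  expect_setequal(p$rumen_only, "A")
  expect_length(p$rumen_defined_only, 0)
  expect_length(p$both_media_only, 0)
})

test_that("partition regions are disjoint, exhaustive, and match enumeration", {
  set.seed(31)
  otus <- sprintf("o%03d", 1:500)
  rumen <- sample(otus, 260)
  defined <- sample(otus, 150)
  undefined <- sample(otus, 180)
  fx <- membership_fixture(rumen, defined, undefined)
  p <- partition_otus(fx$table, fx$metadata)

  regions <- list(p$rumen_only, p$rumen_defined_only, p$rumen_undefined_only,
                  p$rumen_both_media, p$both_media_only, p$defined_only,
                  p$undefined_only)
  all_ids <- unlist(regions)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_setequal(all_ids, union(rumen, union(defined, undefined)))
  expect_equal(length(p$shared) + length(p$plate_only), length(p$plates_all))

  # independent enumeration over the 2^3 membership patterns
  universe <- union(rumen, union(defined, undefined))
  pat <- paste0(as.integer(universe %in% rumen),
                as.integer(universe %in% defined),
                as.integer(universe %in% undefined))
  counts <- table(factor(pat, levels = c("100", "110", "101", "111",
                                         "011", "010", "001")))
  expect_equal(unname(vapply(regions, length, integer(1))), as.vector(counts))
})

test_that("partition is invariant to sample and OTU order", {
  fx <- membership_fixture(c("A", "B", "C"), c("B", "D"), c("B", "C", "E"))
  p1 <- partition_otus(fx$table, fx$metadata)
  shuffled <- fx$table[sample(nrow(fx$table)), c(1, 4, 2, 3)]
  p2 <- partition_otus(shuffled, fx$metadata[c(3, 1, 2), ])
  for (r in c("rumen_only", "shared", "plate_only", "defined_only")) {
    expect_setequal(p1[[r]], p2[[r]])
  }
})

test_that("cultivable fraction reports the shared share of the rumen pool", {
  fx <- membership_fixture(c("A", "B", "C", "D"), c("A", "B"), c("B"))
  p <- partition_otus(fx$table, fx$metadata)
  expect_equal(cultivable_fraction(p), 0.5)

  # plates disjoint from rumen -> 0; plates covering rumen -> 1
  fx0 <- membership_fixture(c("A", "B"), c("X"), c("Y"))
  expect_equal(cultivable_fraction(partition_otus(fx0$table, fx0$metadata)), 0)
  fx1 <- membership_fixture(c("A", "B"), c("A", "B"), c("A"))
  expect_equal(cultivable_fraction(partition_otus(fx1$table, fx1$metadata)), 1)
})

test_that("the printed worked example truncates to a whole percent", {
  expect_equal(percent_value(686 / 2881), 23)
  expect_equal(percent_value(61 / 1698, digits = 1), 3.6)
  expect_equal(percent_value(0.5), 50)
})

test_that("medium gain equals unique OTUs over the other medium's richness", {
  set.seed(12)
  otus <- sprintf("o%03d", 1:300)
  defined <- sample(otus, 120)
  undefined <- sample(otus, 100)
  fx <- membership_fixture(sample(otus, 50), defined, undefined)
  p <- partition_otus(fx$table, fx$metadata)
  expect_equal(medium_gain(p, "defined"),
               length(setdiff(defined, undefined)) / length(undefined))
  expect_equal(medium_gain(p, "undefined"),
               length(setdiff(undefined, defined)) / length(defined))

  # added medium contributing nothing unique
  fx2 <- membership_fixture(c("A"), c("B", "C"), c("B", "C", "D"))
  expect_equal(medium_gain(partition_otus(fx2$table, fx2$metadata), "defined"), 0)
})

test_that("per-dilution shared proportions match brute-force recomputation", {
  b <- cached_bundle(7)
  tblf <- filter_low_count_otus(b$table)
  sh <- shared_per_dilution(tblf, b$metadata)
  expect_equal(nrow(sh), 12)  # 6 dilutions x 2 media

  for (i in sample(nrow(sh), 4)) {
    d <- sh$dilution_exponent[i]; m <- sh$medium[i]
    rumen_set <- detected_otus(tblf, sprintf("rumen_d%d", d))
    plate_ids <- b$metadata$sample_id[b$metadata$source == "plate" &
                                        b$metadata$medium == m &
                                        b$metadata$dilution_exponent == d]
    plate_set <- detected_otus(tblf, plate_ids)
    expect_equal(sh$proportion[i],
                 length(intersect(rumen_set, plate_set)) / length(rumen_set))
  }

  # plates detecting exactly the rumen OTUs give 1; disjoint sets give 0
  fx <- membership_fixture(c("A", "B"), c("A", "B"), c("X"))
  sh2 <- shared_per_dilution(fx$table, fx$metadata)
  expect_equal(sh2$proportion[sh2$medium == "defined"], 1)
  expect_equal(sh2$proportion[sh2$medium == "undefined"], 0)
})

test_that("rare biosphere is the plate-only complement of the shared set", {
  fx <- membership_fixture(c("A", "B", "C"), c("B", "D"), c("B", "C", "E"))
  p <- partition_otus(fx$table, fx$metadata)
  expect_setequal(rare_biosphere(p), c("D", "E"))

  fx2 <- membership_fixture(c("A", "B"), c("A"), c("B"))
  expect_length(rare_biosphere(partition_otus(fx2$table, fx2$metadata)), 0)

  b <- cached_bundle(7)
  p3 <- partition_otus(filter_low_count_otus(b$table), b$metadata)
  expect_equal(length(rare_biosphere(p3)) + length(p3$shared),
               length(p3$plates_all))
})

test_that("cultivable fraction never drops when plates are added", {
  b <- cached_bundle(7)
  tblf <- filter_low_count_otus(b$table)
  plate_ids <- b$metadata$sample_id[b$metadata$source == "plate"]
  some <- b$metadata |>
    dplyr::filter(source != "plate" | sample_id %in% plate_ids[1:8])
  sub_tbl <- tblf[, c("otu_id", some$sample_id)]
  f_small <- cultivable_fraction(partition_otus(sub_tbl, some))
  f_full <- cultivable_fraction(partition_otus(tblf, b$metadata))
  expect_lte(f_small, f_full)
})

test_that("deep-rare colonized taxa land in the rare biosphere unless chance-detected", {
  b <- cached_bundle(7)
  tblf <- filter_low_count_otus(b$table)
  p <- partition_otus(tblf, b$metadata)
  rumen_ids <- b$metadata$sample_id[b$metadata$source == "rumen"]
  # taxa whose expected reads are < 1 in every rumen sample but that were
  # detected on a plate
  expected_reads <- b$params$read_depth * b$truth$abundance[tblf$otu_id]
  plate_detected <- detected_otus(
    tblf, b$metadata$sample_id[b$metadata$source == "plate"])
  candidates <- intersect(tblf$otu_id[expected_reads < 1], plate_detected)
  expect_gt(length(candidates), 0)
  escaped <- setdiff(candidates, rare_biosphere(p))
  # any candidate not in the rare biosphere must have been detected in rumen
  rumen_detected <- detected_otus(tblf, rumen_ids)
  expect_true(all(escaped %in% rumen_detected))
})

test_that("cohort survey frequencies equal brute-force column scans", {
  cohort <- random_otu_tbl(12, 30, seed = 15, lambda = 0.3)
  otus <- c(cohort$otu_id[1:10], "ghost_otu")
  sv <- cohort_survey(otus, cohort)
  brute <- vapply(otus, function(o) {
    if (!o %in% cohort$otu_id) return(0L)
    sum(as.matrix(cohort[cohort$otu_id == o, -1]) >= 1)
  }, integer(1))
  expect_equal(sv$n_detected, unname(brute))
  expect_equal(sv$frequency, unname(brute) / 12)
  expect_equal(sv$frequency[sv$otu_id == "ghost_otu"], 0)

  everywhere <- make_otu_tbl(matrix(1, 1, 5), otu_ids = "omni")
  expect_equal(cohort_survey("omni", everywhere)$frequency, 1)
})
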