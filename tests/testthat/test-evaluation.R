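test_that("species-level splits keep every species in the reference set", {
  set.seed(1)
  sizes <- c(3, 6, 4, 1, 9, 12)
  ds <- barcode_dataset(
    accession = sprintf("R%03d", seq_len(sum(sizes))),
    species = rep(paste0("sp", seq_along(sizes)), sizes),
    sequence = vapply(seq_len(sum(sizes)), function(i) random_dna(60),
                      character(1)))
  plan <- species_level_split(ds, repetitions = 5, seed = 10)
  expect_length(plan$folds, 5L)
  for (f in plan$folds) {
    # disjoint cover
    expect_equal(sort(c(f$reference, f$query)), seq_len(nrow(ds)))
    expect_length(intersect(f$reference, f$query), 0L)
    # balanced coverage: every species in the reference set
    expect_setequal(unique(ds$species[f$reference]), unique(ds$species))
    # per-species counts follow the 2/3 rule
    ref_by_sp <- table(ds$species[f$reference])
    expect_equal(unname(ref_by_sp[paste0("sp", 1:6)]),
                 c(3, 4, 3, 1, 6, 8), ignore_attr = TRUE)
  }
  # repetitions differ (randomized membership) but are seed-reproducible
  expect_false(identical(plan$folds[[1]], plan$folds[[2]]))
  plan2 <- species_level_split(ds, repetitions = 5, seed = 10)
  expect_identical(plan$folds, plan2$folds)
})

test_that("k-fold splits partition records into near-equal query folds", {
  ds <- barcode_dataset(sprintf("R%03d", 1:766), rep("sp", 766),
                        rep("ACGT", 766))
  ds$species <- rep(paste0("sp", 1:20), length.out = 766)
  plan <- k_fold_split(ds, k = 5, seed = 3)
  sizes <- sort(vapply(plan$folds, function(f) length(f$query), integer(1)),
                decreasing = TRUE)
  expect_equal(sizes, c(154L, 153L, 153L, 153L, 153L))
  # each record queried exactly once across folds
  all_q <- unlist(lapply(plan$folds, function(f) f$query))
  expect_equal(sort(all_q), 1:766)
  for (f in plan$folds) {
    expect_equal(sort(c(f$reference, f$query)), 1:766)
  }
  # small cases
  ds10 <- barcode_dataset(paste0("r", 1:10), rep(c("a", "b"), 5),
                          replicate(10, random_dna(20)))
  expect_true(all(vapply(k_fold_split(ds10, 5, 1)$folds,
                         function(f) length(f$query), integer(1)) == 2L))
  ds3 <- ds10[1:3, ]; class(ds3) <- class(ds10)
  expect_equal(sort(vapply(k_fold_split(ds3, 2, 1)$folds,
                           function(f) length(f$query), integer(1))), c(1L, 2L))
  expect_error(k_fold_split(ds3, 5, 1), "exceeds")
})

test_that("success rate and its degenerate cases", {
  expect_equal(success_rate(1295, 1295), 1)
  expect_equal(success_rate(3, 4), 0.75)
  expect_equal(success_rate(0, 5), 0)
  expect_error(success_rate(1, 0), "undefined")
  expect_error(success_rate(5, 4))
})

test_that("Wilson intervals match the score-test inversion oracle", {
  for (n in c(5, 30, 135, 340, 1295)) {
    for (k in unique(c(0, 1, floor(n / 3), n - 1, n))) {
      got <- wilson_ci(k, n)
      want <- wilson_oracle(k, n)
      expect_equal(unname(got), unname(want), tolerance = 1e-10)
    }
  }
  # symmetry around 0.5 at p-hat = 0.5
  ci <- wilson_ci(500, 1000)
  expect_equal(ci[["lower"]] + ci[["upper"]], 1, tolerance = 1e-12)
  # lower bound nondecreasing in successes; width shrinks with n
  lows <- vapply(0:20, function(k) wilson_ci(k, 20)[["lower"]], numeric(1))
  expect_true(all(diff(lows) >= 0))
  w1 <- diff(wilson_ci(30, 40))
  w2 <- diff(wilson_ci(300, 400))
  expect_lt(w2, w1)
  expect_error(wilson_ci(1, 0))
})

test_that("percentages print truncated, not rounded", {
  expect_equal(format_percent_trunc(130 / 135), "96.29%")
  expect_equal(format_percent_trunc(1), "100.00%")
  expect_equal(format_percent_trunc(0.984075), "98.40%")
  expect_equal(format_percent_trunc(0), "0.00%")
  expect_error(format_percent_trunc(1.2))
})

test_that("identification pools folds, and excludes unrepresented queries", {
  # well-separated synthetic library: every query species in the reference
  ds <- simulate_barcodes(5, 8, 200, between_divergence = 0.2,
                          within_divergence = 0.001, seed = 21)
  plan <- species_level_split(ds, repetitions = 2, seed = 21)
  rep <- run_identification(ds, plan, encoder = "dv")
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$n_excluded_singletons, 0L)
  expect_equal(rep$success_rate, 1.0)
  expect_equal(rep$n_counted, nrow(rep$assignments))
  # pooled rate equals the weighted mean of per-fold rates
  by_fold <- split(rep$assignments$status, rep$assignments$fold)
  pooled <- sum(vapply(by_fold, function(s) sum(s == "correct"), numeric(1))) /
    sum(vapply(by_fold, length, numeric(1)))
  expect_equal(rep$success_rate, pooled)
  expect_true(rep$ci_lower <= rep$success_rate &&
                rep$success_rate <= rep$ci_upper)

  # a single-record species under k-fold must be excluded exactly once
  ds1 <- inject_singletons(ds, 1, seed = 5)
  plank <- k_fold_split(ds1, k = 5, seed = 8)
  repk <- run_identification(ds1, plank, encoder = "dv")
  excl <- repk$assignments[repk$assignments$status == "excluded_singleton", ]
  expect_equal(nrow(excl), 1L)
  expect_equal(excl$true_species, "Singleton_01")
  expect_equal(repk$n_counted, nrow(repk$assignments) - 1L)

  # report writers produce the documented artifacts
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_report(repk, jp, tp)
  js <- jsonlite::read_json(jp)
  expect_equal(js$n_counted, repk$n_counted)
  expect_equal(nrow(read.delim(tp)), nrow(repk$assignments))
})
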