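test_that("misclassification counting is per classifier, round and patient", {
  y <- c(1L, 0L, 1L, 0L)
  # classifier 1 always right; classifier 2 wrong on patient 3 in 15/20
  sc <- array(0, dim = c(2, 20, 4))
  for (r in 1:20) {
    sc[1, r, ] <- c(0.9, 0.1, 0.9, 0.1)
    sc[2, r, ] <- c(0.9, 0.1, if (r <= 15) 0.1 else 0.9, 0.1)
  }
  tensor <- toy_tensor(sc)
  cnt <- count_misclassifications(tensor, y, 0.5)
  expect_true(all(cnt["C1", ] == 0L))
  expect_equal(unname(cnt["C2", 3]), 15)
  expect_true(all(cnt >= 0 & cnt <= 20))

  # invariant to round order
  perm <- with_seed_test(1L, sample(20L))
  cnt2 <- count_misclassifications(toy_tensor(sc[, perm, , drop = FALSE]),
                                   y, 0.5)
  expect_equal(unclass(cnt), unclass(cnt2), ignore_attr = TRUE)
})

test_that("confounders require the round threshold for every classifier", {
  cnt <- matrix(c(15, 15, 15, 14,   # patient A: one classifier below 15
                  20, 20, 20, 20,   # patient B: flagged
                  15, 15, 15, 15,   # patient C: exactly at the boundary
                  3, 2, 0, 1), nrow = 4,
                dimnames = list(c("RF", "SVM", "XGB", "NB"),
                                c("A", "B", "C", "D")))
  counts <- structure(cnt, class = c("misclass_count", "matrix"),
                      n_rounds = 20L)
  expect_setequal(identify_confounders(counts), c("B", "C"))
  union_set <- identify_confounders(counts, require_all = FALSE)
  expect_setequal(union_set, c("A", "B", "C"))
  expect_true(all(identify_confounders(counts) %in% union_set))

  # lowering the threshold never shrinks the flagged set
  prev <- character()
  for (thr in 20:1) {
    cur <- identify_confounders(counts, round_threshold = thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }

  # non-20-round default follows the 75% rule
  c2 <- structure(cnt[, , drop = FALSE],
                  class = c("misclass_count", "matrix"), n_rounds = 16L)
  expect_setequal(identify_confounders(c2),  # ceiling(0.75*16) = 12
                  c("A", "B", "C"))
})

test_that("Cohen's kappa matches hand and brute-force computations", {
  a <- rep(c(0L, 0L, 1L, 1L), c(20L, 5L, 10L, 15L))
  b <- rep(c(0L, 1L, 0L, 1L), c(20L, 5L, 10L, 15L))
  expect_equal(cohens_kappa(a, b), 0.4)
  expect_equal(cohens_kappa(b, a), 0.4)

  expect_equal(cohens_kappa(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1.0)
  expect_equal(cohens_kappa(rep(1, 5), rep(1, 5)), 1.0) # p_e = p_o = 1
  expect_error(cohens_kappa(1:3, 1:4), "length")

  # exhaustive-style agreement with the contingency formula, length <= 12
  for (s in 1:200) {
    n <- with_seed_test(s, sample(1:12, 1))
    a <- with_seed_test(s * 3L, rbinom(n, 1, 0.5))
    b <- with_seed_test(s * 3L + 1L, rbinom(n, 1, 0.5))
    expect_equal(cohens_kappa(a, b), brute_kappa(a, b), tolerance = 1e-12)
  }
})

test_that("pairwise kappa aggregates per round with qualitative bands", {
  y <- rep(c(1L, 0L), each = 10L)
  sc <- with_seed_test(4L, array(runif(2 * 6 * 20), dim = c(2, 6, 20)))
  sc[2, , ] <- sc[1, , ]  # identical classifiers
  kt <- pairwise_kappa(toy_tensor(sc), y, 0.5)
  expect_identical(nrow(kt), 1L)
  expect_equal(kt$mean, 1.0)
  expect_equal(kt$sd, 0.0)
  expect_identical(kt$band, "great")

  expect_identical(idex:::kappa_band(0.75), "good")
  expect_identical(idex:::kappa_band(0.35), "poor")
  expect_identical(idex:::kappa_band(0.45), "moderate")
  expect_identical(idex:::kappa_band(-0.2), "none")
})

test_that("concordance tables are normalized percentages", {
  y <- rep(c(1L, 0L), each = 10L)
  sc <- with_seed_test(9L, array(runif(2 * 10 * 20), dim = c(2, 10, 20)))
  tensor <- toy_tensor(sc)
  ct <- concordance_table(tensor, y, 0.5, c("C1", "C2"))
  expect_equal(sum(ct$table), 100, tolerance = 1e-9)
  expect_true(all(ct$table >= 0))
  # independent uniform scores at threshold 0.5: all cells near 25%
  expect_true(all(abs(ct$table - 25) < 12))
  expect_equal(sum(ct$histogram), 20)  # patients per round

  sc[2, , ] <- sc[1, , ]
  ct2 <- concordance_table(toy_tensor(sc), y, 0.5, c("C1", "C2"))
  expect_equal(ct2$table[1, 2], 0)
  expect_equal(ct2$table[2, 1], 0)
})

test_that("iterate_consensus removes planted confounders and reports", {
  gen <- generate_cohort(strong_world_config(seed = 77L, n = 150L))
  specs <- default_model_specs(RF = list(n_trees = 40L),
                               XGB = list(n_estimators = 25L,
                                          max_depth = 3L),
                               SVM = list(max_sweeps = 10L))
  sel <- names(which(strong_effect_vector() != 0))
  rep <- iterate_consensus(gen$cohort, specs,
                           cv_plan(6L, 3L, master_seed = 2L),
                           n_iterations = 2L, selection = sel)
  expect_s3_class(rep, "consensus_report")
  expect_identical(rep$n_initial, 150L)

  # disjoint per-iteration removals; included = initial minus removed
  all_removed <- unlist(lapply(rep$iterations, `[[`, "confounding_ids"))
  expect_identical(anyDuplicated(all_removed), 0L)
  expect_setequal(c(rep$included_ids, all_removed),
                  gen$cohort$patient_ids)

  # per-class composition adds up
  for (it in rep$iterations)
    expect_identical(it$n_removed_ide + it$n_removed_non_ide,
                     length(it$confounding_ids))

  # some planted flips recovered even at this small scale
  expect_gt(length(intersect(rep$confounding_ids,
                             gen$truth$confounder_ids)), 0L)

  # serialization
  f <- tempfile(fileext = ".json")
  write_consensus_report(rep, f)
  back <- jsonlite::read_json(f)
  expect_identical(back$n_initial, 150L)
  expect_identical(length(back$included_ids), length(rep$included_ids))
  kcsv <- read.csv(paste0(f, ".kappa.csv"))
  expect_identical(nrow(kcsv), 6L)
  unlink(c(f, paste0(f, ".kappa.csv")))
})

test_that("zero iterations yields a baseline-only report", {
  gen <- generate_cohort(tiny_cohort(n = 40L))
  specs <- default_model_specs(RF = list(n_trees = 15L))[c("RF", "NB")]
  rep <- iterate_consensus(gen$cohort, specs,
                           cv_plan(2L, 2L, master_seed = 1L),
                           n_iterations = 0L, final_eval = FALSE)
  expect_length(rep$iterations, 0L)
  expect_identical(rep$confounding_ids, character())
  expect_setequal(rep$included_ids, gen$cohort$patient_ids)
  expect_null(rep$kappa_after)
})

test_that("removal bookkeeping identities", {
  rs <- removal_summary(486L, 59L)
  expect_identical(rs$n_retained, 427L)
  expect_equal(round(rs$percent_removed), 12)
  expect_error(removal_summary(10L, 11L), "n_removed")
})
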