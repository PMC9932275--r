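test_that("model specs carry the printed defaults and log overrides", {
  rf <- model_spec("RF")
  expect_identical(rf$hyperparameters$n_trees, 500L)
  expect_identical(rf$hyperparameters$min_leaf, 5L)

  xgb <- model_spec("XGB")
  expect_equal(xgb$hyperparameters[c("eta", "n_estimators", "max_depth",
                                     "min_child_weight", "subsample",
                                     "colsample_bytree")],
               list(eta = 0.1, n_estimators = 100L, max_depth = 5L,
                    min_child_weight = 2, subsample = 0.9,
                    colsample_bytree = 1.0))

  sv <- model_spec("SVM")
  expect_identical(sv$hyperparameters$gamma, "scale")

  ov <- model_spec("RF", n_trees = 10L)
  expect_identical(ov$overrides, list(n_trees = 10L))
  expect_error(model_spec("RF", trees = 10), "unknown hyperparameter")
  expect_error(model_spec("LDA"), "arg")

  specs <- default_model_specs()
  expect_identical(names(specs), c("RF", "SVM", "XGB", "NB"))
})

test_that("all four families separate a linearly separable toy", {
  n <- 100L
  x <- with_seed_test(8L, cbind(a = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
                                b = rnorm(n)))
  y <- rep(c(0L, 1L), each = n / 2)
  for (fam in c("RF", "SVM", "XGB", "NB")) {
    spec <- if (fam == "RF") model_spec(fam, n_trees = 100L)
            else model_spec(fam)
    factory <- make_model(spec)
    m <- factory$fit(x, y, seed = 1L)
    sc <- factory$score(m, x)
    expect_true(all(sc >= 0 & sc <= 1), label = fam)
    if (fam %in% c("RF", "XGB"))
      expect_equal(mean((sc > 0.5) == (y == 1L)), 1.0, label = fam)
    else
      expect_gte(mean((sc > 0.5) == (y == 1L)), 0.95)
  }
  expect_error(fit_model(model_spec("NB"), x, rep(0L, n)), "single-class")
})

test_that("repeated CV scores every patient once per round, shared folds", {
  gen <- generate_cohort(tiny_cohort(n = 30L))
  em <- impute(encode(gen$cohort))
  specs <- default_model_specs(RF = list(n_trees = 20L),
                               XGB = list(n_estimators = 10L,
                                          max_depth = 2L),
                               SVM = list(max_sweeps = 10L))
  plan <- cv_plan(n_rounds = 2L, n_folds = 2L, master_seed = 5L)
  tensor <- run_repeated_cv(em$x, gen$cohort$labels, specs, plan)
  expect_false(anyNA(tensor$scores))
  expect_true(all(tensor$scores >= 0 & tensor$scores <= 1))
  expect_identical(dim(tensor$scores), c(4L, 2L, 30L))

  # one fold split per round, shared by construction across classifiers,
  # stratified to within one patient per class
  y <- gen$cohort$labels
  for (r in 1:2) {
    fold <- tensor$folds[r, ]
    for (cl in 0:1) {
      counts <- table(fold[y == cl])
      expect_lte(max(counts) - min(counts), 1)
    }
  }

  # determinism under the master seed
  tensor2 <- run_repeated_cv(em$x, gen$cohort$labels, specs, plan)
  expect_identical(tensor$scores, tensor2$scores)

  # fixed feature subset is honoured and recorded
  t3 <- run_repeated_cv(em$x, y, specs["NB"], plan,
                        selection = c("age", "diameter"))
  expect_identical(t3$selected[[1]][[1]], c("age", "diameter"))

  f <- tempfile(fileext = ".csv")
  write_score_tensor(tensor, f)
  df <- read.csv(f)
  expect_identical(nrow(df), 4L * 2L * 30L)
  got <- df$score[df$classifier == "NB" & df$round == 2L]
  expect_equal(got, unname(tensor$scores["NB", 2, ]))
  unlink(f)
})

test_that("rank AUC equals the brute-force pairwise AUC", {
  for (s in 1:10) {
    n <- with_seed_test(s, sample(20:200, 1))
    y <- with_seed_test(s + 1, rbinom(n, 1, 0.4))
    if (length(unique(y)) < 2) next
    sc <- with_seed_test(s + 2, round(runif(n), 2)) # ties likely
    expect_equal(auc_score(sc, y), brute_auc(sc, y), tolerance = 1e-12)
  }
  expect_equal(auc_score(c(0, 1, 0, 1), c(1, 0, 1, 0)), 0) # anti-perfect
  expect_true(is.na(auc_score(c(0.3, 0.4), c(1, 1))))
})

test_that("performance metrics follow the threshold rule", {
  y <- rep(c(1L, 0L), c(6L, 14L))
  perfect <- array(rep(y, each = 3), dim = c(1, 3, 20))
  tensor <- toy_tensor(perfect)
  perf <- compute_performance(tensor, y, 0.29)
  m <- perf$per_round$C1
  expect_true(all(m == 1))

  # constant 0.5 scores, threshold 0.29: everyone called IDE
  flat <- toy_tensor(array(0.5, dim = c(1, 2, 20)))
  pf <- compute_performance(flat, y, 0.29)
  expect_equal(unname(pf$per_round$C1[1, "sensitivity"]), 1.0)
  expect_equal(unname(pf$per_round$C1[1, "specificity"]), 0.0)

  # permutation invariance of per-round metrics
  perm <- with_seed_test(3L, sample(20L))
  shuf <- toy_tensor(perfect[, , perm, drop = FALSE])
  pp <- compute_performance(shuf, y[perm], 0.29)
  expect_equal(pp$per_round$C1, perf$per_round$C1)

  # undefined metrics are NA, not zero
  y1 <- rep(1L, 20)
  t1 <- toy_tensor(array(0.9, dim = c(1, 1, 20)))
  p1 <- compute_performance(t1, y1, 0.5)
  expect_true(is.na(p1$per_round$C1[1, "specificity"]))
  expect_true(is.na(p1$per_round$C1[1, "auc"]))
  expect_equal(unname(p1$per_round$C1[1, "sensitivity"]), 1.0)
})

test_that("single-class training folds fail with a located error", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("P", 1:6), NULL))
  y <- c(1L, 0L, 0L, 0L, 0L, 0L)
  expect_error(
    run_repeated_cv(x, y, default_model_specs()["NB"],
                    cv_plan(1L, 3L, stratified = FALSE, master_seed = 42L)),
    "round .* fold|single-class")
})
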