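test_that("base value is the weighted mean prediction over the background", {
  bg <- random_background(3L, 8L, 1L)
  const <- function(x) rep(0.42, nrow(x))
  expect_equal(base_value(const, bg), 0.42)

  ident <- function(x) x[, 1]
  bg2 <- background_set(matrix(c(0.2, 0.8), 2, 1,
                               dimnames = list(NULL, "f1")))
  expect_equal(base_value(ident, bg2), 0.5)

  # duplicating rows with halved weights changes nothing
  rows <- bg$rows
  dup <- background_set(rbind(rows, rows),
                        weights = rep(bg$weights / 2, 2))
  lin <- random_linear_model(3L, 2L)
  expect_equal(base_value(lin, dup), base_value(lin, bg))

  expect_error(background_set(matrix(0, 0, 2)), "empty")
  expect_error(background_set(matrix(0, 2, 2), weights = c(-1, 2)),
               "weights")
})

test_that("exact Shapley values satisfy the axioms", {
  for (s in 1:25) {
    M <- with_seed_test(s, sample(3:7, 1))
    bg <- random_background(M, 6L, s + 50L)
    x <- with_seed_test(s + 100L, rnorm(M))
    names(x) <- colnames(bg$rows)
    f1 <- random_nonlinear_model(M, s)
    e1 <- exact_shapley(f1, x, bg)

    # efficiency / local accuracy
    expect_equal(e1$base_value + sum(e1$phi), e1$model_score,
                 tolerance = 1e-9)

    # dummy: a model ignoring feature M gives it phi 0
    fdrop <- function(x) f1(cbind(x[, -M, drop = FALSE], 0))
    ed <- exact_shapley(fdrop, x, bg)
    expect_equal(unname(ed$phi[M]), 0, tolerance = 1e-12)

    # linearity: phi(a f1 + b f2) = a phi(f1) + b phi(f2)
    f2 <- random_linear_model(M, s + 7L)
    fc <- function(x) 2 * f1(x) - 0.5 * f2(x)
    expect_equal(exact_shapley(fc, x, bg)$phi,
                 2 * e1$phi - 0.5 * exact_shapley(f2, x, bg)$phi,
                 tolerance = 1e-9)
  }

  # symmetry: two features entering identically with equal values
  fsym <- function(x) plogis(x[, 1] + x[, 2] + 0.5 * x[, 3])
  rows <- with_seed_test(5L, matrix(rnorm(15), 5, 3))
  rows[, 2] <- rows[, 1]
  colnames(rows) <- paste0("f", 1:3)
  bg <- background_set(rows)
  x <- c(f1 = 0.7, f2 = 0.7, f3 = -0.2)
  es <- exact_shapley(fsym, x, bg)
  expect_equal(unname(es$phi[1]), unname(es$phi[2]), tolerance = 1e-12)

  # additive closed form: phi_j = x_j - mean(background_j)
  fadd <- function(x) rowSums(x)
  ea <- exact_shapley(fadd, x, bg)
  expect_equal(ea$phi, x - colMeans(bg$rows), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(exact_shapley(fadd, rnorm(20), random_background(20, 3, 1)),
               "exact limit")
})

test_that("kernel mode with full enumeration equals exact enumeration", {
  for (s in 1:30) {
    M <- with_seed_test(s, sample(2:10, 1))
    bg <- random_background(M, 5L, s + 30L)
    x <- with_seed_test(s + 60L, rnorm(M))
    names(x) <- colnames(bg$rows)
    f <- random_nonlinear_model(M, s + 5L)
    ee <- exact_shapley(f, x, bg)
    ek <- kernel_shap(f, x, bg, "full")
    expect_lt(max(abs(ee$phi - ek$phi)), 1e-6)
    expect_equal(ek$base_value + sum(ek$phi), ek$model_score,
                 tolerance = 1e-6)
  }
  expect_error(kernel_shap(random_linear_model(6L, 1L),
                           setNames(rnorm(6), paste0("f", 1:6)),
                           random_background(6L, 4L, 2L),
                           n_coalitions = 5L), "M \\+ 2")
})

test_that("sampled kernel mode converges to the exact values", {
  M <- 8L
  bg <- random_background(M, 6L, 11L)
  x <- with_seed_test(12L, rnorm(M)); names(x) <- colnames(bg$rows)
  f <- random_nonlinear_model(M, 13L)
  exact <- exact_shapley(f, x, bg)$phi
  err <- vapply(c(24L, 64L, 160L), function(nc) {
    e <- vapply(1:8, function(s)
      max(abs(kernel_shap(f, x, bg, nc, seed = s)$phi - exact)), 0.0)
    mean(e)
  }, 0.0)
  expect_true(all(diff(err) < 0))         # decreasing mean max-error
  full <- kernel_shap(f, x, bg, 2^M)      # budget >= 2^M falls back to full
  expect_lt(max(abs(full$phi - exact)), 1e-6)
})

test_that("explanations are deterministic and per-row independent", {
  M <- 5L
  train <- with_seed_test(21L, matrix(rnorm(40 * M), 40, M,
                                      dimnames = list(NULL,
                                                      paste0("f", 1:M))))
  test <- with_seed_test(22L, matrix(rnorm(3 * M), 3, M,
                                     dimnames = list(paste0("T", 1:3),
                                                     paste0("f", 1:M))))
  f <- random_nonlinear_model(M, 23L)
  e1 <- explain_patients(f, train, test, method = "exact", bg_k = 10L,
                         seed = 2L)
  e2 <- explain_patients(f, train, test, method = "exact", bg_k = 10L,
                         seed = 2L)
  expect_equal(e1, e2)
  expect_identical(vapply(e1, `[[`, "", "patient_id"), rownames(test))

  # permuting test rows permutes the outputs
  e3 <- explain_patients(f, train, test[c(3, 1, 2), ], method = "exact",
                         bg_k = 10L, seed = 2L)
  expect_equal(e3[[2]]$phi, e1[[1]]$phi)

  # constant model: all-zero attributions
  e0 <- explain_patients(function(x) rep(0.3, nrow(x)), train,
                         test[1, , drop = FALSE], method = "exact")
  expect_equal(unname(e0[[1]]$phi), rep(0, M))

  colnames(test) <- paste0("g", 1:M)
  expect_error(explain_patients(f, train, test), "different features")
})

test_that("positive phi means the feature pushed the score up", {
  # additive model, instance above the background mean on f1, below on f2
  train <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("f1", "f2")))
  f <- function(x) x[, 1] + x[, 2]
  x <- rbind(c(f1 = mean(train[, 1]) + 2, f2 = mean(train[, 2]) - 1))
  e <- explain_patients(f, train, x, method = "exact", bg_k = nrow(train))
  expect_gt(e[[1]]$phi["f1"], 0)
  expect_lt(e[[1]]$phi["f2"], 0)
  expect_equal(e[[1]]$base_value + sum(e[[1]]$phi), e[[1]]$model_score,
               tolerance = 1e-9)
})

test_that("global summary ranks by mean absolute phi", {
  # additive model with distinct coefficient x sd products
  M <- 4L
  coefs <- c(4, -2, 1, 0)
  train <- with_seed_test(31L, matrix(rnorm(120 * M), 120, M,
                                      dimnames = list(NULL,
                                                      paste0("f", 1:M))))
  f <- function(x) drop(x %*% coefs)
  test <- train[1:30, ]
  rownames(test) <- sprintf("T%02d", 1:30)
  ex <- explain_patients(f, train, test, method = "exact",
                         bg_k = nrow(train))
  gs <- global_summary(ex, test)
  expect_identical(gs$ranking$feature, c("f1", "f2", "f3", "f4"))
  expect_true(all(diff(gs$ranking$mean_abs_phi) <= 0))
  expect_setequal(gs$ranking$rank, 1:4)
  expect_equal(gs$ranking$mean_abs_phi[4], 0)  # zero-coefficient feature

  expect_identical(nrow(gs$beeswarm), 30L * 4L)
  expect_true(all(c("patient_id", "feature", "phi", "value") %in%
                    names(gs$beeswarm)))

  f <- tempfile(fileext = ".csv")
  write_explanations(ex, f, test)
  df <- read.csv(f)
  expect_identical(nrow(df), 120L)
  p1 <- df[df$patient_id == df$patient_id[1], ]
  expect_equal(p1$base_value[1] + sum(p1$phi), p1$model_score[1],
               tolerance = 1e-8)
  unlink(f)
})

test_that("confounder explanations use included patients as training set", {
  run <- list()
  gen <- generate_cohort(strong_world_config(seed = 55L, n = 120L))
  sel <- names(which(strong_effect_vector() != 0))
  # a synthetic consensus report: flag ten known patients
  flagged <- gen$cohort$patient_ids[1:10]
  rep <- structure(list(
    iterations = list(), confounding_ids = flagged,
    included_ids = setdiff(gen$cohort$patient_ids, flagged),
    n_initial = 120L, threshold = 0.5), class = "consensus_report")
  ex <- explain_confounders(rep, gen$cohort,
                            model_spec("XGB", n_estimators = 20L,
                                       max_depth = 3L),
                            method = "exact", features = sel, bg_k = 15L)
  expect_length(ex, 10L)
  expect_identical(vapply(ex, `[[`, "", "patient_id"), flagged)
  for (e in ex)
    expect_equal(e$base_value + sum(e$phi), e$model_score,
                 tolerance = 1e-6)

  none <- rep; none$confounding_ids <- character()
  expect_identical(explain_confounders(none, gen$cohort), list())
  bad <- rep; bad$included_ids <- character()
  expect_error(explain_confounders(bad, gen$cohort), "included")
})
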