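#' Classifier specification
#'
#' Builds a `model_spec` for one of the four classifier families with the
#' pipeline's fixed defaults:
#' \describe{
#'   \item{RF}{random forest, 500 trees, minimum 5 observations per leaf,
#'     `mtry = floor(sqrt(p))`.}
#'   \item{XGB}{gradient boosted trees, `eta = 0.1`, `n_estimators = 100`,
#'     `max_depth = 5`, `min_child_weight = 2`, `subsample = 0.9`,
#'     `colsample_bytree = 1.0`, logistic objective returning class
#'     probabilities.}
#'   \item{SVM}{C-SVC with radial basis kernel, `C = 1`,
#'     `gamma = "scale"` (1 / (p * var)); features standardized internally;
#'     decision values mapped to \[0, 1\] by Platt calibration fit on the
#'     training fold so one shared probability threshold applies to all
#'     families.}
#'   \item{NB}{Gaussian naive Bayes on the encoded numeric columns with a
#'     relative variance floor of 1e-9.}
#' }
#' Any override of a default is recorded in the spec's `overrides` field.
#'
#' @param family One of `"RF"`, `"SVM"`, `"XGB"`, `"NB"`.
#' @param ... Named hyperparameter overrides.
#' @return A `model_spec`.
#' @export
model_spec <- function(family = c("RF", "SVM", "XGB", "NB"), ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    RF  = list(n_trees = 500L, min_leaf = 5L, mtry = NA_integer_,
               max_depth = 0L),
    XGB = list(eta = 0.1, n_estimators = 100L, max_depth = 5L,
               min_child_weight = 2, subsample = 0.9,
               colsample_bytree = 1.0),
    SVM = list(C = 1, gamma = "scale", tol = 1e-3, max_sweeps = 200L,
               calibrate = TRUE),
    NB  = list(var_smoothing = 1e-9))
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop_idex("unknown hyperparameter(s) for %s: %s", family,
              paste(bad, collapse = ", "))
  structure(list(family = family,
                 hyperparameters = modifyList(defaults, overrides),
                 overrides = overrides),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(sprintf("%s=%s", names(x$hyperparameters),
                      vapply(x$hyperparameters, format, "")),
              collapse = ", ")
  cat(sprintf("<model_spec> %s (%s)\n", x$family, hp))
  invisible(x)
}

#' Default four-classifier ensemble
#' @param ... Per-family override lists, e.g. `RF = list(n_trees = 100)`.
#' @return Named list of four [model_spec] objects (RF, SVM, XGB, NB).
#' @export
default_model_specs <- function(...) {
  ov <- list(...)
  specs <- lapply(c("RF", "SVM", "XGB", "NB"), function(f)
    do.call(model_spec, c(list(family = f), ov[[f]] %||% list())))
  names(specs) <- c("RF", "SVM", "XGB", "NB")
  specs
}

#' Model factory
#'
#' Returns a factory closure for the spec's family exposing
#' `fit(x, y, seed)` -> fitted model and, on the fitted model,
#' `score(model, x)` -> IDE-class score in \[0, 1\]
#' (see [fit_model()] / [score_model()] for the functional interface).
#'
#' @param spec A [model_spec].
#' @return List with functions `fit` and `score`.
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  list(fit = function(x, y, seed = 1L) fit_model(spec, x, y, seed),
       score = function(model, x) score_model(model, x))
}

#' Fit one classifier
#' @param spec A [model_spec].
#' @param x Numeric matrix (no missing values).
#' @param y Binary 0/1 labels.
#' @param seed Integer seed for any internal randomness.
#' @return An `idex_model`.
#' @export
fit_model <- function(spec, x, y, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_idex("training labels are single-class")
  if (anyNA(x)) stop_idex("training matrix contains missing values")
  hp <- spec$hyperparameters
  fitted <- switch(spec$family,
    RF = {
      mtry <- hp$mtry
      if (is.na(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
      fit <- .rf_fit_cpp(x, y, as.integer(hp$n_trees), as.integer(mtry),
                         as.integer(hp$min_leaf), as.integer(hp$max_depth),
                         as.integer(seed))
      list(trees = fit$trees,
           importance = setNames(fit$importance, colnames(x)))
    },
    XGB = .gbt_fit_cpp(x, y, as.integer(hp$n_estimators), hp$eta,
                       as.integer(hp$max_depth), hp$min_child_weight,
                       hp$subsample, hp$colsample_bytree, as.integer(seed)),
    SVM = fit_svm(x, y, hp, seed),
    NB = fit_nb(x, y, hp))
  structure(list(family = spec$family, spec = spec, fitted = fitted,
                 features = colnames(x)),
            class = "idex_model")
}

#' Score patients with a fitted classifier
#' @param model An `idex_model`.
#' @param x Numeric matrix with the model's training columns.
#' @return Numeric vector of IDE-class scores in \[0, 1\].
#' @export
score_model <- function(model, x) {
  stopifnot(inherits(model, "idex_model"))
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.null(model$features) && !is.null(colnames(x))) {
    if (!all(model$features %in% colnames(x)))
      stop_idex("scoring matrix lacks training features")
    x <- x[, model$features, drop = FALSE]
  }
  storage.mode(x) <- "double"
  out <- switch(model$family,
    RF = .rf_predict_cpp(model$fitted$trees, x),
    XGB = .gbt_predict_cpp(model$fitted$trees, x),
    SVM = score_svm(model$fitted, x),
    NB = score_nb(model$fitted, x))
  pmin(pmax(out, 0), 1)
}

#' @export
predict.idex_model <- function(object, newdata, ...) {
  score_model(object, newdata)
}

#' Feature importance of a fitted random forest
#' @param model An `idex_model` of family RF.
#' @return Named vector of mean-decrease-in-impurity importances.
#' @export
rf_importance <- function(model) {
  stopifnot(inherits(model, "idex_model"), model$family == "RF")
  model$fitted$importance
}

## ---- SVM (standardize -> SMO -> Platt calibration) ----

fit_svm <- function(x, y, hp, seed) {
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  xs <- scale(x, center, scl)
  gamma <- hp$gamma
  if (identical(gamma, "scale")) {
    v <- mean(apply(xs, 2, var))
    gamma <- 1 / (ncol(xs) * max(v, 1e-12))
  }
  ypm <- ifelse(y == 1L, 1, -1)
  fit <- .svm_fit_cpp(xs, ypm, hp$C, gamma, hp$tol,
                      as.integer(hp$max_sweeps), as.integer(seed))
  dec <- .svm_decision_cpp(fit$sv, fit$coef, fit$b, fit$gamma, xs)
  platt <- if (isTRUE(hp$calibrate)) fit_platt(dec, y) else NULL
  list(svm = fit, center = center, scale = scl, platt = platt)
}

score_svm <- function(fitted, x) {
  xs <- scale(x, fitted$center, fitted$scale)
  dec <- .svm_decision_cpp(fitted$svm$sv, fitted$svm$coef, fitted$svm$b,
                           fitted$svm$gamma, xs)
  if (is.null(fitted$platt)) plogis(dec)
  else plogis(-(fitted$platt$A * dec + fitted$platt$B))
}

# Platt 2000 sigmoid fit with smoothed targets, Newton iterations
fit_platt <- function(dec, y, max_iter = 100L) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  t <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  for (it in seq_len(max_iter)) {
    z <- A * dec + B
    p <- plogis(-z)               # P(y=1) = 1/(1+exp(A*d+B))
    # (p - t) is minus the NLL gradient in z, so the solve below is the
    # standard Newton step A <- A - H^{-1} grad
    w <- p * (1 - p)
    gA <- sum(dec * (p - t)); gB <- sum(p - t)
    hAA <- sum(dec * dec * w) + 1e-12
    hAB <- sum(dec * w)
    hBB <- sum(w) + 1e-12
    det <- hAA * hBB - hAB * hAB
    if (!is.finite(det) || abs(det) < 1e-12) break
    dA <- (hBB * gA - hAB * gB) / det
    dB <- (hAA * gB - hAB * gA) / det
    A <- A + dA; B <- B + dB
    if (max(abs(dA), abs(dB)) < 1e-10) break
  }
  list(A = A, B = B)
}

## ---- Gaussian naive Bayes ----

fit_nb <- function(x, y, hp) {
  classes <- c(0L, 1L)
  eps <- hp$var_smoothing * max(apply(x, 2, var), 1e-12)
  stats <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    v <- apply(xc, 2, var)
    v[!is.finite(v)] <- 0 # single-observation class
    list(mean = colMeans(xc),
         var = v + eps,
         prior = nrow(xc) / nrow(x))
  })
  names(stats) <- as.character(classes)
  stats
}

score_nb <- function(fitted, x) {
  loglik <- function(st) {
    rowSums(dnorm(x, rep(st$mean, each = nrow(x)),
                  rep(sqrt(st$var), each = nrow(x)), log = TRUE)) +
      log(st$prior)
  }
  l0 <- loglik(fitted[["0"]]); l1 <- loglik(fitted[["1"]])
  plogis(l1 - l0)
}
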