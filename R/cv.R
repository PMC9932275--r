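#' Repeated stratified cross-validation plan
#'
#' @param n_rounds Number of repeated rounds (default 20).
#' @param n_folds Folds per round (default 5).
#' @param stratified Stratify folds by class (default TRUE); per-fold
#'   prevalence is then within one patient of the cohort prevalence.
#' @param master_seed Integer; round `r` draws its fold split with seed
#'   `master_seed + r`, so rounds are independent but reproducible.
#' @return A `cv_plan`.
#' @export
cv_plan <- function(n_rounds = 20L, n_folds = 5L, stratified = TRUE,
                    master_seed = 1L) {
  if (n_rounds < 1L || n_folds < 2L)
    stop_idex("need n_rounds >= 1 and n_folds >= 2")
  structure(list(n_rounds = as.integer(n_rounds),
                 n_folds = as.integer(n_folds),
                 stratified = isTRUE(stratified),
                 master_seed = as.integer(master_seed)),
            class = "cv_plan")
}

# fold assignment for one round: vector of fold ids 1..n_folds
make_folds <- function(y, n_folds, stratified, seed) {
  n <- length(y)
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(n_folds), n)
    }
    fold
  })
}

#' Run the four-classifier repeated cross-validation engine
#'
#' For each round one stratified fold split is drawn and shared by all
#' classifiers; on each training fold, features are optionally selected
#' (nested Boruta or a fixed set), every classifier is fitted on the
#' selected features, and the held-out fold is scored. Every patient is
#' scored exactly once per classifier per round.
#'
#' @param x Numeric feature matrix with patient ids as row names (output of
#'   [encode()] + [impute()], i.e. `em$x`).
#' @param y Binary 0/1 labels aligned with `x`.
#' @param specs Named list of [model_spec] objects.
#' @param plan A [cv_plan].
#' @param selection `NULL` (use all features), a character vector of feature
#'   names (fixed set), or a list of [boruta_select()] arguments (nested
#'   per-training-fold selection), e.g. `list(alpha = 0.01)`.
#' @return A `score_tensor`: `scores` array `[classifier, round, patient]`,
#'   `folds` matrix `[round, patient]`, `selected` list of per-(round, fold)
#'   feature sets, plus `classifiers`, `patient_ids`, `plan`.
#' @export
run_repeated_cv <- function(x, y, specs = default_model_specs(),
                            plan = cv_plan(), selection = NULL) {
  if (!is.matrix(x)) stop_idex("x must be a matrix (see encode()/impute())")
  if (anyNA(x)) stop_idex("x contains missing values; impute() first")
  y <- as.integer(y)
  n <- nrow(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  ids <- rownames(x) %||% sprintf("P%04d", seq_len(n))
  cls <- names(specs)
  if (is.null(cls)) stop_idex("specs must be a named list")
  scores <- array(NA_real_,
                  dim = c(length(cls), plan$n_rounds, n),
                  dimnames = list(cls, NULL, ids))
  folds <- matrix(NA_integer_, plan$n_rounds, n,
                  dimnames = list(NULL, ids))
  selected <- vector("list", plan$n_rounds)

  fixed_set <- if (is.character(selection)) selection else NULL
  nested <- is.list(selection) && !is.character(selection)

  for (r in seq_len(plan$n_rounds)) {
    fold <- make_folds(y, plan$n_folds, plan$stratified,
                       plan$master_seed + r)
    folds[r, ] <- fold
    selected[[r]] <- vector("list", plan$n_folds)
    for (f in seq_len(plan$n_folds)) {
      test <- fold == f
      ytr <- y[!test]
      if (length(unique(ytr)) < 2L || length(unique(y[test])) < 1L)
        stop_idex("round %d fold %d: training fold is single-class", r, f)
      feats <- colnames(x)
      if (!is.null(fixed_set)) {
        feats <- intersect(colnames(x), fixed_set)
      } else if (nested) {
        args <- c(list(x = x[!test, , drop = FALSE], y = ytr,
                       seed = derive_seed(plan$master_seed, r * 100L + f)),
                  selection)
        br <- do.call(boruta_select, args)
        feats <- br$confirmed
        if (length(feats) == 0L) feats <- colnames(x) # degenerate fallback
      }
      selected[[r]][[f]] <- feats
      xtr <- x[!test, feats, drop = FALSE]
      xte <- x[test, feats, drop = FALSE]
      for (k in seq_along(cls)) {
        m <- fit_model(specs[[k]], xtr, ytr,
                       seed = derive_seed(plan$master_seed,
                                          r * 1000L + f * 10L + k))
        scores[k, r, test] <- score_model(m, xte)
      }
    }
  }
  structure(list(scores = scores, folds = folds, selected = selected,
                 classifiers = cls, patient_ids = ids, plan = plan),
            class = "score_tensor")
}

#' @export
print.score_tensor <- function(x, ...) {
  cat(sprintf("<score_tensor> %d classifiers x %d rounds x %d patients\n",
              dim(x$scores)[1], dim(x$scores)[2], dim(x$scores)[3]))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with ties counted one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @return AUC in \[0, 1\], or `NA` if a class is absent.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_metrics <- function(pred, labels) {
  tp <- sum(pred == 1L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  c(accuracy = (tp + tn) / length(labels), sensitivity = sens,
    specificity = spec, f1 = f1)
}

#' Per-round performance distributions
#'
#' For each classifier and round, hard labels are derived from the
#' out-of-fold scores via the decision threshold (`score > value`) and
#' accuracy, sensitivity, specificity and F1 are computed, together with the
#' threshold-free AUC of the round's scores. Undefined metrics (an absent
#' class) are recorded as `NA`, never as 0.
#'
#' @param tensor A `score_tensor`.
#' @param labels Binary 0/1 labels aligned with the tensor's patients.
#' @param threshold A [prevalence_threshold()] result or a plain number.
#' @return A `performance_distribution`: list per classifier of a
#'   `n_rounds` x 5 metric matrix, plus a `summary` data frame with per-
#'   classifier median and mean +/- sd per metric.
#' @export
compute_performance <- function(tensor, labels, threshold) {
  stopifnot(inherits(tensor, "score_tensor"))
  labels <- as.integer(labels)
  if (anyNA(tensor$scores)) stop_idex("score tensor has unfilled cells")
  metrics <- c("auc", "accuracy", "sensitivity", "specificity", "f1")
  out <- lapply(tensor$classifiers, function(cl) {
    m <- matrix(NA_real_, tensor$plan$n_rounds, length(metrics),
                dimnames = list(NULL, metrics))
    for (r in seq_len(tensor$plan$n_rounds)) {
      sc <- tensor$scores[cl, r, ]
      pred <- hard_labels(sc, threshold)
      m[r, "auc"] <- auc_score(sc, labels)
      m[r, -1] <- binary_metrics(pred, labels)
    }
    m
  })
  names(out) <- tensor$classifiers
  summ <- do.call(rbind, lapply(tensor$classifiers, function(cl) {
    m <- out[[cl]]
    data.frame(classifier = cl, metric = metrics,
               median = apply(m, 2, median, na.rm = TRUE),
               mean = colMeans(m, na.rm = TRUE),
               sd = apply(m, 2, sd, na.rm = TRUE),
               row.names = NULL)
  }))
  structure(list(per_round = out, summary = summ,
                 threshold = threshold_value(threshold)),
            class = "performance_distribution")
}

#' @export
print.performance_distribution <- function(x, ...) {
  cat("<performance_distribution>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Export a score tensor as tidy CSV
#' @param tensor A `score_tensor`.
#' @param path CSV path (classifier, round, patient_id, fold, score).
#' @return `path`, invisibly.
#' @export
write_score_tensor <- function(tensor, path) {
  d <- dim(tensor$scores)
  df <- expand.grid(classifier = tensor$classifiers,
                    round = seq_len(d[2]),
                    patient_id = tensor$patient_ids,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$fold <- tensor$folds[cbind(df$round, match(df$patient_id,
                                                tensor$patient_ids))]
  df$score <- as.vector(tensor$scores)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(classifiers = tensor$classifiers,
         n_rounds = tensor$plan$n_rounds,
         n_folds = tensor$plan$n_folds,
         stratified = tensor$plan$stratified,
         master_seed = tensor$plan$master_seed,
         n_patients = length(tensor$patient_ids)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
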