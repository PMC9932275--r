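#' Boruta-style all-relevant feature selection
#'
#' Iteratively compares each real feature's random-forest importance with
#' that of shadow features (independently permuted copies of the remaining
#' real features). In each iteration a feature scores a *hit* when its
#' mean-decrease-in-impurity importance exceeds the maximum shadow
#' importance; hits are tested against Binomial(n, 0.5) two-sidedly at level
#' `alpha` with Bonferroni correction over the features still undecided:
#' significantly more hits than chance confirms a feature, significantly
#' fewer rejects it (rejected features and their shadows are dropped from
#' subsequent iterations). The loop stops when no feature is left undecided
#' or after `max_iterations`; still-undecided features remain tentative.
#'
#' @param x Numeric feature matrix.
#' @param y Binary 0/1 labels.
#' @param max_iterations Maximum Boruta iterations (default 100).
#' @param alpha Test level before Bonferroni correction (default 0.01).
#' @param n_trees Trees in each internal forest (default 100; smaller than
#'   the classification forest because only the importance ranking matters).
#' @param importance Importance measure the shadow comparison uses:
#'   `"mda_z"` (default) is the across-tree z-score of the out-of-bag
#'   permutation accuracy drop; `"mdi"` is mean decrease in impurity. MDI
#'   rewards in-bootstrap overfitting and lets the per-dataset luckiest
#'   noise feature beat fresh shadows persistently, inflating false
#'   confirmations under the null, so the OOB measure is the default.
#' @param seed Integer seed.
#' @return A `boruta_result`: `confirmed`, `rejected`, `tentative` (a
#'   partition of `colnames(x)`), `hit_counts`, `n_iterations_run`.
#' @export
boruta_select <- function(x, y, max_iterations = 100L, alpha = 0.01,
                          n_trees = 100L,
                          importance = c("mda_z", "mdi"), seed = 1L) {
  importance <- match.arg(importance)
  if (!is.matrix(x) || ncol(x) < 2L) stop_idex("need a matrix with >= 2 features")
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop_idex("y is single-class")
  feats <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
  colnames(x) <- feats
  state <- setNames(rep("tentative", length(feats)), feats)
  hits <- setNames(integer(length(feats)), feats)
  n_done <- 0L

  with_seed(seed, {
    for (it in seq_len(max_iterations)) {
      open <- names(state)[state == "tentative"]
      if (length(open) == 0L) break
      n_done <- it
      # confirmed features stay in the forest (they keep competing for
      # splits); only rejected ones and their shadows are removed
      active <- names(state)[state != "rejected"]
      xs <- x[, active, drop = FALSE]
      # at least 5 shadows: with few active features the max-shadow bar
      # would otherwise collapse and late-stage false confirmations creep in
      src <- active
      while (length(src) < 5L) src <- c(src, active)
      shadow <- apply(x[, src, drop = FALSE], 2, sample)
      colnames(shadow) <- paste0(".shadow.", seq_along(src), ".", src)
      xx <- cbind(xs, shadow)
      # classification trees grown to purity (min leaf 1), as the canonical
      # Boruta forests do; the min-leaf-5 rule belongs to the classifier RF
      fit_fun <- if (importance == "mda_z") .rf_fit_mda_cpp else .rf_fit_cpp
      fit <- fit_fun(xx, y, as.integer(n_trees),
                     max(1L, floor(sqrt(ncol(xx)))), 1L, 0L,
                     sample.int(.Machine$integer.max, 1L))
      imp <- setNames(fit$importance, colnames(xx))
      shadow_max <- max(imp[colnames(shadow)])
      hits[open] <- hits[open] + as.integer(imp[open] > shadow_max)
      # two one-sided binomial tests at alpha/2, Bonferroni over open feats
      a <- (alpha / 2) / length(open)
      p_hi <- pbinom(hits[open] - 1L, it, 0.5, lower.tail = FALSE)
      p_lo <- pbinom(hits[open], it, 0.5)
      state[open[p_hi < a]] <- "confirmed"
      state[open[p_lo < a]] <- "rejected"
    }
  })
  structure(list(confirmed = names(state)[state == "confirmed"],
                 rejected = names(state)[state == "rejected"],
                 tentative = names(state)[state == "tentative"],
                 hit_counts = hits, n_iterations_run = n_done),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf(
    "<boruta_result> %d confirmed, %d rejected, %d tentative (%d iters)\n",
    length(x$confirmed), length(x$rejected), length(x$tentative),
    x$n_iterations_run))
  if (length(x$confirmed))
    cat("  confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  invisible(x)
}

#' Nested Boruta selection frequency
#'
#' Runs [boruta_select()] on every training fold of every round of the plan
#' and reports, per feature, the fraction of the `n_rounds * n_folds` fits in
#' which it was confirmed (tentative counts as not selected).
#'
#' @param x Numeric feature matrix (encoded + imputed).
#' @param y Binary 0/1 labels.
#' @param plan A [cv_plan].
#' @param ... Arguments passed on to [boruta_select()].
#' @return A `selection_frequency`: `frequency` (named, sorted descending),
#'   `n_fits`.
#' @export
nested_selection_frequency <- function(x, y, plan = cv_plan(), ...) {
  y <- as.integer(y)
  feats <- colnames(x)
  count <- setNames(integer(length(feats)), feats)
  n_fits <- 0L
  for (r in seq_len(plan$n_rounds)) {
    fold <- make_folds(y, plan$n_folds, plan$stratified,
                       plan$master_seed + r)
    for (f in seq_len(plan$n_folds)) {
      tr <- fold != f
      br <- boruta_select(x[tr, , drop = FALSE], y[tr],
                          seed = derive_seed(plan$master_seed,
                                             r * 100L + f), ...)
      count[br$confirmed] <- count[br$confirmed] + 1L
      n_fits <- n_fits + 1L
    }
  }
  freq <- sort(count / n_fits, decreasing = TRUE)
  structure(list(frequency = freq, n_fits = n_fits),
            class = "selection_frequency")
}

#' @export
print.selection_frequency <- function(x, ...) {
  cat(sprintf("<selection_frequency> over %d fits\n", x$n_fits))
  print(round(x$frequency, 3))
  invisible(x)
}

#' Keep features selected often enough
#'
#' @param freq A `selection_frequency`.
#' @param cutoff Minimum selection frequency (default 0.60, the pipeline's
#'   rule "selected in at least 60 percent of the nested fits").
#' @return Character vector of features with `frequency >= cutoff`, ranked
#'   by descending frequency. May be empty.
#' @export
select_features <- function(freq, cutoff = 0.60) {
  stopifnot(inherits(freq, "selection_frequency"))
  names(freq$frequency)[freq$frequency >= cutoff]
}

#' Export selection frequencies as CSV (feature, frequency, rank)
#' @param freq A `selection_frequency`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_selection_frequency <- function(freq, path) {
  df <- data.frame(feature = names(freq$frequency),
                   frequency = as.numeric(freq$frequency),
                   rank = seq_along(freq$frequency))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
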