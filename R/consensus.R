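#' Count per-patient misclassifications over rounds
#'
#' For every classifier and patient, the number of rounds whose out-of-fold
#' hard label (score > threshold) disagrees with the true label.
#'
#' @param tensor A `score_tensor` (complete).
#' @param labels Binary 0/1 labels aligned with the tensor's patients.
#' @param threshold A `decision_threshold` or plain number.
#' @return Integer matrix `[classifier, patient]` of class `misclass_count`,
#'   values in `0..n_rounds`.
#' @export
count_misclassifications <- function(tensor, labels, threshold) {
  stopifnot(inherits(tensor, "score_tensor"))
  if (anyNA(tensor$scores)) stop_idex("score tensor has unfilled cells")
  labels <- as.integer(labels)
  t <- threshold_value(threshold)
  d <- dim(tensor$scores)
  counts <- matrix(0L, d[1], d[3],
                   dimnames = list(tensor$classifiers, tensor$patient_ids))
  for (r in seq_len(d[2])) {
    pred <- tensor$scores[, r, , drop = TRUE] > t   # classifier x patient
    if (is.null(dim(pred))) pred <- matrix(pred, nrow = d[1])
    wrong <- sweep(pred, 2, labels == 1L, `!=`)
    counts <- counts + wrong
  }
  structure(counts, class = c("misclass_count", "matrix"),
            n_rounds = d[2])
}

#' Identify confounding patients
#'
#' A patient is flagged when misclassified in at least `round_threshold`
#' rounds by *every* classifier (the all-four intersection rule); with
#' `require_all = FALSE` the union over classifiers is taken instead.
#' With the default 20-round plan the threshold is 15 of 20 (the third
#' quartile upper bound); for other round counts the analogous default is
#' `ceiling(0.75 * n_rounds)`.
#'
#' @param counts A `misclass_count`.
#' @param round_threshold Minimum misclassified rounds (default 15 for 20
#'   rounds, else `ceiling(0.75 * n_rounds)`).
#' @param require_all Require every classifier to exceed the threshold
#'   (default TRUE).
#' @return Character vector of flagged patient ids.
#' @export
identify_confounders <- function(counts, round_threshold = NULL,
                                 require_all = TRUE) {
  stopifnot(inherits(counts, "misclass_count"))
  n_rounds <- attr(counts, "n_rounds")
  if (is.null(round_threshold))
    round_threshold <- if (n_rounds == 20L) 15L
                       else as.integer(ceiling(0.75 * n_rounds))
  over <- unclass(counts) >= round_threshold
  flag <- if (require_all) apply(over, 2, all) else apply(over, 2, any)
  colnames(counts)[flag]
}

#' Cohen's kappa
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e) / (1 - p_e)} between
#' two label vectors, with \eqn{p_o} the observed agreement and \eqn{p_e}
#' the chance agreement from the marginals. Returns 1 when both observed and
#' chance agreement are exactly 1 (two identical constant vectors).
#'
#' @param a,b Equal-length label vectors.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop_idex("label vectors differ in length")
  if (length(a) == 0L) stop_idex("empty label vectors")
  lev <- sort(unique(c(a, b)))
  fa <- factor(a, levels = lev); fb <- factor(b, levels = lev)
  tab <- table(fa, fb) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

kappa_band <- function(mean_kappa) {
  if (is.na(mean_kappa)) NA_character_
  else if (mean_kappa < 0) "none"
  else if (mean_kappa < 0.4) "poor"
  else if (mean_kappa < 0.6) "moderate"
  else if (mean_kappa < 0.8) "good"
  else "great"
}

#' Pairwise inter-classifier kappa (mean +/- sd over rounds)
#'
#' For every pair of classifiers, Cohen's kappa between their hard
#' out-of-fold labels is computed per round, then summarized as mean and sd
#' across rounds, with a qualitative band (poor \[0, 0.4), moderate
#' \[0.4, 0.6), good \[0.6, 0.8), great \[0.8, 1\]; negative means no
#' concordance).
#'
#' @inheritParams count_misclassifications
#' @return Data frame of class `kappa_table`: pair, mean, sd, band.
#' @export
pairwise_kappa <- function(tensor, labels, threshold) {
  stopifnot(inherits(tensor, "score_tensor"))
  cls <- tensor$classifiers
  if (length(cls) < 2L) stop_idex("need at least two classifiers")
  t <- threshold_value(threshold)
  pairs <- utils::combn(cls, 2L)
  d <- dim(tensor$scores)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ks <- vapply(seq_len(d[2]), function(r) {
      cohens_kappa(as.integer(tensor$scores[a, r, ] > t),
                   as.integer(tensor$scores[b, r, ] > t))
    }, 0.0)
    data.frame(pair = paste0(a, "-", b), mean = mean(ks), sd = sd(ks),
               band = kappa_band(mean(ks)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("kappa_table", "data.frame")
  out
}

#' Pairwise concordance table and score map
#'
#' Average over rounds of the joint hard-label distribution of a classifier
#' pair, as percentages over the four agreement cells (IDE/IDE, IDE/non,
#' non/IDE, non/non; they sum to 100), plus the 2-D histogram of the score
#' pairs with the threshold position — the data behind score concordance
#' maps.
#'
#' @inheritParams count_misclassifications
#' @param pair Character vector of two classifier names.
#' @param bins Number of histogram bins per axis (default 20).
#' @return List with `table` (2x2 percentage matrix), `histogram`
#'   (bins x bins count matrix of score pairs over all rounds),
#'   `breaks`, `threshold`.
#' @export
concordance_table <- function(tensor, labels, threshold, pair, bins = 20L) {
  stopifnot(inherits(tensor, "score_tensor"), length(pair) == 2L)
  if (!all(pair %in% tensor$classifiers))
    stop_idex("unknown classifier in pair")
  t <- threshold_value(threshold)
  d <- dim(tensor$scores)
  cells <- matrix(0, 2, 2,
                  dimnames = list(paste0(pair[1], c(":IDE", ":non")),
                                  paste0(pair[2], c(":IDE", ":non"))))
  breaks <- seq(0, 1, length.out = bins + 1L)
  hist2 <- matrix(0L, bins, bins)
  for (r in seq_len(d[2])) {
    sa <- tensor$scores[pair[1], r, ]
    sb <- tensor$scores[pair[2], r, ]
    pa <- sa > t; pb <- sb > t
    cells[1, 1] <- cells[1, 1] + mean(pa & pb)
    cells[1, 2] <- cells[1, 2] + mean(pa & !pb)
    cells[2, 1] <- cells[2, 1] + mean(!pa & pb)
    cells[2, 2] <- cells[2, 2] + mean(!pa & !pb)
    ia <- pmin(pmax(findInterval(sa, breaks, rightmost.closed = TRUE), 1L),
               bins)
    ib <- pmin(pmax(findInterval(sb, breaks, rightmost.closed = TRUE), 1L),
               bins)
    for (k in seq_along(ia)) hist2[ia[k], ib[k]] <- hist2[ia[k], ib[k]] + 1L
  }
  list(table = 100 * cells / d[2], histogram = hist2 / d[2],
       breaks = breaks, threshold = t)
}

#' Iterative consensus procedure
#'
#' The core loop: run the repeated-CV engine, count per-patient
#' misclassifications, flag the patients misclassified in at least
#' `round_threshold` rounds by all classifiers, remove them, and repeat for
#' `n_iterations` iterations (stopping early when no patient is flagged).
#' The decision threshold is computed once from the labels given to
#' iteration 1 and held fixed across iterations unless
#' `recompute_threshold = TRUE`. After the final iteration the engine is run
#' once more on the included patients to obtain the "after" agreement
#' statistics and final performance.
#'
#' @param cohort An `idex_cohort`.
#' @param specs Named list of [model_spec] objects.
#' @param plan A [cv_plan].
#' @param n_iterations Number of removal iterations (default 2).
#' @param round_threshold Passed to [identify_confounders()].
#' @param selection Passed to [run_repeated_cv()].
#' @param impute_policy Passed to [impute()].
#' @param recompute_threshold Recompute the prevalence threshold from each
#'   iteration's input labels (default FALSE).
#' @param final_eval Run a final CV pass on the included cohort for the
#'   "after" kappa table and performance (default TRUE).
#' @return A `consensus_report`; see Details.
#' @details The report holds: `iterations` (per iteration: `confounding_ids`,
#'   `included_ids`, `n_removed_ide` / `n_removed_non_ide`, `threshold`,
#'   `kappa` table of that iteration's run), `confounding_ids` (all removed,
#'   disjoint across iterations), `included_ids`, `kappa_before`,
#'   `kappa_after`, `final_tensor`, `final_performance`, `threshold`.
#' @export
iterate_consensus <- function(cohort, specs = default_model_specs(),
                              plan = cv_plan(), n_iterations = 2L,
                              round_threshold = NULL, selection = NULL,
                              impute_policy = "median_mode",
                              recompute_threshold = FALSE,
                              final_eval = TRUE) {
  stopifnot(inherits(cohort, "idex_cohort"))
  current <- cohort
  threshold <- prevalence_threshold(cohort$labels)
  iterations <- list()
  removed_all <- character()
  kappa_before <- NULL

  run_once <- function(coh, iter) {
    em <- impute(encode(coh), impute_policy)
    sub_plan <- plan
    sub_plan$master_seed <- derive_seed(plan$master_seed, iter)
    run_repeated_cv(em$x, coh$labels, specs, sub_plan, selection)
  }

  i <- 0L
  while (i < n_iterations) {
    i <- i + 1L
    if (length(unique(current$labels)) < 2L)
      stop_idex("iteration %d: included cohort is single-class", i)
    if (recompute_threshold)
      threshold <- prevalence_threshold(current$labels)
    tensor <- run_once(current, i)
    kt <- pairwise_kappa(tensor, current$labels, threshold)
    if (i == 1L) kappa_before <- kt
    counts <- count_misclassifications(tensor, current$labels, threshold)
    flagged <- identify_confounders(counts, round_threshold)
    lab <- current$labels[match(flagged, current$patient_ids)]
    iterations[[i]] <- list(
      confounding_ids = flagged,
      included_ids = setdiff(current$patient_ids, flagged),
      n_removed_ide = sum(lab == 1L),
      n_removed_non_ide = sum(lab == 0L),
      threshold = threshold_value(threshold),
      kappa = kt)
    removed_all <- c(removed_all, flagged)
    current <- subset_cohort(current, setdiff(current$patient_ids, flagged))
    if (length(flagged) == 0L) break
  }

  final_tensor <- NULL; kappa_after <- NULL; final_perf <- NULL
  if (final_eval && n_iterations > 0L) {
    final_tensor <- run_once(current, n_iterations + 1L)
    kappa_after <- pairwise_kappa(final_tensor, current$labels, threshold)
    final_perf <- compute_performance(final_tensor, current$labels,
                                      threshold)
  } else if (n_iterations == 0L) {
    tensor <- run_once(current, 1L)
    kappa_before <- pairwise_kappa(tensor, current$labels, threshold)
  }

  structure(list(iterations = iterations,
                 confounding_ids = removed_all,
                 included_ids = current$patient_ids,
                 n_initial = length(cohort$patient_ids),
                 kappa_before = kappa_before, kappa_after = kappa_after,
                 final_tensor = final_tensor,
                 final_performance = final_perf,
                 threshold = threshold_value(threshold)),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  n_rem <- length(x$confounding_ids)
  cat(sprintf(
    "<consensus_report> %d iterations: removed %d of %d (%.1f%%), %d kept\n",
    length(x$iterations), n_rem, x$n_initial, 100 * n_rem / x$n_initial,
    length(x$included_ids)))
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf("  iteration %d: removed %d (%d IDE, %d non-IDE)\n", i,
                length(it$confounding_ids), it$n_removed_ide,
                it$n_removed_non_ide))
  }
  if (!is.null(x$kappa_before) && !is.null(x$kappa_after)) {
    cat("  mean kappa before -> after:\n")
    for (j in seq_len(nrow(x$kappa_before)))
      cat(sprintf("    %-9s %.2f -> %.2f\n", x$kappa_before$pair[j],
                  x$kappa_before$mean[j], x$kappa_after$mean[j]))
  }
  invisible(x)
}

#' Removal bookkeeping for a consensus run
#'
#' The retained-count identity and exclusion fraction of a removal step:
#' `n_retained = n_initial - n_removed` and
#' `fraction = n_removed / n_initial`.
#'
#' @param n_initial Patients before removal.
#' @param n_removed Patients removed.
#' @return List with `n_retained`, `fraction_removed`,
#'   `percent_removed` (0-100 scale).
#' @export
removal_summary <- function(n_initial, n_removed) {
  if (n_removed < 0 || n_removed > n_initial)
    stop_idex("n_removed must lie in [0, n_initial]")
  list(n_retained = n_initial - n_removed,
       fraction_removed = n_removed / n_initial,
       percent_removed = 100 * n_removed / n_initial)
}

#' Export a consensus report as JSON (and kappa tables as CSV)
#' @param report A `consensus_report`.
#' @param path JSON path; kappa tables go to `<path>.kappa.csv`.
#' @return `path`, invisibly.
#' @export
write_consensus_report <- function(report, path) {
  lst <- list(
    n_initial = report$n_initial,
    n_removed = length(report$confounding_ids),
    confounding_ids = report$confounding_ids,
    included_ids = report$included_ids,
    threshold = report$threshold,
    iterations = lapply(report$iterations, function(it)
      it[c("confounding_ids", "n_removed_ide", "n_removed_non_ide",
           "threshold")]))
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(report$kappa_before) && !is.null(report$kappa_after)) {
    kt <- data.frame(pair = report$kappa_before$pair,
                     before_mean = report$kappa_before$mean,
                     before_sd = report$kappa_before$sd,
                     after_mean = report$kappa_after$mean,
                     after_sd = report$kappa_after$sd)
    write.csv(kt, paste0(path, ".kappa.csv"), row.names = FALSE)
  }
  invisible(path)
}
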