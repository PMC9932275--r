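#' Configuration for a synthetic cohort
#'
#' @param n_patients Number of patients.
#' @param horizon Follow-up horizon label, `"5y"` or `"10y"`. The horizon only
#'   selects the default target prevalence (0.29 at 5 years, 0.49 at 10 years)
#'   and is carried as metadata.
#' @param target_prevalence Desired mean of the latent IDE probability;
#'   defaults to the horizon's prevalence.
#' @param schema List of [feature_schema] objects (default:
#'   [default_paper_schema()]).
#' @param effect_vector Named per-feature coefficients on the label log-odds
#'   applied to standardized feature values (default:
#'   [default_effect_vector()]).
#' @param confounder_fraction Fraction of patients whose label is flipped
#'   after the latent draw; must lie in \[0, 0.5\].
#' @param missingness Optional named per-feature missing rates overriding the
#'   schema's rates; a single unnamed number applies to all features.
#' @param seed Integer seed; identical config + seed reproduces the cohort
#'   bit-for-bit.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 486L, horizon = c("5y", "10y"),
                          target_prevalence = NULL,
                          schema = default_paper_schema(),
                          effect_vector = default_effect_vector(schema),
                          confounder_fraction = 0, missingness = NULL,
                          seed = 1L) {
  horizon <- match.arg(horizon)
  if (is.null(target_prevalence))
    target_prevalence <- if (horizon == "5y") 0.29 else 0.49
  if (n_patients < 2) stop_idex("n_patients must be >= 2")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop_idex("target_prevalence must lie in (0, 1)")
  assert_fraction(confounder_fraction, "confounder_fraction", 0, 0.5)
  if (!is.null(missingness)) {
    if (is.null(names(missingness)) && length(missingness) == 1L) {
      for (nm in names(schema)) schema[[nm]]$missing_rate <- missingness
    } else {
      bad <- setdiff(names(missingness), names(schema))
      if (length(bad)) stop_idex("missingness names unknown: %s",
                                 paste(bad, collapse = ", "))
      for (nm in names(missingness))
        schema[[nm]]$missing_rate <- missingness[[nm]]
    }
  }
  ev <- setNames(numeric(length(schema)), names(schema))
  common <- intersect(names(ev), names(effect_vector))
  ev[common] <- effect_vector[common]
  structure(list(n_patients = as.integer(n_patients), horizon = horizon,
                 target_prevalence = target_prevalence, schema = schema,
                 effect_vector = ev,
                 confounder_fraction = confounder_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  mean <- rep_len(mean, n)
  x <- rnorm(n, mean, sd)
  for (guard in seq_len(100L)) {
    bad <- which(x < lower | x > upper)
    if (!length(bad)) break
    x[bad] <- rnorm(length(bad), mean[bad], sd)
  }
  pmin(pmax(x, lower), upper)
}

# Draw the raw feature table. Two named special cases give the cohort its
# clinical correlation structure: the eradicated/metastatic lymph-node counts
# load on one latent severity variable (pairwise correlation about 0.6), and
# lymph_node_status is (noisily) derived from the metastatic count.
draw_features <- function(schema, n) {
  severity <- rnorm(n)
  cols <- list()
  for (s in schema) {
    g <- s$gen
    if (s$kind == "continuous") {
      mu <- rep(g$mean, n)
      sdv <- g$sd
      if (s$name == "eradicated_lymph_nodes") {
        mu <- mu + 4.5 * severity
        sdv <- 3.5
      }
      if (s$name == "metastatic_lymph_nodes") {
        mu <- mu + 3.0 * severity
        sdv <- 2.0
      }
      x <- rtruncnorm1(n, mu, sdv, g$lower, g$upper)
      if (isTRUE(g$integer)) x <- round(x)
      cols[[s$name]] <- x
    } else {
      codes <- as.integer(names(s$levels))
      probs <- g$probs %||% rep(1 / length(codes), length(codes))
      cols[[s$name]] <- sample(codes, n, replace = TRUE, prob = probs)
    }
  }
  if (!is.null(cols$lymph_node_status) &&
      !is.null(cols$metastatic_lymph_nodes)) {
    status <- as.integer(cols$metastatic_lymph_nodes > 0)
    flip <- runif(n) < 0.05
    cols$lymph_node_status <- ifelse(flip, 1L - status, status)
  }
  as.data.frame(cols, check.names = FALSE)
}

standardize_cols <- function(x) {
  apply(x, 2, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) rep(0, length(col))
    else (col - mean(col)) / s
  })
}

#' Generate a synthetic cohort with planted confounders
#'
#' Draws mixed-type clinical features per the config's schema, assigns labels
#' from a latent logistic model on standardized features
#' \eqn{p_i = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j z_{ij})} with the
#' intercept \eqn{\beta_0} solved (by root finding) so that the mean latent
#' probability matches `target_prevalence`, draws labels Bernoulli(p), flips
#' the labels of a uniformly sampled `confounder_fraction` of patients
#' (recording them as ground truth), and finally applies MCAR missingness per
#' feature.
#'
#' @param config A [cohort_config].
#' @return A list with elements `cohort` (class `idex_cohort`: `features`
#'   data frame with NA for missing, `labels` 0/1, `patient_ids`, `schema`,
#'   `horizon`) and `truth` (class `idex_truth`: `confounder_ids`,
#'   `informative_features`, `latent_prob`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    feats <- draw_features(config$schema, n)
    z <- standardize_cols(feats)
    eta <- drop(z %*% config$effect_vector[colnames(feats)])
    if (!all(is.finite(eta))) stop_idex("non-finite latent predictor")
    target <- config$target_prevalence
    fn <- function(b0) mean(plogis(b0 + eta)) - target
    lo <- qlogis(target) - 20; hi <- qlogis(target) + 20
    if (fn(lo) > 0 || fn(hi) < 0)
      stop_idex(paste0("cannot solve the intercept for target prevalence ",
                       "%.3f: degenerate effect vector"), target)
    b0 <- uniroot(fn, c(lo, hi), tol = 1e-10)$root
    p <- plogis(b0 + eta)
    labels <- rbinom(n, 1L, p)
    ids <- sprintf("P%04d", seq_len(n))

    cohort <- structure(
      list(features = feats, labels = as.integer(labels), patient_ids = ids,
           schema = config$schema, horizon = config$horizon),
      class = "idex_cohort")

    flipped <- character()
    if (config$confounder_fraction > 0) {
      res <- plant_confounders(cohort, config$confounder_fraction,
                               seed = derive_seed(config$seed, 1L))
      cohort <- res$cohort
      flipped <- res$flipped_ids
    }

    # MCAR missingness, applied last so flips never depend on it
    for (s in config$schema) {
      if (s$missing_rate > 0) {
        miss <- runif(n) < s$missing_rate
        cohort$features[[s$name]][miss] <- NA
      }
    }
    truth <- structure(
      list(confounder_ids = flipped,
           informative_features =
             names(which(config$effect_vector != 0)),
           latent_prob = p),
      class = "idex_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Flip the labels of a random subset of patients
#'
#' @param cohort An `idex_cohort`.
#' @param fraction Fraction of patients to flip, in \[0, 0.5\]. The number
#'   flipped is `round(fraction * n)`.
#' @param seed Integer seed.
#' @return List with `cohort` (labels flipped) and `flipped_ids`.
#' @export
plant_confounders <- function(cohort, fraction, seed = 1L) {
  stopifnot(inherits(cohort, "idex_cohort"))
  assert_fraction(fraction, "fraction", 0, 0.5)
  n <- length(cohort$labels)
  k <- round(fraction * n)
  if (k == 0) return(list(cohort = cohort, flipped_ids = character()))
  with_seed(seed, {
    pick <- sample.int(n, k)
    cohort$labels[pick] <- 1L - cohort$labels[pick]
    list(cohort = cohort, flipped_ids = sort(cohort$patient_ids[pick]))
  })
}

#' @export
print.idex_cohort <- function(x, ...) {
  cat(sprintf("<idex_cohort> %d patients, %d features, horizon %s\n",
              length(x$patient_ids), ncol(x$features), x$horizon))
  cat(sprintf("  IDE prevalence: %.3f; missing entries: %d\n",
              mean(x$labels), sum(is.na(x$features))))
  invisible(x)
}

#' Write / read a cohort as CSV plus JSON sidecars
#'
#' The CSV holds `patient_id`, the feature columns in schema order, and
#' `label`; missing values are empty fields. The schema travels in
#' `<path>.schema.json`.
#'
#' @param cohort An `idex_cohort`.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns an
#'   `idex_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  df <- cbind(data.frame(patient_id = cohort$patient_ids,
                         stringsAsFactors = FALSE),
              cohort$features,
              data.frame(label = cohort$labels))
  write.csv(df, path, row.names = FALSE, na = "")
  meta <- list(horizon = cohort$horizon,
               schema = schema_to_list(cohort$schema))
  jsonlite::write_json(meta, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_path <- paste0(path, ".schema.json")
  if (!file.exists(meta_path))
    stop_idex("schema sidecar not found: %s", meta_path)
  meta <- jsonlite::read_json(meta_path)
  schema <- schema_from_list(meta$schema)
  feats <- df[, names(schema), drop = FALSE]
  structure(list(features = feats, labels = as.integer(df$label),
                 patient_ids = as.character(df$patient_id), schema = schema,
                 horizon = meta$horizon),
            class = "idex_cohort")
}

#' @rdname write_cohort
#' @param truth An `idex_truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(confounder_ids = truth$confounder_ids,
         informative_features = truth$informative_features),
    path, auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

# subset a cohort by patient id, preserving order of `ids`
subset_cohort <- function(cohort, ids) {
  idx <- match(ids, cohort$patient_ids)
  if (anyNA(idx)) stop_idex("unknown patient ids in subset")
  cohort$features <- cohort$features[idx, , drop = FALSE]
  cohort$labels <- cohort$labels[idx]
  cohort$patient_ids <- cohort$patient_ids[idx]
  cohort
}
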