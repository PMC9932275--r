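#' Encode a cohort into a numeric matrix
#'
#' Ordinal and categorical features keep their integer codes as single
#' columns (they are never one-hot expanded: the tree models and the
#' attribution displays treat them as ordered codes); continuous features
#' pass through unchanged. Columns follow schema order, rows carry patient
#' ids. Missing values remain `NA` until [impute()].
#'
#' @param cohort An `idex_cohort`.
#' @return An `encoded_matrix`: list with `x` (numeric matrix), `schema`,
#'   and `imputation_log` (empty until imputation).
#' @export
encode <- function(cohort) {
  stopifnot(inherits(cohort, "idex_cohort"))
  schema <- cohort$schema
  feats <- cohort$features[, names(schema), drop = FALSE]
  for (s in schema) {
    v <- feats[[s$name]]
    if (s$kind != "continuous") {
      codes <- as.integer(names(s$levels))
      bad <- which(!is.na(v) & !(v %in% codes))
      if (length(bad))
        stop_idex("patient %s: value %s outside codes of feature `%s`",
                  cohort$patient_ids[bad[1]], v[bad[1]], s$name)
    }
  }
  x <- as.matrix(feats)
  storage.mode(x) <- "double"
  rownames(x) <- cohort$patient_ids
  structure(list(x = x, schema = schema, imputation_log = list()),
            class = "encoded_matrix")
}

#' Impute missing entries of an encoded matrix
#'
#' `median_mode` (default) fills continuous features with the column median
#' and coded features with the column mode (smallest code on ties);
#' `indicator` additionally appends one binary `<feature>_missing` column per
#' feature that had any missing entry. Every fill is recorded in the
#' imputation log.
#'
#' @param em An `encoded_matrix`.
#' @param policy `"median_mode"` or `"indicator"`.
#' @return An `encoded_matrix` with no missing entries.
#' @export
impute <- function(em, policy = c("median_mode", "indicator")) {
  policy <- match.arg(policy)
  stopifnot(inherits(em, "encoded_matrix"))
  x <- em$x
  log <- list()
  extra <- list()
  for (s in em$schema) {
    v <- x[, s$name]
    miss <- is.na(v)
    if (!any(miss)) next
    if (all(miss)) stop_idex("feature `%s` entirely missing", s$name)
    if (s$kind == "continuous") {
      fill <- median(v[!miss])
      method <- "median"
    } else {
      tab <- table(v[!miss])
      fill <- as.numeric(names(tab)[which.max(tab)])
      method <- "mode"
    }
    v[miss] <- fill
    x[, s$name] <- v
    log[[s$name]] <- list(method = method, fill = fill,
                          n_filled = sum(miss))
    if (policy == "indicator")
      extra[[paste0(s$name, "_missing")]] <- as.numeric(miss)
  }
  if (length(extra))
    x <- cbind(x, do.call(cbind, extra))
  structure(list(x = x, schema = em$schema, imputation_log = log),
            class = "encoded_matrix")
}

#' Prevalence-derived decision threshold
#'
#' The classification score cut-off is the positive-class fraction of the
#' cohort: number of IDE patients over total patients. A patient is called
#' IDE when `score > value` (strict inequality; configurable at the call
#' sites that apply it).
#'
#' @param labels Binary 0/1 labels, both classes present.
#' @return A `decision_threshold`: list with `value`, `n_positive`,
#'   `n_total`.
#' @export
prevalence_threshold <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0 || anyNA(labels))
    stop_idex("labels must be non-empty and complete")
  npos <- sum(labels == 1L)
  if (npos == 0L || npos == length(labels))
    stop_idex("threshold degenerate: only one class present")
  structure(list(value = npos / length(labels), n_positive = npos,
                 n_total = length(labels)),
            class = "decision_threshold")
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "decision_threshold")) threshold$value
  else as.numeric(threshold)
}

# hard labels from scores: IDE iff score > threshold (strict by default)
hard_labels <- function(scores, threshold, strict = TRUE) {
  t <- threshold_value(threshold)
  if (strict) as.integer(scores > t) else as.integer(scores >= t)
}

#' @export
print.decision_threshold <- function(x, ...) {
  cat(sprintf("<decision_threshold> %d/%d = %.4f\n", x$n_positive,
              x$n_total, x$value))
  invisible(x)
}

#' Export an encoded matrix as CSV (and its imputation log as JSON)
#' @param em An `encoded_matrix`.
#' @param path CSV path; the log goes to `<path>.log.json` when non-empty.
#' @return `path`, invisibly.
#' @export
write_encoded <- function(em, path) {
  df <- data.frame(patient_id = rownames(em$x), em$x, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  if (length(em$imputation_log))
    jsonlite::write_json(em$imputation_log, paste0(path, ".log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
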