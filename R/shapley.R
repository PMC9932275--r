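#' Background (reference) set for attributions
#'
#' The background carries the "no information" distribution: masked-out
#' features are replaced by background rows, and the base value is the
#' weighted mean model score over the background (the expected prediction
#' over the training set). Optionally the training matrix is summarized to
#' `k` weighted medoids to cap attribution cost.
#'
#' @param x Numeric matrix of reference rows (typically the training set).
#' @param weights Row weights (default uniform); normalized to sum to 1.
#' @param k Optional number of medoids to summarize to (k-means centers
#'   snapped to the nearest actual row, weighted by cluster size).
#' @param seed Seed for the k-means summarization.
#' @return A `background_set` with `rows` and `weights`.
#' @export
background_set <- function(x, weights = NULL, k = NULL, seed = 1L) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) == 0L) stop_idex("background is empty")
  w <- weights %||% rep(1, nrow(x))
  if (length(w) != nrow(x) || any(w < 0) || sum(w) <= 0)
    stop_idex("invalid background weights")
  w <- w / sum(w)
  if (!is.null(k) && k < nrow(x)) {
    with_seed(seed, {
      scl <- apply(x, 2, sd); scl[!is.finite(scl) | scl == 0] <- 1
      km <- kmeans(scale(x, scale = scl), centers = k, nstart = 3L)
      rows <- matrix(0, k, ncol(x), dimnames = list(NULL, colnames(x)))
      wk <- numeric(k)
      for (j in seq_len(k)) {
        members <- which(km$cluster == j)
        cen <- km$centers[j, ]
        d2 <- colSums((t(scale(x[members, , drop = FALSE],
                               scale = scl)) - cen)^2)
        rows[j, ] <- x[members[which.min(d2)], ]
        wk[j] <- sum(w[members])
      }
      x <- rows; w <- wk / sum(wk)
    })
  }
  structure(list(rows = x, weights = w), class = "background_set")
}

#' Base value: expected model score over the background
#' @param model An object scoreable via [score_model()] or a function
#'   mapping a matrix to scores.
#' @param background A [background_set()].
#' @return The weighted mean score, a single number.
#' @export
base_value <- function(model, background) {
  stopifnot(inherits(background, "background_set"))
  sum(score_any(model, background$rows) * background$weights)
}

score_any <- function(model, x) {
  if (is.function(model)) as.numeric(model(x))
  else score_model(model, x)
}

# Coalition value function v(S): features in S are fixed to x's values, the
# rest are replaced by background rows; v(S) is the background-weighted mean
# score. `masks` is a logical matrix (n_coalitions x M); one batched model
# call covers everything.
coalition_values <- function(model, x, background, masks,
                             chunk_rows = 200000L) {
  B <- nrow(background$rows)
  nc <- nrow(masks)
  per <- max(1L, chunk_rows %/% B)
  out <- numeric(nc)
  for (start in seq(1L, nc, by = per)) {
    idx <- start:min(start + per - 1L, nc)
    k <- length(idx)
    big <- background$rows[rep(seq_len(B), times = k), , drop = FALSE]
    xrep <- matrix(rep(x, each = B * k), B * k, length(x))
    maskrep <- masks[rep(idx, each = B), , drop = FALSE]
    big[maskrep] <- xrep[maskrep]
    sc <- score_any(model, big)
    out[idx] <- as.numeric(
      rowsum(sc * rep(background$weights, times = k),
             rep(seq_len(k), each = B)))
  }
  out
}

new_explanation <- function(patient_id, base, phi, score, method,
                            n_coalitions) {
  structure(list(patient_id = patient_id, base_value = base, phi = phi,
                 model_score = score, method = method,
                 n_coalitions_used = n_coalitions),
            class = "idex_explanation")
}

#' @export
print.idex_explanation <- function(x, ...) {
  cat(sprintf("<explanation> %s: base %.4f + sum(phi) %.4f = score %.4f (%s)\n",
              x$patient_id %||% "?", x$base_value, sum(x$phi),
              x$model_score, x$method))
  top <- sort(abs(x$phi), decreasing = TRUE)
  show <- names(head(top, 5L))
  for (f in show) cat(sprintf("  %-28s %+0.4f\n", f, x$phi[f]))
  invisible(x)
}

#' Exact Shapley values by coalition enumeration
#'
#' For each feature j,
#' \deqn{\phi_j = \sum_{S \subseteq F \setminus \{j\}}
#'   \frac{|S|!\,(M-|S|-1)!}{M!}\,[v(S \cup \{j\}) - v(S)]}
#' with \eqn{v(S)} the background-weighted mean model score when the features
#' in S are fixed to the instance's values and the rest are drawn from the
#' background (marginal masking). Satisfies local accuracy exactly:
#' base value + sum(phi) = model score.
#'
#' @param model Scoreable model or function.
#' @param x Numeric feature row (named).
#' @param background A [background_set()].
#' @param exact_limit Maximum number of features M (default 16, i.e. 65536
#'   coalitions); beyond it use [kernel_shap()].
#' @param patient_id Optional id carried into the result.
#' @return An `idex_explanation`.
#' @export
exact_shapley <- function(model, x, background, exact_limit = 16L,
                          patient_id = NULL) {
  x <- drop_to_row(x, background)
  M <- length(x)
  if (M > exact_limit)
    stop_idex("%d features exceed the exact limit %d; use kernel_shap()",
              M, exact_limit)
  n_sub <- bitwShiftL(1L, M)
  masks <- matrix(FALSE, n_sub, M)
  for (j in seq_len(M))
    masks[, j] <- bitwAnd(seq_len(n_sub) - 1L, bitwShiftL(1L, j - 1L)) > 0L
  v <- coalition_values(model, x, background, masks)
  sizes <- rowSums(masks)
  # weight for |S| = s (feature j absent): s!(M-s-1)!/M!, s = 0..M-1
  wt <- exp(lgamma(0:(M - 1) + 1) + lgamma(M - (0:(M - 1))) - lgamma(M + 1))
  phi <- numeric(M)
  all_idx <- seq_len(n_sub) - 1L
  for (j in seq_len(M)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(all_idx, bit) == 0L)
    s <- sizes[without]
    phi[j] <- sum(wt[s + 1] * (v[without + bit] - v[without]))
  }
  names(phi) <- names(x)
  new_explanation(patient_id, v[1], phi, v[n_sub], "exact", n_sub)
}

drop_to_row <- function(x, background) {
  x <- unlist(x)
  M <- ncol(background$rows)
  if (length(x) != M) stop_idex("instance has %d features, background %d",
                                length(x), M)
  if (is.null(names(x)) && !is.null(colnames(background$rows)))
    names(x) <- colnames(background$rows)
  x
}

shapley_kernel_weight <- function(M, s) {
  # pi(z) for coalition size s in 1..M-1
  (M - 1) / (choose(M, s) * s * (M - s))
}

#' Kernel-weighted linear surrogate Shapley values
#'
#' Fits the linear explanation model g by weighted least squares over
#' coalition indicator vectors, with the Shapley kernel
#' \eqn{\pi(z) = (M-1) / [\binom{M}{|z|} |z| (M-|z|)]} as the weight and the
#' local-accuracy constraint that the coefficients plus the base value
#' reproduce the model score. With `n_coalitions = "full"` all \eqn{2^M - 2}
#' non-trivial coalitions enter and the result equals [exact_shapley()] to
#' numerical precision. Otherwise coalition sizes are covered in order of
#' total kernel weight: sizes that fit the budget are enumerated completely
#' (keeping their exact weights), the remainder is sampled without
#' replacement within a size. The empty and full coalitions are always used
#' (they pin the base value and the constraint).
#'
#' @inheritParams exact_shapley
#' @param n_coalitions `"full"` or an integer >= M + 2.
#' @param seed Seed for coalition sampling.
#' @return An `idex_explanation` with method `"kernel"`.
#' @export
kernel_shap <- function(model, x, background, n_coalitions = "full",
                        seed = 1L, patient_id = NULL) {
  x <- drop_to_row(x, background)
  M <- length(x)
  if (M < 1L) stop_idex("need at least one feature")
  if (M == 1L) { # single feature: attribution is the full difference
    base <- base_value(model, background)
    fx <- score_any(model, matrix(x, 1, dimnames = list(NULL, names(x))))
    phi <- setNames(fx - base, names(x))
    return(new_explanation(patient_id, base, phi, fx, "kernel", 2L))
  }

  full_mode <- identical(n_coalitions, "full")
  if (!full_mode) {
    n_coalitions <- as.integer(n_coalitions)
    if (n_coalitions < M + 2L)
      stop_idex("n_coalitions must be at least M + 2 = %d", M + 2L)
  }

  if (full_mode || n_coalitions >= 2^M) {
    masks <- all_masks(M)
    w <- shapley_kernel_weight(M, rowSums(masks))
  } else {
    sampled <- sample_coalitions(M, n_coalitions - 2L, seed)
    masks <- sampled$masks
    w <- sampled$weights
  }

  base <- base_value(model, background)
  fx <- score_any(model, matrix(x, 1, dimnames = list(NULL, names(x))))
  v <- coalition_values(model, x, background, masks)

  # constrained WLS by elimination of the last coefficient:
  # sum(phi) = fx - base
  eyAdj <- v - base - masks[, M] * (fx - base)
  Z <- masks[, -M, drop = FALSE] - masks[, M]
  A <- crossprod(Z * w, Z)
  b <- crossprod(Z * w, eyAdj)
  phi_head <- tryCatch(drop(solve(A, b)),
                       error = function(e) drop(qr.solve(A, b)))
  phi <- c(phi_head, (fx - base) - sum(phi_head))
  names(phi) <- names(x)
  new_explanation(patient_id, base, phi, fx, "kernel", nrow(masks) + 2L)
}

all_masks <- function(M) {
  n_sub <- bitwShiftL(1L, M)
  idx <- seq_len(n_sub - 2L)  # exclude empty (0) and full (2^M - 1)
  masks <- matrix(FALSE, length(idx), M)
  for (j in seq_len(M))
    masks[, j] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0L
  masks
}

# Budgeted coalition sampling, shap-style: walk sizes (paired s and M-s) in
# kernel-weight order; enumerate a size fully if it fits, else sample
# without replacement and spread the size's remaining kernel weight evenly.
sample_coalitions <- function(M, budget, seed) {
  sizes <- seq_len(M - 1L)
  size_w <- vapply(sizes, function(s) shapley_kernel_weight(M, s) *
                     choose(M, s), 0.0)
  ord <- order(size_w, decreasing = TRUE)
  masks_list <- list(); w_list <- list()
  left <- budget
  remaining_sizes <- ord
  for (pos in seq_along(ord)) {
    s <- sizes[ord[pos]]
    n_s <- choose(M, s)
    if (n_s <= left - (length(ord) - pos)) { # keep room for later sizes
      m <- t(utils::combn(M, s, function(ix) {
        z <- logical(M); z[ix] <- TRUE; z
      }))
      masks_list[[length(masks_list) + 1L]] <- m
      w_list[[length(w_list) + 1L]] <-
        rep(shapley_kernel_weight(M, s), n_s)
      left <- left - n_s
      remaining_sizes <- setdiff(remaining_sizes, ord[pos])
    }
  }
  if (left > 0L && length(remaining_sizes) > 0L) {
    rem_sizes <- sizes[remaining_sizes]
    rem_w <- size_w[remaining_sizes]
    alloc <- pmax(1L, floor(left * rem_w / sum(rem_w)))
    while (sum(alloc) > left) alloc[which.max(alloc)] <-
        alloc[which.max(alloc)] - 1L
    with_seed(seed, {
      for (k in seq_along(rem_sizes)) {
        s <- rem_sizes[k]
        ns <- min(alloc[k], choose(M, s))
        if (ns <= 0L) next
        seen <- new.env(hash = TRUE)
        m <- matrix(FALSE, ns, M)
        got <- 0L
        while (got < ns) {
          ix <- sort(sample.int(M, s))
          key <- paste(ix, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            got <- got + 1L
            m[got, ix] <- TRUE
          }
        }
        masks_list[[length(masks_list) + 1L]] <- m
        w_list[[length(w_list) + 1L]] <- rep(rem_w[k] / ns, ns)
      }
    })
  }
  list(masks = do.call(rbind, masks_list), weights = unlist(w_list))
}

#' Explain a set of patients
#'
#' One explanation per test row, with the training matrix (optionally
#' summarized to `bg_k` medoids) as the background.
#'
#' @param model Fitted model (or scoring function).
#' @param train_x Training feature matrix (background source).
#' @param test_x Test feature matrix; row names become patient ids.
#' @param method `"auto"` (exact when M <= `exact_limit`, else kernel),
#'   `"exact"`, or `"kernel"`.
#' @param bg_k Optional background summarization size (default: 50 when the
#'   training set is larger, to keep cost bounded).
#' @param n_coalitions Kernel budget (default `"full"` for M <= 12, else
#'   2048).
#' @param exact_limit Maximum M for exact enumeration (default 16).
#' @param seed Seed (background summarization + coalition sampling).
#' @return List of `idex_explanation`, one per test row.
#' @export
explain_patients <- function(model, train_x, test_x,
                             method = c("auto", "exact", "kernel"),
                             bg_k = NULL, n_coalitions = NULL,
                             exact_limit = 16L, seed = 1L) {
  method <- match.arg(method)
  if (!is.matrix(train_x)) train_x <- as.matrix(train_x)
  if (!is.matrix(test_x)) test_x <- as.matrix(test_x)
  if (!identical(colnames(train_x), colnames(test_x)))
    stop_idex("train and test matrices have different features")
  if (inherits(model, "idex_model") &&
      !all(model$features %in% colnames(train_x)))
    stop_idex("model was fitted on different features")
  M <- ncol(train_x)
  if (method == "auto")
    method <- if (M <= exact_limit) "exact" else "kernel"
  if (is.null(bg_k)) bg_k <- min(50L, nrow(train_x))
  bg <- background_set(train_x, k = bg_k, seed = seed)
  if (is.null(n_coalitions))
    n_coalitions <- if (M <= 12L) "full" else 2048L
  ids <- rownames(test_x) %||% sprintf("row%d", seq_len(nrow(test_x)))
  lapply(seq_len(nrow(test_x)), function(i) {
    if (method == "exact")
      exact_shapley(model, test_x[i, ], bg, exact_limit, ids[i])
    else
      kernel_shap(model, test_x[i, ], bg, n_coalitions,
                  seed = derive_seed(seed, i), patient_id = ids[i])
  })
}

#' Explain the confounding patients of a consensus run
#'
#' Fits the given classifier once on all included patients and explains every
#' confounding patient against that model (included patients form both the
#' training set and the attribution background).
#'
#' @param consensus A `consensus_report`.
#' @param cohort The cohort the consensus was run on.
#' @param spec A [model_spec] (typically the best classifier).
#' @param method,bg_k,n_coalitions,seed Passed to [explain_patients()].
#' @param features Optional feature subset to fit and explain on.
#' @param impute_policy Passed to [impute()].
#' @return List of `idex_explanation`, one per confounding patient (empty
#'   when there are none).
#' @export
explain_confounders <- function(consensus, cohort, spec = model_spec("XGB"),
                                method = "auto", features = NULL,
                                bg_k = NULL, n_coalitions = NULL, seed = 1L,
                                impute_policy = "median_mode") {
  stopifnot(inherits(consensus, "consensus_report"),
            inherits(cohort, "idex_cohort"))
  if (length(consensus$included_ids) == 0L)
    stop_idex("consensus has an empty included set")
  if (length(consensus$confounding_ids) == 0L) return(list())
  em <- impute(encode(cohort), impute_policy)
  x <- em$x
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  inc <- match(consensus$included_ids, rownames(x))
  conf <- match(consensus$confounding_ids, rownames(x))
  y_inc <- cohort$labels[match(consensus$included_ids, cohort$patient_ids)]
  model <- fit_model(spec, x[inc, , drop = FALSE], y_inc, seed = seed)
  explain_patients(model, x[inc, , drop = FALSE], x[conf, , drop = FALSE],
                   method = method, bg_k = bg_k,
                   n_coalitions = n_coalitions, seed = seed)
}

#' Global attribution summary (beeswarm data)
#'
#' Ranks features by mean absolute Shapley value across explanations and
#' collects the per-patient (phi, feature value) pairs behind a beeswarm
#' display.
#'
#' @param explanations List of `idex_explanation`.
#' @param feature_values Optional matrix of the explained instances' feature
#'   values (rows aligned with `explanations`); included in the scatter data
#'   when given.
#' @return A `global_summary`: `ranking` data frame (feature, mean_abs_phi,
#'   rank) and `beeswarm` long data frame (patient_id, feature, phi, value).
#' @export
global_summary <- function(explanations, feature_values = NULL) {
  if (length(explanations) == 0L) stop_idex("no explanations given")
  phi <- do.call(rbind, lapply(explanations, `[[`, "phi"))
  ids <- vapply(explanations, function(e) e$patient_id %||% NA_character_,
                "")
  mean_abs <- colMeans(abs(phi))
  ord <- order(mean_abs, decreasing = TRUE)
  ranking <- data.frame(feature = colnames(phi)[ord],
                        mean_abs_phi = mean_abs[ord],
                        rank = seq_along(ord), row.names = NULL)
  bees <- data.frame(
    patient_id = rep(ids, times = ncol(phi)),
    feature = rep(colnames(phi), each = nrow(phi)),
    phi = as.vector(phi), stringsAsFactors = FALSE)
  if (!is.null(feature_values)) {
    fv <- as.matrix(feature_values)[, colnames(phi), drop = FALSE]
    bees$value <- as.vector(fv)
  }
  structure(list(ranking = ranking, beeswarm = bees),
            class = "global_summary")
}

#' @export
print.global_summary <- function(x, ...) {
  cat("<global_summary> top features by mean |phi|:\n")
  print(head(x$ranking, 10L), digits = 3)
  invisible(x)
}

#' Export explanations as tidy CSV
#'
#' One row per (patient, feature): patient_id, feature, value (if given),
#' phi, base_value, model_score.
#'
#' @param explanations List of `idex_explanation`.
#' @param path CSV path.
#' @param feature_values Optional instance-value matrix aligned with the
#'   explanations.
#' @return `path`, invisibly.
#' @export
write_explanations <- function(explanations, path, feature_values = NULL) {
  rows <- lapply(seq_along(explanations), function(i) {
    e <- explanations[[i]]
    df <- data.frame(patient_id = e$patient_id %||% as.character(i),
                     feature = names(e$phi), phi = as.numeric(e$phi),
                     base_value = e$base_value,
                     model_score = e$model_score,
                     stringsAsFactors = FALSE)
    if (!is.null(feature_values))
      df$value <- as.numeric(feature_values[i, names(e$phi)])
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
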