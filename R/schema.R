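#' Feature schema for a clinical cohort
#'
#' A `feature_schema` describes one column of a patient table: its name, its
#' kind (continuous, ordinal or categorical), the integer encoding of its
#' levels (empty for continuous features), a missing-data rate used by the
#' synthetic generator, and optional generation parameters.
#'
#' @param name Feature name (single string).
#' @param kind One of `"continuous"`, `"ordinal"`, `"categorical"`.
#' @param levels Named character vector mapping integer codes (names) to level
#'   labels, e.g. `c("1" = "quadrantectomy", "2" = "mastectomy")`. Must be
#'   empty for continuous features; codes must be consecutive integers
#'   starting at 0 or 1 with unique labels.
#' @param missing_rate Fraction of entries set missing by the generator.
#' @param gen Optional list of generation parameters. For continuous features:
#'   `mean`, `sd`, `lower`, `upper`, `integer` (truncated normal, optionally
#'   rounded). For coded features: `probs`, the level probabilities.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(name, kind = c("continuous", "ordinal",
                                          "categorical"),
                           levels = character(), missing_rate = 0,
                           gen = NULL) {
  kind <- match.arg(kind)
  assert_fraction(missing_rate, "missing_rate")
  if (kind == "continuous") {
    if (length(levels) > 0)
      stop_idex("continuous feature `%s` cannot have levels", name)
  } else {
    codes <- as.integer(names(levels))
    if (length(codes) < 2 || anyNA(codes))
      stop_idex("feature `%s`: levels must be named by integer codes", name)
    if (!identical(codes, seq(min(codes), length.out = length(codes))) ||
        min(codes) < 0)
      stop_idex("feature `%s`: codes must be consecutive from 0 or 1", name)
    if (anyDuplicated(levels))
      stop_idex("feature `%s`: duplicated level labels", name)
  }
  structure(list(name = name, kind = kind, levels = levels,
                 missing_rate = missing_rate, gen = gen),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %s (%s)", x$name, x$kind))
  if (length(x$levels))
    cat(": ", paste(sprintf("%s=%s", names(x$levels), x$levels),
                    collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

cat_schema <- function(name, labels, probs, missing_rate = 0.05, from = 0L,
                       kind = "categorical") {
  codes <- seq(from, length.out = length(labels))
  feature_schema(name, kind, setNames(labels, codes), missing_rate,
                 gen = list(probs = probs))
}

num_schema <- function(name, mean, sd, lower, upper, integer = FALSE,
                       missing_rate = 0.05) {
  feature_schema(name, "continuous", missing_rate = missing_rate,
                 gen = list(mean = mean, sd = sd, lower = lower,
                            upper = upper, integer = integer))
}

#' Default 28-feature clinical schema
#'
#' The default schema of the synthetic generator: 28 mixed-type features
#' describing a first breast tumor and its therapy pathway, with the integer
#' encodings used throughout the package (e.g. surgery type 1 =
#' quadrantectomy, 2 = mastectomy; HT scheme codes 0-7 with 1 = Tamoxifen).
#' It includes a near-constant HER2 indicator (dominant level frequency
#' >= 0.95) and two lymph-node count features that the generator correlates
#' through a shared latent severity variable. Feature names not fixed by the
#' encoding rules are a plausible clinical reconstruction, not a published
#' list.
#'
#' @param missing_rate Default per-feature missing rate (MCAR), applied to
#'   every feature.
#' @return A list of 28 [feature_schema] objects.
#' @export
default_paper_schema <- function(missing_rate = 0.05) {
  m <- missing_rate
  s <- list(
    num_schema("age", 55, 12, 25, 90, TRUE, m),
    num_schema("diameter", 20, 10, 1, 80, FALSE, m),
    num_schema("er", 60, 35, 0, 100, FALSE, m),
    num_schema("pgr", 50, 35, 0, 100, FALSE, m),
    num_schema("ki67", 25, 15, 0, 95, FALSE, m),
    num_schema("eradicated_lymph_nodes", 12, 6, 0, 35, TRUE, m),
    num_schema("metastatic_lymph_nodes", 2, 3, 0, 25, TRUE, m),
    num_schema("ct_months", 4, 2, 0, 6, FALSE, m),
    cat_schema("in_situ_component",
               c("not present", "present, not typed", "G1", "G2", "G3"),
               c(.55, .10, .10, .15, .10), m, 0L, "ordinal"),
    cat_schema("lvi", c("not present", "present, not typed", "focal",
                        "extended"),
               c(.60, .10, .20, .10), m, 0L, "ordinal"),
    cat_schema("sentinel_lymph_node", c("negative", "not done", "positive"),
               c(.45, .35, .20), m),
    cat_schema("surgery_type", c("quadrantectomy", "mastectomy"),
               c(.65, .35), m, 1L),
    cat_schema("ct_scheme", c("absent", "anthracycline + taxanes",
                              "anthracycline", "taxanes", "CMF", "other"),
               c(.35, .25, .15, .08, .12, .05), m),
    cat_schema("ht_scheme", c("absent", "Tamoxifen", "LHRHa",
                              "Tamoxifen + LHRHa", "Aromatase Inhibitors",
                              "Tamoxifen + Aromatase Inhibitors",
                              "LHRHa + Aromatase Inhibitors", "other"),
               c(.25, .30, .08, .10, .15, .06, .04, .02), m),
    cat_schema("therapy_combination",
               c("No", "HT", "CT", "CT + HT", "CT + trastuzumab",
                 "CT + HT + trastuzumab"),
               c(.08, .30, .20, .30, .06, .06), m),
    cat_schema("multiplicity", c("no", "yes"), c(.75, .25), m),
    cat_schema("grading", c("G1", "G2", "G3"), c(.20, .45, .35), m, 1L,
               "ordinal"),
    cat_schema("lymph_node_status", c("negative", "positive"),
               c(.55, .45), m),
    cat_schema("lymph_node_dissection", c("no", "yes"), c(.35, .65), m),
    cat_schema("ct", c("no", "yes"), c(.35, .65), m),
    cat_schema("ht", c("no", "yes"), c(.25, .75), m),
    cat_schema("trastuzumab", c("no", "yes"), c(.88, .12), m),
    cat_schema("her2", c("negative", "positive"), c(.97, .03), m),
    cat_schema("menopausal_status", c("pre", "post"), c(.40, .60), m),
    cat_schema("histotype", c("ductal", "lobular", "mixed", "other"),
               c(.70, .15, .10, .05), m),
    cat_schema("pt_stage", c("pT1", "pT2", "pT3", "pT4"),
               c(.45, .40, .10, .05), m, 1L, "ordinal"),
    cat_schema("pn_stage", c("pN0", "pN1", "pN2", "pN3"),
               c(.50, .30, .12, .08), m, 0L, "ordinal"),
    cat_schema("radiotherapy", c("no", "yes"), c(.30, .70), m)
  )
  names(s) <- vapply(s, `[[`, "", "name")
  s
}

#' Default effect vector on the label log-odds
#'
#' Per-feature coefficients applied to standardized feature values in the
#' synthetic cohort's latent logistic model. Signs follow the clinical
#' direction of each prognostic factor (e.g. tumor size, Ki67 and metastatic
#' lymph nodes raise IDE risk; age, eradicated lymph nodes and adjuvant
#' therapy lower it); magnitudes around 0.3-1.0 per standard deviation give a
#' strongly separable cohort (latent-model AUC about 0.95-0.98).
#'
#' @param schema A schema list; features absent from the default table get 0.
#' @return Named numeric vector, one coefficient per schema feature.
#' @export
default_effect_vector <- function(schema = default_paper_schema()) {
  eff <- c(age = -0.8, diameter = 1.0, er = 0.8, pgr = -0.5, ki67 = 1.0,
           eradicated_lymph_nodes = -0.7, metastatic_lymph_nodes = 1.0,
           ct_months = -0.4, in_situ_component = 0.4, lvi = 0.6,
           sentinel_lymph_node = 0.3, surgery_type = 0.8, ct_scheme = -0.3,
           ht_scheme = -0.5, multiplicity = 0.6, grading = 0.7,
           lymph_node_status = 0.8, lymph_node_dissection = -0.4,
           ct = -0.3, ht = -0.4)
  out <- setNames(numeric(length(schema)), names(schema))
  common <- intersect(names(out), names(eff))
  out[common] <- eff[common]
  out
}

schema_to_list <- function(schema) {
  lapply(schema, function(s)
    list(name = s$name, kind = s$kind,
         levels = as.list(setNames(as.character(s$levels), names(s$levels))),
         missing_rate = s$missing_rate, gen = s$gen))
}

schema_from_list <- function(lst) {
  out <- lapply(lst, function(s) {
    lv <- unlist(s$levels)
    feature_schema(s$name, s$kind,
                   if (length(lv)) setNames(as.character(lv), names(lv))
                   else character(),
                   s$missing_rate %||% 0,
                   gen = s$gen)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
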