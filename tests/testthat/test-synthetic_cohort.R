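test_that("default schema reproduces the clinical encodings", {
  sch <- default_paper_schema()
  expect_length(sch, 28L)

  surg <- sch[["surgery_type"]]
  expect_identical(names(surg$levels), c("1", "2"))
  expect_identical(unname(surg$levels),
                   c("quadrantectomy", "mastectomy"))

  ht <- sch[["ht_scheme"]]
  expect_identical(names(ht$levels), as.character(0:7))
  expect_identical(unname(ht$levels[["1"]]), "Tamoxifen")

  expect_identical(unname(sch[["ct_scheme"]]$levels[["4"]]), "CMF")
  expect_identical(names(sch[["lvi"]]$levels), as.character(0:3))
  expect_identical(names(sch[["sentinel_lymph_node"]]$levels),
                   as.character(0:2))
  expect_identical(names(sch[["therapy_combination"]]$levels),
                   as.character(0:5))
  expect_identical(names(sch[["in_situ_component"]]$levels),
                   as.character(0:4))

  # constructor property: codes consecutive from 0 or 1
  for (s in sch) {
    if (s$kind == "continuous") next
    codes <- as.integer(names(s$levels))
    expect_identical(codes, seq(min(codes), length.out = length(codes)))
    expect_true(min(codes) %in% c(0L, 1L))
  }
})

test_that("schema constructor rejects malformed level maps", {
  expect_error(feature_schema("x", "categorical",
                              c("0" = "a", "2" = "b")), "consecutive")
  expect_error(feature_schema("x", "categorical",
                              c("0" = "a", "1" = "a")), "duplicated")
  expect_error(feature_schema("x", "continuous", c("0" = "a")), "levels")
  expect_error(feature_schema("x", "continuous", missing_rate = 1.2),
               "missing_rate")
})

test_that("generated cohorts match the stated statistical structure", {
  gen <- generate_cohort(cohort_config(n_patients = 486L, seed = 101L))
  cohort <- gen$cohort
  expect_s3_class(cohort, "idex_cohort")
  expect_length(cohort$patient_ids, 486L)
  expect_false(anyDuplicated(cohort$patient_ids) > 0)
  expect_true(all(cohort$labels %in% 0:1))

  # realized prevalence within 3 binomial standard deviations of target
  sd3 <- 3 * sqrt(0.29 * 0.71 / 486)
  expect_lt(abs(mean(cohort$labels) - 0.29), sd3)

  # surgery type codes are {1, 2}
  surg <- cohort$features$surgery_type
  expect_true(all(surg[!is.na(surg)] %in% c(1, 2)))

  # HER2-like near-constant feature: dominant level frequency >= 0.95
  her2 <- cohort$features$her2
  expect_gte(max(table(her2)) / sum(!is.na(her2)), 0.95)

  # lymph-node counts positively correlated through the latent severity
  cc <- cor(cohort$features$eradicated_lymph_nodes,
            cohort$features$metastatic_lymph_nodes,
            use = "complete.obs")
  expect_gt(cc, 0.3)

  # categorical values all within schema codes
  for (s in cohort$schema) {
    if (s$kind == "continuous") next
    v <- cohort$features[[s$name]]
    expect_true(all(v[!is.na(v)] %in% as.integer(names(s$levels))),
                label = s$name)
  }
})

test_that("confounder planting flips exactly the recorded patients", {
  cfg0 <- cohort_config(n_patients = 200L, seed = 7L,
                        confounder_fraction = 0)
  gen0 <- generate_cohort(cfg0)
  expect_identical(gen0$truth$confounder_ids, character())

  cfg <- cohort_config(n_patients = 200L, seed = 7L,
                       confounder_fraction = 0.12)
  gen <- generate_cohort(cfg)
  ids <- gen$truth$confounder_ids
  expect_length(ids, round(0.12 * 200))
  # flipped labels differ from the no-flip cohort exactly on the planted set
  diff <- gen0$cohort$patient_ids[gen0$cohort$labels != gen$cohort$labels]
  expect_setequal(diff, ids)

  # plant_confounders: paper-sized arithmetic, determinism, no-op, errors
  base <- gen0$cohort
  res1 <- plant_confounders(base, 0.12, seed = 3L)
  res2 <- plant_confounders(base, 0.12, seed = 3L)
  expect_identical(res1$flipped_ids, res2$flipped_ids)
  expect_identical(plant_confounders(base, 0)$flipped_ids, character())
  expect_identical(plant_confounders(base, 0)$cohort$labels, base$labels)
  expect_error(plant_confounders(base, 0.6), "fraction")

  big <- generate_cohort(cohort_config(n_patients = 486L, seed = 1L))$cohort
  expect_length(plant_confounders(big, 0.12, seed = 1L)$flipped_ids, 58L)
})

test_that("identical config and seed reproduce the cohort byte for byte", {
  cfg <- cohort_config(n_patients = 150L, seed = 33L,
                       confounder_fraction = 0.1)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg)$cohort, f1)
  write_cohort(generate_cohort(cfg)$cohort, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # round trip through CSV + JSON sidecar
  back <- read_cohort(f1)
  orig <- generate_cohort(cfg)$cohort
  expect_equal(back$labels, orig$labels)
  expect_equal(back$features, orig$features, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$horizon, orig$horizon)
  unlink(c(f1, f2, paste0(c(f1, f2), ".schema.json")))
})

test_that("prevalence control holds on average over seeds", {
  prev <- vapply(1:20, function(s) {
    mean(generate_cohort(cohort_config(n_patients = 400L,
                                       seed = s))$cohort$labels)
  }, 0.0)
  expect_lt(abs(mean(prev) - 0.29), 0.02)
})

test_that("degenerate effect vectors fail loudly, not silently", {
  sch <- default_paper_schema()
  ev <- setNames(numeric(28), names(sch)); ev["diameter"] <- 60
  expect_error(
    generate_cohort(cohort_config(n_patients = 100L, seed = 1L,
                                  target_prevalence = 1 - 1e-9,
                                  effect_vector = ev)),
    "intercept")
  expect_error(cohort_config(target_prevalence = 0), "target_prevalence")
  expect_error(cohort_config(confounder_fraction = 0.7),
               "confounder_fraction")
})
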