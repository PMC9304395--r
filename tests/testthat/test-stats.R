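test_that("variability analysis produces Map and Patient rows per tissue", {
  obs <- simulate_observations(5, 4, tissues = "stroma",
                               points_per_map = 30, seed = 12)
  res <- variability_analysis(obs)
  expect_setequal(res$term, c("Map", "Patient"))
  expect_equal(unique(res$tissue_type), "stroma")
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$F_value >= 0))
})

test_that("strong patient heterogeneity is detected, absent effects are not", {
  # large patient spread, no map spread: Patient term should dominate
  strong <- stiffness_effects(patient_sd = 1.5, map_sd = 0,
                              patient_tissue_sd = 0)
  hits <- vapply(1:10, function(s) {
    obs <- simulate_observations(6, 4, tissues = "stroma",
                                 points_per_map = 30,
                                 effects = strong, seed = 100 + s)
    res <- variability_analysis(obs)
    res$p_value[res$term == "Patient"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # fully null generator: no random spread and no clinical fixed effects
  null <- stiffness_effects(patient_sd = 0, map_sd = 0, patient_tissue_sd = 0,
                            left_colon = 0, stage_high = 0, ras = 0,
                            perinervous = 0)
  rejections <- vapply(1:10, function(s) {
    obs <- simulate_observations(6, 4, tissues = "stroma",
                                 points_per_map = 30,
                                 effects = null, seed = 200 + s)
    res <- variability_analysis(obs)
    sum(res$p_value < 0.05)
  }, numeric(1))
  expect_lte(mean(rejections), 0.6)  # ~2 tests/run at alpha 0.05
})

test_that("a single patient drops the Patient row with a notice", {
  obs <- simulate_observations(1, 3, tissues = "stroma",
                               points_per_map = 30, seed = 13)
  res <- variability_analysis(obs)
  expect_false("Patient" %in% res$term)
  expect_true("Map" %in% res$term)
  expect_match(attr(res, "notices"), "single patient", all = FALSE)
})

test_that("tissue contrasts reduce to log mean ratios without random noise", {
  # two balanced tissues, no random effects, near-degenerate gamma noise
  eff <- stiffness_effects(patient_sd = 0, patient_tissue_sd = 0, map_sd = 0,
                           gamma_shape = 1e7)
  obs <- simulate_observations(6, 2,
                               tissues = c("distal_normal", "stroma"),
                               points_per_map = 30, effects = eff, seed = 14)
  res <- tissue_contrasts(obs, reference = "normal")
  means <- tapply(obs$E_kPa, obs$tissue_type, mean)
  expect_equal(res$beta[res$contrast == "stroma vs normal"],
               unname(log(means["stroma"] / means["distal_normal"])),
               tolerance = 1e-3)
})

test_that("tissue pooling merges labels as requested", {
  obs <- simulate_observations(4, 4, seed = 15)
  pooled <- pool_tissues(obs, normal = TRUE, tumor_stroma = TRUE)
  expect_false(any(c("distal_normal", "proximal_normal", "tumor_epithelium",
                     "stroma") %in% pooled$tissue_type))
  expect_true(all(c("normal", "T+S", "mixed") %in% pooled$tissue_type))
  res <- tissue_contrasts(obs, reference = "normal", pool_tumor_stroma = TRUE)
  expect_setequal(res$contrast, c("T+S vs normal", "mixed vs normal"))
  expect_error(tissue_contrasts(obs, reference = "bone"), "absent")
})

test_that("clinical associations test one covariate at a time", {
  obs <- simulate_observations(12, 4, seed = 16) |>
    dplyr::filter(tissue_type %in% c("tumor_epithelium", "stroma", "mixed"))
  res <- clinical_associations(
    obs, covariates = c("location", "stage_group", "ras", "msi_status"))
  expect_setequal(res$covariate,
                  c("location", "stage_group", "ras", "msi_status"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_true(all(res$n_maps >= 1))
})

test_that("constant covariates are skipped with a notice", {
  obs <- simulate_observations(6, 2, seed = 17)
  obs$ras <- FALSE
  res <- clinical_associations(obs, covariates = c("ras", "location"))
  expect_false(any(grepl("ras", res$covariate)))
  expect_match(attr(res, "notices"), "constant", all = FALSE)
})

test_that("covariates unrelated to stiffness stay near zero", {
  # a generator with no clinical effects at all: every covariate is null
  eff0 <- stiffness_effects(left_colon = 0, stage_high = 0, ras = 0,
                            perinervous = 0)
  betas <- ps <- numeric(10)
  for (s in 1:10) {
    obs <- simulate_observations(12, 3,
                                 tissues = c("tumor_epithelium", "stroma",
                                             "mixed"),
                                 points_per_map = 30, effects = eff0,
                                 seed = 300 + s)
    res <- clinical_associations(obs, covariates = "mucinous")
    if (nrow(res) == 0) { betas[s] <- NA; ps[s] <- NA; next }
    betas[s] <- res$beta; ps[s] <- res$p_value
  }
  expect_lt(median(abs(betas), na.rm = TRUE), 0.5)
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.7)
})

test_that("descriptive summary reproduces clinical baseline proportions", {
  ref <- reference_cohort()
  tab <- descriptive_summary(ref)
  get <- function(var, lvl, col) {
    unname(tab[[col]][tab$variable == var & tab$level == lvl])
  }
  expect_equal(get("Sex", "F", "percentage"), 61.1)
  expect_equal(get("CRC location", "Right", "percentage"), 55.6)
  expect_equal(get("Stage", "II", "n"), 10L)
  expect_equal(get("MSI status", "MSI", "percentage"), 50)
  # mutation-type percentages are among mutated patients
  expect_equal(get("Mutation type", "KRAS mutated", "n"), 7L)
  expect_equal(get("Mutation type", "KRAS mutated", "percentage"), 58.3)
  # age block
  expect_equal(get("Age (years)", "Median", "value"), "65")
  expect_equal(get("Age (years)", "Range", "value"), "55-85")
})

test_that("descriptive summary handles empty levels and bad schemas", {
  coh <- simulate_cohort(6, freq = list(stage = c(I = 0, II = 1, III = 0,
                                                  IV = 0)), seed = 18)
  tab <- descriptive_summary(coh)
  expect_equal(tab$n[tab$variable == "Stage" & tab$level == "IV"], 0L)
  expect_equal(tab$percentage[tab$variable == "Stage" & tab$level == "IV"], 0)
  expect_error(descriptive_summary(dplyr::select(coh, -age)), "lacks column")
})
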