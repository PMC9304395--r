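#' Pool tissue labels for contrast analyses
#'
#' Two poolings used when contrasting tissue types: distal and proximal
#' normal epithelium merge into `"normal"`, and tumor epithelium plus stroma
#' merge into `"T+S"`.
#'
#' @param data Observation tibble with a `tissue_type` column.
#' @param normal Merge `distal_normal` and `proximal_normal` into `"normal"`.
#' @param tumor_stroma Merge `tumor_epithelium` and `stroma` into `"T+S"`.
#' @return The tibble with `tissue_type` recoded.
#' @export
pool_tissues <- function(data, normal = TRUE, tumor_stroma = FALSE) {
  out <- data
  if (normal) {
    out$tissue_type[out$tissue_type %in%
                      c("distal_normal", "proximal_normal")] <- "normal"
  }
  if (tumor_stroma) {
    out$tissue_type[out$tissue_type %in%
                      c("tumor_epithelium", "stroma")] <- "T+S"
  }
  out
}

#' Intra- and inter-patient stiffness variability within a tissue type
#'
#' For each tissue type, quantifies how much maps of one patient differ from
#' each other (intra-individual variability) and how much patients differ
#' from each other (inter-individual variability), each with a Wald F test
#' from a gamma/log PQL model:
#' * the **Map** row fits map identity as a fixed effect with a patient
#'   random intercept;
#' * the **Patient** row fits patient identity as a fixed effect with a map
#'   random intercept.
#'
#' Patients represented by a single map cannot inform the Map row and tissue
#' types with a single patient get no Patient row (a notice is attached).
#'
#' @param data Observation tibble (`E_kPa`, `patient_id`, `map_id`,
#'   `tissue_type`).
#' @param tissue Optional subset of tissue types; default all present.
#' @return A tibble with one row per (tissue_type, term): `tissue_type`,
#'   `term` (`"Map"`/`"Patient"`), `F_value`, `p_value`, `n_maps`,
#'   `n_patients`; skipped rows are listed in the `notices` attribute.
#' @export
variability_analysis <- function(data, tissue = NULL) {
  stopifnot(all(c("E_kPa", "patient_id", "map_id", "tissue_type") %in%
                  names(data)))
  tissues <- tissue %||% sort(unique(data$tissue_type))
  notices <- character(0)
  rows <- purrr::map(tissues, function(tt) {
    d <- dplyr::filter(data, .data$tissue_type == tt)
    n_maps <- dplyr::n_distinct(d$map_id)
    n_pat <- dplyr::n_distinct(d$patient_id)
    res <- list()
    if (n_maps >= 2) {
      fit_map <- suppressMessages(
        fit_gamma_glmm(d, E_kPa ~ map_id, ~ 1 | patient_id))
      res$Map <- wald_f_test(fit_map, "map_id")
    } else {
      notices <<- c(notices, paste0(tt, ": single map, Map row dropped"))
    }
    if (n_pat >= 2) {
      fit_pat <- suppressMessages(
        fit_gamma_glmm(d, E_kPa ~ patient_id, ~ 1 | map_id))
      res$Patient <- wald_f_test(fit_pat, "patient_id")
    } else {
      notices <<- c(notices,
                    paste0(tt, ": single patient, Patient row dropped"))
    }
    if (length(res) == 0) return(NULL)
    dplyr::bind_rows(res) |>
      dplyr::mutate(
        tissue_type = tt,
        term = dplyr::recode(.data$term, map_id = "Map", patient_id = "Patient"),
        n_maps = n_maps, n_patients = n_pat,
        .before = 1
      ) |>
      dplyr::select("tissue_type", "term", "F_value", "p_value",
                    "n_maps", "n_patients")
  })
  structure(dplyr::bind_rows(rows), notices = notices)
}

#' Tissue-type stiffness contrasts
#'
#' Pairwise comparisons of tissue-type stiffness with the full hierarchical
#' random structure: tissue type fixed; patient, patient-by-tissue and map
#' random intercepts (the patient-by-tissue level carries the cross-effect
#' between maps and tissue types). Reported per non-reference level:
#' log-scale estimate, its SD, t value and p value.
#'
#' @param data Observation tibble (`E_kPa`, `patient_id`, `map_id`,
#'   `tissue_type`).
#' @param reference Reference tissue level, present in the data.
#' @param pool_normal Merge distal and proximal normal epithelium into
#'   `"normal"` before fitting.
#' @param pool_tumor_stroma Merge tumor epithelium and stroma into `"T+S"`.
#' @return A tibble: `contrast` (level vs reference), `beta`, `sd`,
#'   `t_value`, `p_value`, with the fitted `gamma_pql` model in the `fit`
#'   attribute.
#' @export
tissue_contrasts <- function(data, reference = "normal",
                             pool_normal = TRUE, pool_tumor_stroma = FALSE) {
  d <- pool_tissues(data, normal = pool_normal,
                    tumor_stroma = pool_tumor_stroma)
  if (!reference %in% d$tissue_type) {
    stop("reference level `", reference, "` absent from the data",
         call. = FALSE)
  }
  if (dplyr::n_distinct(d$tissue_type) < 2) {
    stop("need at least two tissue types to contrast", call. = FALSE)
  }
  d$tissue_type <- stats::relevel(factor(d$tissue_type), ref = reference)
  fit <- suppressMessages(fit_gamma_glmm(
    d, E_kPa ~ tissue_type, ~ 1 | patient_id / tissue_type / map_id))
  td <- tidy.gamma_pql(fit) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::mutate(contrast = paste0(sub("^tissue_type", "", .data$term),
                                    " vs ", reference)) |>
    dplyr::select("contrast", beta = "estimate", sd = "std.error",
                  t_value = "statistic", p_value = "p.value")
  structure(td, fit = fit, reference = reference)
}

default_reference_levels <- function() {
  list(sex = "F", location = "Left", mucinous = "No", lymphovascular = "No",
       perinervous = "No", stage_group = "I+II", msi_status = "MSI")
}

#' Clinical and molecular covariate associations with tumor stiffness
#'
#' Tests each clinical or molecular covariate, one at a time, against tumor
#' stiffness (tumor epithelium, stroma and mixed-zone observations combined)
#' in a gamma/log PQL model with patient and map random intercepts. For each
#' covariate the table reports the number of maps carrying the non-reference
#' level, the log-scale estimate and the t-test p value. Covariates constant
#' across the data are skipped with a notice.
#'
#' @param data Tumor observation tibble already joined with cohort
#'   covariates (as produced by [simulate_observations()]), or join `cohort`
#'   by `patient_id` first.
#' @param cohort Optional cohort tibble to join on `patient_id`.
#' @param covariates Covariate columns to test; defaults to the clinical
#'   set: sex, location, age, mucinous, lymphovascular, perinervous,
#'   stage_group, kras, nras, ras, braf, msi_status.
#' @param reference_levels Named list of reference levels for factor
#'   covariates (defaults: female, left colon, stage I+II, MSI, "No" for
#'   pathology flags).
#' @return A tibble: `covariate`, `n_maps` (maps at the non-reference
#'   level), `beta`, `p_value`; skipped covariates in the `notices`
#'   attribute.
#' @export
clinical_associations <- function(data, cohort = NULL,
                                  covariates = c("sex", "location", "age",
                                                 "mucinous", "lymphovascular",
                                                 "perinervous", "stage_group",
                                                 "kras", "nras", "ras", "braf",
                                                 "msi_status"),
                                  reference_levels = default_reference_levels()) {
  if (!is.null(cohort)) {
    data <- dplyr::left_join(
      data, dplyr::select(cohort, -dplyr::any_of(c("b_patient"))),
      by = "patient_id")
  }
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate(s) not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  notices <- character(0)
  rows <- purrr::map(covariates, function(cv) {
    d <- data[!is.na(data[[cv]]), , drop = FALSE]
    x <- d[[cv]]
    if (dplyr::n_distinct(x) < 2) {
      notices <<- c(notices, paste0(cv, ": constant across patients, skipped"))
      return(NULL)
    }
    numeric_cov <- is.numeric(x) && !is.logical(x)
    if (!numeric_cov) {
      x <- factor(x)
      ref <- reference_levels[[cv]]
      if (!is.null(ref) && ref %in% levels(x)) x <- stats::relevel(x, ref = ref)
      d[[cv]] <- x
      n_maps <- dplyr::n_distinct(d$map_id[x != levels(x)[1]])
    } else {
      n_maps <- dplyr::n_distinct(d$map_id)
    }
    fml <- stats::as.formula(paste("E_kPa ~", cv))
    fit <- suppressMessages(
      fit_gamma_glmm(d, fml, ~ 1 | patient_id / map_id))
    td <- tidy.gamma_pql(fit)
    td <- td[td$term != "(Intercept)", , drop = FALSE]
    tibble::tibble(
      covariate = if (nrow(td) == 1) cv else paste0(cv, ": ",
                                                    sub(paste0("^", cv), "",
                                                        td$term)),
      n_maps = n_maps,
      beta = td$estimate,
      p_value = td$p.value
    )
  })
  structure(dplyr::bind_rows(rows), notices = notices)
}

#' Descriptive cohort summary
#'
#' Standard clinical baseline table: mean, SD, median and range for age;
#' counts and percentages per level for the categorical covariates
#' (mutation-type percentages are computed among mutated patients, matching
#' clinical reporting practice).
#'
#' @param cohort A cohort tibble (see [simulate_cohort()] /
#'   [reference_cohort()]).
#' @return A tibble: `variable`, `level`, `n`, `percentage` (categorical
#'   rows) and `value` (age summary rows).
#' @export
descriptive_summary <- function(cohort) {
  need <- c("age", "sex", "location", "mucinous", "lymphovascular",
            "perinervous", "stage", "msi_status", "mutation_status",
            "kras", "nras", "braf")
  missing_col <- setdiff(need, names(cohort))
  if (length(missing_col)) {
    stop("cohort table lacks column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  n_total <- nrow(cohort)
  age_rows <- tibble::tibble(
    variable = "Age (years)",
    level = c("Mean +/- SD", "Median", "Range"),
    n = NA_integer_, percentage = NA_real_,
    value = c(sprintf("%.1f +/- %.1f", mean(cohort$age), sd(cohort$age)),
              sprintf("%.0f", median(cohort$age)),
              sprintf("%.0f-%.0f", min(cohort$age), max(cohort$age)))
  )
  cat_var <- function(var, label, levels_order = NULL) {
    x <- cohort[[var]]
    lv <- levels_order %||% sort(unique(x))
    tibble::tibble(
      variable = label, level = lv,
      n = unname(vapply(lv, function(l) sum(x == l), integer(1))),
      value = NA_character_
    ) |>
      dplyr::mutate(percentage = round(100 * .data$n / n_total, 1))
  }
  cat_rows <- dplyr::bind_rows(
    cat_var("sex", "Sex", c("M", "F")),
    cat_var("location", "CRC location", c("Right", "Left")),
    cat_var("mucinous", "Mucinous component", c("Yes", "No")),
    cat_var("lymphovascular", "Lymphovascular infiltration", c("Yes", "No")),
    cat_var("perinervous", "Perinervous infiltration", c("Yes", "No")),
    cat_var("stage", "Stage", c("I", "II", "III", "IV")),
    cat_var("msi_status", "MSI status", c("MSS", "MSI")),
    cat_var("mutation_status", "Mutation status",
            intersect(c("WT", "Mutated (1)", "Mutated (>=2)"),
                      unique(cohort$mutation_status)))
  )
  n_mut <- sum(cohort$mutation_status != "WT")
  mut_rows <- tibble::tibble(
    variable = "Mutation type",
    level = c("KRAS mutated", "NRAS mutated", "BRAF mutated"),
    n = c(sum(cohort$kras), sum(cohort$nras), sum(cohort$braf)),
    value = NA_character_
  ) |>
    dplyr::mutate(percentage = if (n_mut > 0) {
      round(100 * .data$n / n_mut, 1)
    } else {
      0
    })
  dplyr::bind_rows(age_rows, cat_rows, mut_rows) |>
    dplyr::select("variable", "level", "n", "percentage", "value")
}
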