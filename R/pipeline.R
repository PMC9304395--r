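#' Run the full synthetic-cohort stiffness pipeline
#'
#' End-to-end execution of every stage on simulated data: cohort generation,
#' per-map ground-truth stiffness fields and raw force curves (with a
#' configurable fraction of artifact curves), per-curve Hertz fitting and
#' quality control, map assembly, coverage filtering, and the statistics
#' layer (descriptive summary, variability, tissue contrasts, clinical
#' associations where estimable). All randomness derives from `seed`.
#'
#' @param n_patients Patients to simulate.
#' @param maps_per_patient Force maps per patient (tissues cycle over
#'   `tissues`).
#' @param tissues Tissue types assigned to successive maps of a patient.
#' @param config An [afm_config()]. The default pipeline uses a 25 nm piezo
#'   sampling step to keep the demo quick; pass a config with finer spacing
#'   for production-sized curves.
#' @param effects A [stiffness_effects()] generator setting.
#' @param artifact_rate Fraction of pixels per map corrupted by a random
#'   artifact kind.
#' @param coverage_threshold_um Map-retention threshold on the coverage
#'   index, µm.
#' @param out_dir Optional directory: when given, raw curves (TSV) and all
#'   result tables (CSV + JSON summary) are written there.
#' @param seed Integer seed.
#' @param overwrite Passed to [write_results()].
#' @return A `mechamap_run` list: `cohort`, `pixels` (per-curve fits with QC
#'   flags), `coverage`, `observations` (valid pixels of retained maps),
#'   `descriptive`, `coverage_anova`, `variability`, `contrasts`,
#'   `clinical`, `counts`, and `no_data` (TRUE when no map survived
#'   filtering, in which case the statistics entries are `NULL`).
#' @export
run_pipeline <- function(n_patients = 4, maps_per_patient = 2,
                         tissues = c("distal_normal", "tumor_epithelium",
                                     "stroma", "mixed"),
                         config = afm_config(sample_spacing_nm = 25),
                         effects = stiffness_effects(),
                         artifact_rate = 0.1,
                         coverage_threshold_um = 8,
                         out_dir = NULL, seed = 1L, overwrite = FALSE) {
  cohort <- simulate_cohort(n_patients, effects = effects, seed = seed)
  map_plan <- tidyr::expand_grid(
    patient_id = cohort$patient_id,
    map_index = seq_len(maps_per_patient)
  ) |>
    dplyr::mutate(
      map_id = paste0(.data$patient_id, "_M", .data$map_index),
      tissue_type = tissues[(.data$map_index - 1L) %% length(tissues) + 1L]
    ) |>
    dplyr::left_join(cohort, by = "patient_id")

  all_pixels <- list()
  all_curves <- if (!is.null(out_dir)) list() else NULL
  counts <- c(permanent_contact = 0L, ill_defined_contact = 0L,
              too_noisy = 0L, non_converged = 0L, passed = 0L)
  kinds_pool <- c("permanent_contact", "short_baseline", "high_noise")
  for (i in seq_len(nrow(map_plan))) {
    row <- map_plan[i, ]
    map_seed <- (seed %% 20000L) * 7919L + i
    eta <- map_linear_predictor(effects, row$tissue_type, row) +
      withr::with_seed(map_seed, rnorm(1, 0, effects$map_sd))
    field <- simulate_stiffness_field(eta, effects$gamma_shape,
                                      grid_n = config$grid_n,
                                      seed = map_seed + 1L)
    kinds <- withr::with_seed(map_seed + 2L, {
      k <- rep("clean", config$grid_n^2)
      n_bad <- round(artifact_rate * length(k))
      if (n_bad > 0) {
        k[sample(length(k), n_bad)] <- sample(kinds_pool, n_bad, replace = TRUE)
      }
      k
    })
    fm <- simulate_force_map(
      field, config, artifact_kinds = kinds,
      map_id = row$map_id, patient_id = row$patient_id,
      slide_id = paste0(row$patient_id, "_S1"), probe_id = "probe1",
      tissue_type = row$tissue_type, seed = map_seed + 3L
    )
    px <- process_map(fm$curves, fm$manifest, config)
    counts <- counts + attr(px, "exclusions")
    all_pixels[[i]] <- px
    if (!is.null(out_dir)) all_curves[[i]] <- fm$curves
  }
  pixels <- dplyr::bind_rows(all_pixels)
  attr(pixels, "exclusions") <- counts

  retained <- filter_maps(pixels, threshold_um = coverage_threshold_um,
                          pitch_um = config$pitch_um)
  coverage <- attr(retained, "coverage_report")
  no_data <- nrow(retained) == 0 || sum(retained$valid) == 0

  descriptive <- descriptive_summary(cohort)
  cov_anova <- variability <- contrasts <- clinical <- obs <- NULL
  if (!no_data) {
    obs <- retained |>
      dplyr::filter(.data$valid) |>
      dplyr::select("patient_id", "map_id", "tissue_type", "E_kPa") |>
      dplyr::left_join(cohort, by = "patient_id")
    cov_anova <- tryCatch(coverage_anova(coverage), error = function(e) NULL)
    variability <- tryCatch(variability_analysis(obs), error = function(e) NULL)
    contrasts <- tryCatch(tissue_contrasts(obs), error = function(e) NULL)
    tumor_obs <- dplyr::filter(
      obs, .data$tissue_type %in% c("tumor_epithelium", "stroma", "mixed"))
    clinical <- if (nrow(tumor_obs) > 0) {
      tryCatch(clinical_associations(tumor_obs), error = function(e) NULL)
    }
  } else {
    message("no maps survived coverage filtering: no data for statistics")
  }

  out <- structure(
    list(cohort = cohort, pixels = pixels, coverage = coverage,
         observations = obs, descriptive = descriptive,
         coverage_anova = cov_anova, variability = variability,
         contrasts = contrasts, clinical = clinical,
         counts = counts, no_data = no_data, seed = seed, config = config),
    class = "mechamap_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_force_curves(dplyr::bind_rows(all_curves),
                       file.path(out_dir, "force_curves.tsv"))
    write_results(
      list(pixels = pixels, coverage = coverage, observations = obs,
           descriptive = descriptive, variability = variability,
           contrasts = if (!is.null(contrasts)) tibble::as_tibble(contrasts),
           clinical = if (!is.null(clinical)) tibble::as_tibble(clinical)),
      out_dir, config = config, seed = seed, counts = counts,
      overwrite = overwrite
    )
  }
  out
}

#' @export
print.mechamap_run <- function(x, ...) {
  cat("<mechamap_run>\n")
  cat(sprintf("  %d patients, %d curves processed (%d passed QC)\n",
              nrow(x$cohort), sum(x$counts[c("permanent_contact",
                                             "ill_defined_contact",
                                             "too_noisy", "passed")],
                                  x$counts["non_converged"]),
              x$counts["passed"]))
  cat("  exclusions:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  if (x$no_data) {
    cat("  no data after coverage filtering\n")
  } else {
    cat(sprintf("  %d maps retained of %d\n",
                sum(x$coverage$retained), nrow(x$coverage)))
  }
  invisible(x)
}
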