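#' Default covariate frequencies for the virtual cohort
#'
#' Marginal frequencies of the clinical and molecular covariates used by
#' [simulate_cohort()]. Defaults reproduce the composition of an 18-patient
#' colon-adenocarcinoma cohort: 11/18 female, 8/18 left-sided tumors, 8/18
#' mucinous, 10/18 with lymphovascular infiltration, 5/18 with perinervous
#' infiltration, stage I/II/III/IV in 1/10/3/4 patients, 9/18 microsatellite
#' instable, and a mutation mix with 8/18 RAS-mutated of which 7/8 carry a
#' KRAS mutation.
#'
#' Each scalar frequency is the probability of the *non-reference* level
#' (reference levels: female, right colon, non-mucinous, no infiltration,
#' stage I+II, MSI, wild type); setting every frequency to zero yields
#' all-reference patients.
#'
#' @return A named list of frequencies.
#' @export
cohort_frequencies <- function() {
  list(
    male = 7 / 18,
    left_colon = 8 / 18,
    mucinous = 8 / 18,
    lymphovascular = 10 / 18,
    perinervous = 5 / 18,
    stage = c(I = 1, II = 10, III = 3, IV = 4) / 18,
    mss = 9 / 18,
    ras = 8 / 18,
    kras_given_ras = 7 / 8,
    braf = 5 / 18
  )
}

#' Simulate a virtual patient cohort
#'
#' Draws per-patient clinical and molecular covariates from configurable
#' marginal frequencies, together with the true patient-level random
#' intercept (log-kPa scale) later injected into the stiffness generator.
#' Identical seeds give identical cohorts.
#'
#' @param n_patients Number of patients (>= 1).
#' @param freq Frequencies as from [cohort_frequencies()]; entries may be
#'   overridden. Scalars are probabilities of the non-reference level.
#' @param effects Generator settings from [stiffness_effects()] (supplies the
#'   patient random-intercept SD).
#' @param seed Integer seed.
#' @return A tibble with one row per patient: `patient_id`, `age`, `sex`
#'   (`F`/`M`), `location` (`Right`/`Left`), `mucinous`, `lymphovascular`,
#'   `perinervous` (`No`/`Yes`), `stage` (`I`–`IV`), `stage_group`
#'   (`I+II`/`III+IV`), `msi_status` (`MSI`/`MSS`), `kras`, `nras`, `braf`,
#'   `ras` (logical), `mutation_status`, and the ground-truth random
#'   intercept `b_patient` (log scale).
#' @examples
#' simulate_cohort(5, seed = 1)
#' @export
simulate_cohort <- function(n_patients, freq = cohort_frequencies(),
                            effects = stiffness_effects(), seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1) {
    stop("`n_patients` must be a positive count", call. = FALSE)
  }
  n <- as.integer(n_patients)
  fr <- utils::modifyList(cohort_frequencies(), freq)
  withr::with_seed(seed, {
    stage_p <- fr$stage / sum(fr$stage)
    stage <- names(stage_p)[apply(rmultinom(n, 1, stage_p), 2, which.max)]
    ras <- runif(n) < fr$ras
    kras <- ras & (runif(n) < fr$kras_given_ras)
    nras <- ras & !kras
    braf <- runif(n) < fr$braf
    tibble::tibble(
      patient_id = sprintf("P%02d", seq_len(n)),
      age = pmin(pmax(round(rnorm(n, 67.6, 9.7)), 40), 95),
      sex = ifelse(runif(n) < fr$male, "M", "F"),
      location = ifelse(runif(n) < fr$left_colon, "Left", "Right"),
      mucinous = ifelse(runif(n) < fr$mucinous, "Yes", "No"),
      lymphovascular = ifelse(runif(n) < fr$lymphovascular, "Yes", "No"),
      perinervous = ifelse(runif(n) < fr$perinervous, "Yes", "No"),
      stage = stage,
      stage_group = ifelse(stage %in% c("I", "II"), "I+II", "III+IV"),
      msi_status = ifelse(runif(n) < fr$mss, "MSS", "MSI"),
      kras = kras, nras = nras, braf = braf, ras = ras,
      mutation_status = dplyr::case_when(
        kras + nras + braf >= 2 ~ "Mutated (>=2)",
        kras | nras | braf ~ "Mutated (1)",
        TRUE ~ "WT"
      ),
      b_patient = rnorm(n, 0, effects$patient_sd)
    )
  })
}

#' Frozen 18-patient reference cohort
#'
#' A deterministic cohort whose covariate margins match the published
#' 18-patient descriptive table exactly: 11 female / 7 male, 10 right / 8
#' left colon, 8 mucinous, 10 lymphovascular and 5 perinervous infiltrations,
#' stages I/II/III/IV = 1/10/3/4, 9 MSI / 9 MSS, 6 wild-type patients, 8
#' RAS-mutated of whom 7 carry KRAS (87.5%). The printed mutation-type rows
#' are not mutually consistent (11 single + 1 double mutation cannot yield
#' 7+1+4 gene hits); this table preserves the KRAS/NRAS/RAS counts and the
#' single/double split, at the cost of 5 rather than 4 BRAF carriers. Ages
#' are synthetic values consistent with the printed summary (range 55–85,
#' median 65, mean about 67.7).
#'
#' The joint assignment across patients is synthetic: only the margins are
#' anchored to the published counts.
#'
#' @return A tibble with the same schema as [simulate_cohort()] (without
#'   `b_patient`).
#' @export
reference_cohort <- function() {
  sexes <- rep(c("F", "M"), c(11, 7))
  tibble::tibble(
    patient_id = sprintf("P%02d", 1:18),
    age = c(55, 56, 57, 58, 60, 62, 63, 64, 64, 66, 67, 69, 73, 77, 79, 81, 83, 85),
    sex = sexes[c(1:6, 12:14, 7:9, 15:17, 10:11, 18)],
    location = rep(c("Right", "Left"), c(10, 8))[c(1:5, 11:14, 6:10, 15:18)],
    mucinous = rep(c("Yes", "No"), c(8, 10))[c(1:4, 9:13, 5:8, 14:18)],
    lymphovascular = rep(c("Yes", "No"), c(10, 8))[c(1:5, 11:14, 6:10, 15:18)],
    perinervous = rep(c("Yes", "No"), c(5, 13))[c(1:3, 6:12, 4:5, 13:18)],
    stage = c("II", "I", "II", "III", "II", "IV", "II", "III", "II", "IV",
              "II", "III", "II", "IV", "II", "IV", "II", "II"),
    msi_status = rep(c("MSI", "MSS"), 9),
    kras = c(rep(TRUE, 7), rep(FALSE, 11)),
    nras = c(rep(FALSE, 7), TRUE, rep(FALSE, 10)),
    braf = c(rep(FALSE, 6), TRUE, FALSE, rep(TRUE, 4), rep(FALSE, 6))
  ) |>
    dplyr::mutate(
      stage_group = ifelse(.data$stage %in% c("I", "II"), "I+II", "III+IV"),
      ras = .data$kras | .data$nras,
      mutation_status = dplyr::case_when(
        .data$kras + .data$nras + .data$braf >= 2 ~ "Mutated (>=2)",
        .data$kras | .data$nras | .data$braf ~ "Mutated (1)",
        TRUE ~ "WT"
      )
    )
}

#' Generator settings for the stiffness ground truth
#'
#' Parameters of the hierarchical gamma model the synthetic data are drawn
#' from, and that the statistics layer must invert. Stiffness for a pixel of
#' map m, tissue t, patient i is gamma-distributed with log-mean
#' \deqn{\eta = \log(\mu_0) + \beta_t + x_i'\gamma + b_i + b_{it} + b_m,}
#' where `mu_0` is the normal-mucosa mean (kPa), `beta_t` the tissue effect,
#' `gamma` the clinical effects, and the `b` terms independent Gaussian
#' random intercepts for patient, patient x tissue, and map.
#'
#' Default effect magnitudes are the study-scale values: normal mucosa mean
#' 0.07 kPa (soft, below 0.1 kPa); tissue effects (log scale, vs normal
#' epithelium) tumor epithelium +0.192, stroma +2.18, mixed +1.75; clinical
#' effects left location +0.564, stage III+IV +0.90, RAS mutation +0.498,
#' perinervous infiltration +0.625 (all other covariates 0). Random-effect
#' SDs (patient 0.6, patient x tissue 0.1, map 0.2) and gamma shape 2 are
#' calibrated so that at the study design (about 20 patients with one map
#' per tissue, around 56 values per map) a tumor-vs-normal contrast carries
#' a standard error near 0.08 on the log scale, matching the reported
#' uncertainty of that contrast. A per-probe offset exists but defaults to
#' zero.
#'
#' @param ... Named overrides of any default.
#' @return A `stiffness_effects` list.
#' @export
stiffness_effects <- function(...) {
  defaults <- list(
    baseline_kPa = 0.07,
    tissue = c(distal_normal = 0, proximal_normal = 0,
               tumor_epithelium = 0.192, stroma = 2.18, mixed = 1.75),
    left_colon = 0.564,
    stage_high = 0.90,
    ras = 0.498,
    perinervous = 0.625,
    male = 0, mucinous = 0, lymphovascular = 0, mss = 0, braf = 0, age = 0,
    patient_sd = 0.6,
    patient_tissue_sd = 0.1,
    map_sd = 0.2,
    probe_sd = 0,
    gamma_shape = 2
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown effect setting(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (length(over)) defaults <- utils::modifyList(defaults, over)
  stopifnot(defaults$gamma_shape > 0, defaults$baseline_kPa > 0)
  structure(defaults, class = "stiffness_effects")
}

# linear predictor (log kPa) for one map given a cohort row and tissue type
map_linear_predictor <- function(effects, tissue_type, patient_row = NULL) {
  eta <- log(effects$baseline_kPa) + unname(effects$tissue[tissue_type])
  if (!is.null(patient_row)) {
    eta <- eta +
      effects$left_colon * (patient_row$location == "Left") +
      effects$stage_high * (patient_row$stage_group == "III+IV") +
      effects$ras * patient_row$ras +
      effects$perinervous * (patient_row$perinervous == "Yes") +
      effects$male * (patient_row$sex == "M") +
      effects$mucinous * (patient_row$mucinous == "Yes") +
      effects$lymphovascular * (patient_row$lymphovascular == "Yes") +
      effects$mss * (patient_row$msi_status == "MSS") +
      effects$braf * patient_row$braf +
      patient_row$b_patient
  }
  unname(eta)
}

#' Simulate a ground-truth stiffness field
#'
#' Draws a grid of true per-pixel Young's moduli from a gamma distribution
#' with mean `exp(linear_predictor)` (kPa) and the given shape; pixels are
#' independent by default. With `correlation_range > 0` a smoothed Gaussian
#' copula introduces spatial autocorrelation for robustness experiments.
#'
#' @param linear_predictor Log mean stiffness, log(kPa).
#' @param gamma_shape Gamma shape parameter (> 0); the pixel coefficient of
#'   variation is `1/sqrt(shape)`.
#' @param grid_n Pixels per side.
#' @param seed Integer seed.
#' @param correlation_range Range (in pixels) of optional spatial smoothing
#'   of the latent field; 0 (default) gives independent pixels.
#' @return A `grid_n` x `grid_n` matrix of true moduli in kPa.
#' @examples
#' field <- simulate_stiffness_field(log(0.07), 2, seed = 1)
#' mean(field)
#' @export
simulate_stiffness_field <- function(linear_predictor, gamma_shape = 2,
                                     grid_n = 10L, seed = 1L,
                                     correlation_range = 0) {
  if (!is.numeric(gamma_shape) || gamma_shape <= 0) {
    stop("`gamma_shape` must be positive", call. = FALSE)
  }
  mu <- exp(linear_predictor)
  withr::with_seed(seed, {
    n <- grid_n * grid_n
    if (correlation_range > 0) {
      latent <- matrix(rnorm(n), grid_n, grid_n)
      w <- ceiling(correlation_range)
      sm <- latent
      for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
        ri <- max(1, i - w):min(grid_n, i + w)
        rj <- max(1, j - w):min(grid_n, j + w)
        sm[i, j] <- mean(latent[ri, rj])
      }
      u <- stats::pnorm(as.vector(sm) / sd(as.vector(sm)))
      vals <- stats::qgamma(u, shape = gamma_shape, scale = mu / gamma_shape)
    } else {
      vals <- rgamma(n, shape = gamma_shape, scale = mu / gamma_shape)
    }
    matrix(vals, grid_n, grid_n)
  })
}

#' Simulate per-map stiffness observations for the statistics layer
#'
#' Fast generator of quality-filtered stiffness observations (no force
#' curves): patients with covariates, maps per patient with tissue labels,
#' and gamma-distributed moduli per map under the hierarchical model of
#' [stiffness_effects()]. This is the generator used for null-calibration
#' and parameter-recovery experiments.
#'
#' @param n_patients Number of patients.
#' @param maps_per_patient Maps per patient; tissues are assigned by cycling
#'   through `tissues`.
#' @param tissues Character vector of tissue types to cycle over.
#' @param points_per_map Either `"study"` (draw per-map counts like the
#'   filtered study maps: centred on 56 values, truncated to 21–93) or a
#'   fixed integer.
#' @param effects A [stiffness_effects()] object.
#' @param cohort Optional pre-built cohort tibble (from [simulate_cohort()]);
#'   default simulates one with the same seed.
#' @param seed Integer seed.
#' @return A tibble of observations: `patient_id`, `map_id`, `tissue_type`,
#'   `E_kPa`, joined cohort covariates, plus a `truth` attribute holding the
#'   effects object and the per-map linear predictors.
#' @export
simulate_observations <- function(n_patients = 20, maps_per_patient = 4,
                                  tissues = c("distal_normal",
                                              "tumor_epithelium",
                                              "stroma", "mixed"),
                                  points_per_map = "study",
                                  effects = stiffness_effects(),
                                  cohort = NULL, seed = 1L) {
  stopifnot(n_patients >= 1, maps_per_patient >= 1)
  if (is.null(cohort)) {
    cohort <- simulate_cohort(n_patients, effects = effects, seed = seed)
  }
  withr::with_seed(seed + 1L, {
    maps <- tidyr::expand_grid(
      patient_id = cohort$patient_id,
      map_index = seq_len(maps_per_patient)
    ) |>
      dplyr::mutate(
        map_id = paste0(.data$patient_id, "_M", .data$map_index),
        tissue_type = tissues[(.data$map_index - 1L) %% length(tissues) + 1L]
      ) |>
      dplyr::left_join(cohort, by = "patient_id")
    # patient x tissue random intercepts, shared across maps of one tissue
    pt_tissue <- maps |>
      dplyr::distinct(.data$patient_id, .data$tissue_type) |>
      dplyr::mutate(b_pt_tissue = rnorm(dplyr::n(), 0, effects$patient_tissue_sd))
    maps <- maps |>
      dplyr::left_join(pt_tissue, by = c("patient_id", "tissue_type")) |>
      dplyr::mutate(
        b_map = rnorm(dplyr::n(), 0, effects$map_sd),
        n_pts = if (identical(points_per_map, "study")) {
          pmin(pmax(round(rnorm(dplyr::n(), 56, 15)), 21), 93)
        } else {
          rep(as.integer(points_per_map), dplyr::n())
        }
      )
    maps$eta <- vapply(seq_len(nrow(maps)), function(i) {
      map_linear_predictor(effects, maps$tissue_type[i], maps[i, ])
    }, numeric(1)) + maps$b_pt_tissue + maps$b_map
    obs <- maps[rep(seq_len(nrow(maps)), maps$n_pts), ]
    obs$E_kPa <- rgamma(nrow(obs),
                        shape = effects$gamma_shape,
                        scale = exp(obs$eta) / effects$gamma_shape)
    out <- obs |>
      dplyr::select(-dplyr::any_of(c("b_patient", "b_pt_tissue", "b_map",
                                     "eta", "map_index", "n_pts"))) |>
      tibble::as_tibble()
    attr(out, "truth") <- list(effects = effects,
                               maps = tibble::as_tibble(maps))
    out
  })
}

#' Simulate the raw force curves of one force map
#'
#' Generates one indentation cycle per grid pixel for a map with the given
#' true stiffness field, optionally corrupting a subset of pixels with
#' acquisition artifacts, and returns both the long curve table and the map
#' manifest expected by [process_map()].
#'
#' @param field Matrix of true moduli in kPa (e.g.
#'   [simulate_stiffness_field()]), `grid_n` x `grid_n`.
#' @param config An [afm_config()].
#' @param artifact_kinds Character vector recycled over pixels (row-major)
#'   giving each curve's [artifact_spec()] kind; default all `"clean"`.
#' @param map_id,patient_id,slide_id,probe_id,tissue_type Manifest metadata.
#' @param noise_sd Force noise for clean curves, N.
#' @param seed Integer seed.
#' @return A list with `curves` (long tibble: `curve_id`, `z`, `force`,
#'   `segment`) and `manifest` (one row per curve with grid positions and
#'   the artifact kind injected, for bookkeeping).
#' @export
simulate_force_map <- function(field, config = afm_config(),
                               artifact_kinds = "clean",
                               map_id = "M1", patient_id = "P01",
                               slide_id = "S1", probe_id = "probe1",
                               tissue_type = "distal_normal",
                               noise_sd = 20e-12, seed = 1L) {
  stopifnot(is.matrix(field), nrow(field) == config$grid_n,
            ncol(field) == config$grid_n, all(field > 0))
  n <- config$grid_n
  grid <- tidyr::expand_grid(grid_row = 0:(n - 1), grid_col = 0:(n - 1))
  kinds <- rep_len(artifact_kinds, nrow(grid))
  curve_ids <- sprintf("%s_r%02d_c%02d", map_id, grid$grid_row, grid$grid_col)
  curves <- purrr::pmap(
    list(grid$grid_row, grid$grid_col, kinds, seq_along(curve_ids)),
    function(r, cc, kind, i) {
      fc <- simulate_force_curve(
        E_true = field[r + 1, cc + 1] * 1000,  # kPa -> Pa
        config = config, artifact = artifact_spec(kind),
        seed = (seed %% 20000L) * 100003L + i, noise_sd = noise_sd
      )
      fc$curve_id <- curve_ids[i]
      fc
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::select("curve_id", "z", "force", "segment")
  manifest <- dplyr::mutate(
    grid,
    curve_id = curve_ids, patient_id = patient_id, slide_id = slide_id,
    map_id = map_id, probe_id = probe_id, tissue_type = tissue_type,
    artifact = kinds,
    E_true_kPa = field[cbind(grid$grid_row + 1, grid$grid_col + 1)],
    .before = 1
  )
  list(curves = curves, manifest = manifest)
}
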