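#' Read force curves from the plain-text TSV dialect
#'
#' The on-disk interchange format for force curves is a UTF-8, tab-delimited
#' table with a mandatory header `curve_id  segment  z_nm  force_pN`, one
#' sample per row, human-scale units (nm, pN), `"."` decimal separator.
#' Values are converted to SI (m, N) on read. Rows that fail to parse
#' quarantine their whole curve, as do curves whose `z` is not monotone
#' within a segment; the remaining curves still load.
#'
#' @param path Path to a curve TSV file.
#' @return A long tibble (`curve_id`, `z`, `force`, `segment`) with a
#'   `quarantine` attribute listing dropped curves and reasons.
#' @export
read_force_curves <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  need <- c("curve_id", "segment", "z_nm", "force_pN")
  if (!all(need %in% header)) {
    stop("malformed curve file: header must contain ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  raw <- suppressWarnings(readr::read_tsv(
    path, col_types = readr::cols(
      curve_id = readr::col_character(),
      segment = readr::col_character(),
      z_nm = readr::col_double(),
      force_pN = readr::col_double()
    ),
    progress = FALSE
  ))
  bad_rows <- !stats::complete.cases(raw[, need]) |
    !raw$segment %in% c("approach", "retract")
  quarantine <- tibble::tibble(curve_id = character(0), reason = character(0))
  if (any(bad_rows)) {
    quarantine <- dplyr::bind_rows(
      quarantine,
      tibble::tibble(curve_id = unique(raw$curve_id[bad_rows]),
                     reason = "unparseable row(s)"))
  }
  ok <- dplyr::filter(raw, !.data$curve_id %in% quarantine$curve_id)
  mono_bad <- ok |>
    dplyr::group_by(.data$curve_id, .data$segment) |>
    dplyr::summarise(mono = all(diff(.data$z_nm) >= 0) ||
                       all(diff(.data$z_nm) <= 0), .groups = "drop") |>
    dplyr::filter(!.data$mono)
  if (nrow(mono_bad)) {
    quarantine <- dplyr::bind_rows(
      quarantine,
      tibble::tibble(curve_id = unique(mono_bad$curve_id),
                     reason = "non-monotone z within a segment"))
    ok <- dplyr::filter(ok, !.data$curve_id %in% mono_bad$curve_id)
  }
  out <- tibble::tibble(
    curve_id = ok$curve_id,
    z = ok$z_nm * 1e-9,
    force = ok$force_pN * 1e-12,
    segment = ok$segment
  )
  structure(out, quarantine = quarantine)
}

#' Write force curves in the TSV dialect
#'
#' @param curves Long curve tibble (`curve_id`, `z`, `force`, `segment`) in
#'   SI units.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curves <- function(curves, path) {
  stopifnot(all(c("curve_id", "z", "force", "segment") %in% names(curves)))
  readr::write_tsv(
    tibble::tibble(
      curve_id = curves$curve_id,
      segment = curves$segment,
      z_nm = curves$z * 1e9,
      force_pN = curves$force * 1e12
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' Write and read the acquisition configuration as YAML
#'
#' Persists an [afm_config()] (plus optional extra settings such as QC
#' constants or a seed) so a processing run can be reproduced from its
#' configuration file alone. The round trip is lossless.
#'
#' @param config An [afm_config()].
#' @param path Output path (YAML).
#' @param extra Optional named list of additional scalar settings stored
#'   alongside the acquisition fields.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path, extra = list()) {
  stopifnot(inherits(config, "afm_config"))
  payload <- list(acquisition = unclass(config), extra = extra)
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config()` returns a list with `config` (an
#'   `afm_config`) and `extra`.
#' @export
read_run_config <- function(path) {
  payload <- yaml::read_yaml(path)
  cfg <- payload$acquisition
  cfg$grid_n <- as.integer(cfg$grid_n)
  list(config = structure(cfg, class = "afm_config"),
       extra = payload$extra)
}

#' Write pipeline result tables and a run summary
#'
#' Writes every supplied table as a CSV with a deterministic file name, plus
#' a `run_summary.json` with the configuration hash, seed and processing
#' counts, so identical runs produce identical summaries.
#'
#' @param results Named list of tibbles (e.g. `maps`, `coverage`,
#'   `observations`, `descriptive`, `variability`, `contrasts`,
#'   `clinical`); `NULL` entries are skipped.
#' @param out_dir Output directory (created if absent).
#' @param config The [afm_config()] used (hashed into the summary).
#' @param seed The run seed.
#' @param counts Named integer vector of curves processed / excluded per
#'   criterion (e.g. the `exclusions` attribute of [process_map()]).
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, config = afm_config(),
                          seed = NA_integer_, counts = integer(0),
                          overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- results[!vapply(results, is.null, logical(1))]
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    if (file.exists(p) && !overwrite) {
      stop("refusing to overwrite ", p, " (set overwrite = TRUE)",
           call. = FALSE)
    }
    readr::write_csv(tibble::as_tibble(results[[nm]]), p, progress = FALSE)
    paths <- c(paths, p)
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  if (file.exists(summary_path) && !overwrite) {
    stop("refusing to overwrite ", summary_path, call. = FALSE)
  }
  summary <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = seed,
    counts = as.list(counts),
    tables = names(results)
  )
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, summary_path))
}
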