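#' Square-root display transform for stiffness values
#'
#' Per-pixel moduli follow a right-skewed gamma-like distribution with many
#' values near 0.1 kPa; a square-root transform spreads the low end into a
#' readable colour scale. Invalid pixels (`NA`) stay invalid.
#'
#' @param values Numeric vector or matrix of stiffness values, kPa (>= 0).
#' @return Element-wise square root, same shape as the input.
#' @export
sqrt_display <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("stiffness values must be non-negative", call. = FALSE)
  }
  sqrt(values)
}

# physical pixel-centre coordinates in um for 0-based grid indices
pixel_coords <- function(grid_row, grid_col, pitch_um) {
  cbind(x = (grid_col + 0.5) * pitch_um, y = (grid_row + 0.5) * pitch_um)
}

#' Nearest-neighbour coverage index of stiffness maps
#'
#' Quality filtering leaves holes in a force map; a map that kept too few,
#' too scattered pixels should not enter the statistics. For every valid
#' pixel the Euclidean distance to its nearest other valid pixel is computed
#' on physical pixel-centre coordinates; the coverage index of the map is the
#' mean of these minimal distances (µm). A fully covered regular grid scores
#' exactly the pixel pitch; higher values indicate poorer coverage. A map
#' with fewer than two valid pixels has an undefined index (`NA`) and is
#' never retained.
#'
#' @param maps A pixel-level tibble with columns `map_id`, `grid_row`,
#'   `grid_col` and either `valid` (logical) or `E_kPa` (`NA` = invalid),
#'   e.g. the output of [process_map()].
#' @param pitch_um Pixel pitch, µm (default 5 = 50 µm side / 10 pixels;
#'   endpoint-inclusive spacing 50/9 can be passed instead).
#' @param threshold_um Retention threshold on the index, µm.
#' @return A tibble with one row per map: `map_id`, `n_valid`, `index_um`,
#'   `retained` (index <= threshold), plus any map-level metadata columns
#'   (`patient_id`, `tissue_type`, ...) constant within a map.
#' @examples
#' px <- tidyr::expand_grid(grid_row = 0:9, grid_col = 0:9)
#' px$map_id <- "M1"; px$valid <- TRUE
#' coverage_index(px)  # full 10x10 grid at pitch 5 -> index 5
#' @export
coverage_index <- function(maps, pitch_um = 5, threshold_um = 8) {
  stopifnot(all(c("map_id", "grid_row", "grid_col") %in% names(maps)))
  if (!"valid" %in% names(maps)) {
    if (!"E_kPa" %in% names(maps)) {
      stop("need a `valid` or `E_kPa` column", call. = FALSE)
    }
    maps$valid <- !is.na(maps$E_kPa)
  }
  meta_cols <- intersect(c("patient_id", "slide_id", "probe_id", "tissue_type"),
                         names(maps))
  maps |>
    dplyr::group_by(.data$map_id) |>
    dplyr::group_modify(function(d, key) {
      v <- d[d$valid, , drop = FALSE]
      idx <- NA_real_
      if (nrow(v) >= 2) {
        dm <- as.matrix(dist(pixel_coords(v$grid_row, v$grid_col, pitch_um)))
        diag(dm) <- Inf
        idx <- mean(apply(dm, 1, min))
      }
      meta <- d[1, meta_cols, drop = FALSE]
      dplyr::bind_cols(
        tibble::tibble(n_valid = nrow(v), index_um = idx,
                       retained = !is.na(idx) & idx <= threshold_um),
        meta
      )
    }) |>
    dplyr::ungroup()
}

#' Filter stiffness maps by coverage
#'
#' Keeps only the maps whose nearest-neighbour coverage index does not exceed
#' the threshold (default 8 µm). Filtering is idempotent.
#'
#' @inheritParams coverage_index
#' @return The retained subset of `maps` (same pixel-level shape), with an
#'   attribute `coverage_report`: the full [coverage_index()] table, the
#'   removed maps carrying `retained = FALSE`.
#' @export
filter_maps <- function(maps, threshold_um = 8, pitch_um = 5) {
  if (nrow(maps) == 0) {
    return(structure(maps, coverage_report = coverage_index(maps, pitch_um,
                                                            threshold_um)))
  }
  cov <- coverage_index(maps, pitch_um = pitch_um, threshold_um = threshold_um)
  keep <- cov$map_id[cov$retained]
  structure(dplyr::filter(maps, .data$map_id %in% keep),
            coverage_report = cov, exclusions = attr(maps, "exclusions"))
}

#' Weighted ANOVA of map coverage across tissue types
#'
#' Tests whether map coverage differs between tissue types before pooling
#' maps: a one-way ANOVA of the coverage index on tissue type, weighting each
#' map by its number of valid pixels.
#'
#' @param coverage A [coverage_index()] table including a `tissue_type`
#'   column (maps with undefined index are dropped).
#' @return A one-row tibble: `F_value`, `p_value`, `df_between`, `df_within`.
#' @export
coverage_anova <- function(coverage) {
  stopifnot(all(c("index_um", "n_valid", "tissue_type") %in% names(coverage)))
  d <- coverage[!is.na(coverage$index_um), , drop = FALSE]
  if (length(unique(d$tissue_type)) < 2) {
    stop("coverage ANOVA needs at least two tissue types", call. = FALSE)
  }
  if (nrow(d) < 3) stop("too few maps for an ANOVA", call. = FALSE)
  fit <- lm(index_um ~ tissue_type, data = d, weights = d$n_valid)
  a <- suppressWarnings(anova(fit))
  Fv <- a$`F value`[1]
  pv <- a$`Pr(>F)`[1]
  scale_ss <- sum(d$n_valid * d$index_um^2)
  if (!is.finite(Fv) || a$`Sum Sq`[1] <= 1e-12 * scale_ss) {
    # no between-group variation at all (e.g. identical indices): F = 0
    Fv <- 0; pv <- 1
  }
  tibble::tibble(
    F_value = Fv, p_value = pv,
    df_between = a$Df[1], df_within = a$Df[2]
  )
}

#' Plot a stiffness map on the square-root colour scale
#'
#' @param map Pixel-level tibble (one map) with `grid_row`, `grid_col`,
#'   `E_kPa` and optionally `valid`.
#' @param pitch_um Pixel pitch, µm.
#' @return A ggplot object.
#' @export
plot_stiffness_map <- function(map, pitch_um = 5) {
  if (!"valid" %in% names(map)) map$valid <- !is.na(map$E_kPa)
  d <- dplyr::mutate(
    map,
    x = (.data$grid_col + 0.5) * pitch_um,
    y = (.data$grid_row + 0.5) * pitch_um,
    shown = ifelse(.data$valid, .data$E_kPa, NA_real_)
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$shown)) +
    ggplot2::geom_tile(width = pitch_um, height = pitch_um) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt", na.value = "grey85",
                                  name = "E (kPa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
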