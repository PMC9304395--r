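#' Acquisition configuration for AFM force-map experiments
#'
#' Bundles the instrument and acquisition-geometry settings shared by the
#' force-curve simulator and the curve-processing stage. Defaults mirror a
#' soft-tissue force-spectroscopy setup: a 10.2 µm colloidal silica bead glued
#' to a soft cantilever (spring constant 0.15–0.24 N/m), a 2 nN force trigger,
#' a 2 µm/s approach, indentation cycles of up to 50 µm of piezo travel, and a
#' 10 x 10 pixel grid covering a 50 x 50 µm region of a 20 µm thick section.
#'
#' All quantities are stored in SI units internally (m, N, N/m); the
#' constructor takes the human-scale units its arguments advertise.
#'
#' @param bead_diameter_um Diameter of the spherical probe, µm.
#' @param spring_constant Cantilever spring constant, N/m.
#' @param force_trigger_nN Maximum force threshold ending the approach, nN.
#' @param approach_speed_um_s Loading rate, µm/s (metadata only; the
#'   elastic model is rate-independent).
#' @param max_ramp_um Maximum piezo travel per indentation cycle, µm.
#' @param grid_n Pixels per side of the square force map.
#' @param map_side_um Side length of the mapped region, µm.
#' @param section_thickness_um Tissue section thickness, µm. The default fit
#'   window caps indentation at 10% of this thickness so the stiff substrate
#'   under the section does not contaminate the modulus.
#' @param poisson_ratio Poisson ratio of the sample; 0.5 treats soft hydrated
#'   tissue as incompressible.
#' @param sample_spacing_nm Piezo sampling step along z, nm per point.
#'
#' @return An object of class `afm_config` (a named list in SI units, with
#'   `pitch_um` derived as `map_side_um / grid_n`).
#' @examples
#' cfg <- afm_config()
#' cfg$force_trigger  # 2e-9 N
#' @export
afm_config <- function(bead_diameter_um = 10.2,
                       spring_constant = 0.2,
                       force_trigger_nN = 2,
                       approach_speed_um_s = 2,
                       max_ramp_um = 50,
                       grid_n = 10L,
                       map_side_um = 50,
                       section_thickness_um = 20,
                       poisson_ratio = 0.5,
                       sample_spacing_nm = 10) {
  stopifnot(
    bead_diameter_um > 0, spring_constant > 0, force_trigger_nN > 0,
    approach_speed_um_s > 0, max_ramp_um > 0, map_side_um > 0,
    section_thickness_um > 0, sample_spacing_nm > 0
  )
  if (grid_n < 2) stop("`grid_n` must be at least 2", call. = FALSE)
  if (poisson_ratio < 0 || poisson_ratio >= 0.5 + 1e-8) {
    stop("`poisson_ratio` must lie in [0, 0.5]", call. = FALSE)
  }
  if (!(spring_constant >= 0.05 && spring_constant <= 2)) {
    warning("spring constant ", spring_constant,
            " N/m is outside the usual soft-cantilever range")
  }
  structure(
    list(
      bead_radius    = bead_diameter_um * 1e-6 / 2,  # m
      spring_constant = spring_constant,             # N/m
      force_trigger  = force_trigger_nN * 1e-9,      # N
      approach_speed = approach_speed_um_s * 1e-6,   # m/s
      max_ramp       = max_ramp_um * 1e-6,           # m
      grid_n         = as.integer(grid_n),
      map_side       = map_side_um * 1e-6,           # m
      section_thickness = section_thickness_um * 1e-6,
      poisson_ratio  = poisson_ratio,
      sample_spacing = sample_spacing_nm * 1e-9,     # m
      pitch_um       = map_side_um / grid_n
    ),
    class = "afm_config"
  )
}

#' @export
print.afm_config <- function(x, ...) {
  cat("<afm_config>\n")
  cat(sprintf("  bead radius       %.2f um\n", x$bead_radius * 1e6))
  cat(sprintf("  spring constant   %.3f N/m\n", x$spring_constant))
  cat(sprintf("  force trigger     %.2f nN\n", x$force_trigger * 1e9))
  cat(sprintf("  max ramp          %.1f um @ %.1f um/s\n",
              x$max_ramp * 1e6, x$approach_speed * 1e6))
  cat(sprintf("  grid              %d x %d over %.0f x %.0f um (pitch %.2f um)\n",
              x$grid_n, x$grid_n, x$map_side * 1e6, x$map_side * 1e6,
              x$pitch_um))
  cat(sprintf("  section thickness %.0f um, Poisson ratio %.2f\n",
              x$section_thickness * 1e6, x$poisson_ratio))
  invisible(x)
}

#' Default indentation fit window
#'
#' Maximum indentation depth used in the Hertz fit: 10% of the section
#' thickness, so the rigid substrate under the section contributes negligibly
#' to the measured modulus.
#'
#' @param config An [afm_config()].
#' @return Depth in m.
#' @export
default_delta_max <- function(config) 0.1 * config$section_thickness
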