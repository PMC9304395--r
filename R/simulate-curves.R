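#' Specify an acquisition artifact for simulated curves
#'
#' Curves on real tissue fail quality control in stereotyped ways; the
#' simulator reproduces the three failure modes the processing stage must
#' reject, plus clean curves:
#' * `"clean"` — well-behaved Hertzian curve with a long flat baseline.
#' * `"permanent_contact"` — the tip never leaves the tissue, so the approach
#'   has no pre-contact baseline at all.
#' * `"short_baseline"` — contact occurs so early that less than 2 µm of flat
#'   baseline precedes it, leaving the contact point ill-defined.
#' * `"high_noise"` — force-channel noise comparable to the trigger force.
#'
#' @param kind One of `"clean"`, `"permanent_contact"`, `"short_baseline"`,
#'   `"high_noise"`.
#' @param magnitude Dimensionless scale of the artifact. For `"high_noise"`
#'   it is the noise standard deviation as a fraction of the trigger force
#'   (default 0.4); for `"short_baseline"` the baseline length in µm
#'   (default 1); ignored for the other kinds.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(kind = c("clean", "permanent_contact",
                                   "short_baseline", "high_noise"),
                          magnitude = NULL) {
  kind <- match.arg(kind)
  if (is.null(magnitude)) {
    magnitude <- switch(kind, high_noise = 0.4, short_baseline = 1, 1)
  }
  stopifnot(is.numeric(magnitude), magnitude > 0)
  structure(list(kind = kind, magnitude = magnitude), class = "artifact_spec")
}

#' Simulate one AFM indentation cycle
#'
#' Generates an approach/retract force-distance cycle for a sample of true
#' Young's modulus `E_true`. The approach is a flat zero-force baseline until
#' the contact point `z0`, then Hertzian loading with cantilever-deflection
#' coupling: at piezo position z past contact the depth delta solves
#' `z - z0 = delta + F(delta)/k`, with `F` the Hertz sphere force. The ramp
#' ends when the force reaches the trigger or the piezo range is exhausted
#' (then the curve carries `truncated = TRUE`). The retract mirrors the
#' approach with an optional adhesion well just past the contact point;
#' retraction is simulated only so downstream code has both segments to
#' handle — the modulus is always fitted on the approach.
#'
#' @param E_true True Young's modulus, Pa.
#' @param config An [afm_config()].
#' @param artifact An [artifact_spec()]; default clean.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param z0_um Contact-point position along the ramp, µm from the start of
#'   the approach (default 25, i.e. 25 µm of pre-contact baseline). Overridden
#'   by artifact kinds that manipulate the baseline.
#' @param noise_sd Additive Gaussian force noise, N (default 20 pN, a
#'   plausible force-channel noise floor for soft cantilevers in liquid).
#'   Set 0 for noiseless curves. Overridden by the `"high_noise"` artifact.
#' @param adhesion_nN Depth of the retract adhesion well, nN (default 0.1).
#'
#' @return A tibble with columns `z` (piezo position, m, increasing toward
#'   the sample on approach), `force` (N) and `segment`
#'   (`"approach"`/`"retract"`), with attributes `z0_true` (m), `E_true`,
#'   `truncated`, and `artifact`.
#' @examples
#' cfg <- afm_config()
#' fc <- simulate_force_curve(1000, cfg, seed = 1)
#' attr(fc, "z0_true") * 1e6
#' @export
simulate_force_curve <- function(E_true, config = afm_config(),
                                 artifact = artifact_spec("clean"),
                                 seed = NULL, z0_um = 25,
                                 noise_sd = 20e-12, adhesion_nN = 0.1) {
  if (!is.numeric(E_true) || length(E_true) != 1 || E_true <= 0) {
    stop("`E_true` must be a single positive modulus in Pa", call. = FALSE)
  }
  stopifnot(inherits(config, "afm_config"), inherits(artifact, "artifact_spec"))
  z0 <- z0_um * 1e-6
  if (artifact$kind == "permanent_contact") z0 <- -0.5e-6
  if (artifact$kind == "short_baseline") z0 <- artifact$magnitude * 1e-6
  if (artifact$kind == "high_noise") {
    noise_sd <- artifact$magnitude * config$force_trigger
  }

  build <- function() {
    ds <- config$sample_spacing
    z <- seq(0, config$max_ramp, by = ds)
    delta <- solve_indentation(z - z0, E_true, config$bead_radius,
                               config$poisson_ratio, config$spring_constant)
    f <- hertz_force(delta, E_true, config$bead_radius, config$poisson_ratio)
    hit <- which(f >= config$force_trigger)
    truncated <- length(hit) == 0
    keep <- if (truncated) seq_along(z) else seq_len(max(hit[1], 2L))
    z <- z[keep]; f <- f[keep]
    n <- length(z)

    # retract: elastic unloading mirrors the approach (no hysteresis in a
    # purely elastic model) plus a shallow adhesion well past pull-off
    fr <- rev(f)
    zr <- rev(z)
    if (adhesion_nN > 0) {
      w <- 0.5e-6
      fr <- fr - adhesion_nN * 1e-9 * exp(-((zr - z0) / w)^2) * (zr <= z0)
    }
    out <- tibble::tibble(
      z = c(z, zr),
      force = c(f, fr),
      segment = rep(c("approach", "retract"), c(n, n))
    )
    if (noise_sd > 0) out$force <- out$force + rnorm(nrow(out), 0, noise_sd)
    structure(out,
              z0_true = z0, E_true = E_true, truncated = truncated,
              artifact = artifact$kind, noise_sd = noise_sd)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
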