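#' @keywords internal
approach_segment <- function(curve) {
  dplyr::filter(curve, .data$segment == "approach")
}

# centered running mean (odd window) with edge padding
running_mean <- function(x, k) {
  k <- k - (1 - k %% 2)  # force odd
  if (k <= 1 || length(x) < k) return(x)
  sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  h <- (k - 1) %/% 2
  n <- length(x)
  sm[seq_len(h)] <- sm[h + 1]
  sm[(n - h + 1):n] <- sm[n - h]
  sm
}

#' Baseline-correct a force curve
#'
#' Identifies the pre-contact window of the approach segment, fits a straight
#' line to it, and subtracts that line from the whole curve so the
#' pre-contact force has zero mean. The rough contact location is found on a
#' noise-adaptively smoothed force trace, so heavy force-channel noise does
#' not masquerade as an early contact.
#'
#' If less than `min_precontact_um` of pre-contact travel exists (the tip was
#' already touching the tissue when the ramp started), no baseline can be
#' defined; the curve is returned unchanged and the `no_precontact` flag is
#' raised for the quality-control stage — this is a verdict, not an error.
#'
#' @param curve A force-curve tibble (`z`, `force`, `segment`).
#' @param min_precontact_um Minimum pre-contact travel (µm) for a usable
#'   baseline window; below this the curve counts as permanent contact.
#' @return The curve tibble with corrected `force` and a `baseline` attribute:
#'   a list with `slope` (N/m), `intercept` (N), `precontact_um`,
#'   `no_precontact`, `noise_sd` (estimated from the corrected window, N) and
#'   `rough_z0` (m).
#' @export
baseline_correct <- function(curve, min_precontact_um = 0.5) {
  app <- approach_segment(curve)
  if (nrow(app) < 2) stop("approach segment needs at least 2 samples", call. = FALSE)
  z <- app$z; f <- app$force
  # robust noise estimate from first differences (baseline-dominated)
  noise_raw <- mad(diff(f)) / sqrt(2)
  k <- min(51L, max(1L, nrow(app) %/% 4L))
  k <- k - (1L - k %% 2L)
  k <- max(1L, k)
  sm <- running_mean(f, k)
  level <- quantile(sm, 0.05, names = FALSE)
  amp <- max(sm) - level
  thr <- level + max(0.1 * amp, 3 * noise_raw / sqrt(k), 1e-13)
  below <- which(sm <= thr)
  rough_idx <- if (length(below) == 0) 0L else max(below)
  rough_z0 <- if (rough_idx == 0L) z[1] else z[rough_idx]
  precontact_um <- (rough_z0 - z[1]) * 1e6

  info <- list(slope = NA_real_, intercept = NA_real_,
               precontact_um = precontact_um,
               no_precontact = precontact_um < min_precontact_um,
               noise_sd = noise_raw, rough_z0 = rough_z0)
  if (info$no_precontact) {
    attr(curve, "baseline") <- info
    return(curve)
  }
  margin <- max(0.1e-6, 3 * (k * stats::median(diff(z))))
  win <- which(z <= rough_z0 - pmin(margin, 0.3 * (rough_z0 - z[1])))
  if (length(win) < 2) win <- seq_len(max(2L, rough_idx - 1L))
  fit <- lm(f[win] ~ z[win])
  cf <- coef(fit)
  corrected <- curve
  corrected$force <- curve$force - (cf[1] + cf[2] * curve$z)
  info$slope <- unname(cf[2]); info$intercept <- unname(cf[1])
  info$noise_sd <- sd(corrected$force[corrected$segment == "approach"][win])
  if (!is.finite(info$noise_sd)) info$noise_sd <- noise_raw
  attr(corrected, "baseline") <- info
  corrected
}

baseline_info <- function(curve) {
  info <- attr(curve, "baseline")
  if (is.null(info)) stop("curve has not been baseline-corrected", call. = FALSE)
  info
}

#' Detect the contact point of a baseline-corrected approach curve
#'
#' Scans the corrected approach force for the first persistent excursion
#' above a noise-scaled threshold; the contact point estimate is the last
#' sample before that excursion. If the threshold is never persistently
#' exceeded (as on very noisy curves) the smoothed rough contact location
#' from the baseline stage is used instead. The estimate is later refined
#' jointly with the modulus inside [fit_hertz_curve()].
#'
#' Also checks the flatness precondition for a well-defined contact point:
#' at least `flat_window_um` of contiguous baseline immediately before the
#' contact point, with absolute local slope below
#' `2 * noise_sd / 1 µm` on the corrected force.
#'
#' @param curve A baseline-corrected force curve (see [baseline_correct()]).
#' @param noise_sd Force-noise standard deviation (N); default taken from the
#'   baseline attribute.
#' @param flat_window_um Required flat pre-contact stretch, µm.
#' @param run_length Consecutive above-threshold samples that count as a
#'   persistent excursion.
#' @return A list: `z0` (m, `NA` if no contact point exists), `idx`,
#'   `flat_um` (flat stretch available before contact), `flat_ok`,
#'   `no_contact`.
#' @export
detect_contact_point <- function(curve, noise_sd = NULL, flat_window_um = 2,
                                 run_length = 5L) {
  info <- baseline_info(curve)
  if (info$no_precontact) {
    return(list(z0 = NA_real_, idx = NA_integer_, flat_um = 0,
                flat_ok = FALSE, no_contact = TRUE))
  }
  if (is.null(noise_sd)) noise_sd <- info$noise_sd
  app <- approach_segment(curve)
  z <- app$z; f <- app$force
  tau <- max(3 * noise_sd, 1e-13)
  exceed <- f > tau
  r <- rle(exceed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) > 0) {
    i <- starts[hit[1]]
    idx <- max(i - 1L, 1L)
  } else {
    idx <- which.min(abs(z - info$rough_z0))
  }
  z0 <- z[idx]
  flat_um <- (z0 - z[1]) * 1e6
  flat_ok <- FALSE
  if (flat_um >= flat_window_um) {
    win <- which(z >= z0 - flat_window_um * 1e-6 & z <= z0)
    slope <- unname(coef(lm(f[win] ~ z[win]))[2])
    slope_limit <- 2 * max(noise_sd, 1e-13) / 1e-6  # N per m of travel
    flat_ok <- abs(slope) < slope_limit
  }
  list(z0 = z0, idx = idx, flat_um = flat_um, flat_ok = flat_ok,
       no_contact = FALSE)
}

#' Convert piezo travel to indentation depth
#'
#' Past the contact point the piezo travel divides between cantilever
#' deflection and sample indentation: `delta = (z - z0) - F/k`. Returns the
#' post-contact (depth, force) pairs ordered by increasing depth, with depth
#' clipped at zero.
#'
#' @param curve A (baseline-corrected) force curve.
#' @param z0 Contact point, m.
#' @param k Cantilever spring constant, N/m.
#' @return A tibble with columns `delta` (m) and `force` (N).
#' @examples
#' # a single sample 1 um past contact at 0.1 nN with k = 0.2 N/m indents
#' # 1 um - 0.5 nm = 0.9995 um
#' @export
compute_indentation <- function(curve, z0, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) {
    stop("`k` must be a single positive spring constant in N/m", call. = FALSE)
  }
  app <- approach_segment(curve)
  if (z0 < min(app$z) - 1e-12 || z0 > max(app$z) + 1e-12) {
    stop("`z0` lies outside the approach z range", call. = FALSE)
  }
  post <- app[app$z > z0, , drop = FALSE]
  tibble::tibble(
    delta = pmax((post$z - z0) - post$force / k, 0),
    force = post$force
  ) |>
    dplyr::arrange(.data$delta)
}

#' Fit the Hertz sphere model to indentation data
#'
#' Least-squares estimate of the Young's modulus from (depth, force) pairs.
#' For fixed contact point the Hertz model is linear in the modulus:
#' `F = F0 + b * delta^(3/2)` with `b = (4/3) E sqrt(R) / (1 - nu^2)`, so the
#' fit reduces to ordinary least squares of force on `delta^(3/2)` with a free
#' force offset. Only pairs with `0 < delta <= delta_max` enter the fit;
#' `delta_max` defaults to 10% of a 20 µm section.
#'
#' @param data A tibble with columns `delta` (m) and `force` (N), e.g. from
#'   [compute_indentation()].
#' @param R Bead radius, m.
#' @param nu Poisson ratio.
#' @param delta_max Maximum indentation used in the fit, m.
#' @return A `hertz_fit` object: `E` (Pa), `F0` (N), `rss` (N^2), `n_fit`,
#'   `converged`, `reason`, and the geometry used. `z0` is `NA` here and
#'   filled in by [fit_hertz_curve()].
#' @export
fit_hertz <- function(data, R, nu = 0.5, delta_max = 2e-6) {
  stopifnot(all(c("delta", "force") %in% names(data)), R > 0, delta_max > 0)
  use <- data$delta > 0 & data$delta <= delta_max
  out <- list(E = NA_real_, z0 = NA_real_, F0 = NA_real_, rss = NA_real_,
              n_fit = sum(use), converged = FALSE, reason = NA_character_,
              R = R, nu = nu, delta_max = delta_max)
  if (sum(use) < 5) {
    out$reason <- "fewer than 5 usable (delta, force) pairs"
    return(structure(out, class = "hertz_fit"))
  }
  x <- data$delta[use]^1.5
  y <- data$force[use]
  X <- cbind(1, x)
  cf <- qr.coef(qr(X), y)
  res <- y - X %*% cf
  b <- cf[2]
  E <- b * 0.75 * (1 - nu^2) / sqrt(R)
  if (is.na(E)) {
    out$reason <- "degenerate design (constant depth)"
    return(structure(out, class = "hertz_fit"))
  }
  if (E < 0) {
    E <- 0
    out$reason <- "negative unconstrained modulus clipped to 0"
  }
  out$E <- unname(E)
  out$F0 <- unname(cf[1])
  out$rss <- sum(res^2)
  out$converged <- TRUE
  structure(out, class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("<hertz_fit>\n")
  if (x$converged) {
    cat(sprintf("  E = %.4g Pa (%.4g kPa), F0 = %.3g N\n", x$E, x$E / 1000, x$F0))
    if (!is.na(x$z0)) cat(sprintf("  contact point z0 = %.4f um\n", x$z0 * 1e6))
    cat(sprintf("  rss = %.3g N^2 on %d samples (delta <= %.2g um)\n",
                x$rss, x$n_fit, x$delta_max * 1e6))
  } else {
    cat("  not converged:", x$reason, "\n")
  }
  invisible(x)
}

#' @method tidy hertz_fit
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble::tibble(
    term = c("E_Pa", "z0_m", "F0_N"),
    estimate = c(x$E, x$z0, x$F0)
  )
}

#' @method glance hertz_fit
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble::tibble(E_kPa = x$E / 1000, z0_um = x$z0 * 1e6, rss = x$rss,
                 n_fit = x$n_fit, converged = x$converged)
}

#' Fit the Hertz model to a raw force curve with contact-point refinement
#'
#' End-to-end per-curve modulus extraction: baseline correction, threshold
#' contact-point detection, then joint refinement of the contact point by
#' minimizing the Hertz fit residual sum of squares over a window around the
#' detected contact point (the modulus and force offset are profiled out in
#' closed form at each candidate contact point).
#'
#' @param curve A force-curve tibble; corrected automatically if needed.
#' @param config An [afm_config()] supplying bead radius, spring constant and
#'   Poisson ratio.
#' @param delta_max Fit window, m; default [default_delta_max()] (10% of
#'   section thickness).
#' @param refine_window_um Half-width of the contact-point refinement
#'   interval, µm.
#' @return A `hertz_fit` with `z0` filled in, plus attributes `baseline` and
#'   `contact` carrying the intermediate diagnostics.
#' @export
fit_hertz_curve <- function(curve, config = afm_config(),
                            delta_max = default_delta_max(config),
                            refine_window_um = 1) {
  if (is.null(attr(curve, "baseline"))) curve <- baseline_correct(curve)
  info <- baseline_info(curve)
  cp <- detect_contact_point(curve)
  if (cp$no_contact) {
    out <- structure(
      list(E = NA_real_, z0 = NA_real_, F0 = NA_real_, rss = NA_real_,
           n_fit = 0L, converged = FALSE,
           reason = "no contact point (permanent contact)",
           R = config$bead_radius, nu = config$poisson_ratio,
           delta_max = delta_max),
      class = "hertz_fit")
    attr(out, "baseline") <- info; attr(out, "contact") <- cp
    return(out)
  }
  app <- approach_segment(curve)
  zmin <- min(app$z); zmax <- max(app$z)
  ds <- config$sample_spacing
  lo <- max(zmin, cp$z0 - refine_window_um * 1e-6)
  hi <- min(zmax - 5 * ds, cp$z0 + refine_window_um * 1e-6)
  # lean profile objective: for fixed z0, (E, F0) solve in closed form.
  # Candidate contact points change how many samples enter the fit, so raw
  # RSS is not comparable across them (a late z0 keeps 5 points and fits
  # their noise); the residual variance rss/(n - 2) is.
  appz <- app$z; appf <- app$force
  k <- config$spring_constant
  big <- .Machine$double.xmax / 2
  rss_at <- function(z0) {
    sel <- appz > z0
    if (sum(sel) < 5) return(big)
    delta <- (appz[sel] - z0) - appf[sel] / k
    keep <- delta > 0 & delta <= delta_max
    n <- sum(keep)
    if (n < 5) return(big)
    ft <- stats::.lm.fit(cbind(1, delta[keep]^1.5), appf[sel][keep])
    sum(ft$residuals^2) / (n - 2)
  }
  z0_best <- cp$z0
  if (hi > lo) {
    # the RSS landscape is jagged at the sample scale (the fit window gains
    # or loses samples as z0 crosses them), so golden-section search over the
    # whole window is unreliable: scan candidate contact points one sample
    # apart first, then refine continuously within the winning sample
    cand <- seq(lo, hi, by = ds)
    scan <- vapply(cand, rss_at, numeric(1))
    z0_scan <- cand[which.min(scan)]
    opt <- optimize(rss_at,
                    lower = max(lo, z0_scan - 1.5 * ds),
                    upper = min(hi, z0_scan + 1.5 * ds), tol = 1e-12)
    best_obj <- min(opt$objective, min(scan))
    z0_best <- if (opt$objective <= min(scan)) opt$minimum else z0_scan
    if (rss_at(cp$z0) < best_obj) z0_best <- cp$z0
  }
  fit <- fit_hertz(compute_indentation(curve, z0_best, config$spring_constant),
                   R = config$bead_radius, nu = config$poisson_ratio,
                   delta_max = delta_max)
  fit$z0 <- z0_best
  attr(fit, "baseline") <- info
  attr(fit, "contact") <- cp
  fit
}

#' Quality-control verdict for one force curve
#'
#' Applies the three exclusion rules used when filtering tissue force maps:
#' 1. *permanent contact* — the tip was in contact with the tissue for the
#'    whole indentation cycle, so no pre-contact baseline exists;
#' 2. *ill-defined contact point* — the curve is not flat over at least
#'    `flat_window_um` (default 2 µm) before the mechanical contact point;
#' 3. *too noisy* — force-channel noise comparable to the trigger force,
#'    operationalized as a pre-contact force standard deviation of at least
#'    `c_noise * trigger`.
#'
#' Rules 2 and 3 presuppose a pre-contact window, so a permanent-contact
#' curve trips rule 1 only. A verdict is always returned; QC never errors.
#'
#' @param curve A baseline-corrected force curve.
#' @param fit Optional `hertz_fit` for the curve (its stored contact
#'   diagnostics are reused when present).
#' @param noise_sd Pre-contact force standard deviation, N; default estimated
#'   from the baseline window.
#' @param trigger Force trigger, N.
#' @param c_noise Fraction of the trigger the baseline noise must reach to
#'   count as "comparable" (rule 3).
#' @param flat_window_um Flat-baseline requirement of rule 2, µm.
#' @return A one-row tibble: `permanent_contact`, `ill_defined_contact`,
#'   `too_noisy`, `pass`.
#' @export
qc_curve <- function(curve, fit = NULL, noise_sd = NULL, trigger = 2e-9,
                     c_noise = 0.25, flat_window_um = 2) {
  if (is.null(attr(curve, "baseline"))) curve <- baseline_correct(curve)
  info <- baseline_info(curve)
  cp <- if (!is.null(fit) && !is.null(attr(fit, "contact"))) {
    attr(fit, "contact")
  } else {
    detect_contact_point(curve, flat_window_um = flat_window_um)
  }
  if (is.null(noise_sd)) noise_sd <- info$noise_sd
  permanent <- isTRUE(cp$no_contact)
  ill_defined <- !permanent && !isTRUE(cp$flat_ok)
  noisy <- !permanent && is.finite(noise_sd) && noise_sd >= c_noise * trigger
  tibble::tibble(
    permanent_contact = permanent,
    ill_defined_contact = ill_defined,
    too_noisy = noisy,
    pass = !permanent && !ill_defined && !noisy
  )
}

#' Process one force curve end to end
#'
#' Baseline correction, contact detection, Hertz fit and QC verdict, reduced
#' to a one-row tibble suitable for binding across a whole force map.
#'
#' @inheritParams fit_hertz_curve
#' @inheritParams qc_curve
#' @return A one-row tibble: `E_kPa`, `z0_um`, `F0_N`, `rss`, `n_fit`,
#'   `converged`, `precontact_um`, `noise_sd_N`, the three QC flags and
#'   `pass` (QC pass *and* converged fit).
#' @export
process_curve <- function(curve, config = afm_config(),
                          delta_max = default_delta_max(config),
                          c_noise = 0.25, flat_window_um = 2) {
  curve <- baseline_correct(curve)
  info <- baseline_info(curve)
  fit <- fit_hertz_curve(curve, config, delta_max = delta_max)
  qc <- qc_curve(curve, fit, trigger = config$force_trigger,
                 c_noise = c_noise, flat_window_um = flat_window_um)
  dplyr::bind_cols(
    tibble::tibble(
      E_kPa = fit$E / 1000, z0_um = fit$z0 * 1e6, F0_N = fit$F0,
      rss = fit$rss, n_fit = fit$n_fit, converged = fit$converged,
      precontact_um = info$precontact_um, noise_sd_N = info$noise_sd
    ),
    qc
  ) |>
    dplyr::mutate(pass = .data$pass & .data$converged)
}

#' Process all curves of a force map into a stiffness map
#'
#' Runs the full per-curve pipeline over every curve of a map and assembles
#' the gridded stiffness map: each pixel holds the fitted Young's modulus in
#' kPa where the curve passed QC and converged, and is invalid otherwise.
#' When two curves claim the same grid pixel the one appearing last in the
#' manifest wins, with a warning.
#'
#' @param curves A long tibble of force-curve samples with columns
#'   `curve_id`, `z`, `force`, `segment` (e.g. from [read_force_curves()] or
#'   [simulate_force_map()]).
#' @param manifest A tibble linking `curve_id` to `patient_id`, `slide_id`,
#'   `map_id`, `probe_id`, `tissue_type`, `grid_row`, `grid_col`.
#' @param config An [afm_config()].
#' @param ... Passed on to [process_curve()].
#' @return A tibble of class `stiffness_map`: one row per curve with manifest
#'   metadata, fit results, QC flags, `valid` (= `pass`), plus an
#'   `exclusions` attribute tallying curves lost per criterion.
#' @export
process_map <- function(curves, manifest, config = afm_config(), ...) {
  stopifnot(all(c("curve_id", "z", "force", "segment") %in% names(curves)))
  need <- c("curve_id", "map_id", "grid_row", "grid_col")
  if (!all(need %in% names(manifest))) {
    stop("manifest lacks columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "), call. = FALSE)
  }
  if (any(manifest$grid_row < 0 | manifest$grid_row >= config$grid_n |
            manifest$grid_col < 0 | manifest$grid_col >= config$grid_n)) {
    stop("grid indices outside the configured grid", call. = FALSE)
  }
  dup <- duplicated(manifest[, c("map_id", "grid_row", "grid_col")])
  if (any(dup)) {
    warning(sum(dup), " duplicate grid position(s); keeping the last curve")
    manifest <- manifest[!duplicated(manifest[, c("map_id", "grid_row", "grid_col")],
                                     fromLast = TRUE), , drop = FALSE]
  }
  results <- curves |>
    dplyr::filter(.data$curve_id %in% manifest$curve_id) |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(d, key) {
      process_curve(tibble::as_tibble(d), config, ...)
    }) |>
    dplyr::ungroup()
  out <- dplyr::inner_join(manifest, results, by = "curve_id") |>
    dplyr::mutate(valid = .data$pass)
  excl <- c(
    permanent_contact = sum(out$permanent_contact),
    ill_defined_contact = sum(out$ill_defined_contact),
    too_noisy = sum(out$too_noisy),
    non_converged = sum(!out$converged & !out$permanent_contact),
    passed = sum(out$valid)
  )
  structure(tibble::as_tibble(out), exclusions = excl,
            class = c("stiffness_map", class(tibble::tibble())))
}
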