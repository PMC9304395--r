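# Independent oracles used across tests. These deliberately re-derive
# quantities by brute force / closed form, not through the package's own
# computational path.

# brute-force nearest-neighbour coverage index over all pixel pairs
brute_coverage_index <- function(grid_row, grid_col, pitch_um) {
  n <- length(grid_row)
  if (n < 2) return(NA_real_)
  x <- (grid_col + 0.5) * pitch_um
  y <- (grid_row + 0.5) * pitch_um
  mins <- vapply(seq_len(n), function(i) {
    d <- sqrt((x[i] - x[-i])^2 + (y[i] - y[-i])^2)
    min(d)
  }, numeric(1))
  mean(mins)
}

# closed-form Hertz force, written out independently of hertz_force()
hertz_oracle <- function(delta, E, R, nu = 0.5) {
  4 / 3 * E / (1 - nu^2) * R^0.5 * delta^1.5
}

# brute-force (E, z0) grid search minimizing squared force residuals with a
# free force offset, on the same (z, F) data the fitter sees. The z0 grid is
# finer than the piezo sampling so its resolution, not sample quantization,
# bounds the agreement with the continuous fit.
brute_hertz_grid <- function(curve, config, delta_max, z0_center,
                             z0_window_nm = 10, z0_step_nm = 0.1,
                             E_grid = exp(seq(log(20), log(2e5), by = 0.002))) {
  app <- curve[curve$segment == "approach", ]
  z0_grid <- z0_center + seq(-z0_window_nm, z0_window_nm,
                             by = z0_step_nm) * 1e-9
  best <- list(rss = Inf, E = NA, z0 = NA)
  for (z0 in z0_grid) {
    post <- app[app$z > z0, ]
    delta <- pmax((post$z - z0) - post$force / config$spring_constant, 0)
    keep <- delta > 0 & delta <= delta_max
    if (sum(keep) < 5) next
    b <- 4 / 3 * sqrt(config$bead_radius) / (1 - config$poisson_ratio^2) *
      delta[keep]^1.5
    f <- post$force[keep]
    bc <- b - mean(b); fc <- f - mean(f)
    Sbb <- sum(bc^2); Sfb <- sum(fc * bc); Sff <- sum(fc^2)
    rss <- Sff - 2 * E_grid * Sfb + E_grid^2 * Sbb
    i <- which.min(rss)
    if (rss[i] < best$rss) best <- list(rss = rss[i], E = E_grid[i], z0 = z0)
  }
  best
}

# a small clean noiseless test curve, shared by several files
make_clean_curve <- function(E = 1000, config = afm_config(), z0_um = 25) {
  simulate_force_curve(E, config, artifact_spec("clean"), seed = 1,
                       z0_um = z0_um, noise_sd = 0, adhesion_nN = 0)
}

# coarser piezo sampling to keep Monte-Carlo loops quick
fast_config <- function(...) afm_config(sample_spacing_nm = 25, ...)
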