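test_that("baseline correction removes offsets and linear drift", {
  fc <- make_clean_curve()
  # constant +50 pN offset
  off <- fc; off$force <- off$force + 50e-12
  corr <- baseline_correct(off)
  info <- attr(corr, "baseline")
  app <- corr[corr$segment == "approach", ]
  pre <- app$force[app$z < info$rough_z0 - 0.5e-6]
  expect_lt(abs(mean(pre)), 1e-15)
  # linear drift of 1 pN/um
  dr <- fc; dr$force <- dr$force + 1e-6 * dr$z
  corr2 <- baseline_correct(dr)
  app2 <- corr2[corr2$segment == "approach", ]
  pre2 <- app2$force[app2$z < attr(corr2, "baseline")$rough_z0 - 0.5e-6]
  expect_lt(max(abs(pre2)), 1e-15)
})

test_that("baseline correction centres noisy drifting baselines", {
  cfg <- fast_config()
  sigma <- 20e-12
  fc <- simulate_force_curve(1000, cfg, seed = 21, noise_sd = sigma)
  fc$force <- fc$force + 2e-6 * fc$z  # 2 pN/um drift
  corr <- baseline_correct(fc)
  info <- attr(corr, "baseline")
  app <- corr[corr$segment == "approach", ]
  pre <- app$force[app$z < info$rough_z0 - 0.5e-6]
  expect_lt(abs(mean(pre)), 3 * sigma / sqrt(length(pre)))
  expect_false(info$no_precontact)
})

test_that("contact detection recovers a noiseless contact point exactly", {
  cfg <- afm_config()
  fc <- baseline_correct(make_clean_curve(config = cfg))
  cp <- detect_contact_point(fc)
  expect_false(cp$no_contact)
  expect_lt(abs(cp$z0 - 25e-6), cfg$sample_spacing + 1e-12)
  expect_true(cp$flat_ok)
})

test_that("permanent contact yields the no-contact sentinel", {
  fc <- simulate_force_curve(1000, afm_config(),
                             artifact_spec("permanent_contact"),
                             seed = 2, noise_sd = 0)
  cp <- detect_contact_point(baseline_correct(fc))
  expect_true(cp$no_contact)
  expect_true(is.na(cp$z0))
})

test_that("contact detection stays within a few samples under noise", {
  cfg <- fast_config()
  errs <- vapply(1:100, function(i) {
    fc <- simulate_force_curve(1000, cfg, seed = 1000 + i, noise_sd = 20e-12)
    cp <- detect_contact_point(baseline_correct(fc))
    abs(cp$z0 - attr(fc, "z0_true"))
  }, numeric(1))
  expect_lt(median(errs), 5 * cfg$sample_spacing)
})

test_that("indentation kinematics convert travel to depth", {
  curve <- tibble::tibble(
    z = c(0, 0.5e-6, 1.0e-6),
    force = c(0, 0, 0.1e-9),
    segment = "approach"
  )
  di <- compute_indentation(curve, z0 = 0, k = 0.2)
  # 1 um of travel at 0.1 nN with k = 0.2 N/m: delta = 1 um - 0.5 nm
  expect_equal(di$delta[2], 0.9995e-6, tolerance = 1e-12)
  # zero deflection: depth equals travel
  expect_equal(di$delta[1], 0.5e-6)
  # stiff-cantilever limit
  di_stiff <- compute_indentation(curve, z0 = 0, k = 1e9)
  expect_equal(di_stiff$delta, c(0.5e-6, 1.0e-6), tolerance = 1e-12)
  expect_error(compute_indentation(curve, 0, k = -1), "positive")
  expect_error(compute_indentation(curve, z0 = 5e-6, k = 0.2), "range")
})

test_that("fit_hertz recovers exact Hertz data and scales linearly", {
  cfg <- afm_config()
  delta <- seq(1e-8, 2e-6, length.out = 60)
  dat <- tibble::tibble(delta = delta,
                        force = hertz_oracle(delta, 1000, cfg$bead_radius))
  ft <- fit_hertz(dat, R = cfg$bead_radius)
  expect_true(ft$converged)
  expect_equal(ft$E, 1000, tolerance = 1e-10)
  expect_lt(ft$rss, 1e-30)
  # doubling the forces doubles the modulus
  dat2 <- dat; dat2$force <- 2 * dat2$force
  expect_equal(fit_hertz(dat2, R = cfg$bead_radius)$E, 2000,
               tolerance = 1e-10)
})

test_that("fit window delta_max is respected and small-n fits fail softly", {
  cfg <- afm_config()
  delta <- seq(1e-8, 2e-6, length.out = 60)
  dat <- tibble::tibble(delta = delta,
                        force = hertz_oracle(delta, 1000, cfg$bead_radius))
  # samples beyond delta_max carry garbage and must not matter
  beyond <- tibble::tibble(delta = seq(2.1e-6, 4e-6, length.out = 20),
                           force = 1e-7)
  ft <- fit_hertz(dplyr::bind_rows(dat, beyond), R = cfg$bead_radius,
                  delta_max = 2e-6)
  expect_equal(ft$E, 1000, tolerance = 1e-10)

  few <- dat[1:4, ]
  ft2 <- fit_hertz(few, R = cfg$bead_radius)
  expect_false(ft2$converged)
  expect_match(ft2$reason, "fewer than 5")

  # decreasing force vs depth: unconstrained slope negative, clipped to zero
  neg <- tibble::tibble(delta = delta, force = rev(seq_len(60)) * 1e-11)
  ft3 <- fit_hertz(neg, R = cfg$bead_radius)
  expect_equal(ft3$E, 0)
  expect_match(ft3$reason, "clipped")
})

test_that("full-curve fits recover the modulus under realistic noise", {
  cfg <- fast_config()
  errs <- vapply(1:100, function(i) {
    fc <- simulate_force_curve(1000, cfg, seed = 3000 + i, noise_sd = 20e-12)
    ft <- fit_hertz_curve(fc, cfg)
    abs(ft$E - 1000) / 1000
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("results are unit-safe across the nm/pN file boundary", {
  cfg <- afm_config()
  fc <- simulate_force_curve(1200, cfg, seed = 5, noise_sd = 10e-12)
  fc$curve_id <- "c1"
  direct <- fit_hertz_curve(fc, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curves(fc, path)
  back <- read_force_curves(path)
  roundtrip <- fit_hertz_curve(back[back$curve_id == "c1", ], cfg)
  expect_equal(roundtrip$E, direct$E, tolerance = 1e-6)
})

test_that("QC criteria flag exactly their targeted failure modes", {
  cfg <- afm_config()
  clean <- process_curve(simulate_force_curve(1000, cfg, seed = 4,
                                              noise_sd = 0), cfg)
  expect_true(clean$pass)
  expect_false(any(clean$permanent_contact, clean$ill_defined_contact,
                   clean$too_noisy))

  for (kind in c("permanent_contact", "short_baseline", "high_noise")) {
    r <- process_curve(
      simulate_force_curve(1000, cfg, artifact_spec(kind), seed = 4), cfg)
    flags <- c(permanent_contact = r$permanent_contact,
               ill_defined_contact = r$ill_defined_contact,
               too_noisy = r$too_noisy)
    intended <- switch(kind, permanent_contact = "permanent_contact",
                       short_baseline = "ill_defined_contact",
                       high_noise = "too_noisy")
    expect_true(unname(flags[intended]), label = paste(kind, "flagged"))
    expect_false(any(flags[setdiff(names(flags), intended)]),
                 label = paste(kind, "flags only its criterion"))
    expect_false(r$pass)
  }
})

test_that("the noise criterion is a threshold on baseline sd vs trigger", {
  cfg <- afm_config()
  # sd 0.6 nN >= 0.25 * 2 nN: too noisy; sd 0.3 nN: acceptable
  noisy <- simulate_force_curve(1000, cfg, seed = 6, noise_sd = 0.6e-9)
  quiet <- simulate_force_curve(1000, cfg, seed = 6, noise_sd = 0.3e-9)
  expect_true(qc_curve(baseline_correct(noisy),
                       trigger = cfg$force_trigger)$too_noisy)
  expect_false(qc_curve(baseline_correct(quiet),
                        trigger = cfg$force_trigger)$too_noisy)
})

test_that("map processing tallies exclusions and keeps the survivors", {
  cfg <- fast_config()
  field <- simulate_stiffness_field(log(1), gamma_shape = 8, seed = 31)
  kinds <- rep("clean", 100)
  kinds[1:10] <- "permanent_contact"
  kinds[11:16] <- "short_baseline"
  kinds[17:20] <- "high_noise"
  fm <- simulate_force_map(field, cfg, artifact_kinds = kinds, seed = 31)
  px <- process_map(fm$curves, fm$manifest, cfg)
  expect_s3_class(px, "stiffness_map")
  expect_equal(nrow(px), 100)
  expect_equal(sum(px$valid), 80)
  excl <- attr(px, "exclusions")
  expect_equal(unname(excl["permanent_contact"]), 10)
  expect_equal(unname(excl["ill_defined_contact"]), 6)
  expect_equal(unname(excl["too_noisy"]), 4)
})

test_that("all-artifact maps retain no pixels", {
  cfg <- fast_config()
  field <- simulate_stiffness_field(log(1), gamma_shape = 8, seed = 32)
  fm <- simulate_force_map(field, cfg, artifact_kinds = "permanent_contact",
                           seed = 32)
  px <- process_map(fm$curves, fm$manifest, cfg)
  expect_equal(sum(px$valid), 0)
})

test_that("duplicate grid positions keep the last curve with a warning", {
  cfg <- fast_config()
  fc1 <- simulate_force_curve(500, cfg, seed = 1, noise_sd = 0)
  fc2 <- simulate_force_curve(5000, cfg, seed = 2, noise_sd = 0)
  fc1$curve_id <- "a"; fc2$curve_id <- "b"
  curves <- dplyr::bind_rows(fc1, fc2)[, c("curve_id", "z", "force", "segment")]
  manifest <- tibble::tibble(
    curve_id = c("a", "b"), patient_id = "P01", slide_id = "S1",
    map_id = "M1", probe_id = "pr1", tissue_type = "stroma",
    grid_row = 0L, grid_col = 0L
  )
  expect_warning(px <- process_map(curves, manifest, cfg), "duplicate")
  expect_equal(nrow(px), 1)
  expect_equal(px$curve_id, "b")
  expect_equal(px$E_kPa, 5, tolerance = 1e-3)
})
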