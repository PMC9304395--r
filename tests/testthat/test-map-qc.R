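make_pixels <- function(mask, map_id = "M1", tissue = "stroma") {
  # mask: 10x10 logical matrix of valid pixels
  g <- tidyr::expand_grid(grid_row = 0:9, grid_col = 0:9)
  g$map_id <- map_id
  g$tissue_type <- tissue
  g$valid <- mask[cbind(g$grid_row + 1, g$grid_col + 1)]
  g
}

test_that("square-root display transform is element-wise and mask-preserving", {
  expect_equal(sqrt_display(0.04), 0.2)
  expect_equal(sqrt_display(1), 1)
  m <- matrix(c(4, NA, 0.25, 1), 2)
  expect_equal(sqrt_display(m), matrix(c(2, NA, 0.5, 1), 2))
  expect_error(sqrt_display(-1), "non-negative")
})

test_that("coverage index matches closed forms on canonical layouts", {
  full <- make_pixels(matrix(TRUE, 10, 10))
  cov_full <- coverage_index(full, pitch_um = 5)
  expect_equal(cov_full$index_um, 5)
  expect_true(cov_full$retained)

  corners <- matrix(FALSE, 10, 10); corners[1, 1] <- corners[10, 10] <- TRUE
  cov_c <- coverage_index(make_pixels(corners), pitch_um = 5)
  expect_equal(cov_c$index_um, 45 * sqrt(2), tolerance = 1e-12)
  expect_false(cov_c$retained)

  checker <- outer(1:10, 1:10, function(i, j) (i + j) %% 2 == 0)
  cov_ch <- coverage_index(make_pixels(checker), pitch_um = 5)
  expect_equal(cov_ch$index_um, 5 * sqrt(2), tolerance = 1e-12)
  expect_true(cov_ch$retained)  # 7.07 < 8
})

test_that("coverage index equals the brute-force all-pairs oracle", {
  set.seed(99)
  for (i in 1:20) {
    mask <- matrix(runif(100) < runif(1, 0.1, 0.9), 10, 10)
    if (sum(mask) < 2) next
    px <- make_pixels(mask)
    got <- coverage_index(px, pitch_um = 5)$index_um
    want <- brute_coverage_index(px$grid_row[px$valid], px$grid_col[px$valid], 5)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("degenerate maps get an undefined index and are not retained", {
  one <- matrix(FALSE, 10, 10); one[3, 4] <- TRUE
  cov1 <- coverage_index(make_pixels(one))
  expect_true(is.na(cov1$index_um))
  expect_false(cov1$retained)
  none <- coverage_index(make_pixels(matrix(FALSE, 10, 10)))
  expect_equal(none$n_valid, 0)
  expect_false(none$retained)
})

test_that("removing pixels never improves coverage on regular fixtures", {
  set.seed(7)
  mask <- matrix(TRUE, 10, 10)
  px <- make_pixels(mask)
  idx_prev <- coverage_index(px)$index_um
  for (drop in 1:20) {
    valid_ix <- which(px$valid)
    px$valid[sample(valid_ix, 1)] <- FALSE
    idx_now <- coverage_index(px)$index_um
    expect_gte(idx_now + 1e-12, idx_prev)
    idx_prev <- idx_now
  }
})

test_that("map filtering retains by threshold and is idempotent", {
  full <- make_pixels(matrix(TRUE, 10, 10), "Mfull")
  checker <- make_pixels(outer(1:10, 1:10,
                               function(i, j) (i + j) %% 2 == 0), "Mcheck")
  corners_m <- matrix(FALSE, 10, 10); corners_m[1, 1] <- corners_m[10, 10] <- TRUE
  corners <- make_pixels(corners_m, "Mcorner")
  maps <- dplyr::bind_rows(full, checker, corners)

  kept <- filter_maps(maps, threshold_um = 8)
  expect_setequal(unique(kept$map_id), c("Mfull", "Mcheck"))
  report <- attr(kept, "coverage_report")
  expect_equal(nrow(report), 3)
  expect_false(report$retained[report$map_id == "Mcorner"])

  twice <- filter_maps(kept, threshold_um = 8)
  strip <- function(x) {
    x <- tibble::as_tibble(x)
    attr(x, "coverage_report") <- NULL
    attr(x, "exclusions") <- NULL
    x
  }
  expect_equal(strip(twice), strip(kept))

  expect_equal(nrow(filter_maps(maps[0, ], threshold_um = 8)), 0)
  all_kept <- filter_maps(maps, threshold_um = Inf)
  expect_setequal(unique(all_kept$map_id), c("Mfull", "Mcheck", "Mcorner"))
})

test_that("coverage ANOVA reduces to the squared t test for two groups", {
  set.seed(3)
  cov <- tibble::tibble(
    map_id = paste0("M", 1:12),
    index_um = c(rnorm(6, 5, 0.5), rnorm(6, 6, 0.5)),
    n_valid = 80,
    tissue_type = rep(c("stroma", "tumor_epithelium"), each = 6)
  )
  res <- coverage_anova(cov)
  tt <- t.test(index_um ~ tissue_type, data = cov, var.equal = TRUE)
  expect_equal(res$F_value, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("identical coverage in all groups gives F = 0, p = 1", {
  cov <- tibble::tibble(
    map_id = paste0("M", 1:8), index_um = 5, n_valid = 50,
    tissue_type = rep(c("a", "b"), each = 4)
  )
  res <- coverage_anova(cov)
  expect_equal(res$F_value, 0)
  expect_equal(res$p_value, 1)
  expect_error(coverage_anova(cov[cov$tissue_type == "a", ]), "two tissue")
})

test_that("weighted coverage ANOVA holds its nominal size under the null", {
  set.seed(11)
  reps <- 2000
  rej <- vapply(seq_len(reps), function(i) {
    n_valid <- sample(30:95, 15, replace = TRUE)
    cov <- tibble::tibble(
      map_id = paste0("M", 1:15),
      # null: no tissue effect; index precision grows with valid points,
      # which is exactly what the n_valid weighting assumes
      index_um = 5 + rnorm(15, 0, 10 / sqrt(n_valid)),
      n_valid = n_valid,
      tissue_type = rep(c("a", "b", "c"), each = 5)
    )
    coverage_anova(cov)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.011)
})
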