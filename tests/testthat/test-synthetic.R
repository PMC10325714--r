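test_that("straight uniform gland has trivial ground-truth geometry", {
  p <- gland_shape_params(100, 10, axis_col = 20)
  g <- generate_gland_mask(p, 140, 40)
  geo <- g$geometry
  expect_equal(geo$pa, 99)
  expect_equal(geo$pb, 99)
  expect_equal(geo$L_central, 99)
  expect_equal(geo$sigma_w, 0)
  expect_equal(deformation_coefficient(geo), 1.0)
})

test_that("sinusoidal ground-truth boundary lengths match the integration oracle", {
  p <- gland_shape_params(100, 10, amplitude_px = 10, wavelength_px = 100,
                          axis_col = 30)
  geo <- gland_truth_geometry(p)
  arc <- oracle_sine_arc_length(10, 100, 99)
  chord <- oracle_sine_chord(10, 100, 99)
  expect_equal(geo$pa, arc, tolerance = 1e-5)
  expect_equal(geo$pb, arc, tolerance = 1e-5)
  expect_equal(geo$L_central, chord, tolerance = 1e-9)
  expect_equal(geo$pa / geo$L_central, arc / chord, tolerance = 1e-5)
})

test_that("linear width taper yields the direct-summation moments", {
  # width 10 -> 20 over 101 rows
  p <- gland_shape_params(101, 10, width_slope = 0.1, axis_col = 30)
  geo <- gland_truth_geometry(p)
  widths <- 10 + 0.1 * (0:100)
  expect_equal(geo$n, 101)
  expect_equal(geo$w_avg, 15)
  expect_equal(geo$sigma_w, oracle_sigma_w(widths))
})

test_that("gland rasterization rejects degenerate inputs", {
  expect_error(gland_shape_params(100, 5, width_slope = -0.1),
               "degenerate width")
  p <- gland_shape_params(100, 10, axis_col = 3)
  expect_error(generate_gland_mask(p, 140, 40), "out of canvas")
  expect_error(generate_gland_mask(gland_shape_params(100, 10, axis_col = 20),
                                   50, 40), "out of canvas")
})

test_that("scene generation is pure given the seed", {
  s1 <- generate_eyelid_scene(12, seed = 7)
  s2 <- generate_eyelid_scene(12, seed = 7)
  expect_identical(s1, s2)
  s3 <- generate_eyelid_scene(12, seed = 8)
  expect_false(identical(s1$image, s3$image))
})

test_that("noise-free scene image is a deterministic function of the mask", {
  s <- generate_eyelid_scene(6, noise_sd = 0, seed = 1)
  sm <- EBImage::imageData(EBImage::gblur(s$mask * 1.0, sigma = 1.5))
  expect_equal(s$image, matrix(pmin(pmax(0.1 + 0.7 * sm, 0), 1),
                               nrow(s$mask), ncol(s$mask)))
})

test_that("scene mask has exactly n_glands components", {
  s <- generate_eyelid_scene(12, seed = 21)
  expect_length(label_glands(s$mask), 12)
})

test_that("infeasible packing is rejected", {
  expect_error(
    generate_eyelid_scene(4, spacing_px = 20,
                          shape_ranges = list(amplitude_px = c(20, 20)),
                          seed = 1),
    "infeasible packing")
})

test_that("amplitude solving inverts the deformation formula", {
  base <- gland_shape_params(140, 11, wavelength_px = 100)
  for (target in c(1.2, 1.8, 2.5)) {
    a <- solve_gland_amplitude(target, base, amp_max = 35)
    p <- base; p$amplitude_px <- a
    expect_equal(deformation_coefficient(gland_truth_geometry(p)), target,
                 tolerance = 1e-3)
  }
  expect_equal(solve_gland_amplitude(1.0, base, amp_max = 35), 0)
  expect_error(solve_gland_amplitude(0.8, base, amp_max = 35),
               "unreachable target")
  expect_error(solve_gland_amplitude(50, base, amp_max = 35),
               "unreachable target")
})

test_that("cohort generation is deterministic and matches its design", {
  spec <- cohort_spec(n_subjects = 12, seed = 5)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$values, c2$values)
  v <- c1$values
  expect_equal(nrow(v), 12 * 2 * 10)
  # each subject has one treatment and one control eye with opposite laterality
  by_subj <- split(v, v$subject_id)
  for (d in by_subj) {
    expect_setequal(unique(d$group), c("treatment", "control"))
    expect_setequal(unique(d$laterality), c("OD", "OS"))
    expect_length(unique(d$laterality[d$group == "treatment"]), 1)
  }
})

test_that("generated cohorts recover the requested per-gland effects", {
  spec <- cohort_spec(n_subjects = 250, seed = 3)
  dm <- paired_diff_matrix(generate_cohort(spec)$values)
  eff <- spec$per_gland_effect
  se <- apply(dm, 2, sd) / sqrt(nrow(dm))
  expect_true(all(abs(colMeans(dm) - eff) <= 2 * se))
  # the paired-difference SD is sqrt(2) * noise_sd by construction
  expect_equal(mean(apply(dm, 2, sd)), sqrt(2) * spec$noise_sd,
               tolerance = 0.05)
})

test_that("between-eye correlation is induced by the shared subject term", {
  spec <- cohort_spec(n_subjects = 400, per_gland_effect = rep(0, 10),
                      between_eye_corr = 0.6, seed = 11)
  v <- generate_cohort(spec)$values
  tv <- v[v$group == "treatment", ]; cv <- v[v$group == "control", ]
  tv <- tv[order(tv$subject_id, tv$gland_index), ]
  cv <- cv[order(cv$subject_id, cv$gland_index), ]
  r <- cor(tv$D, cv$D)
  expect_gt(r, 0.5)
  expect_lt(r, 0.7)
})

test_that("rendered scenes realize the deformation targets", {
  spec <- cohort_spec(n_subjects = 2, per_gland_effect = rep(0.5, 10),
                      baseline = rep(1.8, 10), noise_sd = 0.08, seed = 5)
  cr <- generate_cohort(spec, render = TRUE)
  expect_length(cr$scenes, 4)
  pg <- analyze_cohort(cr)
  mg <- merge(pg, cr$values, by = c("subject_id", "laterality", "gland_index"))
  expect_lt(max(abs(mg$D.x - mg$D.y)), 0.05)
})

test_that("unreachable rendering targets raise an error", {
  spec <- cohort_spec(n_subjects = 2, per_gland_effect = rep(0, 10),
                      baseline = rep(0.5, 10), noise_sd = 0, seed = 1)
  expect_error(generate_cohort(spec, render = TRUE), "unreachable target")
})

test_that("ground-truth and raster geometry agree within 2% for widths >= 6", {
  for (A in c(0, 6, 12, 18)) for (lam in c(80, 120)) {
    p <- gland_shape_params(140, 8, amplitude_px = A, wavelength_px = lam,
                            axis_col = 40, phase_rad = 0.9)
    g <- generate_gland_mask(p, 180, 80)
    e <- extract_geometry(g$mask)
    tt <- g$geometry
    expect_lt(abs(e$pa / tt$pa - 1), 0.02)
    expect_lt(abs(e$pb / tt$pb - 1), 0.02)
    expect_lt(abs(e$L_central / tt$L_central - 1), 0.02)
  }
})

test_that("scenes round-trip through PNG + JSON sidecar", {
  dir <- withr::local_tempdir()
  sc <- generate_eyelid_scene(6, seed = 9)
  paths <- write_scene(sc, file.path(dir, "eye.png"))
  back <- read_scene(file.path(dir, "eye.png"))
  expect_identical(back$mask, sc$mask)
  expect_lt(max(abs(back$image - sc$image)), 1 / 255)  # 8-bit quantization
  for (j in seq_along(sc$gland_params))
    expect_equal(unclass(back$gland_params[[j]]),
                 unclass(sc$gland_params[[j]]), tolerance = 1e-12)
})

test_that("rendered cohorts round-trip through the manifest on disk", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_subjects = 2, per_gland_effect = rep(0.3, 10),
                      baseline = rep(1.5, 10), noise_sd = 0.05, seed = 2)
  cr <- generate_cohort(spec, render = TRUE)
  write_cohort(cr, dir)
  pg_disk <- analyze_cohort(dir)
  pg_mem <- analyze_cohort(cr)
  rownames(pg_disk) <- rownames(pg_mem) <- NULL
  expect_equal(pg_disk[order(pg_disk$subject_id, pg_disk$laterality,
                             pg_disk$gland_index), ],
               pg_mem[order(pg_mem$subject_id, pg_mem$laterality,
                            pg_mem$gland_index), ])
})
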