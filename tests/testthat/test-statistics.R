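test_that("paired t matches hand computation and stats::t.test", {
  d <- c(1, 1, 1, -1)
  r <- paired_t(d)
  expect_equal(r$mean, 0.5)
  expect_equal(r$sd, 1.0)
  expect_equal(r$t, 1.0)
  expect_equal(r$df, 3)
  tt <- t.test(d)
  expect_equal(r$p, tt$p.value)
  expect_equal(r$ci, as.vector(tt$conf.int))
  expect_error(paired_t(rep(2, 5)), "zero-variance")
  expect_error(paired_t(1), "at least 2")
})

test_that("symmetric zero-mean differences give t = 0, p = 1", {
  r <- paired_t(c(-2, -1, 0, 1, 2))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
})

test_that("paired t is invariant to adding a constant to both eyes", {
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20); shift <- rnorm(20)
  expect_equal(paired_t(a - b), paired_t((a + shift) - (b + shift)))
})

test_that("printed paired-t columns reproduce from mean/SE", {
  expect_equal(t_from_summary(0.634, 0.194), 3.266, tolerance = 0.001)
  expect_equal(t_from_summary(1.207, 0.257), 4.691, tolerance = 0.0015)
  expect_equal(t_from_summary(0, 1), 0)
  expect_error(t_from_summary(1, 0), "positive")
})

test_that("summary CIs reproduce printed intervals", {
  expect_equal(ci_from_summary(4.563, 0.589, 35), c(3.367, 5.759),
               tolerance = 5e-4)
  expect_equal(ci_from_summary(1.983, 0.454 / 6, 35), c(1.830, 2.137),
               tolerance = 5e-4)
  expect_equal(ci_from_summary(5, 0, 10), c(5, 5))
  lo_hi <- ci_from_summary(1, 1e-9, 30)
  expect_lt(lo_hi[2] - lo_hi[1], 1e-7)
  expect_error(ci_from_summary(1, 1, 0), "df")
})

test_that("group size recovers from printed SD/SE ratios", {
  expect_equal(infer_n_from_summary(3.536, 0.589)$n, 36)
  expect_equal(infer_n_from_summary(0.384, 0.064)$n, 36)
  expect_equal(infer_n_from_summary(2, 2)$n, 1)
  expect_equal(infer_n_from_summary(3.536, 0.589)$raw, (3.536 / 0.589)^2)
})

test_that("summary ANOVA equals raw ANOVA on moment-matched data", {
  m <- published$treatment_sites$mean
  s <- published$treatment_sites$sd
  a_sum <- anova_from_summary(m, s, 36)
  groups <- groups_from_summary(m, s, 36)
  a_raw <- anova_raw(groups)
  expect_equal(a_raw$F, a_sum$F, tolerance = 1e-9)
  expect_equal(a_raw$p, a_sum$p, tolerance = 1e-9)
  # and against stats::aov as an independent route
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(seq_along(groups), lengths(groups))))
  aa <- summary(stats::aov(y ~ g, data = df))[[1]]
  expect_equal(a_raw$F, aa[["F value"]][1], tolerance = 1e-8)
})

test_that("ANOVA degenerate cases error or vanish as expected", {
  expect_equal(anova_from_summary(c(1, 1, 1), c(1, 1, 1), 10)$F, 0)
  expect_error(anova_from_summary(c(1, 2), c(0, 0), 10), "zero within-group")
  expect_equal(anova_raw(list(c(1, 2), c(1, 2)))$F, 0)
  expect_error(anova_raw(list(c(0, 0), c(1, 1))), "zero within-group")
})

test_that("LSD separates well-separated groups and is empty for identical ones", {
  set.seed(3)
  a <- rnorm(36, 10, 1); b <- rnorm(36, 0, 1)
  r <- lsd_posthoc(list(a, b), labels = c("A", "B"))
  expect_equal(r$ordering, "A > B")
  base <- rnorm(36)
  same <- lsd_posthoc(list(base + 0.01, base, base - 0.01))
  expect_equal(same$ordering, "")
  expect_length(same$unplaced, 0)
})

test_that("LSD on the published treatment profile puts glands 5,6 on top", {
  r <- lsd_from_summary(published$treatment_sites$mean,
                        published$treatment_sites$sd, 36,
                        labels = as.character(1:10))
  expect_setequal(r$blocks[[1]], c("5", "6"))
  # glands 3 and 4 outrank the peripheral glands, as printed
  p34 <- r$p_matrix[c("3", "4"), c("1", "2", "9", "10")]
  expect_true(all(p34 < 0.05))
})

test_that("independent t matches stats::t.test in both variance modes", {
  set.seed(6)
  a <- rnorm(20, 1); b <- rnorm(25, 0)
  rp <- independent_t(a, b)
  tp <- t.test(a, b, var.equal = TRUE)
  expect_equal(rp$t, unname(tp$statistic))
  expect_equal(rp$p, tp$p.value)
  rw <- independent_t(a, b, var_equal = FALSE)
  tw <- t.test(a, b)
  expect_equal(rw$t, unname(tw$statistic))
  expect_equal(rw$df, unname(tw$parameter))
  expect_equal(independent_t(a, a)$t, 0)
  expect_error(independent_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("independent t sign follows the mean ordering", {
  set.seed(8)
  lo <- rnorm(10, 0, 0.01); hi <- rnorm(10, 1, 0.01)
  expect_lt(independent_t(lo, hi)$t, -50)
  expect_gt(independent_t(hi, lo)$t, 50)
})

test_that("emit_tables produces the three tables with sane structure", {
  spec <- cohort_spec(n_subjects = 30, seed = 14)
  tabs <- emit_tables(generate_cohort(spec)$values)
  expect_s3_class(tabs, "cohort_tables")
  expect_equal(tabs$paired$gland_index, 1:10)
  expect_true(all(tabs$paired$ci_lo <= tabs$paired$mean_diff &
                    tabs$paired$mean_diff <= tabs$paired$ci_hi))
  expect_true(all(tabs$paired$p >= 0 & tabs$paired$p <= 1))
  expect_equal(tabs$treatment_sites$n, rep(30, 10))
  expect_true(tabs$anova$treatment$F > tabs$anova$control$F)
  dir <- withr::local_tempdir()
  paths <- write_tables(tabs, dir)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths[1])
  expect_equal(back$mean_diff, tabs$paired$mean_diff)
})

test_that("emit_tables excludes incomplete subjects with a warning", {
  spec <- cohort_spec(n_subjects = 6, seed = 15)
  v <- generate_cohort(spec)$values
  v <- v[!(v$subject_id == "S003" & v$gland_index == 4 &
             v$group == "treatment"), ]
  expect_warning(tabs <- emit_tables(v), "S003")
  expect_equal(tabs$meta$n_subjects, 5)
})

test_that("duplicated identical subjects surface zero-variance per gland", {
  spec <- cohort_spec(n_subjects = 2, seed = 16)
  v <- generate_cohort(spec)$values
  v2 <- v[v$subject_id == "S001", ]
  v2$subject_id <- "S002"
  ws <- capture_warnings(
    tabs <- emit_tables(rbind(v[v$subject_id == "S001", ], v2)))
  expect_true(all(grepl("zero-variance|zero within-group", ws)))
  expect_length(grep("^gland \\d+: zero-variance", ws), 10)
  expect_true(all(is.na(tabs$paired$p)))
})

test_that("zero-effect cohorts give uniform paired-t p-values", {
  spec0 <- cohort_spec(per_gland_effect = rep(0, 10), seed = 1)
  ps <- c()
  for (i in 1:60) {
    sp <- spec0; sp$seed <- 5000 + i
    dm <- paired_diff_matrix(generate_cohort(sp)$values)
    ps <- c(ps, apply(dm, 2, function(d) paired_t(d)$p))
  }
  frac <- mean(ps < 0.05)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.08)
})
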