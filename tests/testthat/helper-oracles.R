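# Independent oracles used across the suite. These deliberately avoid the
# package's geometry code paths: arc lengths come from direct trapezoid
# integration of the analytic derivative, summary statistics from direct
# summation.

# Arc length of x(y) = A * sin(2*pi*y/lambda + phase) + offset over
# y in [0, y_max], by dense trapezoid integration of sqrt(1 + x'(y)^2).
oracle_sine_arc_length <- function(A, lambda, y_max, phase = 0, n = 2e4) {
  y <- seq(0, y_max, length.out = n)
  k <- 2 * pi / lambda
  dx <- A * k * cos(k * y + phase)
  f <- sqrt(1 + dx^2)
  sum((f[-1] + f[-n]) / 2) * (y_max / (n - 1))
}

# Chord of the same sinusoid between its endpoints.
oracle_sine_chord <- function(A, lambda, y_max, phase = 0) {
  k <- 2 * pi / lambda
  sqrt(y_max^2 + (A * sin(k * y_max + phase) - A * sin(phase))^2)
}

# Width-variation term by direct summation with the n + 1 denominator.
oracle_sigma_w <- function(widths) {
  m <- sum(widths) / length(widths)
  sqrt(sum((widths - m)^2) / (length(widths) + 1))
}

# A straight axis-aligned rectangular gland mask.
make_rect_mask <- function(rows = 160, cols = 60, height = 100, width = 10,
                           top = NULL, left = NULL) {
  if (is.null(top)) top <- (rows - height) %/% 2 + 1
  if (is.null(left)) left <- (cols - width) %/% 2 + 1
  m <- matrix(0L, rows, cols)
  m[top:(top + height - 1), left:(left + width - 1)] <- 1L
  m
}

# Paired difference matrix (subjects x glands) from a cohort values table.
paired_diff_matrix <- function(values) {
  tv <- values[values$group == "treatment", ]
  cv <- values[values$group == "control", ]
  tv <- tv[order(tv$subject_id, tv$gland_index), ]
  cv <- cv[order(cv$subject_id, cv$gland_index), ]
  stopifnot(all(tv$subject_id == cv$subject_id),
            all(tv$gland_index == cv$gland_index))
  matrix(tv$D - cv$D, ncol = 10, byrow = TRUE)
}

# Published summary rows (bundled fixture), loaded once for the suite.
published <- gland_summary_tables()
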