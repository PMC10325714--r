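#' Gland shape parameters
#'
#' Parameterizes a single synthetic meibomian gland as a vertical sinusoidal
#' centerline with a linearly tapered width. Coordinates are 1-based pixel
#' centres; rows run down the image and the gland axis is the row direction
#' (glands appear as near-vertical bright bands, as in en-face meibography of
#' the everted upper eyelid). This family spans straight uniform glands to
#' strongly distorted ones while controlling boundary arc length (via
#' `amplitude_px`, `wavelength_px`) and width variation (via `width_slope`)
#' independently.
#'
#' @param length_px integer > 0, extent of the gland along its axis (rows).
#' @param base_width_px width (columns) at the top row, > 0.
#' @param amplitude_px sinusoidal centerline amplitude, >= 0.
#' @param wavelength_px sinusoidal wavelength, > 0.
#' @param width_slope linear width change per row; the width must stay
#'   positive over the whole gland.
#' @param phase_rad phase of the sinusoid at the top row.
#' @param axis_col column of the centerline anchor (mean centerline column).
#' @return An object of class `gland_shape_params`.
#' @export
gland_shape_params <- function(length_px, base_width_px, amplitude_px = 0,
                               wavelength_px = 100, width_slope = 0,
                               phase_rad = 0, axis_col = 0) {
  length_px <- as.integer(length_px)
  stopifnot(length_px > 0, base_width_px > 0, amplitude_px >= 0,
            wavelength_px > 0)
  w_end <- base_width_px + width_slope * (length_px - 1)
  if (min(base_width_px, w_end) <= 0)
    stop("degenerate width: gland width must stay positive along the axis",
         call. = FALSE)
  structure(list(length_px = length_px, base_width_px = base_width_px,
                 amplitude_px = amplitude_px, wavelength_px = wavelength_px,
                 width_slope = width_slope, phase_rad = phase_rad,
                 axis_col = axis_col),
            class = "gland_shape_params")
}

# Continuous centerline column and width at axial position y (0-based, in
# pixels from the gland's top row).
gland_centerline_fun <- function(p) {
  function(y) p$axis_col +
    p$amplitude_px * sin(2 * pi * y / p$wavelength_px + p$phase_rad)
}
gland_width_fun <- function(p) {
  function(y) p$base_width_px + p$width_slope * y
}

new_gland_geometry <- function(centerline, left, right, widths,
                               pa, pb, L_central) {
  n <- length(widths)
  w_avg <- mean(widths)
  # width-variation term uses the n + 1 denominator of the published formula
  sigma_w <- sqrt(sum((widths - w_avg)^2) / (n + 1))
  structure(list(centerline = centerline, left = left, right = right,
                 widths = widths, w_avg = w_avg, sigma_w = sigma_w,
                 pa = pa, pb = pb, L_central = L_central, n = n),
            class = "gland_geometry")
}

#' @export
print.gland_geometry <- function(x, ...) {
  cat(sprintf(
    "gland_geometry: n = %d width samples, w_avg = %.2f px, sigma_w = %.3f px\n",
    x$n, x$w_avg, x$sigma_w))
  cat(sprintf("  pa = %.2f  pb = %.2f  L_central = %.2f px  (pa*pb/L^2 = %.4f)\n",
              x$pa, x$pb, x$L_central, x$pa * x$pb / x$L_central^2))
  invisible(x)
}

#' Analytic ground-truth geometry of a parametric gland
#'
#' Computes the gland geometry (boundary arc lengths, central-line length,
#' width profile) from the continuous parameterization rather than from any
#' raster. Boundary curves are the horizontal offsets of the centerline by
#' half the local width; `pa`/`pb` are their arc lengths from dense trapezoid
#' integration; `L_central` is the straight-line (chord) length of the central
#' line between its endpoints; widths are sampled at integer rows, matching
#' the raster extractor's convention.
#'
#' @param params a [gland_shape_params()] object.
#' @param n_dense number of integration points for the boundary arc lengths.
#' @return A `gland_geometry` object.
#' @export
gland_truth_geometry <- function(params, n_dense = 1e4) {
  L <- params$length_px
  xf <- gland_centerline_fun(params)
  wf <- gland_width_fun(params)
  yi <- seq_len(L) - 1
  widths <- wf(yi)
  if (any(widths <= 0)) stop("degenerate width", call. = FALSE)

  yd <- seq(0, L - 1, length.out = max(n_dense, 2L))
  xd <- xf(yd)
  wd <- wf(yd)
  pa <- polyline_length(yd, xd - wd / 2)
  pb <- polyline_length(yd, xd + wd / 2)
  xi <- xf(yi)
  L_central <- sqrt((L - 1)^2 + (xi[L] - xi[1])^2)

  new_gland_geometry(
    centerline = data.frame(row = yi + 1, col = xi),
    left       = data.frame(row = yi + 1, col = xi - widths / 2),
    right      = data.frame(row = yi + 1, col = xi + widths / 2),
    widths = widths, pa = pa, pb = pb, L_central = L_central)
}

#' Rasterize a gland and return its analytic ground truth
#'
#' Row `r` of the gland covers `round(width(r))` contiguous pixels centred on
#' the centerline column, so the rasterized width profile equals the rounded
#' nominal profile exactly and a constant-width gland has zero raster width
#' variation. The gland is placed vertically centred on the canvas.
#'
#' @param params a [gland_shape_params()] object.
#' @param canvas_rows,canvas_cols canvas dimensions.
#' @return A list with `mask` (0/1 integer matrix) and `geometry`
#'   (the [gland_truth_geometry()] of `params`).
#' @export
generate_gland_mask <- function(params, canvas_rows, canvas_cols) {
  L <- params$length_px
  if (L > canvas_rows) stop("out of canvas", call. = FALSE)
  geom <- gland_truth_geometry(params)
  top <- (canvas_rows - L) %/% 2
  xf <- gland_centerline_fun(params)
  wf <- gland_width_fun(params)
  yi <- seq_len(L) - 1
  x <- xf(yi)
  wpix <- pmax(round(wf(yi)), 1L)
  leftc <- round(x - (wpix - 1) / 2)
  rightc <- leftc + wpix - 1L
  if (min(leftc) < 1 || max(rightc) > canvas_cols)
    stop("out of canvas", call. = FALSE)
  mask <- matrix(0L, canvas_rows, canvas_cols)
  for (i in seq_len(L)) mask[top + i, leftc[i]:rightc[i]] <- 1L
  list(mask = mask, geometry = geom)
}

# Assemble a scene from a list of gland parameter sets anchored on an evenly
# spaced grid of axis columns. The image is a smoothed mask intensity plus
# optional additive Gaussian noise (drawn from the current RNG stream),
# clipped to [0, 1].
build_scene <- function(gland_params, spacing_px, margin_px = 20,
                        noise_sd = 0, canvas_rows = NULL,
                        fg_level = 0.8, bg_level = 0.1, blur_sigma = 1.5) {
  n <- length(gland_params)
  canvas_cols <- as.integer(2 * margin_px + n * spacing_px)
  if (is.null(canvas_rows))
    canvas_rows <- as.integer(max(vapply(gland_params, `[[`, 1L, "length_px")) +
                                2 * margin_px)
  half_slot <- spacing_px / 2 - 1
  for (p in gland_params) {
    w_max <- max(p$base_width_px,
                 p$base_width_px + p$width_slope * (p$length_px - 1))
    if (p$amplitude_px + w_max / 2 > half_slot)
      stop("infeasible packing: gland extent exceeds its spacing slot",
           call. = FALSE)
  }
  mask <- matrix(0L, canvas_rows, canvas_cols)
  geoms <- vector("list", n)
  for (j in seq_len(n)) {
    p <- gland_params[[j]]
    p$axis_col <- margin_px + (j - 0.5) * spacing_px
    gland_params[[j]] <- p
    g <- generate_gland_mask(p, canvas_rows, canvas_cols)
    mask <- mask | g$mask
    geoms[[j]] <- g$geometry
  }
  mask <- matrix(as.integer(mask), canvas_rows, canvas_cols)
  sm <- EBImage::imageData(EBImage::gblur(mask * 1.0, sigma = blur_sigma))
  image <- bg_level + (fg_level - bg_level) * sm
  if (noise_sd > 0)
    image <- image + rnorm(length(image), 0, noise_sd)
  image <- matrix(clip01(image), canvas_rows, canvas_cols)
  structure(list(image = image, mask = mask, gland_params = gland_params,
                 truth_geometries = geoms),
            class = "eyelid_scene")
}

#' Generate a synthetic eyelid scene
#'
#' Draws per-gland shape parameters uniformly from the supplied ranges and
#' rasterizes `n_glands` non-overlapping glands left-to-right on an evenly
#' spaced grid. The grayscale image is the smoothed mask intensity plus
#' additive Gaussian noise, clipped to `[0, 1]`; with `noise_sd = 0` the image
#' is a deterministic function of the mask. The whole scene is deterministic
#' given `seed`.
#'
#' @param n_glands number of glands (>= 1), ordered left-to-right.
#' @param spacing_px horizontal spacing between gland axes.
#' @param shape_ranges named list of `c(min, max)` ranges for the
#'   [gland_shape_params()] fields (excluding `axis_col`).
#' @param noise_sd additive Gaussian noise SD on the `[0, 1]` intensity scale.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param ... passed to the internal scene assembler (`margin_px`,
#'   `canvas_rows`, `fg_level`, `bg_level`, `blur_sigma`).
#' @return An `eyelid_scene`: list with `image`, `mask`, `gland_params`,
#'   `truth_geometries` (index-aligned, left-to-right).
#' @export
generate_eyelid_scene <- function(n_glands, spacing_px = 60,
                                  shape_ranges = list(), noise_sd = 0.02,
                                  seed = NULL, ...) {
  stopifnot(n_glands >= 1)
  rng <- utils::modifyList(list(
    length_px = c(120, 160), base_width_px = c(9, 13),
    amplitude_px = c(0, 12), wavelength_px = c(80, 120),
    width_slope = c(0, 0), phase_rad = c(0, 2 * pi)), shape_ranges)
  u <- function(r) runif(1, r[1], r[2])
  with_seed(seed, {
    params <- lapply(seq_len(n_glands), function(j) {
      gland_shape_params(
        length_px = round(u(rng$length_px)),
        base_width_px = u(rng$base_width_px),
        amplitude_px = u(rng$amplitude_px),
        wavelength_px = u(rng$wavelength_px),
        width_slope = u(rng$width_slope),
        phase_rad = u(rng$phase_rad))
    })
    build_scene(params, spacing_px = spacing_px, noise_sd = noise_sd, ...)
  })
}

#' Solve the centerline amplitude that attains a target deformation
#'
#' One-dimensional search (on the analytic ground-truth geometry) for the
#' sinusoidal amplitude at which a gland with otherwise fixed shape reaches a
#' requested deformation coefficient.
#'
#' @param target_D requested deformation coefficient.
#' @param params a [gland_shape_params()] object; its `amplitude_px` is
#'   ignored.
#' @param amp_max largest admissible amplitude (packing limit).
#' @param variant deformation-coefficient variant, see
#'   [deformation_coefficient()].
#' @param tol absolute tolerance on the achieved coefficient.
#' @return The amplitude in pixels.
#' @export
solve_gland_amplitude <- function(target_D, params, amp_max,
                                  variant = "normalized_plus_one",
                                  tol = 1e-6) {
  d_of <- function(a) {
    p <- params; p$amplitude_px <- a
    deformation_coefficient(gland_truth_geometry(p, n_dense = 2000), variant)
  }
  d0 <- d_of(0)
  if (target_D < d0 - 1e-9)
    stop(sprintf(
      "unreachable target deformation: %.4f is below the variant minimum %.4f",
      target_D, d0), call. = FALSE)
  if (target_D <= d0) return(0)
  if (d_of(amp_max) < target_D)
    stop(sprintf(
      "unreachable target deformation: %.4f exceeds the packing limit", target_D),
      call. = FALSE)
  stats::uniroot(function(a) d_of(a) - target_D, c(0, amp_max),
                 tol = tol)$root
}

#' Specification of a paired two-eye synthetic cohort
#'
#' Defaults emulate the published study's design: 10 central glands per upper
#' eyelid, one treated and one untreated contralateral eye per subject,
#' control-eye baseline deformation profile and per-gland treatment effects
#' taken from the bundled published summary tables, and a paired-difference SD
#' matching the published pair-5 row (noise_sd = 3.536 / sqrt(2)). The group
#' size defaults to the n = 36 recovered from the published SD/SE ratios.
#'
#' @param n_subjects number of subjects (>= 2); each contributes both eyes.
#' @param per_gland_effect length-10 additive deformation shift for the
#'   treated eye, gland 1 (temporal) to 10 (nasal).
#' @param baseline length-10 control-eye mean deformation profile.
#' @param between_eye_corr within-subject between-eye correlation in `[0, 1)`,
#'   induced by a shared subject-level Gaussian term.
#' @param noise_sd per-eye, per-gland Gaussian noise SD; the implied
#'   paired-difference SD is `sqrt(2) * noise_sd`.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 36,
                        per_gland_effect = gland_summary_tables()$paired$mean_diff,
                        baseline = gland_summary_tables()$control_sites$mean,
                        between_eye_corr = 0.5,
                        noise_sd = 3.536 / sqrt(2),
                        seed = 1L) {
  stopifnot(n_subjects >= 2, length(per_gland_effect) == 10,
            length(baseline) == 10, noise_sd >= 0,
            between_eye_corr >= 0, between_eye_corr < 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 per_gland_effect = as.numeric(per_gland_effect),
                 baseline = as.numeric(baseline),
                 between_eye_corr = between_eye_corr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a paired two-eye cohort
#'
#' For subject `s`, gland `g`: the control eye's deformation target is
#' `baseline[g] + b_s + eps`, the treated eye's is
#' `baseline[g] + effect[g] + b_s + eps'`, where `b_s` is a subject-level
#' Gaussian shared by both eyes (inducing the between-eye correlation) and
#' `eps` is independent per eye and gland with SD `noise_sd`. The treated
#' laterality (OD/OS) is randomized per subject. With `render = TRUE` each eye
#' is additionally rasterized as a 12-gland scene whose central ten glands
#' realize the deformation targets: the sinusoidal amplitude of each gland is
#' solved from the target via [solve_gland_amplitude()], so targets below the
#' variant minimum raise an error.
#'
#' @param spec a [cohort_spec()].
#' @param render rasterize scenes for every eye (slower); otherwise only the
#'   deformation values are generated.
#' @param scene named list of rendering options: `n_glands` (default 12),
#'   `spacing_px` (80), `length_px` (140), `base_width_px` (11),
#'   `wavelength_px` (100), `noise_sd` (0.02), `flank_D` (target for the two
#'   non-central flank glands; default the variant minimum).
#' @return A list with `values` (data.frame: subject_id, laterality, group,
#'   gland_index, D — the generated true deformation value) and, when
#'   rendered, `scenes` (named list per
#'   subject/eye with the `eyelid_scene`, laterality and group).
#' @export
generate_cohort <- function(spec, render = FALSE, scene = list()) {
  stopifnot(inherits(spec, "cohort_spec"))
  sc <- utils::modifyList(list(
    n_glands = 12L, spacing_px = 80, length_px = 140L, base_width_px = 11,
    wavelength_px = 100, noise_sd = 0.02, flank_D = NULL), scene)
  rho <- spec$between_eye_corr
  sigma_b <- if (rho > 0) spec$noise_sd * sqrt(rho / (1 - rho)) else 0

  with_seed(spec$seed, {
    ns <- spec$n_subjects
    sid <- sprintf("S%03d", seq_len(ns))
    treated_lat <- sample(c("OD", "OS"), ns, replace = TRUE)
    b <- rnorm(ns, 0, sigma_b)
    d_ctrl <- matrix(spec$baseline, ns, 10, byrow = TRUE) + b +
      matrix(rnorm(ns * 10, 0, spec$noise_sd), ns, 10)
    d_trt <- matrix(spec$baseline + spec$per_gland_effect, ns, 10,
                    byrow = TRUE) + b +
      matrix(rnorm(ns * 10, 0, spec$noise_sd), ns, 10)
    values <- data.frame(
      subject_id = rep(sid, each = 20),
      laterality = as.vector(vapply(treated_lat, function(l)
        rep(c(l, setdiff(c("OD", "OS"), l)), each = 10), character(20))),
      group = rep(rep(c("treatment", "control"), each = 10), ns),
      gland_index = rep(1:10, 2 * ns),
      D = as.vector(vapply(seq_len(ns), function(s)
        c(d_trt[s, ], d_ctrl[s, ]), numeric(20))),
      stringsAsFactors = FALSE)
    out <- list(values = values, spec = spec)
    if (render) {
      scenes <- list()
      for (s in seq_len(ns)) {
        for (grp in c("treatment", "control")) {
          lat <- if (grp == "treatment") treated_lat[s]
          else setdiff(c("OD", "OS"), treated_lat[s])
          d <- if (grp == "treatment") d_trt[s, ] else d_ctrl[s, ]
          scenes[[paste(sid[s], lat, sep = "_")]] <-
            c(render_eye_scene(d, lat, sc),
              list(subject_id = sid[s], laterality = lat, group = grp))
        }
      }
      out$scenes <- scenes
    }
    out
  })
}

# Rasterize one eye: n_glands evenly spaced; the central ten carry the
# temporal->nasal deformation targets (image order depends on laterality:
# for OD the temporal side is image-left), the flanks a minimal target.
render_eye_scene <- function(targets, laterality, sc) {
  stopifnot(length(targets) == 10, sc$n_glands >= 12)
  base <- gland_shape_params(length_px = sc$length_px,
                             base_width_px = sc$base_width_px,
                             wavelength_px = sc$wavelength_px)
  flank_D <- if (is.null(sc$flank_D))
    deformation_coefficient(gland_truth_geometry(base, n_dense = 2000))
  else sc$flank_D
  n_flank <- sc$n_glands - 10L
  left_flanks <- n_flank %/% 2L
  image_targets <- c(rep(flank_D, left_flanks),
                     if (laterality == "OD") targets else rev(targets),
                     rep(flank_D, n_flank - left_flanks))
  amp_max <- sc$spacing_px / 2 - sc$base_width_px / 2 - 1.5
  params <- lapply(image_targets, function(d) {
    p <- base
    p$phase_rad <- runif(1, 0, 2 * pi)
    p$amplitude_px <- solve_gland_amplitude(d, p, amp_max = amp_max)
    p
  })
  list(scene = build_scene(params, spacing_px = sc$spacing_px,
                           noise_sd = sc$noise_sd),
       image_targets = image_targets)
}
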