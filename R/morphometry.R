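#' Label gland components in a binary mask
#'
#' 8-connected component labeling (row-run encoding with union-find), with
#' components below `min_area` discarded. Components are returned ordered
#' left-to-right by centroid column; ties are broken by topmost row.
#'
#' @param mask 0/1 matrix.
#' @param min_area minimum pixel count for a component to be kept.
#' @return A list of components, each a list with `rows`, `cols` (pixel
#'   coordinates), `area`, `centroid_col`, `centroid_row`, `top_row`.
#' @export
label_glands <- function(mask, min_area = 30) {
  stopifnot(is_binary_mask(mask))
  nr <- nrow(mask)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  # run-length encode each row; link runs that 8-touch a run in the row above
  runs <- vector("list", nr)
  for (r in seq_len(nr)) {
    v <- mask[r, ]
    if (!any(v == 1)) next
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values == 1)
    row_runs <- data.frame(start = starts[fg], end = ends[fg], label = NA_integer_)
    for (k in seq_len(nrow(row_runs))) {
      parent[length(parent) + 1L] <- length(parent) + 1L
      row_runs$label[k] <- length(parent)
    }
    prev <- if (r > 1) runs[[r - 1]] else NULL
    if (!is.null(prev)) {
      for (k in seq_len(nrow(row_runs))) {
        touch <- prev$end + 1L >= row_runs$start[k] &
          prev$start - 1L <= row_runs$end[k]
        for (j in which(touch)) union(row_runs$label[k], prev$label[j])
      }
    }
    runs[[r]] <- row_runs
  }
  if (length(parent) == 0) return(list())
  roots <- vapply(seq_along(parent), find, 1L)
  comp_id <- match(roots, unique(roots))
  comps <- vector("list", max(comp_id))
  for (r in seq_len(nr)) {
    rr <- runs[[r]]
    if (is.null(rr)) next
    for (k in seq_len(nrow(rr))) {
      id <- comp_id[rr$label[k]]
      cols <- rr$start[k]:rr$end[k]
      comps[[id]] <- rbind(comps[[id]], cbind(rep(r, length(cols)), cols))
    }
  }
  comps <- lapply(comps, function(m) {
    list(rows = m[, 1], cols = m[, 2], area = nrow(m),
         centroid_col = mean(m[, 2]), centroid_row = mean(m[, 1]),
         top_row = min(m[, 1]))
  })
  comps <- Filter(function(cc) cc$area >= min_area, comps)
  ord <- order(vapply(comps, `[[`, 0, "centroid_col"),
               vapply(comps, `[[`, 0, "top_row"))
  comps[ord]
}

# Rotation angle (radians) aligning the principal axis of a point cloud with
# the row direction; the second-moment eigenvector of the foreground pixels.
principal_axis_angle <- function(rows, cols) {
  cv <- stats::cov(cbind(rows, cols))
  e <- eigen(cv, symmetric = TRUE)
  v <- e$vectors[, 1]          # (row, col) direction of largest variance
  if (v[1] < 0) v <- -v        # point down the image
  atan2(v[2], v[1])
}

#' Extract gland geometry from one connected component
#'
#' The component is rotated so that its axis is vertical; rows are then
#' sampled every `step_px` along the axis. The axis can be the image row
#' direction (`align = "none"`) or the principal axis — the second-moment
#' eigenvector of the foreground pixels (`align = "principal"`). The default
#' `align = "auto"` extracts in both frames when they differ appreciably and
#' keeps the one with the smaller `w_avg + sigma_w`: sampling a band
#' obliquely to its true axis inflates and destabilizes the measured widths,
#' so the frame with the smaller, more stable width profile is the
#' better-aligned one. This matters because upper-eyelid glands
#' are anatomically near-vertical while a strongly sinuous vertical gland can
#' have a genuinely tilted second-moment axis (the sinuosity itself tilts
#' the second moment), and realigning such a gland would corrupt its width
#' profile. Per sampled row, the left/right boundary
#' points are the extreme foreground columns, the width is
#' `right - left + 1`, and the center point is their midpoint. Boundary arc
#' lengths `pa`, `pb` are polyline lengths of the boundary sequences after a
#' centred moving-average smoothing of the column profiles (window
#' `smooth_window`), which removes the upward staircase bias of
#' integer-quantized boundaries; widths are taken from the raw extremes.
#' `L_central` is the straight-line length of the central line between its
#' first and last points.
#'
#' @param component a component from [label_glands()], or a 0/1 mask with one
#'   connected component.
#' @param step_px axial sampling step in pixels.
#' @param smooth_window odd moving-average window for the boundary profiles.
#' @param align `"auto"` (smaller-mean-width frame, see above),
#'   `"principal"` (always realign), or `"none"` (image rows are the axis).
#' @return A `gland_geometry` object.
#' @export
extract_geometry <- function(component, step_px = 1, smooth_window = 5,
                             align = c("auto", "principal", "none")) {
  align <- match.arg(align)
  if (is.matrix(component)) {
    idx <- which(component == 1, arr.ind = TRUE)
    component <- list(rows = idx[, 1], cols = idx[, 2])
  }
  r <- as.numeric(component$rows)
  cl <- as.numeric(component$cols)
  if (length(r) < 2) stop("gland too short", call. = FALSE)
  if (align == "auto") {
    th <- principal_axis_angle(r, cl)
    if (abs(th) < 2 * pi / 180)
      return(extract_at_angle(r, cl, 0, step_px, smooth_window))
    g0 <- tryCatch(extract_at_angle(r, cl, 0, step_px, smooth_window),
                   error = function(e) NULL)
    g1 <- tryCatch(extract_at_angle(r, cl, th, step_px, smooth_window),
                   error = function(e) NULL)
    if (is.null(g0) && is.null(g1))
      return(extract_at_angle(r, cl, 0, step_px, smooth_window))
    if (is.null(g0)) return(g1)
    if (is.null(g1)) return(g0)
    # the well-aligned frame has both smaller and more stable widths
    return(if (g1$w_avg + g1$sigma_w < g0$w_avg + g0$sigma_w) g1 else g0)
  }
  theta <- if (align == "none") 0 else principal_axis_angle(r, cl)
  extract_at_angle(r, cl, theta, step_px, smooth_window)
}

extract_at_angle <- function(r, cl, theta, step_px, smooth_window) {
  ct <- cos(theta); st <- sin(theta)
  r0 <- mean(r); c0 <- mean(cl)
  ra <- ct * (r - r0) + st * (cl - c0)   # axial coordinate
  ca <- -st * (r - r0) + ct * (cl - c0)  # transverse coordinate

  bin <- floor((ra - min(ra)) / step_px)
  nb <- max(bin) + 1L
  if (nb < 2L) stop("gland too short", call. = FALSE)
  present <- tabulate(bin + 1L, nbins = nb) > 0
  if (!all(present)) stop("fragmented gland", call. = FALSE)
  left <- vapply(split(ca, bin), min, 0)
  right <- vapply(split(ca, bin), max, 0)
  ord <- order(as.integer(names(left)))
  left <- left[ord]; right <- right[ord]
  widths <- right - left + 1
  axis_pos <- (sort(unique(bin)) + 0.5) * step_px

  left_s <- moving_average(left, smooth_window)
  right_s <- moving_average(right, smooth_window)
  center <- (left_s + right_s) / 2
  pa <- polyline_length(axis_pos, left_s)
  pb <- polyline_length(axis_pos, right_s)
  nbp <- length(center)
  L_central <- sqrt((axis_pos[nbp] - axis_pos[1])^2 + (center[nbp] - center[1])^2)

  new_gland_geometry(
    centerline = data.frame(row = axis_pos, col = center),
    left       = data.frame(row = axis_pos, col = left_s),
    right      = data.frame(row = axis_pos, col = right_s),
    widths = widths, pa = pa, pb = pb, L_central = L_central)
}

#' Per-gland deformation coefficient
#'
#' Combines the arc-chord ratio of the gland boundaries,
#' `pa * pb / L_central^2`, with the width-variation term
#' `sigma_w = sqrt(sum((w_i - w_avg)^2) / (n + 1))`. Three combiners are
#' provided:
#' \describe{
#'   \item{`"as_printed"`}{`(pa*pb/L^2) * sigma_w` — the literal published
#'     expression; it carries pixel units and is 0 (not 1) on a straight
#'     uniform gland, at odds with the published statements that the
#'     coefficient is dimensionless with minimum 1. Kept for fidelity.}
#'   \item{`"normalized"`}{`(pa*pb/L^2) * (sigma_w / w_avg)` — dimensionless,
#'     minimum 0.}
#'   \item{`"normalized_plus_one"` (default)}{`(pa*pb/L^2) * (1 + sigma_w /
#'     w_avg)` — the only variant that is both dimensionless and attains its
#'     minimum 1 on a straight uniform gland, consistent with both published
#'     properties.}
#' }
#'
#' @param geom a `gland_geometry`.
#' @param variant one of `"normalized_plus_one"`, `"normalized"`,
#'   `"as_printed"`.
#' @return The deformation coefficient (dimensionless for the normalized
#'   variants).
#' @export
deformation_coefficient <- function(geom,
                                    variant = c("normalized_plus_one",
                                                "normalized", "as_printed")) {
  variant <- match.arg(variant)
  if (geom$L_central == 0) stop("degenerate geometry: zero central length",
                                call. = FALSE)
  if (geom$w_avg == 0) stop("degenerate geometry: zero average width",
                            call. = FALSE)
  ratio <- geom$pa * geom$pb / geom$L_central^2
  switch(variant,
         as_printed = ratio * geom$sigma_w,
         normalized = ratio * (geom$sigma_w / geom$w_avg),
         normalized_plus_one = ratio * (1 + geom$sigma_w / geom$w_avg))
}

#' Analyze one eye: central-ten gland deformation records
#'
#' Labels the gland components, selects the ten central glands around the
#' midline of the overall gland area, numbers them 1 (most temporal) to 10
#' (most nasal) according to laterality, and computes each gland's geometry
#' and deformation coefficient. Glands touching the image border are excluded
#' before selection (incomplete geometry).
#'
#' @param mask 0/1 gland mask for one upper eyelid.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param group optional group label carried into the output.
#' @param subject_id optional subject identifier carried into the output.
#' @param temporal_side `"left"` or `"right"` image side; default derived
#'   from laterality (OD: temporal = image left), overridable because
#'   acquisition mirroring is device-dependent.
#' @param variant deformation-coefficient variant.
#' @param min_area,step_px,smooth_window passed to [label_glands()] and
#'   [extract_geometry()].
#' @return An `eye_record`: data.frame with one row per gland index 1..10
#'   (gland_index, pa, pb, L_central, w_avg, sigma_w, n, D) plus attributes
#'   `laterality`, `group`, `subject_id`, `variant`.
#' @export
analyze_eye <- function(mask, laterality = c("OD", "OS"), group = NA_character_,
                        subject_id = NA_character_, temporal_side = NULL,
                        variant = "normalized_plus_one", min_area = 30,
                        step_px = 1, smooth_window = 5) {
  laterality <- match.arg(laterality)
  comps <- label_glands(mask, min_area = min_area)
  comps <- Filter(function(cc) {
    min(cc$rows) > 1 && max(cc$rows) < nrow(mask) &&
      min(cc$cols) > 1 && max(cc$cols) < ncol(mask)
  }, comps)
  if (length(comps) < 10)
    stop(sprintf("insufficient glands (%d < 10)", length(comps)), call. = FALSE)
  midline <- find_midline(comps)
  sel <- select_central_10(comps, midline, laterality = laterality,
                           temporal_side = temporal_side)
  rec <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
    geom <- extract_geometry(comps[[sel$component_id[i]]], step_px = step_px,
                             smooth_window = smooth_window)
    data.frame(gland_index = sel$gland_index[i], pa = geom$pa, pb = geom$pb,
               L_central = geom$L_central, w_avg = geom$w_avg,
               sigma_w = geom$sigma_w, n = geom$n,
               D = deformation_coefficient(geom, variant))
  }))
  rec <- rec[order(rec$gland_index), ]
  rownames(rec) <- NULL
  structure(rec, laterality = laterality, group = group,
            subject_id = subject_id, variant = variant,
            class = c("eye_record", "data.frame"))
}
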