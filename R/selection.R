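#' Midline of the overall gland area
#'
#' The area-weighted centroid column of the union of all gland pixels —
#' equivalently the mean centroid column of the components weighted by their
#' areas. Robust to a single stray peripheral gland, unlike the midpoint of
#' the extreme columns.
#'
#' @param components component list from [label_glands()].
#' @return The midline column (numeric).
#' @export
find_midline <- function(components) {
  if (length(components) == 0) stop("no gland components", call. = FALSE)
  areas <- vapply(components, `[[`, 0, "area")
  cols <- vapply(components, `[[`, 0, "centroid_col")
  sum(areas * cols) / sum(areas)
}

#' Select and number the ten central glands
#'
#' Picks the five glands nearest the midline (by centroid column) on each
#' side and numbers the selected ten from the temporal extreme (gland 1) to
#' the nasal extreme (gland 10). A centroid exactly on the midline is
#' assigned to the side with fewer glands (ties to the temporal side). The
#' default orientation follows standard en-face meibography: for OD the
#' temporal side is image-left, for OS image-right; override `temporal_side`
#' for mirrored acquisitions.
#'
#' @param components component list from [label_glands()].
#' @param midline midline column, see [find_midline()].
#' @param laterality `"OD"` or `"OS"`.
#' @param temporal_side `"left"` or `"right"`, or `NULL` to derive from
#'   laterality.
#' @return A data.frame (`gland_index_map`): gland_index 1..10, component_id
#'   (index into `components`), centroid_col, side; attributes `laterality`,
#'   `temporal_side`, `midline`.
#' @export
select_central_10 <- function(components, midline, laterality = c("OD", "OS"),
                              temporal_side = NULL) {
  laterality <- match.arg(laterality)
  if (is.null(temporal_side))
    temporal_side <- if (laterality == "OD") "left" else "right"
  temporal_side <- match.arg(temporal_side, c("left", "right"))

  cols <- vapply(components, `[[`, 0, "centroid_col")
  side <- ifelse(cols < midline, "left", ifelse(cols > midline, "right", "on"))
  if (any(side == "on")) {
    for (i in which(side == "on")) {
      nl <- sum(side == "left"); nr <- sum(side == "right")
      side[i] <- if (nl < nr) "left" else if (nr < nl) "right"
      else temporal_side
    }
  }
  for (s in c("left", "right")) {
    if (sum(side == s) < 5)
      stop(sprintf("fewer than 5 glands on the %s side of the midline (%d)",
                   s, sum(side == s)), call. = FALSE)
  }
  pick <- function(s) {
    idx <- which(side == s)
    idx[order(abs(cols[idx] - midline))][1:5]
  }
  sel <- c(pick("left"), pick("right"))
  ord <- order(cols[sel], decreasing = (temporal_side == "right"))
  sel <- sel[ord]
  structure(data.frame(gland_index = 1:10, component_id = sel,
                       centroid_col = cols[sel],
                       side = side[sel], stringsAsFactors = FALSE),
            laterality = laterality, temporal_side = temporal_side,
            midline = midline,
            class = c("gland_index_map", "data.frame"))
}
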