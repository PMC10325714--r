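#' The registered augmentation transforms
#'
#' Eleven transform types: the geometric ones (`crop`, `hflip`, `cutout`,
#' `translate_x`, `translate_y`, `rotate`, `shear_x`) are applied with
#' identical parameters to image and mask (mask by nearest neighbour, fill
#' background); the photometric ones (`equalize`, `contrast`, `brightness`,
#' `sharpness`) touch the image only. Each transform has a linear
#' magnitude-to-parameter map over M = 1..10, documented in
#' [aug_magnitude_map()].
#'
#' @return Character vector of the 11 registered transform names.
#' @export
aug_registry <- function() {
  c("crop", "hflip", "cutout", "translate_x", "translate_y", "rotate",
    "shear_x", "equalize", "contrast", "brightness", "sharpness")
}

aug_geometric <- function() {
  c("crop", "hflip", "cutout", "translate_x", "translate_y", "rotate",
    "shear_x")
}

#' Magnitude-to-parameter maps of the augmentation transforms
#'
#' All maps are linear in the magnitude M (1..10): M = 10 gives the maximum
#' documented effect, M = 1 the smallest nonzero effect; M = 0 is not part of
#' the scheme. Maxima: rotation ±30°, translation ±20% of the dimension,
#' shear ±0.3, crop 15% of each dimension per side, cutout side 30% of the
#' short dimension, contrast factor 1±0.8, brightness shift ±0.4, sharpness
#' amount 1.0, equalize blend 1.0.
#'
#' @param name transform name from [aug_registry()].
#' @param magnitude integer in 1..10.
#' @return The transform's scalar parameter at that magnitude.
#' @export
aug_magnitude_map <- function(name, magnitude) {
  stopifnot(magnitude %in% 1:10)
  switch(name,
         rotate = 3 * magnitude,          # degrees
         translate_x = 0.02 * magnitude,  # fraction of width
         translate_y = 0.02 * magnitude,  # fraction of height
         shear_x = 0.03 * magnitude,
         crop = 0.015 * magnitude,        # fraction removed per side
         cutout = 0.03 * magnitude,       # hole side / min(dim)
         contrast = 0.08 * magnitude,     # |factor - 1|
         brightness = 0.04 * magnitude,   # additive shift
         sharpness = 0.1 * magnitude,     # unsharp amount
         equalize = 0.1 * magnitude,      # blend weight
         hflip = NA_real_,                # magnitude-free involution
         stop(sprintf("unregistered transform '%s'", name), call. = FALSE))
}

#' Sample a random augmentation policy
#'
#' Draws `N` distinct transforms uniformly without replacement from the
#' 11-transform registry and an independent uniform magnitude in 1..10 for
#' each (magnitudes are sampled per operation, not once per policy).
#'
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param N number of operations, 0 <= N <= 11; the working default is 2.
#' @return An `aug_policy`: list with `ops` (data.frame: name, magnitude)
#'   and `N`.
#' @export
sample_policy <- function(seed = NULL, N = 2) {
  if (N > length(aug_registry()) || N < 0)
    stop(sprintf("N must be between 0 and %d", length(aug_registry())),
         call. = FALSE)
  with_seed(seed, {
    nm <- if (N > 0) sample(aug_registry(), N) else character(0)
    mg <- if (N > 0) sample(1:10, N, replace = TRUE) else integer(0)
    structure(list(ops = data.frame(name = nm, magnitude = mg,
                                    stringsAsFactors = FALSE),
                   N = as.integer(N)),
              class = "aug_policy")
  })
}

#' @export
print.aug_policy <- function(x, ...) {
  cat(sprintf("aug_policy with %d op(s):\n", x$N))
  if (x$N > 0)
    cat(sprintf("  %s (M = %d)\n", x$ops$name, x$ops$magnitude), sep = "")
  invisible(x)
}

# Inverse-mapped affine warp: output pixel (r, c) takes the input value at
# A %*% (p - centre) + centre + shift. `interp` "nearest" or "bilinear";
# out-of-canvas samples take `fill`.
warp_affine <- function(mat, A, shift = c(0, 0),
                        interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  nr <- nrow(mat); nc <- ncol(mat)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  r <- matrix(seq_len(nr), nr, nc) - cr
  cl <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cc
  sr <- A[1, 1] * r + A[1, 2] * cl + cr + shift[1]
  sc <- A[2, 1] * r + A[2, 2] * cl + cc + shift[2]
  if (interp == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    out <- matrix(fill, nr, nc)
    out[ok] <- mat[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- mat[cbind(ri[ok], ci[ok])]
    v
  }
  (1 - fr) * (1 - fc) * gv(r0, c0) + (1 - fr) * fc * gv(r0, c0 + 1) +
    fr * (1 - fc) * gv(r0 + 1, c0) + fr * fc * gv(r0 + 1, c0 + 1)
}

#' Rotate an image about its centre
#'
#' @param mat numeric matrix.
#' @param angle_deg counter-clockwise rotation in degrees.
#' @param interp `"bilinear"` or `"nearest"`.
#' @param fill value for pixels mapped from outside the canvas.
#' @return The rotated matrix, same dimensions.
#' @export
rotate_image <- function(mat, angle_deg, interp = "bilinear", fill = 0) {
  th <- angle_deg * pi / 180
  A <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  warp_affine(mat, A, interp = interp, fill = fill)
}

translate_image <- function(mat, dr, dc, fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(fill, nr, nc)
  src_r <- seq_len(nr) - dr
  src_c <- seq_len(nc) - dc
  okr <- src_r >= 1 & src_r <= nr
  okc <- src_c >= 1 & src_c <= nc
  out[which(okr), which(okc)] <- mat[src_r[okr], src_c[okc]]
  out
}

hist_equalize <- function(mat, levels = 256) {
  q <- pmin(floor(mat * levels), levels - 1)
  cdf <- cumsum(tabulate(q + 1, nbins = levels)) / length(q)
  matrix(cdf[q + 1], nrow(mat), ncol(mat))
}

# Draw the stochastic parameters (signs, positions) of one op from the
# current RNG stream, then apply it to image and mask.
apply_one_op <- function(image, mask, name, magnitude) {
  if (!name %in% aug_registry())
    stop(sprintf("unregistered transform '%s'", name), call. = FALSE)
  p <- aug_magnitude_map(name, magnitude)
  nr <- nrow(image); nc <- ncol(image)
  geo <- function(f) list(image = f(image, 0), mask = f(mask, 0L))
  switch(name,
    hflip = list(image = image[, nc:1], mask = mask[, nc:1]),
    rotate = {
      ang <- p * sample(c(-1, 1), 1)
      list(image = rotate_image(image, ang, "bilinear"),
           mask = rotate_image(mask, ang, "nearest", fill = 0L))
    },
    translate_x = {
      d <- round(p * nc) * sample(c(-1, 1), 1)
      geo(function(m, f) translate_image(m, 0, d, f))
    },
    translate_y = {
      d <- round(p * nr) * sample(c(-1, 1), 1)
      geo(function(m, f) translate_image(m, d, 0, f))
    },
    shear_x = {
      s <- p * sample(c(-1, 1), 1)
      A <- matrix(c(1, 0, -s, 1), 2, 2, byrow = TRUE)
      list(image = warp_affine(image, A, interp = "bilinear"),
           mask = warp_affine(mask, A, interp = "nearest", fill = 0L))
    },
    crop = {
      mr <- round(p * nr); mc <- round(p * nc)
      zero_border <- function(m, f) {
        out <- m
        if (mr > 0) { out[seq_len(mr), ] <- f; out[nr - seq_len(mr) + 1, ] <- f }
        if (mc > 0) { out[, seq_len(mc)] <- f; out[, nc - seq_len(mc) + 1] <- f }
        out
      }
      geo(zero_border)
    },
    cutout = {
      side <- max(1, round(p * min(nr, nc)))
      r0 <- sample(seq_len(max(1, nr - side + 1)), 1)
      c0 <- sample(seq_len(max(1, nc - side + 1)), 1)
      hole <- function(m, f) {
        m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- f
        m
      }
      geo(hole)
    },
    equalize = list(image = clip01((1 - p) * image + p * hist_equalize(image)),
                    mask = mask),
    contrast = {
      f <- 1 + p * sample(c(-1, 1), 1)
      list(image = clip01(0.5 + f * (image - 0.5)), mask = mask)
    },
    brightness = {
      d <- p * sample(c(-1, 1), 1)
      list(image = clip01(image + d), mask = mask)
    },
    sharpness = {
      blur <- EBImage::imageData(EBImage::gblur(image, sigma = 1.5))
      list(image = clip01(image + p * (image - blur)), mask = mask)
    })
}

#' Apply an augmentation policy to an image/mask pair
#'
#' Operations are applied in policy order. Geometric transforms use identical
#' parameters for image and mask (nearest neighbour on the mask, background
#' fill outside the canvas), photometric transforms leave the mask untouched.
#' Output dimensions are always preserved. Fully deterministic given
#' `(policy, seed)`.
#'
#' @param image grayscale matrix in `[0, 1]`.
#' @param mask 0/1 matrix, same dimensions.
#' @param policy an `aug_policy` from [sample_policy()].
#' @param seed integer seed for the transforms' stochastic parameters
#'   (signs, hole positions), or `NULL`.
#' @return List with the transformed `image` and `mask`.
#' @export
apply_policy <- function(image, mask, policy, seed = NULL) {
  assert_same_dim(image, mask)
  stopifnot(inherits(policy, "aug_policy"), is_binary_mask(mask))
  with_seed(seed, {
    cur <- list(image = image, mask = mask)
    for (i in seq_len(nrow(policy$ops)))
      cur <- apply_one_op(cur$image, cur$mask,
                          policy$ops$name[i], policy$ops$magnitude[i])
    cur$mask <- matrix(as.integer(cur$mask), nrow(mask), ncol(mask))
    cur
  })
}

#' Serialize / deserialize an augmentation policy as JSON
#'
#' @param policy an `aug_policy`.
#' @param path file path; for [read_policy()] the file to read.
#' @return `write_policy` invisibly returns `path`; `read_policy` returns the
#'   `aug_policy`.
#' @export
write_policy <- function(policy, path) {
  jsonlite::write_json(list(N = policy$N, ops = policy$ops), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ops <- as.data.frame(x$ops, stringsAsFactors = FALSE)
  if (nrow(ops) > 0 && !all(ops$name %in% aug_registry()))
    stop("unregistered transform in policy file", call. = FALSE)
  structure(list(ops = ops, N = as.integer(x$N)), class = "aug_policy")
}
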