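# Circle and box representations, annotation normalization, and deterministic
# circle-fitting primitives shared by every refinement stage.
#
# Coordinate convention: 0-based pixel indices, x rightward, y downward
# (image convention). Centers are continuous (sub-pixel) coordinates; the
# pixel at matrix position [i, j] has center (x = j - 1, y = i - 1).

#' Pixel-space circle
#'
#' @param cx,cy Center coordinates in pixels (x rightward, y downward).
#' @param r Radius in pixels, non-negative.
#' @return An object of class `circle`.
#' @export
circle <- function(cx, cy, r) {
  if (!is_scalar_num(cx) || !is_scalar_num(cy) || !is_scalar_num(r)) {
    hw_error("circle parameters must be finite scalars", "parameter")
  }
  if (r < 0) hw_error("circle radius must be non-negative", "parameter")
  structure(list(cx = unname(cx), cy = unname(cy), r = unname(r)),
            class = "circle")
}

#' @export
print.circle <- function(x, ...) {
  cat(sprintf("circle: center (%.3f, %.3f), r = %.3f px\n", x$cx, x$cy, x$r))
  invisible(x)
}

#' Resolution-independent circle annotation
#'
#' Class 0 denotes the femoral head, class 1 the acetabular cup. Coordinates
#' are fractions of image width/height; the radius is a fraction of the mean
#' image dimension (W + H) / 2.
#'
#' @param cls Class id, 0 or 1.
#' @param x,y Normalized center, each in \[0, 1\].
#' @param r Normalized radius, non-negative.
#' @return An object of class `norm_circle`.
#' @export
norm_circle <- function(cls, x, y, r) {
  if (!cls %in% c(0, 1)) hw_error("class id must be 0 (femoral head) or 1 (cup)", "parameter")
  if (x < 0 || x > 1 || y < 0 || y > 1) {
    hw_error("normalized center must lie in [0, 1]", "parameter")
  }
  if (r < 0) hw_error("normalized radius must be non-negative", "parameter")
  structure(list(cls = as.integer(cls), x = x, y = y, r = r), class = "norm_circle")
}

#' Normalized bounding box ("cls x_center y_center width height")
#'
#' @param cls Class id.
#' @param x,y Normalized box center.
#' @param w,h Normalized width and height, non-negative.
#' @return An object of class `norm_box`.
#' @export
norm_box <- function(cls, x, y, w, h) {
  if (x < 0 || x > 1 || y < 0 || y > 1) {
    hw_error("normalized box center must lie in [0, 1]", "parameter")
  }
  if (w < 0 || h < 0) hw_error("box width/height must be non-negative", "parameter")
  structure(list(cls = as.integer(cls), x = x, y = y, w = w, h = h), class = "norm_box")
}

#' Image dimensions
#'
#' @param W,H Width and height in pixels (positive integers).
#' @return An object of class `image_dims`.
#' @export
image_dims <- function(W, H) {
  if (!is_scalar_num(W) || !is_scalar_num(H) || W < 1 || H < 1 ||
      W != round(W) || H != round(H)) {
    hw_error("image dimensions must be positive integers", "invalid_dimension")
  }
  structure(list(W = as.integer(W), H = as.integer(H)), class = "image_dims")
}

#' Dimensions of a grayscale image matrix
#'
#' @param img Numeric matrix, image convention `img[y + 1, x + 1]`.
#' @return An `image_dims` object.
#' @export
dims_of <- function(img) image_dims(ncol(img), nrow(img))

#' Normalize a pixel-space circle
#'
#' Converts a pixel-space circle to the resolution-independent form used by
#' the annotation format: x = cx / W, y = cy / H, r = r_px / ((W + H) / 2).
#'
#' @param c A [circle()].
#' @param dims An [image_dims()].
#' @param cls Class id (0 femoral head, 1 cup).
#' @return A [norm_circle()].
#' @export
normalize_circle <- function(c, dims, cls = 0) {
  stopifnot(inherits(c, "circle"), inherits(dims, "image_dims"))
  norm_circle(
    cls,
    x = c$cx / dims$W,
    y = c$cy / dims$H,
    r = c$r / ((dims$W + dims$H) / 2)
  )
}

#' Map a normalized circle back to pixel space
#'
#' Exact inverse of [normalize_circle()] up to floating precision.
#'
#' @param nc A [norm_circle()].
#' @param dims An [image_dims()].
#' @return A [circle()].
#' @export
denormalize_circle <- function(nc, dims) {
  stopifnot(inherits(nc, "norm_circle"), inherits(dims, "image_dims"))
  circle(
    cx = nc$x * dims$W,
    cy = nc$y * dims$H,
    r = nc$r * ((dims$W + dims$H) / 2)
  )
}

#' Circumscribing box of a normalized circle
#'
#' The box keeps the circle center and has normalized extents
#' w = r (1 + H/W), h = r (1 + W/H), so that in pixel space the box side
#' equals the circle diameter exactly in both axes.
#'
#' @param nc A [norm_circle()].
#' @param dims An [image_dims()].
#' @return A [norm_box()].
#' @export
circle_to_normbox <- function(nc, dims) {
  stopifnot(inherits(nc, "norm_circle"), inherits(dims, "image_dims"))
  W <- dims$W
  H <- dims$H
  norm_box(
    nc$cls,
    x = nc$x,
    y = nc$y,
    w = nc$r * (1 + H / W),
    h = nc$r * (1 + W / H)
  )
}

# Vectorized circumcircles through point triplets, used by RANSAC. Each of
# p1/p2/p3 is an n x 2 matrix of (x, y). Degenerate (collinear/coincident)
# triplets yield NA rows.
circles_from_triplets <- function(p1, p2, p3) {
  x1 <- p1[, 1]; y1 <- p1[, 2]
  x2 <- p2[, 1]; y2 <- p2[, 2]
  x3 <- p3[, 1]; y3 <- p3[, 2]
  # Perpendicular-bisector linear system for the center.
  a1 <- 2 * (x2 - x1); b1 <- 2 * (y2 - y1)
  c1 <- x2^2 - x1^2 + y2^2 - y1^2
  a2 <- 2 * (x3 - x1); b2 <- 2 * (y3 - y1)
  c2 <- x3^2 - x1^2 + y3^2 - y1^2
  det <- a1 * b2 - a2 * b1
  # Degeneracy: triangle area below 1e-9 x squared point spread.
  cross <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  spread2 <- pmax(
    (x2 - x1)^2 + (y2 - y1)^2,
    (x3 - x1)^2 + (y3 - y1)^2,
    (x3 - x2)^2 + (y3 - y2)^2
  )
  bad <- !is.finite(det) | abs(cross) / 2 <= 1e-9 * spread2 | spread2 == 0
  cx <- (c1 * b2 - c2 * b1) / det
  cy <- (a1 * c2 - a2 * c1) / det
  r <- sqrt((x1 - cx)^2 + (y1 - cy)^2)
  cx[bad] <- NA_real_
  cy[bad] <- NA_real_
  r[bad] <- NA_real_
  cbind(cx = cx, cy = cy, r = r)
}

#' Circle through three points
#'
#' @param p1,p2,p3 Numeric length-2 vectors (x, y) in pixels.
#' @return A [circle()] passing through all three points.
#' @export
circle_from_three_points <- function(p1, p2, p3) {
  m <- circles_from_triplets(
    matrix(p1, 1, 2), matrix(p2, 1, 2), matrix(p3, 1, 2)
  )
  if (anyNA(m)) {
    hw_error("points are collinear or coincident; no unique circle", "degenerate_geometry")
  }
  circle(m[1, "cx"], m[1, "cy"], m[1, "r"])
}

#' Algebraic least-squares circle fit
#'
#' Kasa fit: minimizes the algebraic residual
#' sum((x - cx)^2 + (y - cy)^2 - r^2)^2, which is a linear least-squares
#' problem. Exact when the points lie on a circle; deterministic, so suitable
#' as the RANSAC polish step.
#'
#' @param points n x 2 numeric matrix of (x, y) pixel coordinates, n >= 3.
#' @return A [circle()].
#' @export
fit_circle_lsq <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) {
    hw_error("at least 3 points are required to fit a circle", "degenerate_geometry")
  }
  x <- points[, 1]
  y <- points[, 2]
  # Collinearity check via principal axes of the centered cloud.
  xc <- x - mean(x)
  yc <- y - mean(y)
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv[1] == 0 || sv[2] <= 1e-9 * sv[1]) {
    hw_error("points are collinear or coincident; circle fit is degenerate",
             "degenerate_geometry")
  }
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- solve(crossprod(A), crossprod(A, b))
  cx <- sol[1]
  cy <- sol[2]
  r2 <- sol[3] + cx^2 + cy^2
  circle(cx, cy, sqrt(max(r2, 0)))
}
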