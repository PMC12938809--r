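# ROI acquisition: box type, box-to-circle proposals, margin cropping, and
# the ground-truth-jitter oracle provider used as a detector stand-in.
# Any function image -> list of roi_box can serve as an ROI provider, which
# decouples the geometric pipeline from the external detector.

#' Region-of-interest box
#'
#' Half-open pixel box \[x0, x1) x \[y0, y1) in image coordinates.
#'
#' @param x0,y0,x1,y1 Box corners in pixels, x1 > x0 and y1 > y0.
#' @param confidence Detector confidence in \[0, 1\].
#' @param cls Class id (0 femoral head, 1 cup, NA implant-level ROI).
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x0, y0, x1, y1, confidence = 1, cls = NA_integer_) {
  if (!(x1 > x0) || !(y1 > y0)) {
    hw_error("roi box must have positive extent", "geometry")
  }
  if (confidence < 0 || confidence > 1) {
    hw_error("confidence must lie in [0, 1]", "parameter")
  }
  structure(
    list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
         confidence = confidence, cls = cls),
    class = "roi_box"
  )
}

#' Initial circle proposal from an ROI box
#'
#' Uses the box center as circle center and half the average box extent as
#' the initial radius, so that the proposal exactly inverts the
#' circumscribing-box construction (box side = 2 r).
#'
#' @param box A [roi_box()].
#' @return A [circle()].
#' @export
box_to_circle_proposal <- function(box) {
  stopifnot(inherits(box, "roi_box"))
  w <- box$x1 - box$x0
  h <- box$y1 - box$y0
  circle(
    cx = (box$x0 + box$x1) / 2,
    cy = (box$y0 + box$y1) / 2,
    r = (w + h) / 4
  )
}

#' Crop an ROI with a safety margin
#'
#' Expands the box by `margin_frac` of its extent on each side, clips to the
#' image, and returns the subimage together with the integer offset that maps
#' subimage coordinates back to full-image coordinates exactly.
#'
#' @param img Image matrix.
#' @param box A [roi_box()].
#' @param margin_frac Non-negative fractional margin per side.
#' @return List with `image` (matrix) and `offset` (named c(x, y), 0-based).
#' @export
crop_roi <- function(img, box, margin_frac = 0.15) {
  stopifnot(inherits(box, "roi_box"))
  if (margin_frac < 0) hw_error("margin_frac must be >= 0", "parameter")
  W <- ncol(img)
  H <- nrow(img)
  w <- box$x1 - box$x0
  h <- box$y1 - box$y0
  x0 <- floor(max(0, box$x0 - margin_frac * w))
  y0 <- floor(max(0, box$y0 - margin_frac * h))
  x1 <- ceiling(min(W, box$x1 + margin_frac * w))
  y1 <- ceiling(min(H, box$y1 + margin_frac * h))
  if (x1 <= 0 || y1 <= 0 || x0 >= W || y0 >= H || x1 <= x0 || y1 <= y0) {
    hw_error("roi box lies outside the image", "out_of_bounds")
  }
  list(
    image = img[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE],
    offset = c(x = x0, y = y0)
  )
}

#' Oracle ROI provider from ground-truth circles
#'
#' Test double for an external detector: emits the circumscribing boxes of
#' ground-truth circles, optionally perturbed by uniform relative jitter on
#' center and size. Reproducible for a fixed seed.
#'
#' @param truth List of [norm_circle()] annotations.
#' @param dims An [image_dims()].
#' @param jitter Non-negative relative jitter amplitude (fraction of the box
#'   extent for the center shift; fraction of 1 for the size scale).
#' @param seed Integer seed; NULL leaves the RNG stream untouched.
#' @return List of [roi_box()], one per truth circle, clipped to the image.
#' @export
oracle_roi_provider <- function(truth, dims, jitter = 0, seed = NULL) {
  stopifnot(inherits(dims, "image_dims"))
  if (jitter < 0) hw_error("jitter must be >= 0", "parameter")
  make <- function() {
    lapply(truth, function(nc) {
      bx <- circle_to_normbox(nc, dims)
      cx <- bx$x * dims$W
      cy <- bx$y * dims$H
      w <- bx$w * dims$W
      h <- bx$h * dims$H
      if (jitter > 0) {
        cx <- cx + stats::runif(1, -jitter, jitter) * w
        cy <- cy + stats::runif(1, -jitter, jitter) * h
        w <- w * (1 + stats::runif(1, -jitter, jitter))
        h <- h * (1 + stats::runif(1, -jitter, jitter))
      }
      roi_box(
        x0 = max(0, cx - w / 2), y0 = max(0, cy - h / 2),
        x1 = min(dims$W, cx + w / 2), y1 = min(dims$H, cy + h / 2),
        confidence = 1, cls = nc$cls
      )
    })
  }
  if (is.null(seed)) make() else with_seed(seed, make())
}

#' Read detector output boxes
#'
#' Parses the ingestion format "cls conf x_center y_center width height"
#' (normalized floats, one box per line) into pixel-space ROI boxes.
#'
#' @param path Text file path.
#' @param dims An [image_dims()].
#' @return List of [roi_box()].
#' @export
read_detections <- function(path, dims) {
  stopifnot(inherits(dims, "image_dims"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != 6 || anyNA(f)) {
      hw_error(sprintf("line %d: expected 6 numeric fields 'cls conf x y w h'", i),
               "parse")
    }
    cx <- f[3] * dims$W
    cy <- f[4] * dims$H
    w <- f[5] * dims$W
    h <- f[6] * dims$H
    roi_box(
      x0 = max(0, cx - w / 2), y0 = max(0, cy - h / 2),
      x1 = min(dims$W, cx + w / 2), y1 = min(dims$H, cy + h / 2),
      confidence = f[2], cls = as.integer(f[1])
    )
  })
}
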