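# Contrast enhancement, adaptive Canny thresholds, and the combined edge
# signal consumed by Edge-Snap, RANSAC harvesting and the Hough fallback.
#
# Images are numeric matrices in [0, 255], image convention img[y + 1, x + 1].

#' Enhance a grayscale radiograph
#'
#' Applies contrast-limited adaptive histogram equalization (CLAHE), an
#' edge-preserving bilateral filter, and optional unsharp masking. A constant
#' image is returned unchanged (no structure is invented).
#'
#' @param img Numeric matrix in \[0, 255\] (single channel).
#' @param clahe_clip CLAHE clip limit.
#' @param clahe_tiles Number of CLAHE tiles per axis.
#' @param bilateral_d Bilateral filter window diameter (odd, pixels).
#' @param bilateral_sigma_color Bilateral range sigma (gray levels).
#' @param bilateral_sigma_space Bilateral spatial sigma (pixels).
#' @param sharpen Apply unsharp masking after filtering.
#' @param unsharp_amount Unsharp gain (1.0 doubles the high-pass residual).
#' @param unsharp_sigma Gaussian sigma of the unsharp low-pass (pixels).
#' @return Enhanced image matrix, same dimensions, values in \[0, 255\].
#' @export
enhance <- function(img, clahe_clip = 2, clahe_tiles = 8,
                    bilateral_d = 9, bilateral_sigma_color = 75,
                    bilateral_sigma_space = 75,
                    sharpen = TRUE, unsharp_amount = 1, unsharp_sigma = 1.5) {
  if (!is.matrix(img)) {
    hw_error("enhance() expects a single-channel image matrix", "channel")
  }
  if (diff(range(img)) == 0) {
    return(img)
  }
  out <- clahe_enhance(img, clip = clahe_clip, tiles = clahe_tiles)
  out <- bilateral_filter(out, d = bilateral_d,
                          sigma_color = bilateral_sigma_color,
                          sigma_space = bilateral_sigma_space)
  if (sharpen && unsharp_amount > 0) {
    low <- EBImage::gblur(out, sigma = unsharp_sigma, boundary = "replicate")
    out <- out + unsharp_amount * (out - low)
  }
  clamp(out, 0, 255)
}

# CLAHE via EBImage; the implementation requires dimensions divisible by the
# tile counts, so the image is border-replicated up to the next multiple and
# cropped back afterwards. EBImage images are (x, y): transpose in and out.
clahe_enhance <- function(img, clip = 2, tiles = 8) {
  H <- nrow(img)
  W <- ncol(img)
  padH <- (tiles - H %% tiles) %% tiles
  padW <- (tiles - W %% tiles) %% tiles
  pad <- img[c(seq_len(H), rep(H, padH)), c(seq_len(W), rep(W, padW)), drop = FALSE]
  eq <- EBImage::clahe(t(pad) / 255, nx = tiles, ny = tiles, limit = clip)
  out <- t(as.matrix(eq))[seq_len(H), seq_len(W), drop = FALSE] * 255
  out
}

# Edge-preserving bilateral filter (range + spatial Gaussian weights),
# vectorized over window offsets.
bilateral_filter <- function(img, d = 9, sigma_color = 75, sigma_space = 75) {
  rad <- floor(d / 2)
  if (rad < 1) return(img)
  num <- matrix(0, nrow(img), ncol(img))
  den <- matrix(0, nrow(img), ncol(img))
  inv2sc <- 1 / (2 * sigma_color^2)
  inv2ss <- 1 / (2 * sigma_space^2)
  for (dy in -rad:rad) {
    for (dx in -rad:rad) {
      sw <- exp(-(dy * dy + dx * dx) * inv2ss)
      nb <- nbr(img, dy, dx)
      w <- sw * exp(-(nb - img)^2 * inv2sc)
      num <- num + w * nb
      den <- den + w
    }
  }
  num / den
}

#' Adaptive Canny thresholds from the median gray level
#'
#' With v the median intensity and sigma the fractional band (default 0.33),
#' the hysteresis thresholds are t_low = max(0, (1 - sigma) v) and
#' t_high = min(255, (1 + sigma) v). Depends on the intensity distribution
#' only through the median, so it is invariant to pixel permutation.
#'
#' @param img Numeric image matrix in \[0, 255\].
#' @param sigma Fractional threshold band in (0, 1).
#' @return An object of class `canny_params` with fields v, sigma, t_low, t_high.
#' @export
adaptive_canny_thresholds <- function(img, sigma = 0.33) {
  if (length(img) == 0) hw_error("empty image", "empty_input")
  if (!is_scalar_num(sigma) || sigma <= 0 || sigma >= 1) {
    hw_error("sigma must lie in (0, 1)", "parameter")
  }
  v <- stats::median(img)
  structure(
    list(
      v = v,
      sigma = sigma,
      t_low = max(0, (1 - sigma) * v),
      t_high = min(255, (1 + sigma) * v)
    ),
    class = "canny_params"
  )
}

# Full Canny chain on an image matrix: Gaussian smoothing, Sobel gradients,
# non-maximum suppression along the quantized gradient direction, and
# hysteresis linking. Returns edges (logical), grad_mag, grad_dir.
canny_edges <- function(img, t_low, t_high, gauss_sigma = 1.2) {
  g <- if (gauss_sigma > 0) {
    EBImage::gblur(img, sigma = gauss_sigma, boundary = "replicate")
  } else {
    img
  }
  gx <- (nbr(g, -1, 1) + 2 * nbr(g, 0, 1) + nbr(g, 1, 1)) -
    (nbr(g, -1, -1) + 2 * nbr(g, 0, -1) + nbr(g, 1, -1))
  gy <- (nbr(g, 1, -1) + 2 * nbr(g, 1, 0) + nbr(g, 1, 1)) -
    (nbr(g, -1, -1) + 2 * nbr(g, -1, 0) + nbr(g, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  dir <- atan2(gy, gx)

  # Non-maximum suppression: compare against the two neighbours along the
  # gradient direction, quantized to 4 sectors.
  sector <- (round(dir / (pi / 4))) %% 4
  nms <- matrix(0, nrow(img), ncol(img))
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1)) # (dy, dx) per sector
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- nbr(mag, o[1], o[2])
    n2 <- nbr(mag, -o[1], -o[2])
    keep <- sector == s & mag >= n1 & mag >= n2
    nms[keep] <- mag[keep]
  }

  strong <- nms >= t_high & nms > 0
  weak <- nms >= t_low & nms > 0
  edges <- hysteresis_link(weak, strong)
  list(edges = edges, grad_mag = mag, grad_dir = dir)
}

# Keep weak pixels connected (8-connectivity) to a strong pixel. bwlabel is
# 4-connected, so components are taken on the 3x3-dilated weak mask: two
# 8-adjacent weak pixels always share a dilated pixel. (This also links weak
# chains separated by a single background pixel, a harmless over-merge for
# edge validation purposes.)
hysteresis_link <- function(weak, strong) {
  if (!any(strong)) {
    return(matrix(FALSE, nrow(weak), ncol(weak)))
  }
  dil <- weak
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy != 0 || dx != 0) dil <- dil | nbr(weak, dy, dx)
    }
  }
  lab <- EBImage::bwlabel(dil * 1)
  keep_ids <- unique(lab[strong])
  keep_ids <- keep_ids[keep_ids > 0]
  weak & matrix(lab %in% keep_ids, nrow(weak), ncol(weak))
}

#' Combined edge signal over an ROI
#'
#' Builds the per-pixel response used by all refinement stages:
#' `combined = w_canny * edges + w_grad * grad_mag / max(grad_mag)`,
#' together with the binary Canny mask, gradient magnitude and gradient
#' direction.
#'
#' @param img Numeric image matrix in \[0, 255\] (typically [enhance()]d).
#' @param params A `canny_params` object from [adaptive_canny_thresholds()].
#' @param weights Length-2 numeric: (w_canny, w_grad).
#' @param gauss_sigma Gaussian smoothing sigma for the gradient operator.
#' @return An object of class `edge_map` with fields edges, grad_mag,
#'   grad_dir, combined, W, H, params.
#' @export
edge_signal <- function(img, params = adaptive_canny_thresholds(img),
                        weights = c(0.5, 0.5), gauss_sigma = 1.2) {
  if (length(weights) != 2 || any(!is.finite(weights))) {
    hw_error("edge weights must be two finite numbers", "parameter")
  }
  cn <- canny_edges(img, params$t_low, params$t_high, gauss_sigma = gauss_sigma)
  mmax <- max(cn$grad_mag)
  norm_mag <- if (mmax > 0) cn$grad_mag / mmax else cn$grad_mag * 0
  combined <- weights[1] * (cn$edges * 1) + weights[2] * norm_mag
  structure(
    list(
      edges = cn$edges,
      grad_mag = cn$grad_mag,
      grad_dir = cn$grad_dir,
      combined = combined,
      W = ncol(img),
      H = nrow(img),
      params = params
    ),
    class = "edge_map"
  )
}

# Canny edge pixels of an edge map as a table of 0-based coordinates with
# their combined response and gradient direction.
edge_points <- function(em) {
  idx <- which(em$edges)
  if (length(idx) == 0) {
    return(list(
      x = numeric(0), y = numeric(0),
      response = numeric(0), dir = numeric(0)
    ))
  }
  i <- ((idx - 1) %% em$H) + 1
  j <- ((idx - 1) %/% em$H) + 1
  list(
    x = j - 1,
    y = i - 1,
    response = em$combined[idx],
    dir = em$grad_dir[idx]
  )
}
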