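# Edge-driven circle refinement: radial Edge-Snap, RANSAC fitting, circular
# Hough fallback, cup candidate search with composite scoring, anatomical
# filtering, and the fit_prosthesis orchestrator.

#' Edge-Snap configuration
#'
#' @param n_angles Number of radial directions sampled (>= 8).
#' @param annulus_frac Half-width of the radial search band as a fraction of
#'   the current radius, in (0, 1).
#' @param min_support_frac Minimum fraction of angles whose peak response
#'   must exceed the noise floor for the snap to be accepted.
#' @param noise_floor Combined-response level below which a radial peak is
#'   treated as noise (the default assumes edge weights summing to 1).
#' @param r_step Radial sampling step in pixels.
#' @return An object of class `edge_snap_config`.
#' @export
edge_snap_config <- function(n_angles = 360, annulus_frac = 0.2,
                             min_support_frac = 0.1, noise_floor = 0.3,
                             r_step = 0.25) {
  if (n_angles < 8) hw_error("n_angles must be >= 8", "parameter")
  if (annulus_frac <= 0 || annulus_frac >= 1) {
    hw_error("annulus_frac must lie in (0, 1)", "parameter")
  }
  structure(
    list(n_angles = as.integer(n_angles), annulus_frac = annulus_frac,
         min_support_frac = min_support_frac, noise_floor = noise_floor,
         r_step = r_step),
    class = "edge_snap_config"
  )
}

#' RANSAC configuration
#'
#' @param n_iter Number of triplet hypotheses (all triplets are enumerated
#'   instead when there are fewer than n_iter of them, which makes small
#'   instances exactly equivalent to exhaustive search).
#' @param inlier_tol Inlier band: a point is an inlier when its distance to
#'   the circle, |dist(point, center) - r|, is at most this many pixels.
#' @param ring_frac Ring half-width for point harvesting, as a fraction of r.
#' @param seed Integer RNG seed for triplet sampling.
#' @return An object of class `ransac_config`.
#' @export
ransac_config <- function(n_iter = 500, inlier_tol = 2, ring_frac = 0.15,
                          seed = 42) {
  if (n_iter < 1) hw_error("n_iter must be >= 1", "parameter")
  if (inlier_tol <= 0) hw_error("inlier_tol must be > 0", "parameter")
  structure(
    list(n_iter = as.integer(n_iter), inlier_tol = inlier_tol,
         ring_frac = ring_frac, seed = seed),
    class = "ransac_config"
  )
}

#' Radial Edge-Snap refinement
#'
#' Samples the combined edge signal along `n_angles` rays from the circle
#' center within an annulus of half-width `annulus_frac * r` around the
#' current radius, takes the per-angle radius of maximal response, and pools
#' the supported angles with a robust weighted median (weights = peak
#' responses, radius ties resolved downward). The center is unchanged; center
#' refinement is delegated to RANSAC or the candidate grid.
#'
#' @param em An `edge_map` from [edge_signal()].
#' @param c0 Initial [circle()] in edge-map coordinates.
#' @param cfg An [edge_snap_config()].
#' @return List with `circle` (snapped) and `support` (fraction of angles
#'   whose peak exceeds the noise floor). When support is below
#'   `min_support_frac` the input radius is kept.
#' @export
edge_snap <- function(em, c0, cfg = edge_snap_config()) {
  stopifnot(inherits(em, "edge_map"), inherits(c0, "circle"))
  r0 <- c0$r
  radii <- seq(max(1, r0 * (1 - cfg$annulus_frac)),
               r0 * (1 + cfg$annulus_frac),
               by = cfg$r_step)
  if (length(radii) < 2) radii <- c(max(0.5, r0 - 1), r0, r0 + 1)
  ang <- seq(0, 2 * pi, length.out = cfg$n_angles + 1)[-(cfg$n_angles + 1)]
  X <- c0$cx + outer(cos(ang), radii)
  Y <- c0$cy + outer(sin(ang), radii)
  vals <- matrix(bilinear_sample(em$combined, as.vector(X), as.vector(Y), fill = NA),
                 nrow = length(ang))
  if (all(is.na(vals))) {
    hw_error("circle annulus lies fully outside the edge map", "out_of_bounds")
  }
  vals[is.na(vals)] <- 0
  peak_idx <- max.col(vals, ties.method = "first") # first = lowest radius on ties
  peak_val <- vals[cbind(seq_along(ang), peak_idx)]
  supported <- peak_val >= cfg$noise_floor
  support <- mean(supported)
  if (support < cfg$min_support_frac) {
    return(list(circle = c0, support = support))
  }
  r_new <- weighted_median_low(radii[peak_idx[supported]], peak_val[supported])
  list(circle = circle(c0$cx, c0$cy, r_new), support = support)
}

#' Harvest high-response edge points in a thin ring
#'
#' Returns Canny edge pixels whose combined response exceeds the given
#' quantile (taken over all edge pixels of the map) and whose radial distance
#' from the circle lies within `ring_frac * r`.
#'
#' @param em An `edge_map`.
#' @param c A [circle()].
#' @param ring_frac Ring half-width as a fraction of the radius.
#' @param response_quantile Quantile of edge-pixel responses in \[0, 1\].
#' @return n x 2 matrix of (x, y) pixel coordinates (possibly 0 rows).
#' @export
harvest_ring_points <- function(em, c, ring_frac = 0.15,
                                response_quantile = 0.5) {
  stopifnot(inherits(em, "edge_map"), inherits(c, "circle"))
  ep <- edge_points(em)
  if (length(ep$x) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("x", "y"))))
  }
  thr <- stats::quantile(ep$response, response_quantile, names = FALSE)
  d <- sqrt((ep$x - c$cx)^2 + (ep$y - c$cy)^2)
  keep <- ep$response >= thr & abs(d - c$r) <= ring_frac * c$r
  cbind(x = ep$x[keep], y = ep$y[keep])
}

#' RANSAC circle fitting
#'
#' Hypothesizes circles from random point triplets, scores them by inlier
#' count (ties broken by lower mean inlier residual), and polishes the winner
#' with an algebraic least-squares fit on its inliers. When the number of
#' distinct triplets does not exceed `n_iter`, all triplets are enumerated,
#' making the search exhaustive and deterministic.
#'
#' @param points n x 2 matrix of (x, y) points, n >= 3.
#' @param cfg A [ransac_config()].
#' @return List with `circle`, `inlier_count`, `inlier_fraction` (both
#'   evaluated for the final polished circle).
#' @export
ransac_circle <- function(points, cfg = ransac_config()) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) hw_error("RANSAC needs at least 3 points", "insufficient_data")
  n_tripl <- choose(n, 3)
  if (n_tripl <= cfg$n_iter) {
    idx <- t(utils::combn(n, 3))
  } else {
    idx <- with_seed(cfg$seed, {
      matrix(replicate(cfg$n_iter, sample.int(n, 3)), ncol = 3, byrow = TRUE)
    })
  }
  hyp <- circles_from_triplets(points[idx[, 1], , drop = FALSE],
                               points[idx[, 2], , drop = FALSE],
                               points[idx[, 3], , drop = FALSE])
  ok <- which(!is.na(hyp[, 1]))
  if (length(ok) == 0) {
    hw_error("all sampled triplets are degenerate", "degenerate_geometry")
  }
  px <- points[, 1]
  py <- points[, 2]
  best <- NULL
  best_count <- -1L
  best_resid <- Inf
  for (k in ok) {
    resid <- abs(sqrt((px - hyp[k, 1])^2 + (py - hyp[k, 2])^2) - hyp[k, 3])
    inl <- resid <= cfg$inlier_tol
    cnt <- sum(inl)
    if (cnt > best_count ||
        (cnt == best_count && cnt > 0 && mean(resid[inl]) < best_resid)) {
      best_count <- cnt
      best_resid <- if (cnt > 0) mean(resid[inl]) else Inf
      best <- list(hyp = hyp[k, ], inliers = inl)
    }
  }
  final <- if (best_count >= 3) {
    tryCatch(
      fit_circle_lsq(points[best$inliers, , drop = FALSE]),
      hipwear_degenerate_geometry = function(e) {
        circle(best$hyp[1], best$hyp[2], best$hyp[3])
      }
    )
  } else {
    circle(best$hyp[1], best$hyp[2], best$hyp[3])
  }
  resid <- abs(sqrt((px - final$cx)^2 + (py - final$cy)^2) - final$r)
  cnt <- sum(resid <= cfg$inlier_tol)
  list(circle = final, inlier_count = cnt, inlier_fraction = cnt / n)
}

#' Circular Hough transform with gradient-direction voting
#'
#' Each Canny edge pixel casts two votes per radius, at the two candidate
#' centers along its gradient direction (the rim polarity is unknown, so both
#' rays are used). The accumulator is argmax-searched per radius and peaks
#' are returned after non-maximum suppression in (center, radius) space.
#'
#' @param em An `edge_map`.
#' @param r_min,r_max Radius search range in pixels, r_min < r_max.
#' @param r_step Radius bin width in pixels.
#' @param n_peaks Maximum number of peaks returned.
#' @param min_frac Candidate cells must score at least this fraction of the
#'   global accumulator maximum.
#' @return List of `list(circle, score)` sorted by score descending; empty
#'   when the edge map has no edge pixels.
#' @export
hough_circles <- function(em, r_min, r_max, r_step = 1, n_peaks = 5,
                          min_frac = 0.4) {
  stopifnot(inherits(em, "edge_map"))
  if (!(r_min < r_max)) hw_error("r_min must be < r_max", "parameter")
  ep <- edge_points(em)
  if (length(ep$x) == 0) return(list())
  radii <- seq(r_min, r_max, by = r_step)
  W <- em$W
  H <- em$H
  cand <- list()
  gmax <- 0
  cosd <- cos(ep$dir)
  sind <- sin(ep$dir)
  for (r in radii) {
    cx <- round(c(ep$x + r * cosd, ep$x - r * cosd))
    cy <- round(c(ep$y + r * sind, ep$y - r * sind))
    keep <- cx >= 0 & cx < W & cy >= 0 & cy < H
    if (!any(keep)) next
    lin <- cy[keep] * W + cx[keep] + 1
    votes <- tabulate(lin, nbins = W * H)
    vmax <- max(votes)
    if (vmax == 0) next
    gmax <- max(gmax, vmax)
    cells <- which(votes >= vmax * 0.6)
    cand[[length(cand) + 1]] <- data.frame(
      cx = (cells - 1) %% W,
      cy = (cells - 1) %/% W,
      r = r,
      score = votes[cells]
    )
  }
  if (length(cand) == 0) return(list())
  cand <- do.call(rbind, cand)
  cand <- cand[cand$score >= gmax * min_frac, , drop = FALSE]
  # Deterministic ordering: score desc, then radius, y, x ascending.
  cand <- cand[order(-cand$score, cand$r, cand$cy, cand$cx), , drop = FALSE]
  picked <- list()
  for (i in seq_len(nrow(cand))) {
    ci <- cand[i, ]
    dup <- FALSE
    for (p in picked) {
      dc <- sqrt((p$circle$cx - ci$cx)^2 + (p$circle$cy - ci$cy)^2)
      rm_ <- min(p$circle$r, ci$r)
      if (dc < max(3, 0.2 * rm_) && abs(p$circle$r - ci$r) <= max(2, 0.1 * rm_)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      picked[[length(picked) + 1]] <-
        list(circle = circle(ci$cx, ci$cy, ci$r), score = ci$score)
      if (length(picked) >= n_peaks) break
    }
  }
  picked
}

#' Cup candidate grid
#'
#' Deterministic grid of center shifts (within `shift_frac * r` per axis) and
#' radius scales around an initial cup proposal. With `n_shifts = 1` and
#' `n_scales = 1` the grid is the proposal itself; with odd `n_shifts` and a
#' scale grid containing 1 the proposal is always a member.
#'
#' @param c0 Initial cup [circle()].
#' @param n_shifts Shift positions per axis (total n_shifts^2 centers).
#' @param shift_frac Maximum center shift as a fraction of r.
#' @param scale_range Length-2 numeric (low, high), 0 < low < high.
#' @param n_scales Number of radius scales.
#' @return List of [circle()] of length n_shifts^2 * n_scales.
#' @export
generate_cup_candidates <- function(c0, n_shifts = 5, shift_frac = 0.08,
                                    scale_range = c(0.85, 1.15), n_scales = 7) {
  stopifnot(inherits(c0, "circle"))
  if (scale_range[1] <= 0 || scale_range[1] >= scale_range[2]) {
    hw_error("scale_range must satisfy 0 < low < high", "parameter")
  }
  shifts <- if (n_shifts == 1) 0 else {
    seq(-shift_frac * c0$r, shift_frac * c0$r, length.out = n_shifts)
  }
  scales <- if (n_scales == 1) 1 else {
    seq(scale_range[1], scale_range[2], length.out = n_scales)
  }
  out <- vector("list", length(shifts)^2 * length(scales))
  k <- 0
  for (dx in shifts) {
    for (dy in shifts) {
      for (s in scales) {
        k <- k + 1
        out[[k]] <- circle(c0$cx + dx, c0$cy + dy, c0$r * s)
      }
    }
  }
  out
}

#' Composite cup-candidate score
#'
#' Six image-driven criteria, each in \[0, 1\] (the longest-arc component is
#' reported in radians and normalized by 2 pi inside the total):
#' edge support (sharpness of the edge evidence at the fitted radius),
#' angular coverage, longest contiguous supporting arc, alignment between the
#' local gradient and the circle normal (polarity-aware: a bright implant
#' interior puts the gradient anti-parallel to the outward normal at the true
#' contour), proximity of the center to the ROI center, and the fraction of
#' supporting points lying outside the femoral-head circle. The total is the
#' weighted mean with weights normalized to sum 1.
#'
#' @param cand Candidate [circle()].
#' @param em An `edge_map`.
#' @param femoral Femoral-head [circle()] (for the outside fraction).
#' @param roi_center Length-2 numeric (x, y): ROI center in map coordinates.
#' @param weights Six non-negative weights, sum > 0.
#' @param n_bins Angular bins for coverage/arc statistics.
#' @return An object of class `candidate_score`.
#' @export
score_cup_candidate <- function(cand, em, femoral, roi_center,
                                weights = rep(1, 6) / 6, n_bins = 72) {
  stopifnot(inherits(cand, "circle"), inherits(em, "edge_map"))
  if (length(weights) != 6 || any(weights < 0) || sum(weights) <= 0) {
    hw_error("weights must be 6 non-negative numbers with positive sum", "parameter")
  }
  w <- weights / sum(weights)
  ep <- edge_points(em)
  tol <- max(2, 0.02 * cand$r)
  wide <- max(3 * tol, 0.08 * cand$r)

  edge_support <- 0
  coverage <- 0
  arc <- 0
  alignment <- 0
  outside <- 0
  if (length(ep$x) > 0) {
    d <- sqrt((ep$x - cand$cx)^2 + (ep$y - cand$cy)^2)
    near <- abs(d - cand$r) <= wide
    supp <- abs(d - cand$r) <= tol
    if (any(near)) edge_support <- sum(supp) / sum(near)
    if (any(supp)) {
      phi <- atan2(ep$y[supp] - cand$cy, ep$x[supp] - cand$cx)
      bins <- floor((phi + pi) / (2 * pi) * n_bins) %% n_bins
      occupied <- tabulate(bins + 1, nbins = n_bins) > 0
      coverage <- mean(occupied)
      arc <- longest_circular_run(occupied) * 2 * pi / n_bins
      # Polarity-aware alignment: the implant is brighter than its
      # surroundings, so at the true contour the intensity gradient points
      # inward (anti-parallel to the outward normal). This separates the
      # outer cup-rim boundary from the inner liner boundary, whose gradient
      # points outward.
      alignment <- mean(pmax(0, -cos(ep$dir[supp] - phi)))
      if (!is.null(femoral)) {
        df <- sqrt((ep$x[supp] - femoral$cx)^2 + (ep$y[supp] - femoral$cy)^2)
        outside <- mean(df > femoral$r)
      } else {
        outside <- 1
      }
    }
  }
  dc <- sqrt((cand$cx - roi_center[1])^2 + (cand$cy - roi_center[2])^2)
  proximity <- max(0, 1 - dc / (0.5 * sqrt(em$W^2 + em$H^2)))
  comps <- c(edge_support, coverage, arc / (2 * pi), alignment, proximity, outside)
  structure(
    list(
      edge_support = edge_support,
      angular_coverage = coverage,
      longest_arc = arc,
      gradient_alignment = alignment,
      center_proximity = proximity,
      outside_fraction = outside,
      total = sum(w * comps)
    ),
    class = "candidate_score"
  )
}

# Longest circular run of TRUE in a logical vector.
longest_circular_run <- function(b) {
  n <- length(b)
  if (all(b)) return(n)
  if (!any(b)) return(0L)
  r <- rle(c(b, b))
  max(r$lengths[r$values])
}

#' Anatomical plausibility filter for a femoral-head/cup pair
#'
#' A pair passes when the cup radius strictly exceeds the femoral radius, the
#' head sits strictly inside the cup with at least `min_gap` pixels of
#' joint-space clearance (cup.r - femoral.r - center distance >= min_gap),
#' the cup center lies within the ROI, and the Canny edge density in a thin
#' ring band around each circle reaches `min_edge_density`.
#'
#' @param femoral,cup [circle()] objects in edge-map coordinates.
#' @param em An `edge_map`.
#' @param min_gap Minimum joint-space gap in pixels.
#' @param min_edge_density Minimum ring-band edge density in \[0, 1\].
#' @param roi Optional [roi_box()] in the same coordinates.
#' @return List with `pass` (logical) and `reasons` (character, every
#'   violated rule).
#' @export
anatomical_filter <- function(femoral, cup, em, min_gap = 1,
                              min_edge_density = 0.1, roi = NULL) {
  reasons <- character(0)
  if (!(cup$r > femoral$r)) {
    reasons <- c(reasons, "radius ordering: cup radius must exceed femoral radius")
  }
  dc <- sqrt((cup$cx - femoral$cx)^2 + (cup$cy - femoral$cy)^2)
  if (!(cup$r - femoral$r - dc >= min_gap)) {
    reasons <- c(reasons, "joint-space gap: head must sit inside the cup with a positive gap")
  }
  if (!is.null(roi)) {
    if (cup$cx < roi$x0 || cup$cx >= roi$x1 || cup$cy < roi$y0 || cup$cy >= roi$y1) {
      reasons <- c(reasons, "cup center outside ROI")
    }
  }
  for (nm in c("femoral", "cup")) {
    cc <- if (nm == "femoral") femoral else cup
    if (ring_edge_density(em, cc) < min_edge_density) {
      reasons <- c(reasons, sprintf("edge density: %s ring support below threshold", nm))
    }
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

# Fraction of angular positions with a Canny edge pixel within +/- band px of
# the circle radius (nearest-pixel lookup).
ring_edge_density <- function(em, c, n_angles = 180, band = 2) {
  ang <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  radii <- seq(max(0, c$r - band), c$r + band, by = 1)
  hit <- rep(FALSE, n_angles)
  edge_num <- em$edges * 1
  for (r in radii) {
    x <- round(c$cx + r * cos(ang))
    y <- round(c$cy + r * sin(ang))
    ok <- x >= 0 & x < em$W & y >= 0 & y < em$H
    v <- rep(0, n_angles)
    v[ok] <- edge_num[cbind(y[ok] + 1, x[ok] + 1)]
    hit <- hit | (v > 0)
  }
  mean(hit)
}

# Shift a circle between crop and full-image coordinates.
shift_circle <- function(c, dx, dy) circle(c$cx + dx, c$cy + dy, c$r)

#' Fit femoral-head and cup circles in a radiograph
#'
#' End-to-end refinement: the femoral head is obtained by Edge-Snap followed
#' by ring-point harvesting and RANSAC; the cup by a candidate grid around
#' its proposal, per-candidate Edge-Snap (optionally RANSAC-polished),
#' composite scoring and anatomical filtering. When the best cup score falls
#' below the fallback threshold, a circular Hough transform is run on an
#' edge map recomputed with relaxed Canny thresholds, and its candidates are
#' re-scored under the same criteria; a Hough candidate replaces the
#' incumbent only when strictly higher-scoring.
#'
#' @param img Grayscale image matrix in \[0, 255\].
#' @param rois List of [roi_box()]: either per-class boxes (cls 0 and 1) or a
#'   single implant-level ROI.
#' @param config A [hip_config()] list.
#' @return An object of class `prosthesis_fit` with fields `femoral`, `cup`
#'   (full-image coordinates), `femoral_score`, `cup_score`, `method`
#'   ("ransac" or "hough_fallback"), `support` (per-circle Edge-Snap
#'   support), and `diagnostics`.
#' @export
fit_prosthesis <- function(img, rois, config = hip_config()) {
  if (length(rois) == 0) hw_error("at least one ROI is required", "input")
  diag <- list()
  note <- function(...) diag[[length(diag) + 1]] <<- sprintf(...)

  cls_of <- vapply(rois, function(b) as.integer(b$cls %||% NA_integer_), 1L)
  fem_box <- rois[which(cls_of == 0L)][1][[1]]
  cup_box <- rois[which(cls_of == 1L)][1][[1]]
  if (is.null(fem_box) || is.null(cup_box)) {
    # Single implant-level ROI: cup proposal from the box, femoral from the
    # typical head/cup radius ratio.
    impl <- rois[[1]]
    cup0_full <- box_to_circle_proposal(impl)
    fem0_full <- circle(cup0_full$cx, cup0_full$cy, cup0_full$r / 1.7)
    union_box <- impl
    note("single implant-level ROI; femoral proposal at r = cup/1.7")
  } else {
    fem0_full <- box_to_circle_proposal(fem_box)
    cup0_full <- box_to_circle_proposal(cup_box)
    union_box <- roi_box(
      min(fem_box$x0, cup_box$x0), min(fem_box$y0, cup_box$y0),
      max(fem_box$x1, cup_box$x1), max(fem_box$y1, cup_box$y1),
      confidence = 1, cls = NA_integer_
    )
  }

  cr <- crop_roi(img, union_box, margin_frac = config$roi$margin_frac)
  ox <- cr$offset["x"]
  oy <- cr$offset["y"]
  enh <- enhance(
    cr$image,
    clahe_clip = config$preprocess$clahe_clip,
    clahe_tiles = config$preprocess$clahe_tiles,
    bilateral_d = config$preprocess$bilateral_d,
    bilateral_sigma_color = config$preprocess$bilateral_sigma_color,
    bilateral_sigma_space = config$preprocess$bilateral_sigma_space,
    sharpen = config$preprocess$sharpen,
    unsharp_amount = config$preprocess$unsharp_amount,
    unsharp_sigma = config$preprocess$unsharp_sigma
  )
  params <- adaptive_canny_thresholds(enh, sigma = config$preprocess$canny_sigma)
  em <- edge_signal(enh, params, weights = config$preprocess$edge_weights,
                    gauss_sigma = config$preprocess$canny_gauss_sigma)
  note("ROI crop %dx%d at offset (%d, %d); Canny thresholds (%.1f, %.1f)",
       em$W, em$H, ox, oy, params$t_low, params$t_high)

  fem0 <- shift_circle(fem0_full, -ox, -oy)
  cup0 <- shift_circle(cup0_full, -ox, -oy)
  rcfg <- config$refine
  snap_cfg <- do.call(edge_snap_config, rcfg$edge_snap)

  # --- femoral head: snap -> harvest -> RANSAC ---
  fem_snap <- edge_snap(em, fem0, snap_cfg)
  femoral <- fem_snap$circle
  pts <- harvest_ring_points(em, femoral,
                             ring_frac = rcfg$ransac$ring_frac,
                             response_quantile = rcfg$ransac$response_quantile)
  note("femoral: snap r %.2f -> %.2f (support %.2f), %d ring points",
       fem0$r, femoral$r, fem_snap$support, nrow(pts))
  if (nrow(pts) >= 3) {
    rr <- tryCatch(
      ransac_circle(pts, ransac_config(n_iter = rcfg$ransac$n_iter,
                                       inlier_tol = rcfg$ransac$inlier_tol,
                                       seed = rcfg$seed)),
      hipwear_error = function(e) NULL
    )
    if (!is.null(rr) &&
        abs(rr$circle$r - femoral$r) <= rcfg$cup$radius_jump_frac * femoral$r) {
      femoral <- rr$circle
      note("femoral: RANSAC inliers %d (%.2f)", rr$inlier_count, rr$inlier_fraction)
    } else {
      note("femoral: RANSAC rejected (radius jump or failure); snapped circle kept")
    }
  }

  # --- cup: candidate grid -> snap (-> RANSAC) -> score -> filter ---
  roi_center <- c((union_box$x0 + union_box$x1) / 2 - ox,
                  (union_box$y0 + union_box$y1) / 2 - oy)
  roi_crop <- roi_box(union_box$x0 - ox, union_box$y0 - oy,
                      union_box$x1 - ox, union_box$y1 - oy)
  cup_snap_cfg <- edge_snap_config(
    n_angles = rcfg$cup$snap_n_angles,
    annulus_frac = rcfg$cup$snap_annulus_frac,
    min_support_frac = rcfg$edge_snap$min_support_frac,
    noise_floor = rcfg$edge_snap$noise_floor,
    r_step = rcfg$edge_snap$r_step
  )
  cands <- generate_cup_candidates(cup0,
                                   n_shifts = rcfg$cup$n_shifts,
                                   shift_frac = rcfg$cup$shift_frac,
                                   scale_range = rcfg$cup$scale_range,
                                   n_scales = rcfg$cup$n_scales)
  snapped <- lapply(cands, function(cc) {
    tryCatch(edge_snap(em, cc, cup_snap_cfg)$circle,
             hipwear_out_of_bounds = function(e) NULL)
  })
  snapped <- Filter(Negate(is.null), snapped)
  key <- vapply(snapped, function(cc) {
    sprintf("%.1f_%.1f_%.1f", round(cc$cx * 2) / 2, round(cc$cy * 2) / 2,
            round(cc$r * 2) / 2)
  }, "")
  snapped <- snapped[!duplicated(key)]
  note("cup: %d grid candidates -> %d unique snapped", length(cands), length(snapped))

  eval_candidate <- function(cc, emap) {
    if (rcfg$cup$use_ransac) {
      p <- harvest_ring_points(emap, cc, ring_frac = rcfg$cup$ring_frac,
                               response_quantile = rcfg$cup$response_quantile)
      if (nrow(p) >= 3) {
        rr <- tryCatch(
          ransac_circle(p, ransac_config(n_iter = rcfg$cup$ransac_n_iter,
                                         inlier_tol = rcfg$ransac$inlier_tol,
                                         seed = rcfg$seed)),
          hipwear_error = function(e) NULL
        )
        if (!is.null(rr) &&
            abs(rr$circle$r - cc$r) <= rcfg$cup$radius_jump_frac * cc$r) {
          cc <- rr$circle
        }
      }
    }
    sc <- score_cup_candidate(cc, emap, femoral, roi_center,
                              weights = rcfg$cup$score_weights)
    flt <- anatomical_filter(femoral, cc, emap,
                             min_gap = rcfg$filter$min_gap,
                             min_edge_density = rcfg$filter$min_edge_density,
                             roi = roi_crop)
    list(circle = cc, score = sc, pass = flt$pass, reasons = flt$reasons)
  }

  evals <- lapply(snapped, eval_candidate, emap = em)
  passing <- Filter(function(e) e$pass, evals)
  incumbent <- NULL
  if (length(passing) > 0) {
    totals <- vapply(passing, function(e) e$score$total, 0)
    incumbent <- passing[[which.max(totals)]]
  }
  best_total <- if (is.null(incumbent)) -Inf else incumbent$score$total
  note("cup: %d/%d candidates pass filter; best total %.3f",
       length(passing), length(evals), best_total)

  method <- "ransac"
  final_em <- em
  if (best_total < rcfg$fallback$threshold) {
    # Fallback: sensitized edge map (relaxed thresholds) + Hough voting.
    relax <- rcfg$fallback$relax
    params2 <- params
    params2$t_low <- params$t_low * relax
    params2$t_high <- params$t_high * relax
    em2 <- edge_signal(enh, params2, weights = config$preprocess$edge_weights,
                       gauss_sigma = config$preprocess$canny_gauss_sigma)
    r_lo <- max(femoral$r * 1.1 + rcfg$filter$min_gap, cup0$r * 0.7)
    r_hi <- cup0$r * 1.5
    # Vote only with edge pixels outside the fitted femoral head: the cup rim
    # must surround the head, and the dense head boundary would otherwise
    # flood the accumulator at small radii.
    em2_vote <- em2
    idx <- which(em2$edges)
    if (length(idx) > 0) {
      yy <- ((idx - 1) %% em2$H)
      xx <- ((idx - 1) %/% em2$H)
      inside <- sqrt((xx - femoral$cx)^2 + (yy - femoral$cy)^2) <=
        femoral$r + rcfg$filter$min_gap + 1
      em2_vote$edges[idx[inside]] <- FALSE
    }
    peaks <- if (r_lo < r_hi) {
      hough_circles(em2_vote, r_lo, r_hi, r_step = rcfg$fallback$r_step,
                    n_peaks = rcfg$fallback$n_peaks)
    } else {
      list()
    }
    note("fallback: relaxed thresholds (%.1f, %.1f), %d Hough peaks",
         params2$t_low, params2$t_high, length(peaks))
    hough_evals <- lapply(peaks, function(p) eval_candidate(p$circle, em2))
    hough_pass <- Filter(function(e) e$pass, hough_evals)
    if (length(hough_pass) > 0) {
      h_tot <- vapply(hough_pass, function(e) e$score$total, 0)
      h_best <- hough_pass[[which.max(h_tot)]]
      # Re-score the incumbent on the same sensitized map for a fair
      # strictly-greater comparison.
      inc_total <- if (is.null(incumbent)) -Inf else {
        score_cup_candidate(incumbent$circle, em2, femoral, roi_center,
                            weights = rcfg$cup$score_weights)$total
      }
      if (h_best$score$total > inc_total) {
        incumbent <- h_best
        method <- "hough_fallback"
        final_em <- em2
        note("fallback: Hough candidate adopted (%.3f > %.3f)",
             h_best$score$total, inc_total)
      } else {
        note("fallback: incumbent retained (%.3f >= %.3f)",
             inc_total, h_best$score$total)
      }
    }
  }

  if (is.null(incumbent)) {
    cond <- errorCondition(
      "no circle pair passed the anatomical filter",
      diagnostics = diag,
      class = c("hipwear_no_valid_fit", "hipwear_error", "error", "condition")
    )
    stop(cond)
  }
  cup <- incumbent$circle
  flt <- anatomical_filter(femoral, cup, final_em,
                           min_gap = rcfg$filter$min_gap,
                           min_edge_density = rcfg$filter$min_edge_density,
                           roi = roi_crop)
  if (!flt$pass) {
    cond <- errorCondition(
      paste("final fit fails the anatomical filter:",
            paste(flt$reasons, collapse = "; ")),
      diagnostics = diag,
      class = c("hipwear_no_valid_fit", "hipwear_error", "error", "condition")
    )
    stop(cond)
  }
  fem_score <- score_cup_candidate(femoral, final_em, femoral, roi_center,
                                   weights = rcfg$cup$score_weights)
  structure(
    list(
      femoral = shift_circle(femoral, ox, oy),
      cup = shift_circle(cup, ox, oy),
      femoral_score = fem_score,
      cup_score = incumbent$score,
      method = method,
      support = c(femoral = fem_snap$support),
      diagnostics = diag
    ),
    class = "prosthesis_fit"
  )
}

#' @export
print.prosthesis_fit <- function(x, ...) {
  cat("prosthesis fit (", x$method, ")\n", sep = "")
  cat(sprintf("  femoral: (%.2f, %.2f) r = %.2f  [score %.3f]\n",
              x$femoral$cx, x$femoral$cy, x$femoral$r, x$femoral_score$total))
  cat(sprintf("  cup:     (%.2f, %.2f) r = %.2f  [score %.3f]\n",
              x$cup$cx, x$cup$cy, x$cup$r, x$cup_score$total))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
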