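# Phantom radiograph generator: bright cup rim annulus enclosing a bright
# femoral-head disc with a joint-space gap, plus Gaussian noise, occluding
# arcs and linear "screw" artifacts. The generator defines the test bed
# standing in for clinical data; the edge pipeline consumes edges, not
# calibrated intensities, so no radiographic physics is attempted.

#' Phantom specification
#'
#' Intensity model (gray levels): background; joint-space interior at
#' background + gap_contrast; femoral disc at interior + head_contrast; cup
#' rim annulus (cup.r - rim_width, cup.r\] at background + rim_contrast. With
#' the defaults the outer rim boundary carries the strongest radial step, so
#' the per-angle edge maximum sits at the annotated cup radius.
#'
#' @param dims An [image_dims()].
#' @param femoral,cup [circle()] objects; cup must enclose the head with a
#'   positive joint-space gap beyond the rim width.
#' @param rim_width Cup rim annulus width in pixels.
#' @param rim_contrast Rim brightness above background.
#' @param head_contrast Femoral-disc brightness above the interior.
#' @param gap_contrast Interior brightness above background.
#' @param background_level Background gray level.
#' @param noise_sigma Additive Gaussian noise sigma (gray levels).
#' @param occlusion_arcs List of c(start, end) angle pairs in radians
#'   (measured from the cup center, x-axis = 0, y-down); rim pixels inside
#'   these arcs are deleted.
#' @param n_screw_lines Number of bright line artifacts.
#' @param seed Integer seed for noise and screw placement.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = image_dims(320, 320),
                         femoral = circle(160, 160, 48),
                         cup = circle(160, 158, 82),
                         rim_width = 6,
                         rim_contrast = 125,
                         head_contrast = 90,
                         gap_contrast = 50,
                         background_level = 60,
                         noise_sigma = 4,
                         occlusion_arcs = list(),
                         n_screw_lines = 0,
                         seed = 1) {
  stopifnot(inherits(dims, "image_dims"),
            inherits(femoral, "circle"), inherits(cup, "circle"))
  if (!(cup$r > femoral$r)) hw_error("cup radius must exceed femoral radius", "spec")
  dc <- sqrt((cup$cx - femoral$cx)^2 + (cup$cy - femoral$cy)^2)
  if (!(cup$r - rim_width - femoral$r - dc > 0)) {
    hw_error("cup must enclose the femoral head with a positive gap inside the rim",
             "spec")
  }
  if (rim_contrast < 0 || head_contrast < 0 || gap_contrast < 0) {
    hw_error("contrasts must be non-negative", "spec")
  }
  structure(
    list(dims = dims, femoral = femoral, cup = cup, rim_width = rim_width,
         rim_contrast = rim_contrast, head_contrast = head_contrast,
         gap_contrast = gap_contrast, background_level = background_level,
         noise_sigma = noise_sigma, occlusion_arcs = occlusion_arcs,
         n_screw_lines = n_screw_lines, seed = seed),
    class = "phantom_spec"
  )
}

# Anti-aliased disc coverage: 1 inside, 0 outside, linear ramp across the
# boundary pixel.
disc_coverage <- function(D, r) clamp(r + 0.5 - D, 0, 1)

#' Render a phantom radiograph
#'
#' Deterministic for a fixed spec (noise and screws are seeded). Returns the
#' 8-bit image together with the ground-truth annotations in normalized
#' "cls x y r" form.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric matrix in \[0, 255\]), `truth` (list of
#'   [norm_circle()]: femoral then cup), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- spec$dims$W
  H <- spec$dims$H
  X <- matrix(rep(0:(W - 1), each = H), H, W)
  Y <- matrix(rep(0:(H - 1), times = W), H, W)
  Dfem <- sqrt((X - spec$femoral$cx)^2 + (Y - spec$femoral$cy)^2)
  Dcup <- sqrt((X - spec$cup$cx)^2 + (Y - spec$cup$cy)^2)
  cov_outer <- disc_coverage(Dcup, spec$cup$r)
  cov_inner <- disc_coverage(Dcup, spec$cup$r - spec$rim_width)
  rim_cov <- pmax(cov_outer - cov_inner, 0)
  if (length(spec$occlusion_arcs) > 0) {
    A <- atan2(Y - spec$cup$cy, X - spec$cup$cx)
    occ <- matrix(FALSE, H, W)
    for (arc in spec$occlusion_arcs) {
      a0 <- arc[1]
      a1 <- arc[2]
      # Normalize angles to (-pi, pi] and handle wrap-around arcs.
      if (a1 >= a0) {
        occ <- occ | (A >= a0 & A <= a1)
      } else {
        occ <- occ | (A >= a0 | A <= a1)
      }
    }
    rim_cov[occ] <- 0
  }
  cov_head <- disc_coverage(Dfem, spec$femoral$r)
  img <- spec$background_level +
    spec$gap_contrast * cov_inner +
    spec$rim_contrast * rim_cov +
    spec$head_contrast * cov_head

  out <- with_seed(spec$seed, {
    im <- img
    if (spec$n_screw_lines > 0) {
      for (k in seq_len(spec$n_screw_lines)) {
        p0 <- c(stats::runif(1, 0, W - 1), stats::runif(1, 0, H - 1))
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.2, 0.5) * min(W, H)
        p1 <- p0 + len * c(cos(ang), sin(ang))
        dseg <- segment_distance(X, Y, p0, p1)
        line_cov <- clamp(1.5 - dseg, 0, 1)
        im <- pmax(im, spec$background_level + 185 * line_cov)
      }
    }
    if (spec$noise_sigma > 0) {
      im <- im + matrix(stats::rnorm(W * H, 0, spec$noise_sigma), H, W)
    }
    im
  })
  out <- clamp(out, 0, 255)
  truth <- list(
    normalize_circle(spec$femoral, spec$dims, cls = 0),
    normalize_circle(spec$cup, spec$dims, cls = 1)
  )
  list(image = out, truth = truth, spec = spec)
}

# Distance from every grid point to the segment p0-p1.
segment_distance <- function(X, Y, p0, p1) {
  vx <- p1[1] - p0[1]
  vy <- p1[2] - p0[2]
  L2 <- vx^2 + vy^2
  t <- ((X - p0[1]) * vx + (Y - p0[2]) * vy) / L2
  t <- clamp(t, 0, 1)
  sqrt((X - (p0[1] + t * vx))^2 + (Y - (p0[2] + t * vy))^2)
}

#' Sample a random phantom specification
#'
#' Draws spec parameters uniformly within the given ranges. The defaults
#' emulate the anatomy of a cemented THA on a 320 x 320 crop: head radius
#' 40-58 px, cup/head radius ratio 1.6-1.85 (prosthetic heads of 28-36 mm
#' diameter in 50-58 mm cups), near-concentric centers, moderate noise and
#' at most 60 degrees of rim occlusion.
#'
#' @param ranges Named list overriding any of the default ranges (each a
#'   c(min, max) pair): r_fem, cup_ratio, center_jitter, cup_offset,
#'   rim_width, noise_sigma, occlusion_deg, n_screws.
#' @param dims An [image_dims()].
#' @param seed Integer seed.
#' @return A [phantom_spec()].
#' @export
sample_phantom_spec <- function(ranges = list(), dims = image_dims(320, 320),
                                seed = 1) {
  def <- list(
    r_fem = c(40, 58),
    cup_ratio = c(1.6, 1.85),
    center_jitter = c(-15, 15),
    cup_offset = c(-3, 3),
    rim_width = c(5, 8),
    noise_sigma = c(0, 8),
    occlusion_deg = c(0, 60),
    n_screws = c(0, 2)
  )
  unknown <- setdiff(names(ranges), names(def))
  if (length(unknown) > 0) {
    hw_error(paste("unknown range name(s):", paste(unknown, collapse = ", ")),
             "parameter")
  }
  rg <- utils::modifyList(def, ranges)
  with_seed(seed, {
    u <- function(p) stats::runif(1, p[1], p[2])
    r_fem <- u(rg$r_fem)
    r_cup <- r_fem * u(rg$cup_ratio)
    cx <- dims$W / 2 + u(rg$center_jitter)
    cy <- dims$H / 2 + u(rg$center_jitter)
    occ_deg <- u(rg$occlusion_deg)
    occ_start <- stats::runif(1, -pi, pi)
    arcs <- if (occ_deg > 1) {
      a1 <- occ_start + occ_deg * pi / 180
      if (a1 > pi) list(c(occ_start, a1 - 2 * pi)) else list(c(occ_start, a1))
    } else {
      list()
    }
    phantom_spec(
      dims = dims,
      femoral = circle(cx, cy, r_fem),
      cup = circle(cx + u(rg$cup_offset), cy + u(rg$cup_offset), r_cup),
      rim_width = u(rg$rim_width),
      noise_sigma = u(rg$noise_sigma),
      occlusion_arcs = arcs,
      n_screw_lines = round(u(rg$n_screws)),
      seed = seed + 1L
    )
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom images (PNG) with circle labels ("cls x y r"), box
#' labels ("cls x y w h") and a JSON manifest listing the per-image seeds and
#' geometry. Deterministic for a fixed seed.
#'
#' @param n Number of phantoms.
#' @param out_dir Output directory (created if needed).
#' @param ranges Parameter ranges, see [sample_phantom_spec()].
#' @param dims An [image_dims()].
#' @param seed Integer base seed.
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(n, out_dir, ranges = list(),
                             dims = image_dims(320, 320), seed = 1) {
  ok <- dir.create(file.path(out_dir, "images"), recursive = TRUE,
                   showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels_circle"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels_box"), showWarnings = FALSE)
  if (!dir.exists(file.path(out_dir, "images"))) {
    hw_error(paste("cannot create output directory", out_dir), "io")
  }
  manifest <- list(seed = seed, n = n, items = list())
  for (i in seq_len(n)) {
    s <- seed * 10000L + i
    spec <- sample_phantom_spec(ranges, dims = dims, seed = s)
    ph <- generate_phantom(spec)
    stem <- sprintf("phantom_%03d", i)
    write_image_gray(ph$image, file.path(out_dir, "images", paste0(stem, ".png")))
    write_circle_annotations(ph$truth,
                             file.path(out_dir, "labels_circle", paste0(stem, ".txt")))
    boxes <- lapply(ph$truth, circle_to_normbox, dims = dims)
    write_box_labels(boxes, file.path(out_dir, "labels_box", paste0(stem, ".txt")))
    manifest$items[[i]] <- list(
      stem = stem, seed = s,
      femoral = unclass(ph$truth[[1]]), cup = unclass(ph$truth[[2]])
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' PRE/POST phantom pair with known wear
#'
#' POST equals PRE with the femoral center translated by `head_shift`, then
#' the whole geometry (dimensions, centers, radii) multiplied by
#' `post_scale`, simulating a magnification change between visits. The
#' expected wear report is computed analytically from the spec circles, so
#' the pair exercises the full fit-then-measure round trip against a known
#' answer. By construction the sf correction cancels `post_scale` exactly.
#'
#' @param base A [phantom_spec()] for the PRE image.
#' @param head_shift Length-2 numeric (dx, dy) pixels applied to the femoral
#'   center at the PRE scale.
#' @param post_scale Positive magnification factor for the POST image.
#' @param seed Integer seed for the POST rendering noise.
#' @return List with `pre`, `post` (phantom lists) and `expected`
#'   (a `wear_report`).
#' @export
generate_pre_post_pair <- function(base, head_shift = c(0, 0), post_scale = 1,
                                   seed = base$seed + 1L) {
  stopifnot(inherits(base, "phantom_spec"))
  if (post_scale <= 0) hw_error("post_scale must be positive", "spec")
  s <- post_scale
  fem_post <- circle((base$femoral$cx + head_shift[1]) * s,
                     (base$femoral$cy + head_shift[2]) * s,
                     base$femoral$r * s)
  cup_post <- circle(base$cup$cx * s, base$cup$cy * s, base$cup$r * s)
  post_spec <- phantom_spec(
    dims = image_dims(round(base$dims$W * s), round(base$dims$H * s)),
    femoral = fem_post, cup = cup_post,
    rim_width = base$rim_width * s,
    rim_contrast = base$rim_contrast,
    head_contrast = base$head_contrast,
    gap_contrast = base$gap_contrast,
    background_level = base$background_level,
    noise_sigma = base$noise_sigma,
    occlusion_arcs = base$occlusion_arcs,
    n_screw_lines = base$n_screw_lines,
    seed = seed
  )
  expected <- compute_wear_report(
    timepoint_geometry(base$femoral, base$cup, "PRE"),
    timepoint_geometry(fem_post, cup_post, "POST")
  )
  list(
    pre = generate_phantom(base),
    post = generate_phantom(post_spec),
    expected = expected
  )
}
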