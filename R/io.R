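# On-disk formats: grayscale PNG images, "cls x y r" circle annotations,
# "cls x y w h" box labels, and the layered pipeline configuration.

#' Read a grayscale image
#'
#' Reads a PNG image as a numeric matrix in \[0, 255\], image convention
#' `img[y + 1, x + 1]`. Multi-channel images are converted by averaging the
#' color channels (radiographs replicate the gray channel anyway).
#'
#' @param path PNG file path.
#' @return Numeric matrix.
#' @export
read_image_gray <- function(path) {
  if (!file.exists(path)) hw_error(paste("no such file:", path), "io")
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    nc <- min(dim(a)[3], 3) # drop alpha
    a <- apply(a[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  a * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img Numeric matrix in \[0, 255\].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_image_gray <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

parse_label_lines <- function(path, n_fields, what) {
  if (!file.exists(path)) hw_error(paste("no such file:", path), "io")
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  rows <- list()
  ln <- 0
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(f) != n_fields || anyNA(f)) {
      hw_error(sprintf("line %d: expected %d numeric fields (%s)", i, n_fields, what),
               "parse")
    }
    if (!f[1] %in% c(0, 1)) {
      hw_error(sprintf("line %d: class id must be 0 or 1", i), "parse")
    }
    if (f[2] < 0 || f[2] > 1 || f[3] < 0 || f[3] > 1) {
      hw_error(sprintf("line %d: normalized center outside [0, 1]", i), "parse")
    }
    rows[[length(rows) + 1]] <- f
  }
  rows
}

#' Read circle annotations ("cls x y r")
#'
#' One structure per non-blank line, whitespace-separated normalized floats;
#' class 0 is the femoral head, class 1 the cup.
#'
#' @param path Text file path.
#' @return List of [norm_circle()].
#' @export
read_circle_annotations <- function(path) {
  rows <- parse_label_lines(path, 4, "cls x y r")
  lapply(rows, function(f) norm_circle(f[1], f[2], f[3], f[4]))
}

#' Write circle annotations ("cls x y r")
#'
#' @param ncs List of [norm_circle()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_circle_annotations <- function(ncs, path) {
  writeLines(
    vapply(ncs, function(nc) {
      sprintf("%d %.6f %.6f %.6f", nc$cls, nc$x, nc$y, nc$r)
    }, ""),
    path
  )
  invisible(path)
}

#' Read normalized box labels ("cls x y w h")
#'
#' @param path Text file path.
#' @return List of [norm_box()].
#' @export
read_box_labels <- function(path) {
  rows <- parse_label_lines(path, 5, "cls x y w h")
  lapply(rows, function(f) norm_box(f[1], f[2], f[3], f[4], f[5]))
}

#' Write normalized box labels ("cls x y w h")
#'
#' @param boxes List of [norm_box()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_box_labels <- function(boxes, path) {
  writeLines(
    vapply(boxes, function(b) {
      sprintf("%d %.6f %.6f %.6f %.6f", b$cls, b$x, b$y, b$w, b$h)
    }, ""),
    path
  )
  invisible(path)
}

hip_config_defaults <- function() {
  list(
    preprocess = list(
      clahe_clip = 2, clahe_tiles = 8,
      bilateral_d = 9, bilateral_sigma_color = 75, bilateral_sigma_space = 75,
      sharpen = TRUE, unsharp_amount = 1, unsharp_sigma = 1.5,
      canny_sigma = 0.33, canny_gauss_sigma = 1.2,
      edge_weights = c(0.5, 0.5)
    ),
    roi = list(margin_frac = 0.15),
    refine = list(
      seed = 42L,
      edge_snap = list(n_angles = 360L, annulus_frac = 0.2,
                       min_support_frac = 0.1, noise_floor = 0.3,
                       r_step = 0.25),
      ransac = list(n_iter = 500L, inlier_tol = 2, ring_frac = 0.1,
                    response_quantile = 0.5),
      cup = list(n_shifts = 5L, shift_frac = 0.08,
                 scale_range = c(0.85, 1.15), n_scales = 7L,
                 snap_annulus_frac = 0.1, snap_n_angles = 240L,
                 use_ransac = TRUE, ransac_n_iter = 300L, ring_frac = 0.08,
                 response_quantile = 0.6, score_weights = rep(1, 6) / 6,
                 radius_jump_frac = 0.25),
      fallback = list(threshold = 0.35, relax = 0.3, n_peaks = 6L, r_step = 1),
      filter = list(min_gap = 1, min_edge_density = 0.1)
    ),
    metrics = list(iou_tau = 0.5, conf_t = 0.25),
    synth = list(W = 320L, H = 320L)
  )
}

merge_config <- function(base, over, path = "") {
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    hw_error(paste0("unknown config key(s): ",
                    paste0(path, unknown, collapse = ", ")), "parameter")
  }
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]],
                                 path = paste0(path, nm, "."))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Returns the layered default configuration, optionally overridden by named
#' nested lists (e.g. `hip_config(refine = list(seed = 7))`). Unknown keys
#' are rejected rather than silently ignored.
#'
#' @param ... Named nested overrides for the sections `preprocess`, `roi`,
#'   `refine`, `metrics`, `synth`.
#' @return Nested configuration list.
#' @export
hip_config <- function(...) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(!nzchar(names(over))))) {
    hw_error("config overrides must be named", "parameter")
  }
  merge_config(hip_config_defaults(), over)
}
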