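# Shared fixtures: hand-built edge maps with exactly known geometry, and
# convenience wrappers around the phantom generator.

# Edge map containing rasterized circles with inward-pointing gradient
# directions (the bright-interior convention of a radiographic implant);
# gives precise control over edge support independently of the Canny chain.
ring_edge_map <- function(W, H, circles, drop_angles = NULL) {
  edges <- matrix(FALSE, H, W)
  mag <- matrix(0, H, W)
  dir <- matrix(0, H, W)
  for (cc in circles) {
    ang <- seq(0, 2 * pi, length.out = max(64, ceiling(4 * pi * cc$r)))
    ang <- ang[-length(ang)]
    if (!is.null(drop_angles)) {
      keep <- !(ang >= drop_angles[1] & ang <= drop_angles[2])
      ang <- ang[keep]
    }
    x <- round(cc$cx + cc$r * cos(ang))
    y <- round(cc$cy + cc$r * sin(ang))
    ok <- x >= 0 & x < W & y >= 0 & y < H
    idx <- cbind(y[ok] + 1, x[ok] + 1)
    edges[idx] <- TRUE
    mag[idx] <- 1
    dir[idx] <- atan2(cc$cy - y[ok], cc$cx - x[ok])
  }
  structure(
    list(edges = edges, grad_mag = mag, grad_dir = dir,
         combined = 0.5 * edges + 0.5 * mag, W = W, H = H, params = NULL),
    class = "edge_map"
  )
}

blank_edge_map <- function(W, H) {
  z <- matrix(0, H, W)
  structure(
    list(edges = matrix(FALSE, H, W), grad_mag = z, grad_dir = z,
         combined = z, W = W, H = H, params = NULL),
    class = "edge_map"
  )
}

# Points sampled exactly on a circle, optionally with radial Gaussian noise.
circle_points <- function(cc, n, radial_sd = 0) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  r <- cc$r + if (radial_sd > 0) stats::rnorm(n, 0, radial_sd) else 0
  cbind(x = cc$cx + r * cos(ang), y = cc$cy + r * sin(ang))
}

random_circle <- function(dims) {
  circle(
    cx = stats::runif(1, 0, dims$W),
    cy = stats::runif(1, 0, dims$H),
    r = stats::runif(1, 0, min(dims$W, dims$H) / 2)
  )
}
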