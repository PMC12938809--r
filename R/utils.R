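# Internal helpers: error conditions, RNG hygiene, matrix shifts, sampling.

# Classed error so callers can distinguish failure modes programmatically.
hw_error <- function(msg, class, ...) {
  stop(errorCondition(
    msg,
    ...,
    class = c(paste0("hipwear_", class), "hipwear_error", "error", "condition")
  ))
}

# Run expr with a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# shift_mat(m, dy, dx)[i, j] == m[i - dy, j - dx] with replicated borders,
# i.e. the content moves down/right by (dy, dx).
shift_mat <- function(m, dy, dx) {
  H <- nrow(m)
  W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) - dy, 1L), H)
  ci <- pmin(pmax(seq_len(W) - dx, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Neighbour access: value at offset (dy, dx) from each pixel.
nbr <- function(m, dy, dx) shift_mat(m, -dy, -dx)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Bilinear interpolation of matrix m (image convention: m[y + 1, x + 1],
# 0-based continuous coordinates). Out-of-domain samples return `fill`.
bilinear_sample <- function(m, x, y, fill = 0) {
  H <- nrow(m)
  W <- ncol(m)
  valid <- is.finite(x) & is.finite(y) & x >= 0 & y >= 0 & x <= (W - 1) & y <= (H - 1)
  xc <- clamp(x, 0, W - 1)
  yc <- clamp(y, 0, H - 1)
  x0 <- pmin(floor(xc), W - 2)
  y0 <- pmin(floor(yc), H - 2)
  if (W == 1) x0 <- rep(0, length(xc))
  if (H == 1) y0 <- rep(0, length(yc))
  fx <- xc - x0
  fy <- yc - y0
  i0 <- y0 + 1
  j0 <- x0 + 1
  i1 <- pmin(i0 + 1, H)
  j1 <- pmin(j0 + 1, W)
  v <- (1 - fx) * (1 - fy) * m[cbind(i0, j0)] +
    fx * (1 - fy) * m[cbind(i0, j1)] +
    (1 - fx) * fy * m[cbind(i1, j0)] +
    fx * fy * m[cbind(i1, j1)]
  v[!valid] <- fill
  v
}

# Weighted median with ties resolved to the lower value.
weighted_median_low <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
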