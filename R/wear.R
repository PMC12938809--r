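# Medial, superior, and resultant 2D wear from PRE/POST circle pairs, with
# femoral-head-radius scale normalization.
#
# The prosthetic femoral head has a constant physical radius, so the ratio of
# its PRE and POST image radii (sf = r_pre / r_post) cancels magnification
# differences between serial radiographs; all POST distances are multiplied
# by sf before differencing.

#' Femoral-head/cup geometry at one timepoint
#'
#' @param femoral,cup [circle()] objects; cup radius must exceed femoral.
#' @param label "PRE" or "POST".
#' @return An object of class `timepoint_geometry`.
#' @export
timepoint_geometry <- function(femoral, cup, label = c("PRE", "POST")) {
  stopifnot(inherits(femoral, "circle"), inherits(cup, "circle"))
  label <- match.arg(label)
  if (!(cup$r > femoral$r)) {
    hw_error("cup radius must exceed femoral radius", "geometry")
  }
  structure(list(femoral = femoral, cup = cup, label = label),
            class = "timepoint_geometry")
}

#' Medial component: head-to-cup center distance
#'
#' Euclidean distance in pixels between the femoral-head and cup centers.
#'
#' @param t A [timepoint_geometry()].
#' @return Distance in pixels.
#' @export
center_distance <- function(t) {
  stopifnot(inherits(t, "timepoint_geometry"))
  sqrt((t$cup$cx - t$femoral$cx)^2 + (t$cup$cy - t$femoral$cy)^2)
}

#' Superior joint-space gap
#'
#' The superior point of each circle is y_top = cy - r (y-down convention);
#' the gap is the absolute difference of the two superior points, which makes
#' the result independent of the y-axis orientation.
#'
#' @param t A [timepoint_geometry()].
#' @return Gap in pixels.
#' @export
superior_gap <- function(t) {
  stopifnot(inherits(t, "timepoint_geometry"))
  abs((t$cup$cy - t$cup$r) - (t$femoral$cy - t$femoral$r))
}

#' Wear report for a PRE/POST pair
#'
#' Computes the scale factor sf = r_fem_PRE / r_fem_POST, the scaled POST
#' center distance and superior gap, the signed medial and superior wear
#' components (delta_d = d_post sf - d_pre, delta_g = g_post sf - g_pre), and
#' the resultant magnitude delta_total = sqrt(delta_d^2 + delta_g^2). With a
#' magnification factor M (pixels per millimetre) the resultant is also
#' reported in millimetres as delta_total / M, the PRE radiograph being the
#' reference scale.
#'
#' @param pre,post [timepoint_geometry()] objects.
#' @param magnification Optional pixel-per-millimetre factor M.
#' @return An object of class `wear_report`.
#' @export
compute_wear_report <- function(pre, post, magnification = NULL) {
  stopifnot(inherits(pre, "timepoint_geometry"),
            inherits(post, "timepoint_geometry"))
  if (post$femoral$r <= 0) {
    hw_error("POST femoral radius must be positive", "scale")
  }
  sf <- pre$femoral$r / post$femoral$r
  d_pre <- center_distance(pre)
  d_post <- center_distance(post)
  g_pre <- superior_gap(pre)
  g_post <- superior_gap(post)
  delta_d <- d_post * sf - d_pre
  delta_g <- g_post * sf - g_pre
  structure(
    list(
      r_fem_pre = pre$femoral$r,
      r_fem_post = post$femoral$r,
      sf = sf,
      d_pre = d_pre,
      d_post = d_post,
      d_post_scaled = d_post * sf,
      g_pre = g_pre,
      g_post = g_post,
      g_post_scaled = g_post * sf,
      delta_d = delta_d,
      delta_g = delta_g,
      delta_total = sqrt(delta_d^2 + delta_g^2),
      magnification = magnification,
      wear_mm = if (is.null(magnification)) NULL else {
        sqrt(delta_d^2 + delta_g^2) / magnification
      }
    ),
    class = "wear_report"
  )
}

#' @export
print.wear_report <- function(x, ...) {
  cat("wear report (PRE reference scale)\n")
  cat(sprintf("  femoral radius PRE/POST: %.6f / %.6f px (sf = %.6f)\n",
              x$r_fem_pre, x$r_fem_post, x$sf))
  cat(sprintf("  medial distance PRE / POST / POST scaled: %.6f / %.6f / %.6f px\n",
              x$d_pre, x$d_post, x$d_post_scaled))
  cat(sprintf("  superior gap   PRE / POST / POST scaled: %.6f / %.6f / %.6f px\n",
              x$g_pre, x$g_post, x$g_post_scaled))
  cat(sprintf("  wear: medial %.6f px, superior %.6f px, resultant %.6f px\n",
              x$delta_d, x$delta_g, x$delta_total))
  if (!is.null(x$wear_mm)) {
    cat(sprintf("  resultant wear: %.6f mm (M = %.6f)\n", x$wear_mm, x$magnification))
  }
  invisible(x)
}

wear_report_fields <- c(
  "r_fem_pre", "r_fem_post", "sf", "d_pre", "d_post", "d_post_scaled",
  "g_pre", "g_post", "g_post_scaled", "delta_d", "delta_g", "delta_total"
)

#' Write a wear report as labelled text
#'
#' One "key value" line per quantity, 6-decimal fixed point; the
#' magnification and millimetre lines are present only when a magnification
#' factor was supplied. The format round-trips through [read_wear_report()].
#'
#' @param report A `wear_report`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_wear_report <- function(report, path) {
  stopifnot(inherits(report, "wear_report"))
  lines <- vapply(wear_report_fields, function(f) {
    sprintf("%s %.6f", f, report[[f]])
  }, "")
  if (!is.null(report$magnification)) {
    lines <- c(lines,
               sprintf("magnification %.6f", report$magnification),
               sprintf("wear_mm %.6f", report$wear_mm))
  }
  tryCatch(writeLines(lines, path),
           error = function(e) hw_error(conditionMessage(e), "io"))
  invisible(path)
}

#' Read a wear report written by [write_wear_report()]
#'
#' @param path Text file path.
#' @return A `wear_report`.
#' @export
read_wear_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(trimws(lines), "\\s+")
  vals <- stats::setNames(
    vapply(kv, function(p) suppressWarnings(as.numeric(p[2])), 0),
    vapply(kv, `[`, "", 1)
  )
  missing <- setdiff(wear_report_fields, names(vals))
  if (length(missing) > 0 || anyNA(vals)) {
    hw_error("malformed wear report file", "parse")
  }
  out <- as.list(vals[wear_report_fields])
  out$magnification <- if ("magnification" %in% names(vals)) vals[["magnification"]] else NULL
  out$wear_mm <- if ("wear_mm" %in% names(vals)) vals[["wear_mm"]] else NULL
  structure(out, class = "wear_report")
}
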