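#' Nuclear region-of-interest polygons
#'
#' A nucleus ROI is a simple closed polygon in sample-plane nanometre
#' coordinates. It bounds every per-nucleus analysis: rendering grids cover
#' its bounding box, localizations outside it are discarded, and the Monte
#' Carlo randomization re-places clusters uniformly inside it.
#'
#' @param vertices numeric matrix (or data.frame) with two columns, the
#'   polygon vertices in nm, listed in order. The polygon is closed
#'   implicitly; a repeated final vertex is tolerated and dropped.
#' @param nucleus_id label for the nucleus this ROI belongs to.
#' @return An object of class `nucleus_roi`: a list with `vertices`
#'   (n x 2 matrix, open ring) and `nucleus_id`.
#' @examples
#' sq <- roi_polygon(cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)), "n1")
#' roi_area(sq)  # 1e6 nm^2
#' @export
roi_polygon <- function(vertices, nucleus_id = "nucleus") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L)
    stopf("ROI polygon needs an n x 2 vertex matrix with n >= 3")
  storage.mode(v) <- "double"
  if (anyNA(v) || any(!is.finite(v))) stopf("ROI vertices must be finite")
  if (isTRUE(all.equal(v[1L, ], v[nrow(v), ]))) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stopf("ROI polygon degenerate after closing")
  r <- structure(list(vertices = unname(v), nucleus_id = nucleus_id),
                 class = "nucleus_roi")
  if (abs(roi_area(r)) <= 0) stopf("ROI polygon has zero area")
  r
}

#' Elliptical nucleus ROI
#'
#' Convenience constructor approximating an ellipse (the typical projected
#' nucleus outline) by a polygon.
#'
#' @param semi_axes numeric length 2, ellipse semi-axes (nm).
#' @param center numeric length 2, ellipse center (nm).
#' @param n_vertices number of polygon vertices used for the approximation.
#' @inheritParams roi_polygon
#' @return A `nucleus_roi`.
#' @export
roi_ellipse <- function(semi_axes, center = c(0, 0), nucleus_id = "nucleus",
                        n_vertices = 256L) {
  if (length(semi_axes) != 2L || any(semi_axes <= 0))
    stopf("semi_axes must be two positive lengths (nm)")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  roi_polygon(cbind(center[1L] + semi_axes[1L] * cos(th),
                    center[2L] + semi_axes[2L] * sin(th)),
              nucleus_id = nucleus_id)
}

#' Read an ROI polygon from a vertex CSV
#'
#' Expects columns `x` and `y` (nm); extra columns are ignored.
#'
#' @param path CSV file of polygon vertices.
#' @inheritParams roi_polygon
#' @return A `nucleus_roi`.
#' @export
read_roi <- function(path, nucleus_id = "nucleus") {
  if (!file.exists(path)) stopf("ROI file not found: %s", path)
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("x", "y") %in% names(d)))
    stopf("ROI CSV must have columns 'x' and 'y' (nm)")
  roi_polygon(cbind(as.numeric(d$x), as.numeric(d$y)), nucleus_id = nucleus_id)
}

#' @export
print.nucleus_roi <- function(x, ...) {
  cat(sprintf("<nucleus_roi '%s': %d vertices, area %.3g um^2>\n",
              x$nucleus_id, nrow(x$vertices), roi_area(x) / 1e6))
  invisible(x)
}

#' Polygon area (shoelace formula)
#' @param roi a `nucleus_roi`.
#' @return Area in nm^2.
#' @export
roi_area <- function(roi) {
  v <- roi$vertices
  x <- v[, 1L]; y <- v[, 2L]
  j <- c(2:nrow(v), 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

roi_bbox <- function(roi) {
  v <- roi$vertices
  c(xmin = min(v[, 1L]), xmax = max(v[, 1L]),
    ymin = min(v[, 2L]), ymax = max(v[, 2L]))
}

#' Test points for ROI membership
#' @param roi a `nucleus_roi`.
#' @param xy n x 2 matrix of points (nm).
#' @return Logical vector, TRUE for points inside the polygon.
#' @export
points_in_roi <- function(roi, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  if (nrow(xy) == 0L) return(logical(0))
  v <- roi$vertices
  bnd <- rbind(v, v[1L, , drop = FALSE])
  mgcv::in.out(bnd, xy)
}

# uniform random points inside an ROI (rejection from the bounding box)
sample_in_roi <- function(roi, n) {
  bb <- roi_bbox(roi)
  out <- matrix(NA_real_, n, 2L)
  got <- 0L
  while (got < n) {
    m <- max(16L, 2L * (n - got))
    p <- cbind(stats::runif(m, bb["xmin"], bb["xmax"]),
               stats::runif(m, bb["ymin"], bb["ymax"]))
    p <- p[points_in_roi(roi, p), , drop = FALSE]
    if (nrow(p) > 0L) {
      take <- min(nrow(p), n - got)
      out[(got + 1L):(got + take), ] <- p[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}
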