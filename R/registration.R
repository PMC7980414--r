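#' Polynomial two-color channel registration
#'
#' Chromatic offsets between color channels are corrected with a 2D
#' polynomial morph map fitted to corresponding fiducial positions.
#' `fit_channel_map()` solves, per output axis, the least-squares
#' coefficients of all monomials `x^p y^q` with `p + q <= degree` mapping
#' the moving channel onto the fixed channel.
#'
#' @param fixed_points,moving_points n x 2 matrices of corresponding
#'   positions (nm) in the fixed (reference) and moving channels.
#' @param degree polynomial degree (>= 1). Degree 1 is affine; degree 2
#'   (the default used by the pipeline) captures smooth field-dependent
#'   chromatic distortion.
#' @return An object of class `channel_map2d`: list with `degree`,
#'   `coeffs_x`, `coeffs_y` (one coefficient per monomial, graded
#'   lexicographic order), and `rms_residual` (nm).
#' @examples
#' p <- cbind(runif(12, 0, 5000), runif(12, 0, 5000))
#' m <- fit_channel_map(p, sweep(p, 2, c(15, -7), "+"), degree = 1)
#' m$rms_residual  # ~0
#' @export
fit_channel_map <- function(fixed_points, moving_points, degree = 2L) {
  fp <- matrix(as.numeric(as.matrix(fixed_points)), ncol = 2L)
  mp <- matrix(as.numeric(as.matrix(moving_points)), ncol = 2L)
  if (nrow(fp) != nrow(mp)) stopf("point lists must have equal length")
  degree <- as.integer(degree)
  if (degree < 1L) stopf("degree must be >= 1")
  ncoef <- (degree + 1L) * (degree + 2L) / 2L
  if (nrow(fp) < ncoef)
    stopf("underdetermined: degree %d needs >= %d point pairs, got %d",
          degree, ncoef, nrow(fp))
  X <- poly_design(mp[, 1L], mp[, 2L], degree)
  # column equilibration: nm-scale monomials span many orders of magnitude
  sc <- apply(abs(X), 2L, max)
  sc[sc == 0] <- 1
  qr_ <- qr(sweep(X, 2L, sc, "/"))
  if (qr_$rank < ncol(X))
    stopf("degenerate fiducial geometry: design matrix rank %d < %d %s",
          qr_$rank, ncol(X), "(collinear points cannot constrain the map)")
  cx <- qr.coef(qr_, fp[, 1L]) / sc
  cy <- qr.coef(qr_, fp[, 2L]) / sc
  res <- cbind(fp[, 1L] - X %*% cx, fp[, 2L] - X %*% cy)
  structure(list(degree = degree, coeffs_x = as.numeric(cx),
                 coeffs_y = as.numeric(cy),
                 rms_residual = sqrt(mean(rowSums(res^2)))),
            class = "channel_map2d")
}

# monomial design matrix, graded lexicographic: 1, x, y, x^2, xy, y^2, ...
poly_design <- function(x, y, degree) {
  cols <- list()
  for (d in 0:degree)
    for (p in d:0)
      cols[[length(cols) + 1L]] <- x^p * y^(d - p)
  do.call(cbind, cols)
}

#' Apply a fitted channel map to a localization table
#'
#' Transforms coordinates from the moving channel's frame into the fixed
#' channel's frame; all other fields are unchanged.
#'
#' @param map a [fit_channel_map()] result.
#' @param table a [loc_table()] (or n x 2 coordinate matrix).
#' @return The transformed table (or matrix).
#' @export
apply_channel_map <- function(map, table) {
  if (is.matrix(table)) {
    X <- poly_design(table[, 1L], table[, 2L], map$degree)
    return(cbind(X %*% map$coeffs_x, X %*% map$coeffs_y))
  }
  X <- poly_design(table$x, table$y, map$degree)
  out <- table
  out$x <- as.numeric(X %*% map$coeffs_x)
  out$y <- as.numeric(X %*% map$coeffs_y)
  out
}

#' @export
print.channel_map2d <- function(x, ...) {
  cat(sprintf("<channel_map2d: degree %d, rms residual %.3g nm>\n",
              x$degree, x$rms_residual))
  invisible(x)
}
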