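#' Threshold spec helpers
#'
#' Segmentation thresholds are either an absolute intensity or a percentile
#' of the nonzero pixel values of the image being segmented (computed per
#' channel per nucleus). The default pipeline rule is the 90th percentile.
#'
#' @param p percentile in (0, 100].
#' @return A threshold spec understood by [segment_clusters()].
#' @export
pct_threshold <- function(p = 90) {
  if (!is.finite(p) || p <= 0 || p > 100) stopf("percentile must be in (0, 100]")
  structure(list(percentile = p), class = "threshold_spec")
}

resolve_threshold <- function(threshold, grid) {
  if (inherits(threshold, "threshold_spec")) {
    nz <- grid[grid > 0]
    if (!length(nz)) return(NA_real_)  # all-zero image -> empty set
    return(unname(stats::quantile(nz, threshold$percentile / 100,
                                  names = FALSE)))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stopf("threshold must be a single number or pct_threshold()")
  threshold
}

#' Segment a rendered image into discrete clusters
#'
#' Particle analysis: the image is thresholded (pixels with value >= the
#' resolved threshold, ties included, zero pixels never), 4-connected
#' components are extracted, and components smaller than `min_area` pixels
#' are discarded as localization noise. Cluster centroids are
#' intensity-weighted over the original (pre-threshold) pixel values.
#'
#' @param image a [render()]ed image.
#' @param threshold absolute intensity, or [pct_threshold()] (default 90th
#'   percentile of nonzero pixels).
#' @param min_area minimum component size in pixels (>= 1; default 3).
#' @return An object of class `cluster_set`: list with `clusters` (each a
#'   list with `cluster_id`, `pixels` (m x 2 grid indices), `values`
#'   (pre-threshold intensities), `centroid` (nm), `area_nm2`,
#'   `total_intensity`), grid geometry (`pixel_size`, `origin`, `dim`),
#'   `channel_id`, `nucleus_id`, `threshold_used`, `min_area_used`.
#' @export
segment_clusters <- function(image, threshold = pct_threshold(90),
                             min_area = 3L) {
  min_area <- as.integer(min_area)
  if (min_area < 1L) stopf("min_area must be >= 1 pixel")
  thr <- resolve_threshold(threshold, image$grid)
  clusters <- list()
  if (is.finite(thr)) {
    mask <- (image$grid >= thr) & (image$grid > 0)
    lab <- EBImage::bwlabel(mask)
    nlab <- max(lab)
    if (nlab > 0L) {
      idx <- which(lab > 0L)
      by_lab <- split(idx, lab[idx])
      keep <- vapply(by_lab, length, 1L) >= min_area
      by_lab <- by_lab[keep]
      nx <- nrow(image$grid)
      for (k in seq_along(by_lab)) {
        lin <- by_lab[[k]]
        ij <- cbind((lin - 1L) %% nx + 1L, (lin - 1L) %/% nx + 1L)
        clusters[[k]] <- make_cluster(k, ij, image$grid[lin], image)
      }
    }
  }
  structure(list(clusters = clusters,
                 channel_id = image$channel_id,
                 nucleus_id = image$nucleus_id,
                 pixel_size = image$pixel_size,
                 origin = image$origin,
                 dim = dim(image$grid),
                 threshold_used = thr,
                 min_area_used = min_area),
            class = "cluster_set")
}

make_cluster <- function(id, ij, values, geom) {
  dimnames(ij) <- NULL
  ctr <- pixel_centers(geom, ij)
  w <- values / sum(values)
  list(cluster_id = id, pixels = ij, values = values,
       centroid = c(sum(ctr[, 1L] * w), sum(ctr[, 2L] * w)),
       area_nm2 = nrow(ij) * geom$pixel_size^2,
       total_intensity = sum(values))
}

#' Intensity-weighted center of mass of a cluster
#'
#' `sum(I_p * p_center) / sum(I_p)` over the cluster's member pixels, using
#' the pre-threshold intensities of the supplied image, in nm.
#'
#' @param cluster one element of a `cluster_set`'s `clusters` list.
#' @param image the [render()]ed image the cluster was segmented from.
#' @return Numeric length 2, the centroid in nm.
#' @export
centroid_of <- function(cluster, image) {
  ij <- cluster$pixels
  if (any(ij[, 1L] < 1L) || any(ij[, 1L] > nrow(image$grid)) ||
      any(ij[, 2L] < 1L) || any(ij[, 2L] > ncol(image$grid)))
    stopf("cluster pixels outside image extent")
  v <- image$grid[cbind(ij[, 1L], ij[, 2L])]
  tot <- sum(v)
  if (tot <= 0) stopf("cluster has zero total intensity; cannot weight")
  ctr <- pixel_centers(image, ij)
  c(sum(ctr[, 1L] * v), sum(ctr[, 2L] * v)) / tot
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set: %d clusters, channel '%s', nucleus '%s', thr %.3g, min_area %d>\n",
    length(x$clusters), x$channel_id, x$nucleus_id,
    x$threshold_used, x$min_area_used))
  invisible(x)
}

#' Summarize a cluster set as a data frame
#' @param object a `cluster_set`.
#' @param ... unused.
#' @return Data frame with one row per cluster (id, centroid, area,
#'   total intensity).
#' @export
summary.cluster_set <- function(object, ...) {
  if (!length(object$clusters))
    return(data.frame(cluster_id = integer(), channel = character(),
                      centroid_x_nm = numeric(), centroid_y_nm = numeric(),
                      area_nm2 = numeric(), total_intensity = numeric()))
  do.call(rbind, lapply(object$clusters, function(cl)
    data.frame(cluster_id = cl$cluster_id, channel = object$channel_id,
               centroid_x_nm = cl$centroid[1L], centroid_y_nm = cl$centroid[2L],
               area_nm2 = cl$area_nm2, total_intensity = cl$total_intensity)))
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$pixel_size, b$pixel_size)) &&
    isTRUE(all.equal(a$origin, b$origin)) && all(a$dim == b$dim)
}

# label matrix (0 = background) from a cluster set
label_matrix <- function(set) {
  lab <- matrix(0L, set$dim[1L], set$dim[2L])
  for (cl in set$clusters)
    lab[cbind(cl$pixels[, 1L], cl$pixels[, 2L])] <- cl$cluster_id
  lab
}

# dilate a pixel-index set by a Euclidean radius given in nm
dilate_pixels <- function(ij, radius_nm, pixel_size, dims) {
  if (radius_nm <= 0) return(ij)
  r <- radius_nm / pixel_size
  ri <- ceiling(r)
  off <- expand.grid(di = -ri:ri, dj = -ri:ri)
  off <- off[off$di^2 + off$dj^2 <= r^2, , drop = FALSE]
  ii <- outer(ij[, 1L], off$di, "+")
  jj <- outer(ij[, 2L], off$dj, "+")
  ok <- ii >= 1L & ii <= dims[1L] & jj >= 1L & jj <= dims[2L]
  key <- unique((as.integer(jj[ok]) - 1L) * dims[1L] + as.integer(ii[ok]))
  cbind((key - 1L) %% dims[1L] + 1L, (key - 1L) %/% dims[1L] + 1L)
}
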