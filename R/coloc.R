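#' Count inter-channel cluster overlaps
#'
#' Two clusters from different channels overlap iff they share at least one
#' rendering-grid pixel. Reports the pair list with shared areas, the
#' number of overlapping pairs, and how many clusters of each channel are
#' overlapped at least once — the counts the per-nucleus colocalization
#' ratio is built from.
#'
#' @param setA,setB [segment_clusters()] results on the same rendering grid
#'   (same pixel size, origin and dimensions).
#' @return An object of class `overlap_report`: list with `pairs` (data
#'   frame `idA`, `idB`, `shared_px`, `shared_area_nm2`),
#'   `n_overlapping_pairs`, `n_clusters_A_with_overlap`,
#'   `n_clusters_B_with_overlap`, `overlap_area_nm2`.
#' @export
count_overlaps <- function(setA, setB) {
  if (!same_grid(setA, setB))
    stopf("cluster sets are on different rendering grids")
  labA <- label_matrix(setA)
  rows <- list()
  for (cl in setB$clusters) {
    hits <- labA[cbind(cl$pixels[, 1L], cl$pixels[, 2L])]
    hits <- hits[hits > 0L]
    if (length(hits)) {
      tb <- table(hits)
      rows[[length(rows) + 1L]] <-
        data.frame(idA = as.integer(names(tb)), idB = cl$cluster_id,
                   shared_px = as.integer(tb))
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(idA = integer(), idB = integer(),
                           shared_px = integer())
  pairs$shared_area_nm2 <- pairs$shared_px * setA$pixel_size^2
  structure(list(pairs = pairs,
                 n_overlapping_pairs = nrow(pairs),
                 n_clusters_A_with_overlap = length(unique(pairs$idA)),
                 n_clusters_B_with_overlap = length(unique(pairs$idB)),
                 overlap_area_nm2 = sum(pairs$shared_area_nm2)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report: %d pairs, %d A / %d B clusters hit, area %g nm^2>\n",
              x$n_overlapping_pairs, x$n_clusters_A_with_overlap,
              x$n_clusters_B_with_overlap, x$overlap_area_nm2))
  invisible(x)
}

#' Monte Carlo randomization of one channel within the nuclear ROI
#'
#' Re-places each cluster of a channel at a uniformly random position
#' inside the ROI by rigid translation on the rendering grid: shape, area
#' and internal pixel intensities are preserved exactly, orientation is
#' unchanged, and placements are independent across clusters (mutual
#' overlap permitted). This is the null model against which real overlap
#' counts are normalized.
#'
#' @param set a `cluster_set`.
#' @param roi the [nucleus_roi()] to place into.
#' @param rng_seed optional integer; with a seed, placement is
#'   deterministic.
#' @param roi_mask optional precomputed logical matrix of in-ROI pixels on
#'   the set's grid (performance; computed when NULL).
#' @param max_tries rejection-sampling cap per cluster before declaring a
#'   cluster unplaceable.
#' @return A new `cluster_set` with translated clusters.
#' @export
randomize_channel <- function(set, roi, rng_seed = NULL, roi_mask = NULL,
                              max_tries = 10000L) {
  if (is.null(roi_mask)) roi_mask <- roi_pixel_mask(set, roi)
  run <- function() {
    out <- set
    out$clusters <- lapply(set$clusters, function(cl)
      place_cluster(cl, set, roi_mask, max_tries))
    out
  }
  if (!is.null(rng_seed)) withr::with_seed(as.integer(rng_seed), run())
  else run()
}

# logical matrix: pixel centers inside the ROI polygon
# A pixel belongs to the placement mask if its center or any corner lies
# inside the polygon — i.e. if an in-ROI localization could render into
# it. Using only pixel centers would give the null a slightly smaller
# support than the observed clusters have at the ROI boundary, biasing
# the colocalization ratio low.
roi_pixel_mask <- function(geom, roi) {
  nx <- geom$dim[1L]; ny <- geom$dim[2L]
  px <- geom$pixel_size
  ij <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  ctr <- pixel_centers(geom, ij)
  inside <- points_in_roi(roi, ctr)
  h <- px / 2
  for (dx in c(-h, h)) for (dy in c(-h, h)) {
    miss <- !inside
    if (!any(miss)) break
    inside[miss] <- points_in_roi(roi, cbind(ctr[miss, 1L] + dx,
                                             ctr[miss, 2L] + dy))
  }
  m <- matrix(inside, nx, ny)
  if (!any(m)) stopf("ROI contains no pixels on this grid")
  attr(m, "bbox") <- c(range(which(rowSums(m) > 0)),
                       range(which(colSums(m) > 0)))
  m
}

place_cluster <- function(cl, geom, roi_mask, max_tries) {
  ij <- cl$pixels
  di <- ij[, 1L] - min(ij[, 1L])
  dj <- ij[, 2L] - min(ij[, 2L])
  h <- max(di); w <- max(dj)
  # anchors are drawn inside the ROI mask's bounding box, so placement is
  # equivariant under rigid translation of the whole scene
  bb <- attr(roi_mask, "bbox")
  if (is.null(bb)) {
    ri <- range(which(rowSums(roi_mask) > 0))
    rj <- range(which(colSums(roi_mask) > 0))
    bb <- c(ri, rj)
  }
  ni <- bb[2L] - h - bb[1L] + 1L
  nj <- bb[4L] - w - bb[3L] + 1L
  if (ni < 1L || nj < 1L)
    stopf("cluster %s larger than the ROI placement window", cl$cluster_id)
  for (k in seq_len(max_tries)) {
    ii <- bb[1L] - 1L + sample.int(ni, 1L) + di
    jj <- bb[3L] - 1L + sample.int(nj, 1L) + dj
    if (all(roi_mask[cbind(ii, jj)]))
      return(make_cluster(cl$cluster_id, cbind(unname(ii), unname(jj)),
                          cl$values, geom))
  }
  stopf("no in-ROI placement found for cluster %s after %d tries",
        cl$cluster_id, max_tries)
}

#' Per-nucleus Monte Carlo colocalization ratio
#'
#' Tier 1 of the analysis. Real overlap statistics between the fixed
#' channel (held as imaged) and the observed second channel are divided by
#' the mean of the same statistics over `n_iterations` Monte Carlo
#' randomizations of the second channel within the ROI. A ratio of 1 means
#' overlap at truly random levels; ratios above 1 indicate enrichment.
#'
#' @param setA_fixed the channel held as imaged (typically the nascent-DNA
#'   channel).
#' @param setB_randomized the channel that is re-placed at random
#'   (typically the immunolabeled protein).
#' @param roi the [nucleus_roi()].
#' @param n_iterations Monte Carlo replicates (>= 1; default 100).
#' @param rng_seed integer seed making the randomization reproducible.
#' @return An object of class `coloc_result`: the real `overlap_report`,
#'   random means/sds per statistic, `ratio_count` and `ratio_area`
#'   (NaN-flagged as `Inf` when the random mean is zero but the real
#'   statistic is not, `NA` when both are zero), the replicate-level
#'   statistics, `n_iterations` and `seed`.
#' @export
coloc_ratio <- function(setA_fixed, setB_randomized, roi,
                        n_iterations = 100L, rng_seed = 1L) {
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stopf("n_iterations must be >= 1")
  real <- count_overlaps(setA_fixed, setB_randomized)
  roi_mask <- roi_pixel_mask(setA_fixed, roi)
  labA <- label_matrix(setA_fixed)
  px2 <- setA_fixed$pixel_size^2
  reps <- withr::with_seed(as.integer(rng_seed), {
    do.call(rbind, lapply(seq_len(n_iterations), function(it) {
      npairs <- 0L; nA <- integer(0); shared <- 0L
      for (cl in setB_randomized$clusters) {
        p <- place_cluster(cl, setB_randomized, roi_mask, 10000L)
        hits <- labA[cbind(p$pixels[, 1L], p$pixels[, 2L])]
        hits <- hits[hits > 0L]
        if (length(hits)) {
          u <- unique(hits)
          npairs <- npairs + length(u)
          nA <- c(nA, u)
          shared <- shared + length(hits)
        }
      }
      data.frame(iteration = it, n_pairs = npairs,
                 n_A_with_overlap = length(unique(nA)),
                 overlap_area_nm2 = shared * px2)
    }))
  })
  rmean <- colMeans(reps[, -1L, drop = FALSE])
  rsd <- vapply(reps[, -1L, drop = FALSE], stats::sd, 1)
  ratio <- function(real_v, rand_m) {
    if (rand_m > 0) real_v / rand_m else if (real_v > 0) Inf else NA_real_
  }
  structure(list(nucleus_id = setA_fixed$nucleus_id, real = real,
                 random_mean = rmean, random_sd = rsd,
                 replicates = reps, n_iterations = n_iterations,
                 ratio_count = ratio(real$n_overlapping_pairs,
                                     rmean[["n_pairs"]]),
                 ratio_area = ratio(real$overlap_area_nm2,
                                    rmean[["overlap_area_nm2"]]),
                 seed = as.integer(rng_seed)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "<coloc_result '%s': real %d pairs vs random %.2f +/- %.2f; ratio_count %.3g, ratio_area %.3g (%d iterations)>\n",
    x$nucleus_id, x$real$n_overlapping_pairs, x$random_mean[["n_pairs"]],
    x$random_sd[["n_pairs"]], x$ratio_count, x$ratio_area, x$n_iterations))
  invisible(x)
}

#' Compare per-nucleus colocalization ratios between two groups
#'
#' Summarizes each group of per-nucleus ratios (mean, median, SE, n) and
#' tests the condition group against the control group with a two-sample
#' t test (pooled Student's by default).
#'
#' @param ratios_condition,ratios_control lists of [coloc_ratio()] results
#'   (or plain numeric vectors of ratios).
#' @param metric `"count"` or `"area"`.
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return List of class `coloc_comparison` with per-group summaries and
#'   the `t_test_two_sample()` result.
#' @export
compare_to_control <- function(ratios_condition, ratios_control,
                               metric = c("count", "area"),
                               variant = c("pooled", "welch")) {
  metric <- match.arg(metric)
  variant <- match.arg(variant)
  pull <- function(z) {
    if (is.numeric(z)) return(z)
    vapply(z, function(r) if (metric == "count") r$ratio_count else
      r$ratio_area, 1)
  }
  a <- pull(ratios_condition); b <- pull(ratios_control)
  if (!length(a) || !length(b)) stopf("both groups must be nonempty")
  summ <- function(v) list(n = length(v), mean = mean(v),
                           median = stats::median(v),
                           se = stats::sd(v) / sqrt(length(v)))
  tt <- if (length(a) >= 2L && length(b) >= 2L)
    t_test_two_sample(a, b, variant = variant)
  else structure(list(t = NA_real_, df = NA_real_, p = NA_real_,
                      variant = variant, degenerate = TRUE,
                      message = "t test refused: each group needs n >= 2"),
                 class = "ttest_result")
  structure(list(metric = metric, condition = summ(a), control = summ(b),
                 mean_difference = mean(a) - mean(b), test = tt),
            class = "coloc_comparison")
}

#' @export
print.coloc_comparison <- function(x, ...) {
  cat(sprintf(
    "<coloc_comparison (%s): condition %.3g (n=%d) vs control %.3g (n=%d); diff %.3g, p = %.3g>\n",
    x$metric, x$condition$mean, x$condition$n, x$control$mean, x$control$n,
    x$mean_difference, x$test$p))
  invisible(x)
}
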