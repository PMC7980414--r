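#' Intercenter distance of two protein subfoci at one focus
#'
#' Tier 3, per-focus measurement. For a three-color-positive focus, each
#' protein channel's center of mass is computed over all of that channel's
#' cluster pixels lying within the focus mask dilated by `capture_radius`
#' (pixels of multiple clusters are pooled into one centroid per channel),
#' intensity-weighted by the pre-threshold pixel values stored at
#' segmentation. The reported distance is the Euclidean separation of the
#' two centroids.
#'
#' @param focus one cluster from the naDNA `cluster_set`.
#' @param clustersA,clustersB protein `cluster_set`s on the same grid.
#' @param capture_radius nm of dilation around the focus mask defining the
#'   capture window (default 300 nm, the upper end of the distal
#'   envelope).
#' @return List of class `distance_sample`: `focus_id`, `d` (nm),
#'   `centroid_A`, `centroid_B`; or `NULL` with a warning-free skip when a
#'   channel contributes no intensity in the window (reason in attribute
#'   `"skip_reason"` of the `NULL` wrapper returned by
#'   [measure_pair_distances()]).
#' @export
subfoci_distance <- function(focus, clustersA, clustersB,
                             capture_radius = 300) {
  if (!same_grid(clustersA, clustersB))
    stopf("protein cluster sets are on different grids")
  win <- dilate_pixels(focus$pixels, capture_radius, clustersA$pixel_size,
                       clustersA$dim)
  key <- (win[, 2L] - 1L) * clustersA$dim[1L] + win[, 1L]
  cA <- pooled_centroid(clustersA, key)
  cB <- pooled_centroid(clustersB, key)
  if (is.null(cA) || is.null(cB)) {
    reason <- if (is.null(cA)) "no_A_intensity_in_window"
              else "no_B_intensity_in_window"
    return(structure(list(focus_id = focus$cluster_id, d = NA_real_,
                          skip_reason = reason),
                     class = "distance_sample"))
  }
  structure(list(focus_id = focus$cluster_id,
                 d = sqrt(sum((cA - cB)^2)),
                 centroid_A = cA, centroid_B = cB, skip_reason = NA),
            class = "distance_sample")
}

pooled_centroid <- function(set, window_keys) {
  xs <- 0; ys <- 0; tot <- 0
  for (cl in set$clusters) {
    k <- (cl$pixels[, 2L] - 1L) * set$dim[1L] + cl$pixels[, 1L]
    inw <- k %in% window_keys
    if (any(inw)) {
      ctr <- pixel_centers(set, cl$pixels[inw, , drop = FALSE])
      v <- cl$values[inw]
      xs <- xs + sum(ctr[, 1L] * v); ys <- ys + sum(ctr[, 2L] * v)
      tot <- tot + sum(v)
    }
  }
  if (tot <= 0) return(NULL)
  c(xs, ys) / tot
}

#' Measure subfocus distances over all three-color-positive foci
#'
#' Applies [subfoci_distance()] to every naDNA focus positive for both
#' proteins (presence per [classify_foci()] at the same capture radius)
#' and collates the distances.
#'
#' @param naDNA,setA,setB `cluster_set`s on a common grid.
#' @param capture_radius nm (default 300).
#' @return Data frame (`focus_id`, `d_nm`, centroid coordinates,
#'   `skip_reason`); skipped foci retain their reason code and an `NA`
#'   distance.
#' @export
measure_pair_distances <- function(naDNA, setA, setB, capture_radius = 300) {
  cls <- classify_foci(naDNA, setA, setB, capture_radius = capture_radius)
  pos <- cls$records$focus_id[cls$records$has_A & cls$records$has_B]
  rows <- lapply(naDNA$clusters[match(pos, vapply(naDNA$clusters,
                                                  `[[`, 1L, "cluster_id"))],
                 function(f) {
    s <- subfoci_distance(f, setA, setB, capture_radius)
    data.frame(focus_id = s$focus_id, d_nm = s$d,
               ax_nm = if (is.na(s$d)) NA_real_ else s$centroid_A[1L],
               ay_nm = if (is.na(s$d)) NA_real_ else s$centroid_A[2L],
               bx_nm = if (is.na(s$d)) NA_real_ else s$centroid_B[1L],
               by_nm = if (is.na(s$d)) NA_real_ else s$centroid_B[2L],
               skip_reason = if (is.na(s$d)) s$skip_reason else
                 NA_character_)
  })
  if (!length(rows))
    return(data.frame(focus_id = integer(), d_nm = numeric(),
                      ax_nm = numeric(), ay_nm = numeric(),
                      bx_nm = numeric(), by_nm = numeric(),
                      skip_reason = character()))
  do.call(rbind, rows)
}

#' Per-molecule inter-channel distances of a dual-labeled species
#'
#' For a species immunostained in two colors (no naDNA reference), each
#' cluster of the first channel serves as the reference subfocus: the
#' second channel's center of mass is pooled over its pixels within the
#' reference mask dilated by `capture_radius`, and the intercenter
#' distance is reported. The collated distances are the empirical
#' "complexed" baseline distribution.
#'
#' @param setA,setB `cluster_set`s of the two colors on a common grid.
#' @param capture_radius nm (default 100; the dual-label error budget is
#'   confined well below this, while neighboring molecules stay outside).
#' @return Numeric vector of distances (nm), one per reference cluster
#'   with measurable signal in both channels.
#' @export
duallabel_distances <- function(setA, setB, capture_radius = 100) {
  d <- vapply(setA$clusters, function(f)
    subfoci_distance(f, setA, setB, capture_radius = capture_radius)$d,
    numeric(1L))
  d[is.finite(d)]
}

#' Fit the subfocus distance histogram with one or two Gaussians
#'
#' The collated intercenter distances are binned and the bin counts are fit
#' by least squares with a one-component and a two-component Gaussian
#' curve; the model is selected by the corrected Akaike criterion (AICc)
#' computed from the residual sum of squares. Fitting the histogram (not a
#' maximum-likelihood mixture on the samples) mirrors how such distance
#' distributions are summarily described; a folded-normal MLE would handle
#' the d >= 0 boundary more strictly and is deliberately not the default.
#'
#' @param d numeric vector of distances (nm), or the data frame returned
#'   by [measure_pair_distances()] (its `d_nm` column is used, `NA`s
#'   dropped). At least 20 samples are required.
#' @param bin_width histogram bin width in nm (default 20).
#' @param proximal_cutoff nm; used for the stored sample-level proximal
#'   fraction (default 135, the dual-label baseline envelope).
#' @return Object of class `distance_fit`: `k` (1 or 2), `components`
#'   (data frame `weight`, `mean`, `sd`, ordered by mean), `candidates`
#'   (per-k AICc and RSS), `bin_width`, `proximal_cutoff`,
#'   `proximal_fraction`, `histogram` (mids/counts), `n`, `samples`.
#' @export
fit_distance_distribution <- function(d, bin_width = 20,
                                      proximal_cutoff = 135) {
  if (is.data.frame(d)) d <- d$d_nm
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 20L)
    stopf("need >= 20 distance samples to fit (got %d)", n)
  if (bin_width <= 0) stopf("bin_width must be positive")
  breaks <- seq(0, (floor(max(d) / bin_width) + 1L) * bin_width, bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  f1 <- fit_gauss_curve(mids, counts, k = 1L, d = d)
  f2 <- fit_gauss_curve(mids, counts, k = 2L, d = d)
  cands <- data.frame(k = c(1L, 2L),
                      rss = c(f1$rss, f2$rss),
                      aicc = c(f1$aicc, f2$aicc),
                      converged = c(f1$converged, f2$converged))
  if (!f1$converged && !f2$converged)
    stopf("neither Gaussian candidate converged (RSS %.3g / %.3g)",
          f1$rss, f2$rss)
  pick <- if (!f2$converged) f1 else if (!f1$converged) f2
          else if (f2$aicc < f1$aicc) f2 else f1
  structure(list(k = pick$k, components = pick$components,
                 candidates = cands, bin_width = bin_width,
                 proximal_cutoff = proximal_cutoff,
                 proximal_fraction = mean(d < proximal_cutoff),
                 histogram = list(mids = mids, counts = counts,
                                  breaks = breaks),
                 n = n, samples = d),
            class = "distance_fit")
}

fit_gauss_curve <- function(mids, counts, k, d) {
  gauss <- function(x, a, mu, s) a * exp(-(x - mu)^2 / (2 * s^2))
  amax <- max(counts)
  fail <- list(k = k, rss = Inf, aicc = Inf, converged = FALSE,
               components = NULL)
  safe_sd <- function(v, fallback) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-3) fallback else s
  }
  if (k == 1L) {
    st <- list(a = amax, mu = mean(d), s = safe_sd(d, 10))
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      counts ~ gauss(mids, a, mu, s), start = st,
      lower = c(a = 0, mu = 0, s = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) return(fail)
    cf <- stats::coef(fit)
    comp <- data.frame(weight = 1, mean = cf[["mu"]], sd = cf[["s"]])
  } else {
    lo <- d[d <= stats::median(d)]; hi <- d[d > stats::median(d)]
    st <- list(a1 = amax, mu1 = mean(lo), s1 = safe_sd(lo, 10),
               a2 = amax / 2, mu2 = mean(hi), s2 = safe_sd(hi, 10))
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      counts ~ gauss(mids, a1, mu1, s1) + gauss(mids, a2, mu2, s2),
      start = st,
      lower = c(a1 = 0, mu1 = 0, s1 = 1e-6, a2 = 0, mu2 = 0, s2 = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 400))), silent = TRUE)
    if (inherits(fit, "try-error")) return(fail)
    cf <- stats::coef(fit)
    w <- c(cf[["a1"]] * cf[["s1"]], cf[["a2"]] * cf[["s2"]])
    if (sum(w) <= 0) return(fail)
    comp <- data.frame(weight = w / sum(w),
                       mean = c(cf[["mu1"]], cf[["mu2"]]),
                       sd = c(cf[["s1"]], cf[["s2"]]))
    comp <- comp[order(comp$mean), ]
    rownames(comp) <- NULL
  }
  rss <- sum(stats::residuals(fit)^2)
  nb <- length(mids); p <- 3L * k + 1L  # + residual variance
  aicc <- nb * log(rss / nb) + 2 * p +
    if (nb - p - 1L > 0L) 2 * p * (p + 1L) / (nb - p - 1L) else Inf
  list(k = k, rss = rss, aicc = aicc, converged = TRUE, components = comp)
}

#' @export
print.distance_fit <- function(x, ...) {
  cat(sprintf("<distance_fit: n = %d, k = %d component%s, bin %g nm>\n",
              x$n, x$k, if (x$k > 1L) "s" else "", x$bin_width))
  print(round(x$components, 2))
  cat(sprintf("  proximal fraction (d < %g nm): %.3f\n",
              x$proximal_cutoff, x$proximal_fraction))
  invisible(x)
}

#' @export
summary.distance_fit <- function(object, ...) {
  list(k = object$k, components = object$components,
       candidates = object$candidates, n = object$n,
       proximal_fraction = object$proximal_fraction,
       classification = classify_proximal_distal(object))
}

#' @export
coef.distance_fit <- function(object, ...) {
  as.matrix(object$components)
}

#' Predict expected histogram density from a distance fit
#'
#' Evaluates the fitted mixture density (unit integral) at the given
#' distances.
#'
#' @param object a `distance_fit`.
#' @param newdata numeric distances (nm); default the histogram bin mids.
#' @param ... unused.
#' @return Numeric densities.
#' @export
predict.distance_fit <- function(object, newdata = NULL, ...) {
  x <- newdata %||% object$histogram$mids
  comp <- object$components
  rowSums(vapply(seq_len(nrow(comp)), function(i)
    comp$weight[i] * stats::dnorm(x, comp$mean[i], comp$sd[i]),
    numeric(length(x))))
}

#' @export
residuals.distance_fit <- function(object, ...) {
  expected <- predict(object, object$histogram$mids) *
    object$n * object$bin_width
  object$histogram$counts - expected
}

#' Draw distances from the fitted mixture
#' @param object a `distance_fit`.
#' @param nsim number of draws.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return Numeric vector of simulated distances (nm, Gaussian components,
#'   not truncated at zero).
#' @export
simulate.distance_fit <- function(object, nsim = 1, seed = NULL, ...) {
  run <- function() {
    comp <- object$components
    i <- sample.int(nrow(comp), nsim, replace = TRUE, prob = comp$weight)
    stats::rnorm(nsim, comp$mean[i], comp$sd[i])
  }
  if (!is.null(seed)) withr::with_seed(as.integer(seed), run()) else run()
}

#' @export
plot.distance_fit <- function(x, ...) {
  h <- x$histogram
  graphics::plot(h$mids, h$counts, type = "h", lwd = 6, lend = 1,
                 col = "grey70", xlab = "intercenter distance (nm)",
                 ylab = "foci", ...)
  xx <- seq(0, max(h$breaks), length.out = 400)
  graphics::lines(xx, predict(x, xx) * x$n * x$bin_width, col = "red3",
                  lwd = 2)
  graphics::abline(v = x$proximal_cutoff, lty = 2)
  invisible(x)
}

#' Classify a fitted distance distribution as proximal, distal or mixed
#'
#' Components with mean below the proximal cutoff are labeled proximal
#' (consistent with a protein complex given the labeling-error budget),
#' the rest distal. The overall call is "mixed" when both a proximal and a
#' distal component carry weight >= 0.2, otherwise the label of the
#' dominant side.
#'
#' @param fit a [fit_distance_distribution()] result.
#' @param baseline optional `distance_fit` of a dual-labeled single
#'   species; when given, its `proximal_cutoff` (or the supplied
#'   `proximal_cutoff`) is used.
#' @param proximal_cutoff nm (default the fit's stored cutoff, normally
#'   135).
#' @return List of class `proximity_call`: per-component labels, overall
#'   `call`, `proximal_fraction`, cutoff used.
#' @export
classify_proximal_distal <- function(fit, baseline = NULL,
                                     proximal_cutoff = NULL) {
  cutoff <- proximal_cutoff %||%
    (if (!is.null(baseline)) baseline$proximal_cutoff else
      fit$proximal_cutoff)
  comp <- fit$components
  labs <- ifelse(comp$mean < cutoff, "proximal", "distal")
  wp <- sum(comp$weight[labs == "proximal"])
  wd <- sum(comp$weight[labs == "distal"])
  call <- if (min(wp, wd) >= 0.2) "mixed" else
    if (wp >= wd) "proximal" else "distal"
  structure(list(component_labels = labs, call = call,
                 weight_proximal = wp, weight_distal = wd,
                 proximal_fraction = mean(fit$samples < cutoff),
                 proximal_cutoff = cutoff),
            class = "proximity_call")
}

#' @export
print.proximity_call <- function(x, ...) {
  cat(sprintf("<proximity_call: %s (w_prox %.2f, w_dist %.2f, cutoff %g nm)>\n",
              x$call, x$weight_proximal, x$weight_distal,
              x$proximal_cutoff))
  invisible(x)
}

#' Two-dimensional protein-protein association distribution map
#'
#' Expands a fitted 1D distance mixture into a 2D intensity map by pairing
#' each axial Gaussian with a perpendicular Gaussian of the same sigma
#' centered at zero: `M(x, y) = sum_i w_i G(x; mu_i, sigma_i) G(y; 0,
#' sigma_i)`, normalized to unit integral over the grid. The map
#' visualizes proximal vs distal structure within damage foci.
#'
#' @param fit a `distance_fit`.
#' @param extent half-extent of the perpendicular axis and padding of the
#'   axial axis, nm; must cover `max(mean) + 3 max(sd)` (default
#'   `max(mean) + 4 max(sd)`).
#' @param grid_step nm per map pixel; must be below the smallest fitted
#'   sigma (undersampling error otherwise).
#' @return Object of class `association_map`: `grid` (matrix), `x`, `y`
#'   axis coordinates (nm), `grid_step`.
#' @export
association_map <- function(fit, extent = NULL, grid_step = 5) {
  comp <- fit$components
  smax <- max(comp$sd); smin <- min(comp$sd)
  need <- max(comp$mean) + 3 * smax
  extent <- extent %||% (max(comp$mean) + 4 * smax)
  if (extent < need)
    stopf("extent %.3g nm does not cover mu_max + 3 sigma_max = %.3g nm",
          extent, need)
  if (grid_step >= smin)
    stopf("grid_step %g nm >= smallest sigma %g nm: map undersampled",
          grid_step, smin)
  xlo <- min(comp$mean) - 4 * smax
  x <- seq(xlo, extent, by = grid_step)
  half <- ceiling(4 * smax / grid_step)
  y <- seq(-half, half) * grid_step
  M <- matrix(0, length(x), length(y))
  for (i in seq_len(nrow(comp)))
    M <- M + comp$weight[i] *
      outer(stats::dnorm(x, comp$mean[i], comp$sd[i]),
            stats::dnorm(y, 0, comp$sd[i]))
  M <- M / (sum(M) * grid_step^2)
  structure(list(grid = M, x = x, y = y, grid_step = grid_step),
            class = "association_map")
}

#' @export
print.association_map <- function(x, ...) {
  cat(sprintf("<association_map: %d x %d @ %g nm, integral %.6f>\n",
              nrow(x$grid), ncol(x$grid), x$grid_step,
              sum(x$grid) * x$grid_step^2))
  invisible(x)
}

#' @export
plot.association_map <- function(x, ...) {
  graphics::image(x$x, x$y, x$grid, useRaster = TRUE,
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "axial offset (nm)", ylab = "perpendicular offset (nm)",
                  asp = 1, ...)
  invisible(x)
}
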