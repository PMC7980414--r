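#' Pipeline run configuration
#'
#' Validates and fills the knobs shared by the tier runners. All
#' randomness in a run flows from `seed` via per-nucleus derived streams,
#' so any rerun with the same config is byte-identical and any single
#' nucleus is reproducible in isolation.
#'
#' @param ... overrides of the defaults: `pixel_size` (rendering grid,
#'   nm/px, default 20), `smoothing_sigma` (rendering blur in px, default
#'   0.7: the smallest smoothing that makes a single blinking molecule's
#'   footprint segmentable at the 3-px minimum area without degrading
#'   two-source separability at 100 nm),
#'   `threshold_percentile` (segmentation threshold as percentile of
#'   nonzero pixels, default 90), `min_area` (px, default 3),
#'   `n_iterations` (Monte Carlo replicates, default 100), `seed`,
#'   `capture_radius` (nm, default 300), `bin_width` (nm, default 20),
#'   `proximal_cutoff` (nm, default 135), `test_variant` (`"pooled"` or
#'   `"welch"`), `fixed_channel` (default `"naDNA"`), `random_channel`
#'   (default `"A"`).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(pixel_size = 20, smoothing_sigma = 0.7,
              threshold_percentile = 90, min_area = 3L,
              n_iterations = 100L, seed = 1L, capture_radius = 300,
              bin_width = 20, proximal_cutoff = 135,
              test_variant = "pooled",
              fixed_channel = "naDNA", random_channel = "A")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  with(cfg, {
    if (!is.numeric(pixel_size) || pixel_size <= 0)
      stopf("pixel_size must be > 0")
    if (smoothing_sigma < 0) stopf("smoothing_sigma must be >= 0")
    if (threshold_percentile <= 0 || threshold_percentile > 100)
      stopf("threshold_percentile must be in (0, 100]")
    if (min_area < 1) stopf("min_area must be >= 1")
    if (n_iterations < 1) stopf("n_iterations must be >= 1")
    if (capture_radius < 0) stopf("capture_radius must be >= 0")
    if (bin_width <= 0) stopf("bin_width must be > 0")
    if (proximal_cutoff <= 0) stopf("proximal_cutoff must be > 0")
    if (!test_variant %in% c("pooled", "welch"))
      stopf("test_variant must be 'pooled' or 'welch'")
  })
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Render and segment every channel of a scene
#'
#' @param scene a `synthetic_scene`, or a list with `tables` (named list
#'   of [loc_table()]s) and `roi`.
#' @param config a [run_config()].
#' @return Named list of `cluster_set`s, one per channel.
#' @export
segment_scene <- function(scene, config = run_config()) {
  lapply(scene$tables, function(tb) {
    img <- render(tb, scene$roi, pixel_size = config$pixel_size,
                  smoothing_sigma = config$smoothing_sigma)
    segment_clusters(img, pct_threshold(config$threshold_percentile),
                     min_area = config$min_area)
  })
}

#' Tier 1 over a cohort: Monte Carlo colocalization ratios
#'
#' Runs [coloc_ratio()] for every nucleus of a cohort, fixed channel held
#' as imaged and the protein channel randomized within the ROI, and
#' returns (optionally writes) one tidy row per nucleus.
#'
#' @param cohort a [generate_cohort()] result, or a named list of scenes
#'   plus a `manifest` data frame.
#' @param config a [run_config()].
#' @param out_csv optional path; when given, the results are written as
#'   CSV.
#' @return Data frame: `nucleus_id`, `condition`, `time_h`, real counts
#'   and areas, random means/sds, `ratio_count`, `ratio_area`, `seed`.
#' @export
run_tier1 <- function(cohort, config = run_config(), out_csv = NULL) {
  mf <- cohort$manifest
  rows <- lapply(seq_len(nrow(mf)), function(r) {
    id <- mf$nucleus_id[r]
    sc <- cohort$scenes[[id]]
    sets <- segment_scene(sc, config)
    fx <- sets[[config$fixed_channel]]
    rn <- sets[[config$random_channel]]
    if (is.null(fx) || is.null(rn))
      stopf("nucleus '%s' lacks channel '%s' or '%s'", id,
            config$fixed_channel, config$random_channel)
    res <- coloc_ratio(fx, rn, sc$roi, n_iterations = config$n_iterations,
                       rng_seed = derive_seed(config$seed, r))
    data.frame(nucleus_id = id, condition = mf$condition[r],
               time_h = mf$time_h[r],
               n_clusters_fixed = length(fx$clusters),
               n_clusters_random = length(rn$clusters),
               real_pairs = res$real$n_overlapping_pairs,
               real_area_nm2 = res$real$overlap_area_nm2,
               random_mean_pairs = res$random_mean[["n_pairs"]],
               random_sd_pairs = res$random_sd[["n_pairs"]],
               random_mean_area_nm2 = res$random_mean[["overlap_area_nm2"]],
               ratio_count = res$ratio_count,
               ratio_area = res$ratio_area,
               seed = res$seed)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Tier 2 over a cohort: per-focus protein presence
#'
#' @inheritParams run_tier1
#' @param channels the two protein channels to classify against the foci.
#' @return List with `per_focus` (data frame over all nuclei) and
#'   `summary` (one row per nucleus: fractions, counts).
#' @export
run_tier2 <- function(cohort, config = run_config(),
                      channels = c("A", "B"), out_csv = NULL) {
  mf <- cohort$manifest
  per_focus <- list(); summ <- list()
  for (r in seq_len(nrow(mf))) {
    id <- mf$nucleus_id[r]
    sets <- segment_scene(cohort$scenes[[id]], config)
    tab <- classify_foci(sets[[config$fixed_channel]],
                         sets[[channels[1L]]], sets[[channels[2L]]],
                         capture_radius = config$capture_radius)
    if (nrow(tab$records))
      per_focus[[r]] <- cbind(nucleus_id = id, tab$records)
    summ[[r]] <- data.frame(nucleus_id = id, condition = mf$condition[r],
                            time_h = mf$time_h[r],
                            n_foci = tab$n_foci_total,
                            n_neither = tab$n_foci_neither,
                            pct_both = tab$fractions[["both"]],
                            pct_A_only = tab$fractions[["A_only"]],
                            pct_B_only = tab$fractions[["B_only"]])
  }
  out <- list(per_focus = do.call(rbind, per_focus),
              summary = do.call(rbind, summ))
  if (!is.null(out_csv)) {
    utils::write.csv(out$summary, out_csv, row.names = FALSE)
    utils::write.csv(out$per_focus,
                     sub("\\.csv$", "_per_focus.csv", out_csv),
                     row.names = FALSE)
  }
  out
}

#' Tier 3 over a cohort: subfocus distances, mixture fit, association map
#'
#' Pools three-color-positive focus distances across the cohort's nuclei
#' (per condition/time pooling is up to the caller via the cohort passed
#' in), fits the 1-2 component Gaussian model, classifies proximal vs
#' distal, and builds the association map.
#'
#' @inheritParams run_tier2
#' @param out_prefix optional path prefix; writes `<prefix>_distances.csv`,
#'   `<prefix>_fit.json`, `<prefix>_map.txt`.
#' @return List: `distances` (data frame), `fit` (`distance_fit`), `call`
#'   (`proximity_call`), `map` (`association_map`).
#' @export
run_tier3 <- function(cohort, config = run_config(),
                      channels = c("A", "B"), out_prefix = NULL) {
  mf <- cohort$manifest
  dists <- do.call(rbind, lapply(seq_len(nrow(mf)), function(r) {
    id <- mf$nucleus_id[r]
    sets <- segment_scene(cohort$scenes[[id]], config)
    d <- measure_pair_distances(sets[[config$fixed_channel]],
                                sets[[channels[1L]]], sets[[channels[2L]]],
                                capture_radius = config$capture_radius)
    if (nrow(d)) cbind(nucleus_id = id, d) else NULL
  }))
  fit <- fit_distance_distribution(dists$d_nm, bin_width = config$bin_width,
                                   proximal_cutoff = config$proximal_cutoff)
  cl <- classify_proximal_distal(fit)
  map <- association_map(fit)
  if (!is.null(out_prefix)) {
    utils::write.csv(dists, paste0(out_prefix, "_distances.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(k = fit$k, components = fit$components,
           candidates = fit$candidates, n = fit$n,
           proximal_fraction = fit$proximal_fraction,
           call = cl$call),
      paste0(out_prefix, "_fit.json"), digits = NA, auto_unbox = TRUE)
    utils::write.table(map$grid, paste0(out_prefix, "_map.txt"),
                       row.names = FALSE, col.names = FALSE)
  }
  list(distances = dists, fit = fit, call = cl, map = map)
}

#' Kinetic traces from tier-1 results
#'
#' @param tier1 the data frame returned by [run_tier1()].
#' @param config a [run_config()] (test variant).
#' @param control_condition label of the undamaged control group.
#' @param out_csv optional CSV path.
#' @return A `kinetic_trace` data frame (see [aggregate_timecourse()]).
#' @export
run_kinetics <- function(tier1, config = run_config(),
                         control_condition = "control", out_csv = NULL) {
  tr <- aggregate_timecourse(tier1, control_condition = control_condition,
                             variant = config$test_variant)
  if (!is.null(out_csv)) utils::write.csv(tr, out_csv, row.names = FALSE)
  tr
}

#' Simulate a cohort under a run configuration
#'
#' Convenience wrapper deriving the generator seed from the config seed.
#'
#' @param design see [generate_cohort()].
#' @param base_params see [generate_cohort()].
#' @param config a [run_config()].
#' @return A `synthetic_cohort`.
#' @export
simulate_cohort <- function(design, base_params = scene_params(),
                            config = run_config()) {
  generate_cohort(design, base_params, seed = derive_seed(config$seed, 0L))
}
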