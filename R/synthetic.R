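#' Parameters of a synthetic nucleus
#'
#' Bundles the generative model under which every pipeline stage is
#' testable: an elliptical nuclear ROI populated with nascent-DNA (naDNA)
#' foci at hard-core-spaced uniform positions; per-focus Bernoulli
#' occupancy by two proteins; proximal (zero true offset) or distal
#' (150-300 nm offset) arrangement of co-occupied pairs; and the SMLM
#' labeling-error budget — per-molecule antibody displacement (a rigid
#' linker, one fixed vector per molecule per channel, magnitude 10-20 nm),
#' per-molecule localization precision (sigma 5-10 nm applied per
#' localization), blinking multiplicity (Poisson, mean 8 localizations per
#' molecule), and a rigid per-nucleus residual two-color mapping shift of
#' the second protein channel (magnitude 10-20 nm).
#'
#' @param roi_semi_axes ellipse semi-axes (nm).
#' @param n_foci naDNA foci per nucleus.
#' @param n_background spurious (non-focus) protein clusters per protein
#'   channel, named vector `c(A = , B = )`.
#' @param pA,pB per-focus occupancy probabilities of proteins A and B.
#' @param arrangement_mix fraction of co-occupied foci whose pair is
#'   proximal (the rest are distal).
#' @param distal_offset_range nm interval of true distal offsets.
#' @param localization_precision nm interval of per-molecule localization
#'   precision sigma.
#' @param mapping_error nm interval of the residual two-color mapping
#'   shift magnitude.
#' @param antibody_displacement nm interval of the rigid antibody linker
#'   displacement magnitude (applied per label, i.e. per channel).
#' @param localizations_per_molecule mean blinking multiplicity.
#' @param focus_n_localizations mean naDNA localizations per focus.
#' @param focus_sigma nm spatial spread of naDNA localizations in a focus.
#' @param min_spacing nm hard-core minimum distance between focus centers.
#' @param proteins protein channels to generate (`c("A", "B")` or `"A"`).
#' @param nucleus_id label.
#' @param seed integer; the whole scene is deterministic given the seed.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(roi_semi_axes = c(5000, 3500),
                         n_foci = 40L,
                         n_background = c(A = 10L, B = 10L),
                         pA = 0.7, pB = 0.7,
                         arrangement_mix = 0.5,
                         distal_offset_range = c(150, 300),
                         localization_precision = c(5, 10),
                         mapping_error = c(10, 20),
                         antibody_displacement = c(10, 20),
                         localizations_per_molecule = 8,
                         focus_n_localizations = 250,
                         focus_sigma = 80,
                         min_spacing = 800,
                         proteins = c("A", "B"),
                         nucleus_id = "nucleus",
                         seed = 1L) {
  chk_iv <- function(v, nm) {
    if (length(v) != 2L || any(v < 0) || v[1L] > v[2L])
      stopf("%s must be a nonnegative interval c(lo, hi)", nm)
  }
  chk_iv(distal_offset_range, "distal_offset_range")
  chk_iv(localization_precision, "localization_precision")
  chk_iv(mapping_error, "mapping_error")
  chk_iv(antibody_displacement, "antibody_displacement")
  if (pA < 0 || pA > 1 || pB < 0 || pB > 1)
    stopf("occupancy probabilities must be in [0, 1]")
  if (arrangement_mix < 0 || arrangement_mix > 1)
    stopf("arrangement_mix must be in [0, 1]")
  if (n_foci < 0) stopf("n_foci must be >= 0")
  structure(as.list(environment())[names(formals(scene_params))],
            class = "scene_params")
}

# hard-core uniform points in an ROI; error when infeasible
hardcore_in_roi <- function(roi, n, min_spacing, what = "foci") {
  pts <- matrix(NA_real_, n, 2L)
  got <- 0L; tries <- 0L
  max_tries <- 2000L * max(1L, n)
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stopf(paste0("could not place %d %s at %g nm spacing in this ROI; ",
                   "reduce the count or the spacing"), n, what, min_spacing)
    p <- sample_in_roi(roi, 1L)
    if (got == 0L ||
        min((pts[seq_len(got), 1L] - p[1L])^2 +
            (pts[seq_len(got), 2L] - p[2L])^2) >= min_spacing^2) {
      got <- got + 1L
      pts[got, ] <- p
    }
  }
  pts
}

# localizations of one labeled molecule in one channel
emit_molecule <- function(pos, params) {
  ab <- runif_vec(1L, params$antibody_displacement[1L],
                  params$antibody_displacement[2L])
  sig <- stats::runif(1L, params$localization_precision[1L],
                      params$localization_precision[2L])
  n <- stats::rpois(1L, params$localizations_per_molecule)
  if (n == 0L) return(matrix(numeric(0), 0L, 2L))
  cbind(pos[1L] + ab[1L] + stats::rnorm(n, 0, sig),
        pos[2L] + ab[2L] + stats::rnorm(n, 0, sig))
}

finish_table <- function(xy, channel_id, nucleus_id) {
  n <- nrow(xy)
  loc_table(xy[, 1L], xy[, 2L],
            frame = if (n) seq_len(n) else integer(0),
            intensity = if (n) stats::rgamma(n, shape = 2, scale = 500)
                        else numeric(0),
            channel_id = channel_id, nucleus_id = nucleus_id)
}

#' Generate one synthetic nucleus
#'
#' Draws a full multi-channel scene under [scene_params()] and returns the
#' per-channel localization tables, the ROI, and a ground-truth ledger for
#' recovery tests. With all error intervals zeroed and proximal
#' arrangement, co-occupied protein pairs coincide exactly.
#'
#' @param params a [scene_params()].
#' @return List of class `synthetic_scene`: `tables` (named list of
#'   [loc_table()]s: `naDNA` plus the requested protein channels), `roi`,
#'   `truth` (data frame: `focus_id`, true center, `has_A`, `has_B`,
#'   `arrangement`, `offset_nm`; mapping shift as attribute
#'   `mapping_shift`), `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(as.integer(params$seed), {
    roi <- roi_ellipse(params$roi_semi_axes,
                       center = params$roi_semi_axes,
                       nucleus_id = params$nucleus_id)
    nf <- params$n_foci
    centers <- if (nf > 0L)
      hardcore_in_roi(roi, nf, params$min_spacing) else
      matrix(numeric(0), 0L, 2L)
    two <- "B" %in% params$proteins
    has_A <- stats::runif(nf) < params$pA
    has_B <- if (two) stats::runif(nf) < params$pB else rep(FALSE, nf)
    co <- has_A & has_B
    arrangement <- rep(NA_character_, nf)
    arrangement[co] <- ifelse(stats::runif(sum(co)) <
                                params$arrangement_mix,
                              "proximal", "distal")
    offset_nm <- rep(NA_real_, nf)
    offset_nm[co & arrangement == "proximal"] <- 0
    ndist <- sum(co & arrangement == "distal", na.rm = TRUE)
    dist_vec <- runif_vec(ndist, params$distal_offset_range[1L],
                          params$distal_offset_range[2L])
    offset_nm[which(co & arrangement == "distal")] <-
      sqrt(rowSums(dist_vec^2))

    na_xy <- list(); a_xy <- list(); b_xy <- list()
    kd <- 0L
    for (f in seq_len(nf)) {
      nloc <- stats::rpois(1L, params$focus_n_localizations)
      na_xy[[f]] <- cbind(centers[f, 1L] +
                            stats::rnorm(nloc, 0, params$focus_sigma),
                          centers[f, 2L] +
                            stats::rnorm(nloc, 0, params$focus_sigma))
      posA <- centers[f, ]
      if (has_A[f]) a_xy[[length(a_xy) + 1L]] <- emit_molecule(posA, params)
      if (two && has_B[f]) {
        posB <- posA
        if (co[f] && arrangement[f] == "distal") {
          kd <- kd + 1L
          posB <- posA + dist_vec[kd, ]
        }
        b_xy[[length(b_xy) + 1L]] <- emit_molecule(posB, params)
      }
    }
    nbg <- params$n_background
    for (ch in intersect(params$proteins, names(nbg))) {
      nb <- as.integer(nbg[[ch]])
      if (nb > 0L) {
        bgpos <- sample_in_roi(roi, nb)
        for (m in seq_len(nb)) {
          e <- emit_molecule(bgpos[m, ], params)
          if (ch == "A") a_xy[[length(a_xy) + 1L]] <- e
          else b_xy[[length(b_xy) + 1L]] <- e
        }
      }
    }
    bind <- function(l) if (length(l)) do.call(rbind, l) else
      matrix(numeric(0), 0L, 2L)
    map_shift <- c(0, 0)
    b_all <- bind(b_xy)
    if (two) {
      map_shift <- as.numeric(runif_vec(1L, params$mapping_error[1L],
                                        params$mapping_error[2L]))
      if (nrow(b_all)) b_all <- sweep(b_all, 2L, map_shift, "+")
    }
    tables <- list(naDNA = finish_table(bind(na_xy), "naDNA",
                                        params$nucleus_id),
                   A = finish_table(bind(a_xy), "A", params$nucleus_id))
    if (two) tables$B <- finish_table(b_all, "B", params$nucleus_id)
    truth <- data.frame(focus_id = seq_len(nf),
                        x = centers[, 1L], y = centers[, 2L],
                        has_A = has_A, has_B = has_B,
                        arrangement = arrangement, offset_nm = offset_nm)
    attr(truth, "mapping_shift") <- map_shift
    structure(list(tables = tables, roi = roi, truth = truth,
                   params = params),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene '%s': %d foci, channels %s, seed %d>\n",
              x$params$nucleus_id, nrow(x$truth),
              paste(names(x$tables), collapse = "/"),
              as.integer(x$params$seed)))
  invisible(x)
}

#' Generate the in-silico dual-label baseline
#'
#' The analog of imaging one protein species immunostained with two
#' different fluorophores: both channels label the same molecules (zero
#' true offset) with independent antibody displacements, precisions and
#' blinking, and the second channel carries the residual mapping shift.
#' The resulting inter-channel center-of-mass distance distribution is the
#' empirical "complexed" reference that defines the proximal envelope.
#'
#' @param params a [scene_params()]; `n_foci` is read as the number of
#'   molecules, and a larger default ROI is advisable (see
#'   [duallabel_params()]).
#' @return A `synthetic_scene` with channels `A` and `B` (no naDNA) and a
#'   `truth` data frame of molecule positions.
#' @export
generate_duallabel_baseline <- function(params = duallabel_params()) {
  stopifnot(inherits(params, "scene_params"))
  withr::with_seed(as.integer(params$seed), {
    roi <- roi_ellipse(params$roi_semi_axes,
                       center = params$roi_semi_axes,
                       nucleus_id = params$nucleus_id)
    n <- params$n_foci
    pos <- hardcore_in_roi(roi, n, params$min_spacing, what = "molecules")
    a_xy <- list(); b_xy <- list()
    for (m in seq_len(n)) {
      a_xy[[m]] <- emit_molecule(pos[m, ], params)
      b_xy[[m]] <- emit_molecule(pos[m, ], params)
    }
    map_shift <- as.numeric(runif_vec(1L, params$mapping_error[1L],
                                      params$mapping_error[2L]))
    bind <- function(l) if (length(l)) do.call(rbind, l) else
      matrix(numeric(0), 0L, 2L)
    b_all <- bind(b_xy)
    if (nrow(b_all)) b_all <- sweep(b_all, 2L, map_shift, "+")
    truth <- data.frame(focus_id = seq_len(n), x = pos[, 1L],
                        y = pos[, 2L], has_A = TRUE, has_B = TRUE,
                        arrangement = "proximal", offset_nm = 0)
    attr(truth, "mapping_shift") <- map_shift
    structure(list(tables = list(A = finish_table(bind(a_xy), "A",
                                                  params$nucleus_id),
                                 B = finish_table(b_all, "B",
                                                  params$nucleus_id)),
                   roi = roi, truth = truth, params = params),
              class = "synthetic_scene")
  })
}

#' Default parameters for the dual-label baseline
#'
#' 1000 molecules in a large ellipse at 250 nm hard-core spacing so that
#' neighboring molecules stay individually segmentable, with the stated
#' error-budget defaults.
#'
#' @param n_molecules number of dual-labeled molecules.
#' @param seed integer seed.
#' @param ... overrides passed to [scene_params()].
#' @return A [scene_params()].
#' @export
duallabel_params <- function(n_molecules = 1000L, seed = 1L, ...) {
  scene_params(roi_semi_axes = c(12000, 8000), n_foci = n_molecules,
               n_background = c(A = 0L, B = 0L), pA = 1, pB = 1,
               arrangement_mix = 1, min_spacing = 250,
               nucleus_id = "duallabel", seed = seed, ...)
}

#' Generate a labeled cohort of synthetic nuclei
#'
#' Expands a condition-by-time design into per-nucleus scenes with derived
#' seeds, recording the planted parameters in a manifest consumable by the
#' kinetics layer.
#'
#' @param design data frame with columns `condition`, `time_h`,
#'   `n_nuclei`, plus optional per-row overrides of [scene_params()]
#'   fields (e.g. `pA`, `arrangement_mix`, `n_foci`).
#' @param base_params the [scene_params()] shared by all nuclei.
#' @param seed master seed; per-nucleus seeds are derived from it so each
#'   nucleus is reproducible in isolation.
#' @return List of class `synthetic_cohort`: `scenes` (named list of
#'   `synthetic_scene`s) and `manifest` (data frame `nucleus_id`,
#'   `condition`, `time_h`, `seed`).
#' @export
generate_cohort <- function(design, base_params = scene_params(),
                            seed = 1L) {
  if (!nrow(design)) stopf("cohort design is empty")
  need <- c("condition", "time_h", "n_nuclei")
  miss <- setdiff(need, names(design))
  if (length(miss)) stopf("design missing column(s): %s",
                          paste(miss, collapse = ", "))
  override_cols <- intersect(names(design),
                             setdiff(names(formals(scene_params)),
                                     c("seed", "nucleus_id")))
  scenes <- list(); rows <- list()
  k <- 0L
  for (r in seq_len(nrow(design))) {
    for (i in seq_len(design$n_nuclei[r])) {
      k <- k + 1L
      id <- sprintf("%s_t%g_n%02d", design$condition[r],
                    design$time_h[r], i)
      if (!is.null(scenes[[id]])) stopf("duplicate nucleus id '%s'", id)
      p <- base_params
      for (cn in override_cols) {
        v <- design[[cn]][r]
        if (!is.na(v)) p[[cn]] <- v
      }
      p$nucleus_id <- id
      p$seed <- derive_seed(seed, k)
      scenes[[id]] <- generate_scene(p)
      rows[[k]] <- data.frame(nucleus_id = id,
                              condition = design$condition[r],
                              time_h = design$time_h[r],
                              seed = p$seed)
    }
  }
  structure(list(scenes = scenes, manifest = do.call(rbind, rows)),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' One localization CSV per channel per nucleus (the same dialect
#' [read_localizations()] reads by default), one ROI vertex CSV per
#' nucleus, a manifest CSV, and the ground truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return The manifest with file-path columns added, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mf <- cohort$manifest
  paths <- lapply(seq_len(nrow(mf)), function(r) {
    id <- mf$nucleus_id[r]
    sc <- cohort$scenes[[id]]
    files <- c()
    for (ch in names(sc$tables)) {
      f <- file.path(dir, sprintf("%s_%s.csv", id, ch))
      write_localizations(sc$tables[[ch]], f)
      files[paste0("file_", ch)] <- f
    }
    rf <- file.path(dir, sprintf("%s_roi.csv", id))
    utils::write.csv(data.frame(x = sc$roi$vertices[, 1L],
                                y = sc$roi$vertices[, 2L]),
                     rf, row.names = FALSE)
    files["file_roi"] <- rf
    tf <- file.path(dir, sprintf("%s_truth.json", id))
    jsonlite::write_json(sc$truth, tf, digits = NA)
    files["file_truth"] <- tf
    as.data.frame(as.list(files))
  })
  mf <- cbind(mf, do.call(rbind, paths))
  utils::write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}
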