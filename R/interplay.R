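#' Classify nascent-DNA foci by two-protein presence
#'
#' Tier 2 of the analysis. Each nascent-DNA (naDNA) focus is scored for the
#' presence of each of two costained proteins: a protein is present iff at
#' least one of its clusters shares a rendering pixel with the focus
#' cluster (optionally dilated by a capture radius for sensitivity
#' analysis). Protein signal not colocalized with naDNA is thereby excluded
#' so that only repair-associated signal is analyzed. Fractions
#' (both / A-only / B-only) are reported over the foci positive for at
#' least one of the two proteins; foci with neither are counted alongside,
#' not in the denominator.
#'
#' @param naDNA `cluster_set` of nascent-DNA foci.
#' @param setA,setB `cluster_set`s of the two protein channels, on the same
#'   grid as `naDNA`.
#' @param capture_radius nm of dilation applied to the focus mask before
#'   the presence test (default 0: plain pixel overlap).
#' @return Object of class `focus_interplay`: `records` (data frame
#'   `focus_id`, `has_A`, `has_B`), `fractions` (named percentages `both`,
#'   `A_only`, `B_only` over the default denominator), `n_foci_total`,
#'   `n_foci_neither`, `denominator_rule`, channel labels.
#' @export
classify_foci <- function(naDNA, setA, setB, capture_radius = 0) {
  if (!same_grid(naDNA, setA) || !same_grid(naDNA, setB))
    stopf("all three cluster sets must share one rendering grid")
  labA <- label_matrix(setA)
  labB <- label_matrix(setB)
  rec <- do.call(rbind, lapply(naDNA$clusters, function(f) {
    ij <- dilate_pixels(f$pixels, capture_radius, naDNA$pixel_size,
                        naDNA$dim)
    idx <- cbind(ij[, 1L], ij[, 2L])
    data.frame(focus_id = f$cluster_id,
               has_A = any(labA[idx] > 0L),
               has_B = any(labB[idx] > 0L))
  }))
  if (is.null(rec))
    rec <- data.frame(focus_id = integer(), has_A = logical(),
                      has_B = logical())
  interplay_table(rec, channel_A = setA$channel_id,
                  channel_B = setB$channel_id,
                  nucleus_id = naDNA$nucleus_id)
}

#' Build a focus-interplay table from per-focus presence calls
#'
#' @param records data frame with `focus_id`, `has_A`, `has_B`.
#' @param channel_A,channel_B,nucleus_id labels.
#' @return A `focus_interplay` object (see [classify_foci()]).
#' @export
interplay_table <- function(records, channel_A = "A", channel_B = "B",
                            nucleus_id = "nucleus") {
  pos <- records$has_A | records$has_B
  n_pos <- sum(pos)
  fr <- if (n_pos > 0L)
    c(both = 100 * sum(records$has_A & records$has_B) / n_pos,
      A_only = 100 * sum(records$has_A & !records$has_B) / n_pos,
      B_only = 100 * sum(!records$has_A & records$has_B) / n_pos)
  else c(both = NA_real_, A_only = NA_real_, B_only = NA_real_)
  structure(list(records = records, fractions = fr,
                 n_foci_total = nrow(records),
                 n_foci_neither = sum(!pos),
                 denominator_rule = "foci positive for >= 1 protein",
                 channel_A = channel_A, channel_B = channel_B,
                 nucleus_id = nucleus_id),
            class = "focus_interplay")
}

#' @export
print.focus_interplay <- function(x, ...) {
  cat(sprintf("<focus_interplay '%s' (%s/%s): %d foci (%d neither)>\n",
              x$nucleus_id, x$channel_A, x$channel_B, x$n_foci_total,
              x$n_foci_neither))
  if (all(is.finite(x$fractions)))
    cat(sprintf("  both %.1f%% | %s only %.1f%% | %s only %.1f%%\n",
                x$fractions[["both"]], x$channel_A,
                x$fractions[["A_only"]], x$channel_B,
                x$fractions[["B_only"]]))
  invisible(x)
}

#' Pool focus-interplay tables across nuclei
#'
#' Default pooling concatenates per-focus records across nuclei before
#' computing fractions; per-cell averaging of fractions is available as an
#' alternative summary.
#'
#' @param tables list of `focus_interplay` objects for one condition.
#' @param method `"pooled"` (default) or `"per_cell"` (mean of per-nucleus
#'   fractions).
#' @return For `"pooled"`, one `focus_interplay`; for `"per_cell"`, a named
#'   numeric of mean fractions.
#' @export
pool_interplay <- function(tables, method = c("pooled", "per_cell")) {
  method <- match.arg(method)
  if (method == "pooled") {
    rec <- do.call(rbind, lapply(tables, function(t) t$records))
    return(interplay_table(rec, channel_A = tables[[1L]]$channel_A,
                           channel_B = tables[[1L]]$channel_B,
                           nucleus_id = "pooled"))
  }
  fr <- do.call(rbind, lapply(tables, function(t) t$fractions))
  colMeans(fr, na.rm = TRUE)
}

#' Dependence and conditional-recruitment summary
#'
#' Interpretive layer over the interplay fractions: conditional presence
#' probabilities P(A | B) and P(B | A) among protein-positive foci, the
#' solo-fraction asymmetry, and a dependence flag — a protein is flagged
#' dependent on its partner when its solo fraction falls below the cutoff
#' (default 5%), i.e. it is essentially never recruited without the
#' partner.
#'
#' @param table a `focus_interplay`.
#' @param solo_cutoff dependence cutoff on the solo fraction, in percent.
#' @return List of class `dependence_summary`.
#' @export
dependence_score <- function(table, solo_cutoff = 5) {
  r <- table$records
  nA <- sum(r$has_A); nB <- sum(r$has_B)
  both <- sum(r$has_A & r$has_B)
  if (sum(r$has_A | r$has_B) == 0L)
    stopf("no protein-positive foci; fractions undefined (0/0)")
  fr <- table$fractions
  structure(list(p_A_given_B = if (nB > 0L) both / nB else NA_real_,
                 p_B_given_A = if (nA > 0L) both / nA else NA_real_,
                 solo_asymmetry = fr[["A_only"]] - fr[["B_only"]],
                 A_dependent_on_B = is.finite(fr[["A_only"]]) &&
                   fr[["A_only"]] < solo_cutoff,
                 B_dependent_on_A = is.finite(fr[["B_only"]]) &&
                   fr[["B_only"]] < solo_cutoff,
                 solo_cutoff = solo_cutoff,
                 channel_A = table$channel_A, channel_B = table$channel_B),
            class = "dependence_summary")
}

#' @export
print.dependence_summary <- function(x, ...) {
  cat(sprintf("<dependence_summary %s/%s: P(A|B)=%.3f P(B|A)=%.3f>\n",
              x$channel_A, x$channel_B, x$p_A_given_B, x$p_B_given_A))
  if (x$A_dependent_on_B)
    cat(sprintf("  %s flagged dependent on %s (solo < %g%%)\n",
                x$channel_A, x$channel_B, x$solo_cutoff))
  if (x$B_dependent_on_A)
    cat(sprintf("  %s flagged dependent on %s (solo < %g%%)\n",
                x$channel_B, x$channel_A, x$solo_cutoff))
  invisible(x)
}
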