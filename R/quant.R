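## Conversion of raw junction counts into molecular-species frequencies,
## background subtraction, and ablation metrics.
##
## The frequency model assumes sequencing depth is proportional to
## population fraction and that each molecule carries at most one
## deletion.  For deletion i with supporting reads x_i, mappability
## factor delta_i and deletant length L_i = L_u - deleted bases:
##
##   f_i = L_u d_i x_i / (L_r r_t - sum_j L_j d_j x_j + sum_j L_u d_j x_j)
##
## with the upper-bound approximation f_i <= L_u d_i x_i / (L_r r_t).

DELTA_CAP <- 10

#' Mappability factor for a junction from a control depth profile
#'
#' The median control depth divided by the mean of the control depth at
#' the two positions defining the junction.  When both junction positions
#' have zero control depth the factor is capped at `r DELTA_CAP` and the
#' junction flagged low-mappability.
#'
#' @param control_depth Numeric vector of per-position control depth over
#'   `[1, L_u]`.
#' @param span Span data.frame ([deletion_span()]).
#' @return data.frame with columns `delta_i`, `low_mappability`.
#' @export
mappability_factor <- function(control_depth, span) {
  med <- median(control_depth)
  if (med <= 0) stop("control depth profile has non-positive median")
  if (nrow(span) == 0L)
    return(data.frame(delta_i = numeric(), low_mappability = logical()))
  at <- (control_depth[span$ls5] + control_depth[span$hs5]) / 2
  low <- at == 0
  delta <- ifelse(low, DELTA_CAP, med / at)
  data.frame(delta_i = pmin(delta, ifelse(low, DELTA_CAP, Inf)),
             low_mappability = low)
}

#' Convert a deletion catalog into a frequency table
#'
#' Applies the depth-proportionality model to express every junction's
#' supporting-read count as a fraction of the mtDNA population, with the
#' remainder assigned to the undeleted species (`f_u`).  Also reports the
#' upper-bound approximation for each junction.
#'
#' The frequency model equates each junction's supporting-read count with
#' the average sequencing depth of its species, i.e., it expects the
#' count of *all* reads overlapping the junction.  A split-read caller
#' with a minimum anchor length only detects reads with at least
#' `min_anchor` bases on both sides, undercounting by the deterministic
#' factor `(L_r - 2 min_anchor + 1) / L_r`.  When the catalog records the
#' anchor length used (as [build_catalog()] catalogs do), the counts are
#' rescaled accordingly before entering the model (`anchor_correction`).
#'
#' @param catalog A `deletion_catalog` from [build_catalog()].
#' @param ref A [circular_reference()].
#' @param control_depth Optional control-sample depth profile used for
#'   mappability factors; when absent, `delta_i = 1` for all junctions
#'   (recorded in the `delta_source` attribute).
#' @param anchor_correction Rescale detected counts to
#'   junction-overlapping equivalents (only applies when the catalog
#'   carries its `min_anchor`).
#' @param min_anchor Override for the anchor length used in the
#'   correction (defaults to the catalog's own record).
#' @return A `frequency_table`: list with `table` (data.frame: `ls5`,
#'   `hs5`, `x_i` as recorded, `delta_i`, `L_i`, `length`, `f_i`,
#'   `f_i_bound`, `f_i_bg`, `wraps`, `possible_insertion`,
#'   `low_mappability`), and scalars `r_t`, `r_u`, `L_r`, `L_u`, `f_u`,
#'   `sample_id`, `delta_source`.
#' @export
frequencies <- function(catalog, ref, control_depth = NULL,
                        anchor_correction = TRUE, min_anchor = NULL) {
  if (catalog$r_t <= 0L) stop("catalog has no mapped reads (r_t = 0)")
  if (catalog$L_r <= 0) stop("catalog has non-positive mean read length")
  calls <- catalog$calls
  L_u <- ref$length
  if (is.null(min_anchor)) min_anchor <- catalog$min_anchor
  if (!is.numeric(min_anchor) || !length(min_anchor)) min_anchor <- NULL
  if (is.null(control_depth)) {
    dd <- data.frame(delta_i = rep(1, nrow(calls)),
                     low_mappability = rep(FALSE, nrow(calls)))
    delta_source <- "none (delta_i = 1)"
  } else {
    dd <- mappability_factor(control_depth, calls)
    delta_source <- "control depth profile"
  }
  L_i <- L_u - calls$length
  x_eff <- calls$x_i
  if (isTRUE(anchor_correction) && !is.null(min_anchor) &&
      nrow(calls) > 0L) {
    W <- catalog$L_r - 2 * min_anchor + 1
    if (W <= 0) stop("mean read length too short for the anchor length")
    x_eff <- calls$x_i * catalog$L_r / W
  }
  num <- L_u * dd$delta_i * x_eff
  denom <- catalog$L_r * catalog$r_t -
    sum(L_i * dd$delta_i * x_eff) + sum(num)
  if (denom <= 0) stop("infeasible frequency computation: denominator <= 0")
  f_i <- num / denom
  bound <- num / (catalog$L_r * catalog$r_t)
  tab <- data.frame(ls5 = calls$ls5, hs5 = calls$hs5, x_i = calls$x_i,
                    delta_i = dd$delta_i, L_i = L_i, length = calls$length,
                    f_i = f_i, f_i_bound = bound, f_i_bg = f_i,
                    wraps = calls$wraps,
                    possible_insertion = calls$possible_insertion,
                    low_mappability = dd$low_mappability)
  r_u <- catalog$r_t - sum(L_i * dd$delta_i * x_eff) / catalog$L_r
  structure(list(table = tab, r_t = catalog$r_t, r_u = r_u,
                 L_r = catalog$L_r, L_u = L_u, f_u = 1 - sum(f_i),
                 sample_id = catalog$sample_id, delta_source = delta_source),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf(
    "<frequency_table> %s: %d junctions, f_u = %.4g, total deletion mass = %.4g\n",
    x$sample_id, nrow(x$table), x$f_u, sum(x$table$f_i_bg)))
  invisible(x)
}

#' Subtract a control background from a frequency table
#'
#' Per exact junction (ls5, hs5; junctions are left-aligned so no fuzzy
#' matching is needed), subtracts the mean control frequency, flooring at
#' zero.  Junctions absent from the controls subtract nothing.
#'
#' @param freqs A `frequency_table`.
#' @param controls A `frequency_table` or list of them; the per-junction
#'   mean of `f_i` across all supplied controls is subtracted (a junction
#'   absent from a control contributes zero to its mean).
#' @return The `frequency_table` with updated `f_i_bg`.
#' @export
subtract_background <- function(freqs, controls) {
  if (inherits(controls, "frequency_table")) controls <- list(controls)
  tab <- freqs$table
  if (length(controls) == 0L || nrow(tab) == 0L) return(freqs)
  key <- paste(tab$ls5, tab$hs5)
  ctl <- numeric(length(key))
  for (ct in controls) {
    m <- match(key, paste(ct$table$ls5, ct$table$hs5))
    ctl <- ctl + ifelse(is.na(m), 0, ct$table$f_i[m])
  }
  ctl <- ctl / length(controls)
  freqs$table$f_i_bg <- pmax(0, tab$f_i - ctl)
  freqs
}

#' Ablation level at biopsy
#'
#' The fraction of mtDNA sequence lost to deletions:
#' `sum_i f_i * (L_u - L_i) / L_u`, computed from background-subtracted
#' frequencies.  Equals the area above the remaining-fraction curve.
#'
#' @param freqs A `frequency_table`.
#' @return Ablation as a fraction in `[0, 1)`.
#' @export
ablation_at_biopsy <- function(freqs) {
  sum(freqs$table$f_i_bg * freqs$table$length / freqs$L_u)
}

#' Project ablation back to the age of disease onset
#'
#' Linear interpolation between zero ablation at birth and the measured
#' level at biopsy: `a_onset = a_biopsy * y_onset / y_biopsy`.
#'
#' @param a_biopsy Ablation fraction at biopsy.
#' @param y_onset,y_biopsy Ages in years, `0 <= y_onset <= y_biopsy`.
#' @return Ablation fraction at onset.
#' @export
ablation_at_onset <- function(a_biopsy, y_onset, y_biopsy) {
  if (y_biopsy <= 0) stop("y_biopsy must be positive")
  if (any(y_onset < 0) || any(y_onset > y_biopsy))
    stop("y_onset must lie in [0, y_biopsy]")
  a_biopsy * y_onset / y_biopsy
}

#' Per-position fraction of mtDNA remaining
#'
#' `profile[p] = 1 - sum` of `f_i_bg` over deletions whose deleted arc
#' covers position `p`.  The mean of `1 - profile` equals
#' [ablation_at_biopsy()].
#'
#' @param freqs A `frequency_table`.
#' @return Numeric vector of length `L_u` in `[0, 1]`.
#' @export
remaining_fraction_profile <- function(freqs) {
  lost <- numeric(freqs$L_u)
  tab <- freqs$table
  for (i in seq_len(nrow(tab))) {
    if (tab$f_i_bg[i] == 0) next
    if (tab$wraps[i]) {
      lost[tab$ls5[i]:freqs$L_u] <- lost[tab$ls5[i]:freqs$L_u] + tab$f_i_bg[i]
      lost[1:tab$hs5[i]] <- lost[1:tab$hs5[i]] + tab$f_i_bg[i]
    } else {
      idx <- tab$ls5[i]:tab$hs5[i]
      lost[idx] <- lost[idx] + tab$f_i_bg[i]
    }
  }
  1 - lost
}

## circular overlap between a deleted arc and a feature interval
span_overlaps_interval <- function(span, start, end, L) {
  # expand both onto the doubled axis and test interval intersection
  s1 <- span$ls5
  e1 <- span$ls5 + span_len_raw(span, L) - 1L
  f1 <- start
  f2 <- if (end >= start) end else end + L
  any_overlap <- function(a1, a2, b1, b2) a1 <= b2 & a2 >= b1
  any_overlap(s1, e1, f1, f2) | any_overlap(s1, e1, f1 + L, f2 + L) |
    any_overlap(s1 + L, e1 + L, f1, f2)
}

span_len_raw <- function(span, L) {
  ifelse(span$wraps, L - span$ls5 + span$hs5 + 1L, span$hs5 - span$ls5 + 1L)
}

#' Resolve named features to reference intervals
#'
#' @param fmap A [feature_map()].
#' @param names Character vector of feature names or categories; a name
#'   matching a category (e.g., `"tRNA"`) selects all features of that
#'   category.
#' @return data.frame of intervals (`start`, `end`).
#' @export
feature_positions <- function(fmap, names) {
  df <- as.data.frame(fmap)
  sel <- df$name %in% names | df$category %in% names
  unknown <- setdiff(names, c(df$name, df$category))
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "))
  df[sel, c("start", "end"), drop = FALSE]
}

#' Ablation of named feature sets, with multiplicative combination
#'
#' For each feature set s, `a_s` is the summed background-subtracted
#' frequency of deletions that remove any base of the set.  When
#' `combine = TRUE` the sets are treated as independently required
#' systems and the combined deficiency is `1 - prod(1 - a_s)`.
#'
#' @param freqs A `frequency_table`.
#' @param fmap A [feature_map()].
#' @param feature_sets Named list; each element a character vector of
#'   feature names/categories (see [feature_positions()]).
#' @param combine Whether to report the multiplicative combination.
#' @return List with `per_set` (named numeric) and, when requested,
#'   `combined`.
#' @export
feature_ablation <- function(freqs, fmap, feature_sets, combine = TRUE) {
  tab <- freqs$table
  per_set <- vapply(feature_sets, function(fnames) {
    iv <- feature_positions(fmap, fnames)
    if (nrow(tab) == 0L || nrow(iv) == 0L) return(0)
    hit <- rep(FALSE, nrow(tab))
    for (j in seq_len(nrow(iv)))
      hit <- hit | span_overlaps_interval(tab, iv$start[j], iv$end[j],
                                          freqs$L_u)
    sum(tab$f_i_bg[hit])
  }, 0.0)
  out <- list(per_set = per_set)
  if (combine) out$combined <- 1 - prod(1 - per_set)
  out
}

#' Muscle-sample geometry: boundary frequency for multi-fiber species
#'
#' From sample mass and tissue density, approximates the sample as a cube,
#' takes one face as the cross-section, and divides by the mean
#' single-fiber cross-sectional area to count truncated fibers.  The
#' reciprocal of the fiber count is the population frequency above which a
#' deletion species must occupy more than one fiber.
#'
#' @param mass_mg Sample mass (mg).
#' @param density_mg_per_uL Tissue density (mg/uL).
#' @param fiber_area_um2 Mean fiber cross-sectional area (um^2).
#' @param nuclei_total Total nuclei in the sample (optional).
#' @param mtdna_total Total mtDNA circles in the sample (optional).
#' @return List: `volume_uL`, `side_mm`, `face_area_mm2`, `fibers`,
#'   `boundary_frequency`, and when supplied `nuclei_per_fiber`,
#'   `mtdna_per_fiber`, `single_copy_frequency`.
#' @export
multi_fiber_boundaries <- function(mass_mg = 20, density_mg_per_uL = 1.06,
                                   fiber_area_um2 = 3630,
                                   nuclei_total = NULL, mtdna_total = NULL) {
  stopifnot(mass_mg > 0, density_mg_per_uL > 0, fiber_area_um2 > 0)
  volume_uL <- mass_mg / density_mg_per_uL          # 1 uL = 1 mm^3
  side_mm <- volume_uL^(1 / 3)
  face_area_mm2 <- side_mm^2
  fibers <- face_area_mm2 * 1e6 / fiber_area_um2
  out <- list(volume_uL = volume_uL, side_mm = side_mm,
              face_area_mm2 = face_area_mm2, fibers = fibers,
              boundary_frequency = 1 / fibers)
  if (!is.null(nuclei_total)) out$nuclei_per_fiber <- nuclei_total / fibers
  if (!is.null(mtdna_total)) {
    out$mtdna_per_fiber <- mtdna_total / fibers
    out$single_copy_frequency <- 1 / mtdna_total
  }
  out
}

#' Write frequency-table artifacts
#'
#' @param freqs A `frequency_table`.
#' @param dir Output directory.
#' @return Invisibly, paths written.
#' @export
write_frequencies <- function(freqs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ft <- file.path(dir, "frequencies.tsv")
  write.table(freqs$table, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- file.path(dir, "remaining_fraction.tsv")
  write.table(data.frame(pos = seq_len(freqs$L_u),
                         remaining = remaining_fraction_profile(freqs)),
              prof, sep = "\t", quote = FALSE, row.names = FALSE)
  ab <- file.path(dir, "ablation.json")
  jsonlite::write_json(list(sample_id = freqs$sample_id,
                            a_biopsy = ablation_at_biopsy(freqs),
                            f_u = freqs$f_u,
                            delta_source = freqs$delta_source),
                       ab, auto_unbox = TRUE, digits = NA)
  invisible(c(ft, prof, ab))
}
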