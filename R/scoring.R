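## IHC quantification: H-score, TIL score, replicate-core aggregation,
## per-core marker summaries, and the median split used for survival
## stratification.

#' Intensity-bin fractions for one core
#'
#' Fractions of cells staining at intensity 0, 1+ (weak), 2+ (moderate)
#' and 3+ (strong). Must sum to 1 within 1e-9.
#'
#' @param f0,f1,f2,f3 fractions in `[0, 1]`.
#' @return numeric vector `c(f0, f1, f2, f3)` of class `ihc_bins`.
#' @export
ihc_bins <- function(f0, f1, f2, f3) {
  v <- c(f0 = f0, f1 = f1, f2 = f2, f3 = f3)
  if (any(!is.finite(v)) || any(v < -1e-12) || any(v > 1 + 1e-12))
    stopf("bin fractions must lie in [0, 1]")
  if (abs(sum(v) - 1) > 1e-9)
    stopf("bin fractions must sum to 1 (got %.12f)", sum(v))
  structure(v, class = "ihc_bins")
}

#' H-score from intensity-bin fractions
#'
#' The pathology H-score: `1 x (% weak) + 2 x (% moderate) + 3 x (% strong)`,
#' i.e. `100 * (f1 + 2*f2 + 3*f3)` on the 0-300 scale.
#'
#' @param bins an [ihc_bins()] object, a numeric vector `(f0, f1, f2, f3)`,
#'   or a data.frame with columns `f0..f3` (one row per core).
#' @return numeric H-score(s) in `[0, 300]`.
#' @export
h_score <- function(bins) {
  if (is.data.frame(bins)) {
    return(vapply(seq_len(nrow(bins)), function(i)
      h_score(ihc_bins(bins$f0[i], bins$f1[i], bins$f2[i], bins$f3[i])), 0))
  }
  if (!inherits(bins, "ihc_bins")) bins <- ihc_bins(bins[1], bins[2], bins[3], bins[4])
  unname(100 * (bins[2] + 2 * bins[3] + 3 * bins[4]))
}

#' TIL score from lymphocyte counts per high-power field
#'
#' Ordinal 0-3 binning of tumor-infiltrating lymphocytes per high-power
#' field (hpf): 3 for more than 20 TIL/hpf, 2 for 11-20, 1 for 1-10,
#' 0 for fewer than 1. Raw pathologist counts are integers; averaged or
#' otherwise fractional inputs falling in the uncovered gap (10, 11) are
#' rounded half-up to the nearest bin boundary first (10.4 -> 10 -> score 1,
#' 10.6 -> 11 -> score 2).
#'
#' @param tils_per_hpf nonnegative numeric vector.
#' @return integer scores in 0..3.
#' @export
til_score <- function(tils_per_hpf) {
  if (any(!is.finite(tils_per_hpf)) || any(tils_per_hpf < 0))
    stopf("TIL counts must be finite and nonnegative")
  x <- tils_per_hpf
  gap <- x > 10 & x < 11
  x[gap] <- round_half_up(x[gap], 0)
  ifelse(x > 20, 3L, ifelse(x >= 11, 2L, ifelse(x >= 1, 1L, 0L)))
}

#' Average replicate-core scores for one patient
#'
#' TMA designs place several consecutive-section cores per patient
#' (typically 3); per-patient scores are the arithmetic mean over the
#' replicate cores.
#'
#' @param scores numeric vector, one value per replicate core.
#' @return scalar mean.
#' @export
aggregate_replicates <- function(scores) {
  if (!length(scores)) stopf("no replicate scores to aggregate")
  if (any(!is.finite(scores))) stopf("non-finite replicate score")
  mean(scores)
}

#' Positive-cell fraction and density for one core
#'
#' @param core a [core_table].
#' @param marker flag column name (see [cell_panel()]).
#' @return named numeric `c(fraction, density_per_mm2)`; fraction is
#'   positives over all cells (0 for an empty core), density is positives
#'   per square millimetre of core area.
#' @export
positive_fraction_and_density <- function(core, marker) {
  stopifnot(inherits(core, "core_table"))
  if (!marker %in% names(core$cells))
    stopf("marker '%s' absent from core '%s'", marker, core$core_id)
  n <- nrow(core$cells)
  pos <- if (n) sum(core$cells[[marker]], na.rm = TRUE) else 0
  c(fraction = if (n) pos / n else 0,
    density_per_mm2 = pos / (core$area_um2 / 1e6))
}

#' Per-patient marker scores from core tables
#'
#' Computes a per-core summary for one marker and averages replicate cores
#' per patient ([aggregate_replicates()]).
#'
#' @param tables list of [core_table] objects.
#' @param marker flag column name.
#' @param kind `"positive_fraction"` or `"density_per_mm2"`.
#' @return data.frame: `patient_id, marker, kind, value, n_replicates`.
#' @export
marker_scores <- function(tables, marker,
                          kind = c("density_per_mm2", "positive_fraction")) {
  kind <- match.arg(kind)
  per_core <- data.frame(
    patient_id = vapply(tables, function(tb) tb$patient_id, ""),
    value = vapply(tables, function(tb)
      positive_fraction_and_density(tb, marker)[[kind]], 0),
    stringsAsFactors = FALSE)
  agg <- stats::aggregate(value ~ patient_id, per_core, mean)
  nrep <- stats::aggregate(value ~ patient_id, per_core, length)
  data.frame(patient_id = agg$patient_id, marker = marker, kind = kind,
             value = agg$value, n_replicates = nrep$value,
             stringsAsFactors = FALSE)
}

#' Median-split stratification labels
#'
#' Splits patients into high/low groups at the cohort median of a marker
#' score. "High" means strictly greater than the median; with skewed
#' markers whose median is 0 (common for sparse NK markers) this puts all
#' zero-score patients in the low group, which is what makes a median
#' split of such markers possible at all.
#'
#' @param scores data.frame with `patient_id` and `value` (and optionally
#'   `marker`), or a named numeric vector.
#' @return data.frame `patient_id, marker, label, threshold`; `label` is
#'   `"high"` or `"low"`.
#' @export
stratify_by_median <- function(scores) {
  if (is.numeric(scores)) {
    scores <- data.frame(patient_id = names(scores) %||%
                           as.character(seq_along(scores)),
                         value = unname(scores), stringsAsFactors = FALSE)
  }
  if (nrow(scores) < 2) stopf("median stratification needs >= 2 patients")
  med <- stats::median(scores$value)
  lab <- ifelse(scores$value > med, "high", "low")
  if (all(lab == "low") && length(unique(scores$value)) == 1L)
    warnf("all scores identical (%.4g): degenerate split, all labelled low",
          med)
  data.frame(patient_id = scores$patient_id,
             marker = scores$marker %||% rep(NA_character_, nrow(scores)),
             label = lab, threshold = med, stringsAsFactors = FALSE)
}
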