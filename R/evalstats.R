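#' Per-organ visibility coverage
#'
#' Automated stand-in for the reader visibility assessment: for each organ
#' instance (left/right kidney, left/right ureter — optionally split into
#' proximal/mid/distal thirds by arc-length fraction — and bladder),
#' the fraction of its ground-truth voxels contained in a focused-view
#' mask. Kidney side is determined from the x centroid of connected
#' components; ureter voxels are assigned a side and an arc position from
#' the phantom's centrelines (standing in for anatomical landmarks).
#'
#' @param truth a [label_volume()] of ground-truth organ labels.
#' @param mask logical array on the same grid.
#' @param centerlines optional per-side ureter centrelines as produced by
#'   [generate_phantom()] (`list(left = list(control, total), ...)`);
#'   required for `split_ureters`.
#' @param split_ureters report ureter thirds (proximal/mid/distal, by arc
#'   fractions 0-1/3, 1/3-2/3, 2/3-1)?
#' @return Data frame with columns `organ`, `side`, `segment`,
#'   `n_voxels`, `coverage` (NA where the organ has no truth voxels).
#' @export
organ_coverage <- function(truth, mask, centerlines = NULL,
                           split_ureters = FALSE) {
  stopifnot(inherits(truth, "label_volume"))
  if (!identical(dim(mask), dim(truth$voxels)))
    stop("mask grid does not match truth grid")
  mask <- as.logical(mask)
  lab <- as.integer(truth$voxels)
  codes <- label_codes()
  rows <- list()
  add <- function(organ, side, segment, sel) {
    n <- sum(sel)
    cov <- if (n == 0) NA_real_ else sum(mask[sel]) / n
    rows[[length(rows) + 1L]] <<- data.frame(
      organ = organ, side = side, segment = segment,
      n_voxels = n, coverage = cov, stringsAsFactors = FALSE)
  }

  # kidneys: split by connected component, side from x centroid
  kmask <- array(lab == codes[["kidney"]], dim = dim(truth$voxels))
  if (any(kmask)) {
    comp <- connected_components(kmask)
    k <- attr(comp, "n_components")
    cx <- vapply(seq_len(k), function(c)
      mean(linear_to_mm(truth, which(comp == c))[, 1]), 0)
    ord <- order(cx)
    side_names <- if (k == 2) c("left", "right") else paste0("c", seq_len(k))
    for (i in seq_len(k))
      add("kidney", side_names[which(ord == i)], "whole",
          as.vector(comp == i))
  } else {
    add("kidney", "left", "whole", logical(length(lab)))
  }

  # ureters: side and arc fraction from centrelines when available
  usel <- lab == codes[["ureter"]]
  if (!is.null(centerlines) && any(usel)) {
    mm <- linear_to_mm(truth, which(usel))
    dists <- lapply(centerlines, function(cl)
      polyline_distance(mm, cl$control))
    dmat <- do.call(cbind, lapply(dists, `[[`, "distance"))
    side_idx <- max.col(-dmat)
    for (s in seq_along(centerlines)) {
      side <- names(centerlines)[s]
      sel_side <- which(usel)[side_idx == s]
      frac <- dists[[s]]$arc[side_idx == s] / centerlines[[s]]$total
      if (split_ureters) {
        segs <- list(proximal = c(0, 1 / 3), mid = c(1 / 3, 2 / 3),
                     distal = c(2 / 3, 1 + 1e-9))
        for (nm in names(segs)) {
          sel <- logical(length(lab))
          sel[sel_side[frac >= segs[[nm]][1] & frac < segs[[nm]][2]]] <- TRUE
          add("ureter", side, nm, sel)
        }
      } else {
        sel <- logical(length(lab))
        sel[sel_side] <- TRUE
        add("ureter", side, "whole", sel)
      }
    }
  } else {
    add("ureter", "both", "whole", usel)
  }

  add("bladder", "single", "whole", lab == codes[["bladder"]])
  do.call(rbind, rows)
}

#' 4-point visibility score from a coverage fraction
#'
#' Bins: 1 for coverage `<= 0.75`; 2 for `(0.75, 0.95]`; 3 for
#' `(0.95, 1)`; 4 for complete coverage (equal to 1 within tolerance
#' `tau`). The printed scale anchors ("<=75", "75-95", "96-99", "100")
#' overlap at their boundaries; these half-open bins are the exhaustive,
#' disjoint reading consistent with those anchors.
#'
#' @param coverage fraction in `[0, 1]` (vectorized).
#' @param tau tolerance below 1 still counted as complete (default 0).
#' @return Integer scores in `{1, 2, 3, 4}`.
#' @export
score_4point <- function(coverage, tau = 0) {
  check_coverage(coverage)
  ifelse(coverage >= 1 - tau, 4L,
         ifelse(coverage > 0.95, 3L,
                ifelse(coverage > 0.75, 2L, 1L)))
}

#' 3-point visibility score from a coverage fraction
#'
#' 3 = completely visible (coverage 1), 2 = miniscule parts not visible
#' (coverage in `[threshold, 1)`), 1 = substantial parts not visible.
#' The "miniscule" cut-off is a stand-in for a human judgment; default
#' 0.95, configurable.
#'
#' @param coverage fraction in `[0, 1]` (vectorized).
#' @param threshold lower bound of the "miniscule" bin, in `(0, 1)`.
#' @return Integer scores in `{1, 2, 3}`.
#' @export
score_3point <- function(coverage, threshold = 0.95) {
  check_coverage(coverage)
  stopifnot(threshold > 0, threshold < 1)
  ifelse(coverage >= 1, 3L, ifelse(coverage >= threshold, 2L, 1L))
}

check_coverage <- function(coverage) {
  if (any(!is.finite(coverage)) || any(coverage < 0) || any(coverage > 1))
    stop("coverage must be within [0, 1]")
  invisible(TRUE)
}

#' Diagnostic accuracy from a 2x2 confusion table
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive predictive
#' value TP/(TP+FP) and negative predictive value TN/(TN+FN), in percent
#' rounded to one decimal for reporting. A ratio whose denominator is zero
#' is reported as `NA` (explicitly undefined, never 0).
#'
#' @param tp,fp,fn,tn non-negative integer counts.
#' @return A `diagnostic_table`: the counts plus `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent, 1 decimal; `NA` if undefined).
#' @export
diagnostic_metrics <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  ratio <- function(num, den) if (den == 0) NA_real_ else
    round(100 * num / den, 1)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 npv = ratio(tn, tn + fn)),
            class = "diagnostic_table")
}

#' @export
print.diagnostic_table <- function(x, ...) {
  cat(sprintf("2x2 table: TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn,
              x$tn))
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat("  sensitivity:", fmt(x$sensitivity), "\n")
  cat("  specificity:", fmt(x$specificity), "\n")
  cat("  PPV:        ", fmt(x$ppv), "\n")
  cat("  NPV:        ", fmt(x$npv), "\n")
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with observed
#' agreement `po` and chance agreement `pe` from the marginal category
#' proportions. Works for any category labels. When `pe = 1` (both raters
#' constant and equal) kappa is undefined and `NA` is returned with a
#' warning.
#'
#' @param rater1,rater2 equal-length vectors of categorical calls over the
#'   same cases.
#' @return Scalar kappa in `[-1, 1]`, or `NA` if undefined.
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2))
    stop("rater vectors must have equal length")
  if (length(rater1) < 1) stop("need at least one case")
  cats <- union(unique(rater1), unique(rater2))
  f1 <- table(factor(rater1, levels = cats)) / length(rater1)
  f2 <- table(factor(rater2, levels = cats)) / length(rater2)
  po <- mean(rater1 == rater2)
  pe <- sum(as.numeric(f1) * as.numeric(f2))
  if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: chance agreement equals 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Concealment check for incidental findings
#'
#' @param incidental_mask logical array of incidental-lesion voxels.
#' @param focused_mask logical focused-view mask on the same grid.
#' @return List with `hidden_fraction` (share of lesion voxels outside the
#'   focused mask; `NA` when there are no lesion voxels) and `all_hidden`
#'   (`TRUE` iff the intersection is empty; vacuously `TRUE`, with a
#'   warning, for an empty lesion mask).
#' @export
concealment_check <- function(incidental_mask, focused_mask) {
  if (!identical(dim(incidental_mask), dim(focused_mask)))
    stop("masks must share the same grid")
  ninc <- sum(incidental_mask)
  if (ninc == 0) {
    warning("incidental mask is empty; concealment vacuously true")
    return(list(hidden_fraction = NA_real_, all_hidden = TRUE))
  }
  hidden <- sum(incidental_mask & !focused_mask)
  list(hidden_fraction = hidden / ninc, all_hidden = hidden == ninc)
}

#' Report visibility percentages the way reader-study tables print them
#'
#' Takes per-organ category counts (completely visualized / substantial
#' part not visible / miniscule part not visible) and returns percentages
#' to one decimal. Reporting convention: the non-complete categories are
#' rounded to the nearest 0.1; the dominant "completely visualized" share
#' is reported as the remainder to 100.0, so each row sums to 100.0
#' exactly.
#'
#' @param counts data frame with columns `organ`, `complete`,
#'   `substantial`, `miniscule` (counts); row total is their sum.
#' @return The input with percentage columns `complete_pct`,
#'   `substantial_pct`, `miniscule_pct` appended.
#' @export
summarize_visibility <- function(counts) {
  stopifnot(all(c("organ", "complete", "substantial", "miniscule") %in%
                  names(counts)))
  n <- counts$complete + counts$substantial + counts$miniscule
  sub_pct <- round(100 * counts$substantial / n, 1)
  min_pct <- round(100 * counts$miniscule / n, 1)
  counts$complete_pct <- 100 - sub_pct - min_pct
  counts$substantial_pct <- sub_pct
  counts$miniscule_pct <- min_pct
  counts
}

#' Case-level proportion, truncated to one decimal
#'
#' Reporting convention for standalone case-level proportions: percent
#' truncated (not rounded) to one decimal, e.g. 26/39 -> 66.6.
#'
#' @param k numerator count.
#' @param n denominator count.
#' @return Percent with one decimal, truncated toward zero.
#' @export
case_rate_pct <- function(k, n) {
  floor(1000 * k / n) / 10
}
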