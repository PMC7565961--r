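#' Overlap between a manual and an automatic cell box
#'
#' Percentage of the manual box covered by the automatic box, computed on
#' the rasterized boxes under the shared pixel-center rule:
#' `100 * |raster(Bm) ∩ raster(Ba)| / |raster(Bm)|`. Note the
#' normalization by the manual area only, which makes the measure
#' asymmetric.
#'
#' @param Bm manual-cell `rotated_box`.
#' @param Ba automatic-cell `rotated_box`.
#' @param dim image dimensions `c(H, W)`.
#' @return Percentage in \[0, 100\].
#' @export
overlap_percent <- function(Bm, Ba, dim) {
  rm_ <- rasterize_box(Bm, dim)
  if (!length(rm_)) stop("manual box rasterizes to zero pixels")
  ra_ <- rasterize_box(Ba, dim)
  100 * length(intersect(rm_, ra_)) / length(rm_)
}

#' Maximum overlap of one manual cell over all automatic cells
#'
#' @param Bm manual-cell `rotated_box`.
#' @param automatic_boxes list of automatic-cell `rotated_box` objects.
#' @param dim image dimensions `c(H, W)`.
#' @return `max_j overlap_percent(Bm, Ba_j)`; 0 when there are no
#'   automatic cells.
#' @export
max_overlap <- function(Bm, automatic_boxes, dim) {
  if (!length(automatic_boxes)) return(0)
  max(vapply(automatic_boxes, function(b) overlap_percent(Bm, b, dim),
             numeric(1)))
}

#' Percentile curve of per-cell overlaps
#'
#' The k-th integer percentile (k = 1..100) of the per-manual-cell
#' maximum overlaps, by linear interpolation between closest order
#' statistics (the standard interpolation of [stats::quantile()], type 7).
#' The curve is non-decreasing by construction.
#'
#' @param Ii_values per-manual-cell maximum overlap percentages (>= 1
#'   value).
#' @return Numeric vector `Pc[1..100]`.
#' @export
percentile_curve <- function(Ii_values) {
  if (!length(Ii_values)) stop("no overlap values: percentile curve undefined")
  unname(stats::quantile(Ii_values, probs = (1:100) / 100, type = 7))
}

#' Area under the overlap percentile curve
#'
#' Trapezoidal integration of the percentile curve, normalized to \[0, 1\]:
#' `AUC = 1e-4 * sum_{k=1}^{100} (Pc(k) + Pc(k+1)) / 2`, closing the last
#' trapezoid with the boundary extension `Pc(101) := Pc(100)`. A constant
#' curve at level c integrates to exactly c/100.
#'
#' @param Pc percentile curve of length 100.
#' @return AUC in \[0, 1\].
#' @export
auc_percentile <- function(Pc) {
  if (length(Pc) != 100L) stop("Pc must have exactly 100 entries")
  Pc_ext <- c(Pc, Pc[100])
  sum((Pc_ext[1:100] + Pc_ext[2:101]) / 2) / 1e4
}

#' Evaluate agreement between manual and automatic detections
#'
#' Computes the full overlap matrix between every manual and every
#' automatic cell box, the per-manual-cell maxima, the count of manual
#' cells matched above 50% (strict), the overlap percentile curve and its
#' AUC.
#'
#' @param manual_records list of `cm_record` objects from the manual mask.
#' @param automatic_records list of `cm_record` objects from the automatic
#'   pipeline.
#' @param dim image dimensions `c(H, W)` shared by both masks.
#' @return An object of class `evaluation_result`: list with `Ii_j`
#'   (Nm x Na matrix), `Ii`, `Na`, `Nm`, `matched_over_50`, `Pc`, `AUC`.
#' @export
evaluate_masks <- function(manual_records, automatic_records, dim) {
  man_boxes <- lapply(manual_records, function(r) r$box)
  aut_boxes <- lapply(automatic_records, function(r) r$box)
  Nm <- length(man_boxes); Na <- length(aut_boxes)
  man_px <- lapply(man_boxes, rasterize_box, dim = dim)
  aut_px <- lapply(aut_boxes, rasterize_box, dim = dim)
  Ii_j <- matrix(0, nrow = Nm, ncol = Na)
  for (i in seq_len(Nm)) {
    if (!length(man_px[[i]])) stop("manual box rasterizes to zero pixels")
    for (j in seq_len(Na)) {
      Ii_j[i, j] <- 100 * length(intersect(man_px[[i]], aut_px[[j]])) /
        length(man_px[[i]])
    }
  }
  Ii <- if (Na == 0L) rep(0, Nm) else apply(Ii_j, 1, max)
  if (Nm == 0L) stop("no manual cells to evaluate")
  Pc <- percentile_curve(Ii)
  structure(list(Ii_j = Ii_j, Ii = Ii, Na = Na, Nm = Nm,
                 matched_over_50 = sum(Ii > 50),
                 Pc = Pc, AUC = auc_percentile(Pc)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf(
    "<evaluation_result> Nm %d, Na %d, matched >50%%: %d, AUC %.3f\n",
    x$Nm, x$Na, x$matched_over_50, x$AUC))
  invisible(x)
}

#' Evaluate a manual mask against automatic detections
#'
#' Runs the manual mask through the same contour-and-box delineation
#' stage as the automatic pipeline (the overlap measure is defined on
#' enclosing rectangles) and evaluates agreement.
#'
#' @param manual_mask a `binary_mask` (role `Mm`).
#' @param automatic_records list of `cm_record` objects.
#' @param config a [pipeline_config()].
#' @return An `evaluation_result`; the manual records are attached as
#'   attribute `manual_records`.
#' @export
evaluate_manual_mask <- function(manual_mask, automatic_records,
                                 config = default_config()) {
  manual_records <- detect_from_mask(manual_mask, config)
  res <- evaluate_masks(manual_records, automatic_records,
                        dim(manual_mask$px))
  attr(res, "manual_records") <- manual_records
  res
}
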