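#' Per-cell record
#'
#' One detected cardiomyocyte: its fitted and padded boxes, morphometry
#' (`L`, `W` in micrometers, aspect ratio `R = L/W`, box area `A = L*W`
#' in um^2, long-axis angle in degrees) and, when a CX43 channel is
#' available, the four compartment fractions `F0`..`F3`, the polar and
#' lateral sums `Fp = F0 + F3`, `Fl = F1 + F2`, and the lateralization
#' percentage `Clat = 100 * Fl / (Fl + Fp)`. Cells without any CX43 signal
#' in their box are flagged `no_signal` and carry `Clat = NA`.
#'
#' @name cm_record
NULL

new_cm_record <- function(id, box, box_expanded, m) {
  structure(list(id = id, box = box, box_expanded = box_expanded,
                 L = m$L, W = m$W, R = m$R, A = m$A,
                 angle = box$angle,
                 F = c(F0 = NA_real_, F1 = NA_real_, F2 = NA_real_,
                       F3 = NA_real_),
                 Fp = NA_real_, Fl = NA_real_, Clat = NA_real_,
                 no_signal = NA),
            class = "cm_record")
}

#' @export
print.cm_record <- function(x, ...) {
  cat(sprintf("<cm_record> id %d: L %.1f um, W %.1f um, R %.2f, A %.1f um^2%s\n",
              x$id, x$L, x$W, x$R, x$A,
              if (!is.na(x$Clat)) sprintf(", Clat %.1f%%", x$Clat) else ""))
  invisible(x)
}

#' Filter cell records by plausible length and width
#'
#' Keeps a record iff `L_range[1] < L < L_range[2]` and
#' `W_range[1] < W < W_range[2]` (strict inequalities, micrometers).
#'
#' @param records list of `cm_record` objects.
#' @param L_range,W_range open plausibility intervals in micrometers.
#' @return The retained records, in their original order.
#' @export
filter_boxes <- function(records, L_range = c(20, 200), W_range = c(5, 50)) {
  if (L_range[1] >= L_range[2] || W_range[1] >= W_range[2])
    stop("filter bounds must be ordered")
  keep <- vapply(records, function(r) {
    r$L > L_range[1] && r$L < L_range[2] &&
      r$W > W_range[1] && r$W < W_range[2]
  }, logical(1))
  records[keep]
}

#' Detect cell boxes in a binary cardiomyocyte mask
#'
#' Shared delineation stage for both automatic and manual masks: external
#' contours are traced, implausible contours discarded, each remaining
#' contour is enclosed in its minimum-area rotated rectangle, the
#' rectangle is padded by `h` pixels, morphometry is computed and
#' implausibly sized boxes are discarded. Ids are assigned in contour
#' discovery order after filtering.
#'
#' @param mask a `binary_mask` (`Ma` or `Mm`).
#' @param config a [pipeline_config()].
#' @return List of `cm_record` objects (CX43 fields unset).
#' @export
detect_from_mask <- function(mask, config = default_config()) {
  stopifnot(inherits(mask, "binary_mask"), inherits(config, "pipeline_config"))
  cts <- find_external_contours(mask)
  cts <- filter_contours(cts, config$scale, config$min_area_um2,
                         config$min_perim_um)
  h <- config_h(config)
  records <- list()
  for (ct in cts) {
    box <- tryCatch(fit_min_area_box(ct), error = function(e) NULL)
    if (is.null(box)) next
    bexp <- expand_box(box, h)
    m <- measure_cm(box, bexp, config$scale)
    records[[length(records) + 1L]] <- new_cm_record(0L, box, bexp, m)
  }
  records <- filter_boxes(records, config$L_range, config$W_range)
  for (i in seq_along(records)) records[[i]]$id <- i
  records
}

# Full pipeline on a channel set: builds all masks and records.
detect_full <- function(channels, config = default_config()) {
  stopifnot(inherits(channels, "channel_set"),
            inherits(config, "pipeline_config"))
  pc <- config$channels
  Mc1 <- build_channel_mask(channels$c1, pc$c1, role = "Mc1")
  Mc2 <- if (!is.null(channels$c2) && !is.null(pc$c2))
    build_channel_mask(channels$c2, pc$c2, role = "Mc2") else NULL
  Mc3 <- if (!is.null(channels$c3) && !is.null(pc$c3))
    build_channel_mask(channels$c3, pc$c3, role = "Mc3") else NULL
  if (is.null(Mc3) && config$invert_c3)
    Mc3 <- binary_mask(!Mc1$px, role = "Mc3", scale = Mc1$scale)
  Ma <- combine_automatic_mask(Mc1, Mc2, Mc3)
  records <- detect_from_mask(Ma, config)
  Mc4 <- NULL; Mt <- NULL
  if (!is.null(channels$c4)) {
    Mc4 <- build_cx43_mask(channels$c4, config$thr_c4)
    dimg <- dim(Mc1$px)
    for (i in seq_along(records)) {
      part <- partition_box(records[[i]]$box_expanded, dimg)
      fr <- compartment_fractions(part, Mc4)
      cl <- compute_clat(fr)
      records[[i]]$F <- fr
      records[[i]]$Fp <- fr[["F0"]] + fr[["F3"]]
      records[[i]]$Fl <- fr[["F1"]] + fr[["F2"]]
      records[[i]]$Clat <- cl$clat
      records[[i]]$no_signal <- cl$no_signal
    }
  }
  Mt <- build_tissue_mask(Mc1, Mc2, Mc3)
  list(records = records, Ma = Ma, Mt = Mt, Mc4 = Mc4,
       Mc1 = Mc1, Mc2 = Mc2, Mc3 = Mc3)
}

#' Detect and measure cardiomyocytes in a channel set
#'
#' End-to-end unsupervised pipeline: per-channel masks, automatic mask
#' combination, contour tracing, plausibility filtering, minimum-area
#' rectangle fitting, box padding and morphometry; CX43 compartment
#' fractions and lateralization are populated when a CX43 channel is
#' present. The pipeline contains no randomness: identical inputs and
#' configuration give identical records.
#'
#' @param channels a `channel_set`.
#' @param config a [pipeline_config()].
#' @return List of `cm_record` objects in contour-discovery order.
#' @export
detect_myocytes <- function(channels, config = default_config()) {
  detect_full(channels, config)$records
}

#' Subset detected cells by a selection manifest
#'
#' Non-interactive counterpart of a supervised review round: keeps the
#' records whose ids appear in the manifest, preserving the original
#' order.
#'
#' @param records list of `cm_record` objects.
#' @param manifest integer vector of record ids to keep.
#' @return The selected records.
#' @export
apply_selection <- function(records, manifest) {
  ids <- vapply(records, function(r) r$id, integer(1))
  manifest <- as.integer(manifest)
  unknown <- setdiff(manifest, ids)
  if (length(unknown))
    stop("selection manifest contains unknown ids: ",
         paste(unknown, collapse = ", "))
  records[ids %in% manifest]
}

#' Tabulate cell records
#'
#' @param records list of `cm_record` objects.
#' @return A data frame with one row per cell: id, box center (px), angle
#'   (deg), `L_um`, `W_um`, `R`, `A_um2`, compartment fractions `F0`..`F3`,
#'   `Clat` (percent, `NA` for no-signal cells) and the `no_signal` flag.
#' @export
cm_table <- function(records) {
  if (!length(records)) {
    return(data.frame(id = integer(0), center_x_px = numeric(0),
                      center_y_px = numeric(0), angle_deg = numeric(0),
                      L_um = numeric(0), W_um = numeric(0), R = numeric(0),
                      A_um2 = numeric(0), F0 = numeric(0), F1 = numeric(0),
                      F2 = numeric(0), F3 = numeric(0), Clat = numeric(0),
                      no_signal = logical(0)))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(id = r$id, center_x_px = r$box$center[1],
               center_y_px = r$box$center[2], angle_deg = r$angle,
               L_um = r$L, W_um = r$W, R = r$R, A_um2 = r$A,
               F0 = r$F[["F0"]], F1 = r$F[["F1"]], F2 = r$F[["F2"]],
               F3 = r$F[["F3"]], Clat = r$Clat, no_signal = r$no_signal)
  }))
}
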