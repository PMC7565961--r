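#' Run the full detection and quantification workflow
#'
#' Executes mask building, cell detection, morphometry and CX43
#' quantification on a channel set (or on image files loaded through
#' [load_channels()]), and serializes the results: a per-cell CSV table,
#' a JSON summary (expression, noise, tissue areas, lateralization
#' distribution and exponential fit) and optionally the intermediate
#' masks and a box overlay. Output files contain no timestamps, so two
#' runs with identical inputs and configuration produce byte-identical
#' files.
#'
#' @param input a `channel_set`, or a list with entries `paths` or
#'   `merged` + `role_assignment` forwarded to [load_channels()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` to skip
#'   writing files.
#' @param manifest optional integer vector of cell ids to keep
#'   (supervised selection).
#' @param save_masks write the intermediate masks as PNG.
#' @param save_overlay write a PNG of c1 with detected boxes drawn.
#' @return A run report: list with `records`, `table`, `stats` (`Cex`,
#'   `r`, tissue areas), `clat_values`, `fit`, `config`, `files`,
#'   `timing_s`.
#' @export
run_detect <- function(input, config = default_config(), out_dir = NULL,
                       manifest = NULL, save_masks = FALSE,
                       save_overlay = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  channels <- if (inherits(input, "channel_set")) input
  else do.call(load_channels, c(input, list(config = config)))
  det <- detect_full(channels, config)
  records <- det$records
  if (!is.null(manifest)) records <- apply_selection(records, manifest)
  if (!length(records)) warning("no cardiomyocytes detected")
  stats <- list(
    tissue_area_mm2_pixel_count = tissue_area(det$Mt, config$scale,
                                              "pixel_count"),
    tissue_area_mm2_max_contour = tissue_area(det$Mt, config$scale,
                                              "max_contour"))
  if (!is.null(det$Mc4)) {
    stats$Cex <- if (sum(det$Mt$px) > 0) compute_cex(det$Mc4, det$Mt) else NA
    stats$r <- if (any(!det$Mt$px)) compute_noise(det$Mc4, det$Mt) else NA
  }
  tab <- cm_table(records)
  clat_values <- tab$Clat[!is.na(tab$Clat)]
  fit <- tryCatch(fit_exponential(clat_values, config$clat_bin_width),
                  error = function(e) NULL)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(out_dir, "cm_table.csv")
    utils::write.csv(format_cm_table(tab), csv, row.names = FALSE,
                     quote = FALSE)
    summ <- c(stats,
              list(n_cells = length(records),
                   clat_values = round(clat_values, 1),
                   fit = if (!is.null(fit)) list(a = fit$a, b = fit$b,
                                                 bin_width = fit$bin_width)))
    js <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    files <- c(csv, js)
    if (save_masks) {
      for (nm in c("Ma", "Mt", "Mc4", "Mc1", "Mc2", "Mc3")) {
        if (!is.null(det[[nm]])) {
          p <- file.path(out_dir, paste0(nm, ".png"))
          write_image(det[[nm]], p)
          files <- c(files, p)
        }
      }
    }
    if (save_overlay) {
      p <- file.path(out_dir, "overlay.png")
      write_overlay(channels$c1, records, p)
      files <- c(files, p)
    }
  }
  list(records = records, table = tab, stats = stats,
       clat_values = clat_values, fit = fit, config = config,
       masks = det[c("Ma", "Mt", "Mc4")], files = files,
       timing_s = proc.time()[["elapsed"]] - t0)
}

# Fixed-precision table for stable on-disk output (Clat with one decimal,
# lengths with two).
format_cm_table <- function(tab) {
  if (!nrow(tab)) return(tab)
  num2 <- c("center_x_px", "center_y_px", "angle_deg", "L_um", "W_um", "R",
            "A_um2")
  for (cn in num2) tab[[cn]] <- sprintf("%.2f", tab[[cn]])
  for (cn in c("F0", "F1", "F2", "F3"))
    tab[[cn]] <- ifelse(is.na(tab[[cn]]), "NA", sprintf("%.4f", tab[[cn]]))
  tab$Clat <- ifelse(is.na(tab$Clat), "NA", sprintf("%.1f", tab$Clat))
  tab
}

draw_segment <- function(px_rgb, x0, y0, x1, y1, col) {
  n <- max(2L, ceiling(2 * sqrt((x1 - x0)^2 + (y1 - y0)^2)))
  xs <- seq(x0, x1, length.out = n); ys <- seq(y0, y1, length.out = n)
  rows <- pmin(pmax(as.integer(floor(ys + 0.5)) + 1L, 1L), dim(px_rgb)[1])
  cols <- pmin(pmax(as.integer(floor(xs + 0.5)) + 1L, 1L), dim(px_rgb)[2])
  for (k in 1:3) px_rgb[cbind(rows, cols, k)] <- col[k]
  px_rgb
}

write_overlay <- function(c1, records, path) {
  g <- c1$px / 255
  rgb <- array(g, c(dim(g), 3))
  for (r in records) {
    v <- r$box$vertices
    for (k in 1:4) {
      k2 <- if (k == 4) 1L else k + 1L
      rgb <- draw_segment(rgb, v[k, 1], v[k, 2], v[k2, 1], v[k2, 2],
                          c(1, 0.1, 0.1))
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Evaluate a manual mask against an automatic run
#'
#' Loads (or accepts) a manually delineated cell mask, runs it through the
#' shared box-delineation stage, computes the overlap matrix against the
#' automatic detections and serializes the per-cell overlaps, the
#' percentile curve and a JSON summary.
#'
#' @param manual a `binary_mask` or path to a mask image (role `Mm`).
#' @param detection a [run_detect()] report, or a list of `cm_record`s.
#' @param config a [pipeline_config()].
#' @param dim image dimensions `c(H, W)`; defaults to the manual mask's.
#' @param out_dir output directory, or `NULL`.
#' @return The `evaluation_result`, with `files` attribute.
#' @export
run_evaluate <- function(manual, detection, config = default_config(),
                         dim = NULL, out_dir = NULL) {
  mask <- if (inherits(manual, "binary_mask")) manual
  else read_mask(manual, role = "Mm", scale = config$scale)
  records <- if (is.list(detection) && !is.null(detection$records))
    detection$records else detection
  if (!is.null(dim) && !identical(as.integer(dim), dim(mask$px)))
    stop("manual mask dimensions do not match the automatic run")
  res <- evaluate_manual_mask(mask, records, config)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    man <- attr(res, "manual_records")
    best_j <- if (res$Na > 0) apply(res$Ii_j, 1, which.max) else
      rep(NA_integer_, res$Nm)
    percell <- data.frame(
      id = vapply(man, function(r) r$id, integer(1)),
      best_j = best_j, Ii = sprintf("%.2f", res$Ii))
    f1 <- file.path(out_dir, "evaluation.csv")
    utils::write.csv(percell, f1, row.names = FALSE, quote = FALSE)
    f2 <- file.path(out_dir, "pc_curve.csv")
    utils::write.csv(data.frame(k = 1:100, Pc = sprintf("%.4f", res$Pc)),
                     f2, row.names = FALSE, quote = FALSE)
    f3 <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(list(Na = res$Na, Nm = res$Nm,
                              matched_over_50 = res$matched_over_50,
                              AUC = res$AUC),
                         f3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(f1, f2, f3)
  }
  attr(res, "files") <- files
  res
}

#' Render a synthetic scene to disk
#'
#' Writes the rendered channels as 8-bit TIFF, the ground-truth cell
#' table as CSV and the ground-truth manual mask as PNG. Deterministic:
#' the same scene seed produces byte-identical files.
#'
#' @param scene a [synthetic_scene()].
#' @param out_dir output directory.
#' @return Invisible list with the rendered `channels`, `truth` and
#'   written `files`.
#' @export
run_synthesize <- function(scene, out_dir) {
  rendered <- render_scene(scene)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in c("c1", "c2", "c3")) {
    p <- file.path(out_dir, paste0(nm, ".tif"))
    write_image(rendered$channels[[nm]], p)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "ground_truth.csv")
  truth <- rendered$truth
  for (cn in c("cx", "cy", "angle", "L_um", "W_um", "phi"))
    truth[[cn]] <- sprintf("%.4f", truth[[cn]])
  utils::write.csv(truth, p, row.names = FALSE, quote = FALSE)
  files <- c(files, p)
  p <- file.path(out_dir, "manual_mask.png")
  write_image(ground_truth_manual_mask(scene), p)
  files <- c(files, p)
  invisible(list(channels = rendered$channels, truth = rendered$truth,
                 files = files))
}
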