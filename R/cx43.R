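#' Global CX43 expression
#'
#' Percentage of tissue pixels that carry CX43 signal: the number of
#' pixels active in both the CX43 mask and the tissue mask, divided by the
#' number of active tissue pixels.
#'
#' @param Mc4 CX43 quantification mask (`binary_mask`).
#' @param Mt tissue mask (`binary_mask`), must be non-empty.
#' @return Percentage in \[0, 100\].
#' @export
compute_cex <- function(Mc4, Mt) {
  check_same_dim(Mc4, Mt)
  denom <- sum(Mt$px)
  if (denom == 0) stop("tissue mask is empty: expression ratio undefined")
  100 * sum(Mt$px & Mc4$px) / denom
}

#' Off-tissue noise level of the CX43 mask
#'
#' Percentage of non-tissue pixels that are active in the CX43 mask:
#' activation outside the tissue mask can only be noise.
#'
#' @param Mc4 CX43 quantification mask.
#' @param Mt tissue mask; must not cover the entire image.
#' @return Percentage in \[0, 100\].
#' @export
compute_noise <- function(Mc4, Mt) {
  check_same_dim(Mc4, Mt)
  denom <- sum(!Mt$px)
  if (denom == 0) stop("tissue mask covers the whole image: noise ratio undefined")
  100 * sum(!Mt$px & Mc4$px) / denom
}

#' Total tissue area
#'
#' Either the count of active tissue pixels, or the area enclosed by the
#' largest external contour of the tissue mask (useful when tissue regions
#' contain many inactive pixels), converted to square millimeters.
#'
#' @param Mt tissue mask (`binary_mask`).
#' @param scale micrometers per pixel.
#' @param method `"pixel_count"` or `"max_contour"`.
#' @return Area in mm^2.
#' @export
tissue_area <- function(Mt, scale, method = c("pixel_count", "max_contour")) {
  method <- match.arg(method)
  if (scale <= 0) stop("scale must be positive")
  apx <- if (method == "pixel_count") {
    sum(Mt$px)
  } else {
    cts <- find_external_contours(Mt)
    if (!length(cts)) 0 else max(vapply(cts, function(ct) ct$area_px2,
                                        numeric(1)))
  }
  area_px_to_um2(apx, scale) * 1e-6
}

#' CX43 fraction per box compartment
#'
#' For each compartment `Hi` of a partitioned cell box, the fraction of
#' its pixels that are active in the CX43 mask: `Fi = |Hi ∩ Mc4| / Ni`.
#' The denominator counts all box pixels inside the image, not only
#' tissue pixels.
#'
#' @param partition a [partition_box()] result.
#' @param Mc4 CX43 quantification mask.
#' @return Named numeric vector `(F0, F1, F2, F3)`.
#' @export
compartment_fractions <- function(partition, Mc4) {
  stopifnot(inherits(partition, "compartment_partition"),
            inherits(Mc4, "binary_mask"))
  if (any(partition$sizes == 0))
    stop("empty compartment: box degenerate or outside the image")
  f <- vapply(partition$compartments,
              function(h) sum(Mc4$px[h]) / length(h), numeric(1))
  names(f) <- paste0("F", 0:3)
  f
}

#' CX43 lateralization percentage
#'
#' `Clat = 100 * Fl / (Fl + Fp)` with polar fraction `Fp = F0 + F3` and
#' lateral fraction `Fl = F1 + F2`. A value of 0 means all CX43 sits at
#' the cell poles, 100 means all of it is lateral. Cells with no CX43
#' signal at all (`Fl + Fp = 0`) are flagged instead of being assigned a
#' value, so they can be excluded from distributions without biasing the
#' low-lateralization bins.
#'
#' @param F numeric vector `(F0, F1, F2, F3)` of compartment fractions.
#' @return List with `clat` (percent, `NA` if no signal) and `no_signal`.
#' @export
compute_clat <- function(F) {
  if (length(F) != 4L || any(F < 0)) stop("F must be four non-negative fractions")
  Fp <- F[[1]] + F[[4]]
  Fl <- F[[2]] + F[[3]]
  if (Fp + Fl == 0) return(list(clat = NA_real_, no_signal = TRUE))
  list(clat = 100 * Fl / (Fl + Fp), no_signal = FALSE)
}

#' Exponential model of the lateralization distribution
#'
#' Frequency model `f(x) = a * exp(-b * x)` fitted to the density
#' histogram of per-cell lateralization percentages.
#'
#' @param a amplitude (> 0).
#' @param b decay rate per lateralization percent (> 0).
#' @param bin_width histogram bin width used for the fit, percent.
#' @return An object of class `exp_fit_model`.
#' @export
exp_fit_model <- function(a, b, bin_width = NA_real_) {
  if (a <= 0 || b <= 0) stop("model parameters must be positive")
  structure(list(a = a, b = b, bin_width = bin_width), class = "exp_fit_model")
}

#' @export
print.exp_fit_model <- function(x, ...) {
  cat(sprintf("<exp_fit_model> f(x) = %.5g * exp(-%.5g x)\n", x$a, x$b))
  invisible(x)
}

#' Fit an exponential curve to histogram densities
#'
#' Nonlinear least squares of `a * exp(-b * x)` on `(centers, density)`
#' pairs, initialized from a log-linear regression on the positive
#' densities.
#'
#' @param centers histogram bin centers.
#' @param density normalized bin frequencies (integrating to ~1).
#' @param bin_width bin width recorded in the returned model.
#' @return An `exp_fit_model` with attributes `residuals` and `fitted`.
#' @export
fit_exp_curve <- function(centers, density, bin_width = NA_real_) {
  ok <- density > 0
  if (sum(ok) < 2L)
    stop("insufficient data: need at least two non-empty bins")
  lmfit <- stats::lm(log(density[ok]) ~ centers[ok])
  start <- list(a = exp(unname(stats::coef(lmfit)[1])),
                b = max(1e-6, -unname(stats::coef(lmfit)[2])))
  df <- data.frame(x = centers, y = density)
  fit <- minpack.lm::nlsLM(y ~ a * exp(-b * x), data = df, start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  model <- exp_fit_model(cf[["a"]], cf[["b"]], bin_width)
  attr(model, "residuals") <- stats::resid(fit)
  attr(model, "fitted") <- stats::fitted(fit)
  model
}

#' Fit the exponential lateralization model to per-cell values
#'
#' Builds a density-normalized histogram of the lateralization
#' percentages with bins of `bin_width` over \[0, 100\] and fits
#' `a * exp(-b * x)` to the bin centers. At least two non-empty bins are
#' required.
#'
#' @param clat_values per-cell lateralization percentages (`NA` values,
#'   e.g. from no-signal cells, are dropped).
#' @param bin_width histogram bin width in percent.
#' @return An `exp_fit_model`.
#' @export
fit_exponential <- function(clat_values, bin_width = 5) {
  x <- clat_values[!is.na(clat_values)]
  if (any(x < 0 | x > 100)) stop("lateralization values must lie in [0, 100]")
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  dens <- h$counts / (length(x) * diff(h$breaks))
  fit_exp_curve(h$mids, dens, bin_width)
}

#' Integrate the exponential lateralization model
#'
#' Closed-form integral of `a * exp(-b * x)` between two lateralization
#' percentages: `(a / b) * (exp(-b * lo) - exp(-b * hi))`. Interpreted as
#' the fraction of cells with lateralization in `[lo, hi]`.
#'
#' @param model an `exp_fit_model`.
#' @param lo,hi integration bounds in percent, `lo <= hi`.
#' @return The integrated fraction.
#' @export
integrate_fraction <- function(model, lo, hi) {
  stopifnot(inherits(model, "exp_fit_model"))
  if (lo > hi) stop("lo must not exceed hi")
  (model$a / model$b) * (exp(-model$b * lo) - exp(-model$b * hi))
}
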