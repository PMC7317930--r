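# Histoblot / immunoblot densitometry: circular-ROI pixel density with
# multi-ROI background subtraction, and lane band quantification normalized
# to a reference band. Scans follow the dark-high convention: density =
# 1 - pixel for images in [0, 1] (255 - pixel for 8-bit input), so stronger
# immunoreactivity (darker) scores higher.

#' Circular region-of-interest specification
#'
#' @param center_mm c(x, y) centre in scan millimetres.
#' @param diameter_mm cursor diameter (default 0.10 mm, the open circular
#'   cursor used for histoblot readout).
#' @param label region label.
#' @return list of class `gq_roi`.
#' @export
roi_spec <- function(center_mm, diameter_mm = 0.10, label = "roi") {
  stopifnot(length(center_mm) == 2, diameter_mm > 0)
  structure(list(center_mm = as.numeric(center_mm),
                 diameter_mm = diameter_mm, label = label),
            class = "gq_roi")
}

invert_intensity <- function(v) 1 - v

#' Mean inverted pixel density over a circular ROI
#'
#' Averages `1 - pixel` over pixels whose centres fall inside the disk.
#'
#' @param image grayscale matrix in [0, 1] (rows = y).
#' @param roi a [roi_spec()].
#' @param mm_per_px scan scale.
#' @return list: `raw_density`, `n_pixels`, `label`.
#' @export
roi_density <- function(image, roi, mm_per_px) {
  h <- nrow(image); w <- ncol(image)
  cx <- roi$center_mm[1] / mm_per_px; cy <- roi$center_mm[2] / mm_per_px
  r <- roi$diameter_mm / 2 / mm_per_px
  if (cx - r < 0 || cy - r < 0 || cx + r > w || cy + r > h) {
    stop("ROI '", roi$label, "' out of image bounds")
  }
  jj <- max(1L, floor(cx - r)):min(w, ceiling(cx + r))
  ii <- max(1L, floor(cy - r)):min(h, ceiling(cy + r))
  d2 <- outer(((ii - 0.5) - cy)^2, ((jj - 0.5) - cx)^2, `+`)
  sel <- d2 <= r * r
  if (!any(sel)) stop("ROI '", roi$label, "' covers no pixel centres")
  vals <- image[ii, jj, drop = FALSE][sel]
  list(raw_density = mean(invert_intensity(vals)), n_pixels = sum(sel),
       label = roi$label)
}

#' Background-subtract a raw ROI density
#'
#' The corrected density is the raw density minus the mean of the background
#' ROI measurements (taken near the protein-containing areas of the
#' membrane). The background set must have exactly the configured count
#' (default 8) in strict mode.
#'
#' @param raw raw density (from [roi_density()]).
#' @param background_values numeric vector of background ROI densities.
#' @param expected_n required number of background measurements (default 8).
#' @param strict error (TRUE, default) or warn on a wrong background count.
#' @param label region label carried into the record.
#' @return data.frame: region, raw_density, background, corrected,
#'   negative_flag.
#' @export
background_subtract <- function(raw, background_values, expected_n = 8,
                                strict = TRUE, label = "region") {
  if (length(background_values) != expected_n) {
    msg <- sprintf("expected %d background determinations, got %d",
                   expected_n, length(background_values))
    if (strict) stop(msg) else warning(msg)
  }
  bg <- mean(background_values)
  corrected <- raw - bg
  data.frame(region = label, raw_density = raw, background = bg,
             corrected = corrected, negative_flag = corrected < 0)
}

#' Normalized band densitometry for a western-blot lane
#'
#' Integrated background-subtracted inverted intensity of the target band
#' window divided by that of the reference band window (e.g. a loading
#' control such as alpha-tubulin). Per-window background is the median
#' inverted intensity of the window's top and bottom border rows.
#'
#' @param image grayscale lane image in [0, 1].
#' @param band_window,reference_window lists with `rows` and `cols` (integer
#'   index vectors); the two windows must be disjoint.
#' @return list: `ratio`, `band_integral`, `reference_integral`.
#' @export
band_quantify <- function(image, band_window, reference_window) {
  win_cells <- function(wn) {
    as.vector(outer(wn$rows, wn$cols, function(i, j) (j - 1L) * nrow(image) + i))
  }
  if (length(intersect(win_cells(band_window), win_cells(reference_window)))) {
    stop("band and reference windows overlap")
  }
  integ <- function(wn) {
    sub <- invert_intensity(image[wn$rows, wn$cols, drop = FALSE])
    border <- c(sub[1, ], sub[nrow(sub), ])
    sum(pmax(sub - stats::median(border), 0))
  }
  b <- integ(band_window); r <- integ(reference_window)
  if (r <= 0) stop("reference band integral <= 0")
  list(ratio = b / r, band_integral = b, reference_integral = r)
}

#' Generate a synthetic histoblot-like scan
#'
#' Labeled polygonal regions with assigned immunoreactivity intensities are
#' rasterized dark-on-bright, Gaussian-blurred (transfer spread) and overlaid
#' with additive noise, so the densitometry stage is testable stand-alone
#' with known generating intensities.
#'
#' @param regions list of lists with `ring` (mm polygon), `intensity`
#'   (0..1 darkness) and `label`.
#' @param width_mm,height_mm scan size.
#' @param mm_per_px scan scale (default 0.01 mm/px).
#' @param blur_mm Gaussian blur sigma (default 0.05 mm).
#' @param noise_sd additive noise sd (default 0.01).
#' @param seed optional seed.
#' @return grayscale matrix in [0, 1] with attribute `mm_per_px`.
#' @export
simulate_blot <- function(regions, width_mm = 6, height_mm = 4,
                          mm_per_px = 0.01, blur_mm = 0.05, noise_sd = 0.01,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- round(width_mm / mm_per_px); h <- round(height_mm / mm_per_px)
  img <- matrix(0, h, w)  # darkness field
  for (rg in regions) {
    ring_px <- rg$ring / mm_per_px
    bx <- range(ring_px[, 1]); by <- range(ring_px[, 2])
    jj <- max(1L, floor(bx[1])):min(w, ceiling(bx[2]))
    ii <- max(1L, floor(by[1])):min(h, ceiling(by[2]))
    if (!length(jj) || !length(ii)) next
    gx <- rep(jj - 0.5, each = length(ii)); gy <- rep(ii - 0.5, length(jj))
    inside <- point_in_polygon(gx, gy, ring_px, eps = 0)
    idx <- cbind(rep(ii, length(jj)), rep(jj, each = length(ii)))[inside, ,
                                                                  drop = FALSE]
    img[idx] <- pmax(img[idx], rg$intensity)
  }
  if (blur_mm > 0) img <- EBImage::gblur(img, sigma = blur_mm / mm_per_px)
  scan <- 1 - img
  if (noise_sd > 0) scan <- scan + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
  scan[] <- pmin(1, pmax(0, scan))
  attr(scan, "mm_per_px") <- mm_per_px
  scan
}
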