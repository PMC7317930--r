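# Rasterization of synthetic scenes into micrograph-like grayscale images.
# Gold particles are drawn as anti-aliased dark disks on a bright textured
# background (additive Gaussian noise plus a low-frequency shading field).
# Images are matrices in [0, 1] with rows = y, columns = x; pixel (i, j) has
# its centre at nm coordinates (origin + (j - 0.5, i - 0.5) * nm_per_px).

#' Default raster noise model
#'
#' @param background_level bright background mean (0..1).
#' @param disk_depth intensity drop of a fully covered particle pixel.
#' @param noise_sd additive Gaussian noise sd.
#' @param shade_amp amplitude of the low-frequency shading field.
#' @param shade_scale_nm spatial scale of the shading field.
#' @return list of class `gq_noise_model`.
#' @export
noise_model <- function(background_level = 0.85, disk_depth = 0.55,
                        noise_sd = 0.05, shade_amp = 0.06,
                        shade_scale_nm = 250) {
  structure(as.list(environment()), class = "gq_noise_model")
}

#' Rasterize a scene into a grayscale image
#'
#' @param scene a `gq_scene` (or a particle table plus explicit bounds).
#' @param nm_per_px raster scale in nm per pixel, in [0.5, 5].
#' @param noise a [noise_model()]; use `noise_model(noise_sd = 0, shade_amp
#'   = 0)` for noiseless rasters.
#' @param particle_diameter_nm drawn disk diameter (default 10 nm).
#' @param margin_nm padding added around the scene bounding box.
#' @param seed optional seed for the noise field.
#' @return numeric matrix in [0, 1] with attributes `nm_per_px` and
#'   `origin_nm` (nm coordinates of the image's top-left corner).
#' @export
rasterize <- function(scene, nm_per_px = NULL, noise = noise_model(),
                      particle_diameter_nm = 10, margin_nm = 60,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm_per_px <- nm_per_px %||% scene$nm_per_px
  if (nm_per_px < 0.5 || nm_per_px > 5) stop("nm_per_px must be in [0.5, 5]")
  if (particle_diameter_nm / nm_per_px < 2) {
    warning("particle diameter < 2 px at this scale; detection unreliable")
  }
  pts <- scene$particles
  xs <- numeric(0); ys <- numeric(0)
  for (p in scene$profiles) { xs <- c(xs, p$ring[, 1]); ys <- c(ys, p$ring[, 2]) }
  if (nrow(pts)) { xs <- c(xs, pts$x_nm); ys <- c(ys, pts$y_nm) }
  if (!length(xs)) stop("cannot rasterize an empty scene with no profiles")
  x0 <- min(xs) - margin_nm; y0 <- min(ys) - margin_nm
  w <- ceiling((max(xs) + margin_nm - x0) / nm_per_px)
  h <- ceiling((max(ys) + margin_nm - y0) / nm_per_px)

  img <- matrix(noise$background_level, nrow = h, ncol = w)
  if (noise$shade_amp > 0) {
    # two randomly oriented low-frequency sinusoids emulate uneven
    # illumination / replica shadowing gradients
    xc <- ((seq_len(w) - 0.5) * nm_per_px + x0) / noise$shade_scale_nm
    yc <- ((seq_len(h) - 0.5) * nm_per_px + y0) / noise$shade_scale_nm
    th <- stats::runif(2, 0, pi); ph <- stats::runif(2, 0, 2 * pi)
    f1 <- outer(yc * sin(th[1]), xc * cos(th[1]), `+`)
    f2 <- outer(yc * sin(th[2]), xc * cos(th[2]), `+`)
    img <- img + noise$shade_amp * (sin(2 * pi * f1 + ph[1]) +
                                    sin(2 * pi * f2 + ph[2])) / 2
  }
  cov <- matrix(0, nrow = h, ncol = w)
  r_px <- (particle_diameter_nm / 2) / nm_per_px
  if (nrow(pts)) {
    for (k in seq_len(nrow(pts))) {
      cx <- (pts$x_nm[k] - x0) / nm_per_px  # in pixel units
      cy <- (pts$y_nm[k] - y0) / nm_per_px
      j0 <- max(1L, floor(cx - r_px - 1)); j1 <- min(w, ceiling(cx + r_px + 1))
      i0 <- max(1L, floor(cy - r_px - 1)); i1 <- min(h, ceiling(cy + r_px + 1))
      if (j0 > j1 || i0 > i1) next
      jj <- j0:j1; ii <- i0:i1
      dx <- (jj - 0.5) - cx; dy <- (ii - 0.5) - cy
      d <- sqrt(outer(dy^2, dx^2, `+`))
      # smooth edge: coverage ramps over one pixel around the disk rim
      cvg <- pmin(pmax(r_px + 0.5 - d, 0), 1)
      cov[ii, jj] <- pmax(cov[ii, jj], cvg)
    }
  }
  img <- img - noise$disk_depth * cov
  if (noise$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, 0, noise$noise_sd), h, w)
  }
  img[] <- pmin(1, pmax(0, img))  # keep matrix dims (pmin drops them)
  attr(img, "nm_per_px") <- nm_per_px
  attr(img, "origin_nm") <- c(x = x0, y = y0)
  img
}
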