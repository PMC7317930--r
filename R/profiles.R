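# Profile geometry: polygonal membrane profiles (P-face / E-face), axon
# terminals with an active-zone subregion, and pre-embedding profiles with a
# membrane contour. Profiles are lists of class "gq_profile".

new_profile <- function(id, ring, face, layer, klass, subregions = list(),
                        membrane_contour = NULL) {
  stopifnot(is.matrix(ring), ncol(ring) == 2, nrow(ring) >= 3)
  if (!is_simple_polygon(ring)) stop("profile ring is self-intersecting")
  area <- polygon_area_um2(ring)
  if (area <= 0) stop("profile has zero area")
  if (length(subregions)) {
    sub_area <- sum(vapply(subregions, polygon_area_um2, numeric(1)))
    if (sub_area > area + 1e-9) stop("subregion areas exceed profile area")
  }
  structure(list(id = id, ring = ring, face = face, layer = layer,
                 klass = klass, subregions = subregions,
                 membrane_contour = membrane_contour, area_um2 = area),
            class = "gq_profile")
}

#' @export
print.gq_profile <- function(x, ...) {
  cat(sprintf("<gq_profile %s> %s/%s face=%s area=%.3f um^2 (%d vertices%s%s)\n",
              x$id, x$layer, x$klass, x$face, x$area_um2, nrow(x$ring),
              if (length(x$subregions)) paste0(", subregions: ",
                paste(names(x$subregions), collapse = ",")) else "",
              if (!is.null(x$membrane_contour)) ", membrane contour" else ""))
  invisible(x)
}

# Slightly irregular closed ring approximating a disk of the requested area.
# Radial jitter keeps point-in-polygon tests honest without risking
# self-intersection (jitter is bounded well below the mean radius).
blob_ring <- function(area_um2, centre = c(0, 0), n_vertices = 24,
                      irregularity = 0.12) {
  area_nm2 <- area_um2 * 1e6
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r0 <- sqrt(area_nm2 / pi)
  r <- r0 * (1 + irregularity * (runif(n_vertices) - 0.5))
  # rescale so the polygon area matches the request
  ring <- cbind(centre[1] + r * cos(theta), centre[2] + r * sin(theta))
  s <- sqrt(area_nm2 / abs(shoelace_area(ring)))
  cbind(centre[1] + s * r * cos(theta), centre[2] + s * r * sin(theta))
}

# Elongated dendrite-like ribbon (aspect ~4:1) with gently wavy long edges.
ribbon_ring <- function(area_um2, centre = c(0, 0), aspect = 4, n_side = 12,
                        waviness = 0.08) {
  area_nm2 <- area_um2 * 1e6
  w <- sqrt(area_nm2 / aspect)          # width in nm
  l <- aspect * w                       # length in nm
  xs <- seq(-l / 2, l / 2, length.out = n_side)
  amp <- waviness * w
  top <- cbind(xs, -w / 2 + amp * sin(seq(0, 2 * pi, length.out = n_side)) +
                 amp * (runif(n_side) - 0.5))
  bot <- cbind(rev(xs), w / 2 + amp * cos(seq(0, 2 * pi, length.out = n_side)) +
                 amp * (runif(n_side) - 0.5))
  ring <- rbind(top, bot)
  s <- sqrt(area_nm2 / abs(shoelace_area(ring)))
  ring <- ring * s
  ring[, 1] <- ring[, 1] + centre[1]; ring[, 2] <- ring[, 2] + centre[2]
  ring
}

#' Construct a membrane profile polygon
#'
#' Builds the polygonal outline of one identified compartment profile, as it
#' would be delineated on a replica micrograph. Shapes are mildly irregular
#' (randomized via the current RNG stream) so geometric code paths are tested
#' on non-trivial polygons.
#'
#' @param shape "blob" (somata, spines, terminals) or "ribbon" (dendrites).
#' @param area_um2 target polygon area in um^2.
#' @param layer one of "so","sp","sr","sr_prox","sr_dist","slm".
#' @param klass one of "soma","apical_dendrite","oblique_dendrite","spine",
#'   "axon_terminal".
#' @param face "P", "E" or "cross_fracture".
#' @param centre centre of the profile in nm.
#' @param id profile identifier.
#' @return A `gq_profile`.
#' @export
make_profile <- function(shape = c("blob", "ribbon"), area_um2, layer, klass,
                         face = "P", centre = c(0, 0), id = "p1") {
  shape <- match.arg(shape)
  face <- match.arg(face, c("P", "E", "cross_fracture"))
  ring <- switch(shape,
                 blob = blob_ring(area_um2, centre),
                 ribbon = ribbon_ring(area_um2, centre))
  new_profile(id, ring, face, layer, klass)
}

#' Construct an axon-terminal profile with an active-zone subregion
#'
#' The active zone is a smaller disk-like polygon fully contained in the
#' terminal outline, mimicking the concave P-face specialization by which
#' terminals are identified on replicas.
#'
#' @param area_um2 terminal area (um^2).
#' @param az_area_um2 active-zone area (um^2); must be < `area_um2`.
#' @param layer CA1 layer label.
#' @param centre centre in nm.
#' @param id profile identifier.
#' @return A `gq_profile` with `subregions$active_zone`.
#' @export
make_terminal_profile <- function(area_um2 = 0.3, az_area_um2 = 0.05,
                                  layer = "sr", centre = c(0, 0), id = "t1") {
  stopifnot(az_area_um2 < area_um2)
  ring <- blob_ring(area_um2, centre, irregularity = 0.08)
  r_term <- sqrt(area_um2 * 1e6 / pi)
  r_az <- sqrt(az_area_um2 * 1e6 / pi)
  # AZ offset toward the membrane edge, kept inside with a safety margin
  off <- max(0, 0.9 * (r_term - r_az) - 0.12 * r_term)
  az <- blob_ring(az_area_um2, centre + c(off, 0), n_vertices = 18,
                  irregularity = 0.05)
  prof <- new_profile(id, ring, "P", layer, "axon_terminal",
                      subregions = list(active_zone = az))
  if (!all(point_in_polygon(az[, 1], az[, 2], ring, eps = 0))) {
    stop("active zone not contained in terminal outline")
  }
  prof
}

#' Construct a pre-embedding profile with a membrane contour
#'
#' Pre-embedding immunogold sections show a dendrite cross-section whose
#' plasma membrane is a closed contour; particles are classified as
#' membrane-associated or intracellular by distance to this contour.
#'
#' @param area_um2 profile area (um^2).
#' @param layer CA1 layer label.
#' @param klass compartment class (dendrite or spine).
#' @param centre centre in nm.
#' @param id profile identifier.
#' @return A `gq_profile` whose `membrane_contour` is the closed outline.
#' @export
make_preembedding_profile <- function(area_um2 = 1.0, layer = "sr",
                                      klass = "oblique_dendrite",
                                      centre = c(0, 0), id = "m1") {
  ring <- blob_ring(area_um2, centre)
  contour <- rbind(ring, ring[1, , drop = FALSE])  # closed polyline
  new_profile(id, ring, "cross_fracture", layer, klass,
              membrane_contour = contour)
}

#' Empty particle table
#'
#' Canonical column layout shared by ground-truth and detected particle sets:
#' `scene_id, profile_id, x_nm, y_nm, label, cluster_id`.
#' @param n number of pre-allocated rows.
#' @return data.frame of class `gq_particles`.
#' @export
empty_particles <- function(n = 0) {
  structure(data.frame(scene_id = character(n), profile_id = character(n),
                       x_nm = numeric(n), y_nm = numeric(n),
                       label = character(n), cluster_id = rep(NA_integer_, n),
                       stringsAsFactors = FALSE),
            class = c("gq_particles", "data.frame"))
}

as_particles <- function(df) {
  need <- c("scene_id", "profile_id", "x_nm", "y_nm", "label", "cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("particle table missing columns: ",
                         paste(miss, collapse = ", "))
  class(df) <- unique(c("gq_particles", class(df)))
  df
}

#' Assemble a scene
#'
#' A scene bundles profiles, ground-truth particles and raster metadata for
#' one synthetic micrograph.
#'
#' @param profiles list of `gq_profile`.
#' @param particles `gq_particles` ground-truth table.
#' @param mode "sds_frl" or "pre_embedding".
#' @param nm_per_px raster scale.
#' @param seed seed recorded for provenance.
#' @param scene_id identifier stamped on the particle table.
#' @return list of class `gq_scene`.
#' @export
make_scene <- function(profiles, particles, mode = c("sds_frl", "pre_embedding"),
                       nm_per_px = 1.0, seed = NA_integer_, scene_id = "scene1") {
  mode <- match.arg(mode)
  if (nrow(particles)) particles$scene_id <- scene_id
  # E-face profiles may carry only background-process particles
  for (p in profiles) {
    if (identical(p$face, "E") && nrow(particles)) {
      lab <- particles$label[particles$profile_id == p$id]
      if (length(lab) && any(lab != "background")) {
        stop("E-face profile ", p$id, " carries non-background particles")
      }
    }
  }
  structure(list(profiles = profiles, particles = particles, mode = mode,
                 nm_per_px = nm_per_px, seed = seed, scene_id = scene_id),
            class = "gq_scene")
}

#' @export
print.gq_scene <- function(x, ...) {
  cat(sprintf("<gq_scene %s> mode=%s, %d profiles, %d particles, %.1f nm/px\n",
              x$scene_id, x$mode, length(x$profiles), nrow(x$particles),
              x$nm_per_px))
  invisible(x)
}
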