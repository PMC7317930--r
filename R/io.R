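# File formats and provenance: particle CSV, GeoJSON profiles, TIFF/PNG
# images, YAML configs, JSON reports. Coordinates are serialized in nm with
# two-decimal fixed point (0.01 nm round-trip precision); every CSV written
# here carries a provenance header line (config hash + seed).

provenance_line <- function(hash = NA, seed = NA) {
  sprintf("# goldquant %s | config_hash=%s | seed=%s",
          as.character(utils::packageVersion("goldquant")),
          as.character(hash), as.character(seed))
}

#' Write a particle table to CSV
#'
#' Schema: `scene_id,profile_id,x_nm,y_nm,label,cluster_id`; coordinates at
#' two-decimal fixed point; a leading `#` provenance comment records the
#' config hash and seed.
#'
#' @param particles `gq_particles` (or compatible data.frame).
#' @param path output path.
#' @param hash,seed provenance fields.
#' @export
write_particles <- function(particles, path, hash = NA, seed = NA) {
  df <- as.data.frame(particles)
  df$x_nm <- sprintf("%.2f", df$x_nm)
  df$y_nm <- sprintf("%.2f", df$y_nm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a particle table from CSV
#'
#' Schema-validated; empty files yield an empty set; malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV path (with or without provenance comment lines).
#' @return `gq_particles`.
#' @export
read_particles <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(empty_particles())
  df <- utils::read.csv(text = body, stringsAsFactors = FALSE)
  need <- c("scene_id", "profile_id", "x_nm", "y_nm", "label", "cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("particle CSV missing fields: ",
                         paste(miss, collapse = ", "))
  if (!nrow(df)) return(empty_particles())
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$x_nm))) |
                 !is.finite(suppressWarnings(as.numeric(df$y_nm))))
  if (length(bad)) {
    hdr_off <- sum(startsWith(lines, "#")) + 1L
    stop("malformed coordinate in row(s) ",
         paste(bad + hdr_off, collapse = ", "), " of ", path)
  }
  df$x_nm <- as.numeric(df$x_nm); df$y_nm <- as.numeric(df$y_nm)
  df$cluster_id <- suppressWarnings(as.integer(df$cluster_id))
  as_particles(df)
}

#' Write profiles as a GeoJSON FeatureCollection
#'
#' Polygons in a flat planar frame (nm); properties carry `id`, `face`,
#' `layer`, `klass`; active zones and membrane contours are emitted as
#' additional features with a `role` property.
#'
#' @param profiles list of `gq_profile`.
#' @param path output path.
#' @export
write_profiles_geojson <- function(profiles, path) {
  close_ring <- function(ring) {
    ring <- round(ring, 2)
    rbind(ring, ring[1, , drop = FALSE])
  }
  feats <- list()
  for (p in profiles) {
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      properties = list(id = p$id, face = p$face, layer = p$layer,
                        klass = p$klass, role = "profile"),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(
                        lapply(seq_len(nrow(close_ring(p$ring))),
                               function(i) close_ring(p$ring)[i, ])))))
    for (nm in names(p$subregions)) {
      sub <- close_ring(p$subregions[[nm]])
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(id = p$id, face = p$face, layer = p$layer,
                          klass = p$klass, role = nm),
        geometry = list(type = "Polygon",
                        coordinates = list(unname(
                          lapply(seq_len(nrow(sub)), function(i) sub[i, ])))))
    }
    if (!is.null(p$membrane_contour)) {
      mc <- round(p$membrane_contour, 2)
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        properties = list(id = p$id, face = p$face, layer = p$layer,
                          klass = p$klass, role = "membrane_contour"),
        geometry = list(type = "LineString",
                        coordinates = unname(
                          lapply(seq_len(nrow(mc)), function(i) mc[i, ]))))
    }
  }
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read profiles from a GeoJSON FeatureCollection
#'
#' @param path GeoJSON path written by [write_profiles_geojson()] (or
#'   following the same property conventions).
#' @return list of `gq_profile`.
#' @export
read_profiles_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) stop("not a FeatureCollection")
  coords_to_matrix <- function(cc) {
    do.call(rbind, lapply(cc, function(pt) c(pt[[1]], pt[[2]])))
  }
  feats <- fc$features
  roles <- vapply(feats, function(f) f$properties$role %||% "profile", "")
  ids <- vapply(feats, function(f) f$properties$id %||% NA_character_, "")
  out <- list()
  for (k in which(roles == "profile")) {
    f <- feats[[k]]
    ring <- coords_to_matrix(f$geometry$coordinates[[1]])
    n <- nrow(ring)
    if (all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    subregions <- list()
    contour <- NULL
    for (j in which(ids == ids[k] & roles != "profile")) {
      fj <- feats[[j]]
      if (roles[j] == "membrane_contour") {
        contour <- coords_to_matrix(fj$geometry$coordinates)
      } else {
        sring <- coords_to_matrix(fj$geometry$coordinates[[1]])
        m <- nrow(sring)
        if (all(sring[1, ] == sring[m, ])) sring <- sring[-m, , drop = FALSE]
        subregions[[roles[j]]] <- sring
      }
    }
    out[[length(out) + 1L]] <- new_profile(
      id = f$properties$id, ring = ring, face = f$properties$face,
      layer = f$properties$layer, klass = f$properties$klass,
      subregions = subregions, membrane_contour = contour)
  }
  out
}

#' Write a grayscale image (16-bit TIFF or PNG)
#'
#' @param image matrix in [0, 1].
#' @param path output path; format chosen by extension (.tif/.tiff/.png).
#' @export
write_image <- function(image, path) {
  img <- image
  img[] <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(img, path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a grayscale image (TIFF or PNG)
#'
#' Multi-channel input is averaged to one channel.
#'
#' @param path image path.
#' @param nm_per_px optional scale recorded as an attribute.
#' @return matrix in [0, 1].
#' @export
read_image <- function(path, nm_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported image format: .", ext)
  if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
  if (!is.null(nm_per_px)) attr(img, "nm_per_px") <- nm_per_px
  img
}

#' Read / write run configuration YAML
#' @param path YAML path.
#' @return named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a provenance JSON for a run directory
#'
#' Records package version, config hash, seed and stage name so that every
#' output bundle self-describes how it was produced.
#'
#' @param dir run directory.
#' @param stage stage name.
#' @param hash config hash.
#' @param seed RNG seed.
#' @export
write_provenance <- function(dir, stage, hash = NA, seed = NA) {
  jsonlite::write_json(
    list(package = "goldquant",
         version = as.character(utils::packageVersion("goldquant")),
         stage = stage, config_hash = as.character(hash), seed = seed,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
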