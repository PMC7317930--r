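# Compartment-wise quantification: particle-to-profile assignment, surface
# densities with E-face background correction, active-zone vs extrasynaptic
# presynaptic densities, membrane vs intracellular partitioning, and the
# per-compartment density-gradient table.

#' Assign particles to profile polygons
#'
#' Point-in-polygon assignment by the nonzero winding rule; points within
#' 1 nm of an edge are assigned to the containing profile. Particles inside
#' no polygon are flagged `"outside"`. Overlapping profiles are an input
#' error (each particle must lie in exactly one profile).
#'
#' @param particles data.frame with `x_nm`, `y_nm`.
#' @param profiles list of `gq_profile`.
#' @return the particle table with a `profile_id` column (`"outside"` when
#'   unassigned).
#' @export
assign_particles <- function(particles, profiles) {
  n <- nrow(particles)
  assigned <- rep("outside", n)
  for (p in profiles) {
    inside <- point_in_polygon(particles$x_nm, particles$y_nm, p$ring, eps = 1)
    clash <- inside & assigned != "outside"
    if (any(clash)) {
      stop("overlapping profiles: particle falls in both ",
           assigned[which(clash)[1]], " and ", p$id)
    }
    assigned[inside] <- p$id
  }
  particles$profile_id <- assigned
  particles
}

#' Surface density of one profile
#'
#' Density = particle count / profile area, reported in particles/um^2.
#'
#' @param particles particle table already assigned to profiles.
#' @param profile a `gq_profile`.
#' @param condition optional named list merged into the record (genotype,
#'   age_months, animal_id, ...).
#' @param min_area_um2 profiles below this area are degenerate and rejected
#'   (default 0.01 um^2).
#' @return one-row data.frame: profile_id, layer, klass, n_particles,
#'   area_um2, density_per_um2 (+ condition columns).
#' @export
compute_density <- function(particles, profile, condition = NULL,
                            min_area_um2 = 0.01) {
  if (profile$area_um2 <= 0) stop("zero-area profile")
  if (profile$area_um2 < min_area_um2) {
    stop(sprintf("degenerate profile %s (%.4f um^2 < %.2f um^2) excluded",
                 profile$id, profile$area_um2, min_area_um2))
  }
  n <- sum(particles$profile_id == profile$id)
  rec <- data.frame(profile_id = profile$id, layer = profile$layer,
                    klass = profile$klass, n_particles = n,
                    area_um2 = profile$area_um2,
                    density_per_um2 = n / profile$area_um2)
  if (!is.null(condition)) for (nm in names(condition)) rec[[nm]] <- condition[[nm]]
  rec
}

#' E-face background correction
#'
#' Nonspecific labeling is measured on E-face structures surrounding the
#' measured P-faces; the corrected density is the P-face density minus the
#' E-face density, floored at zero. Correction is intended at the condition
#' level (mean E-face density per replica), not per profile.
#'
#' @param pface_density,eface_density densities in particles/um^2 (>= 0).
#' @return list: `corrected` and `flag` (TRUE when the E-face density
#'   exceeded the P-face density and the floor was applied).
#' @export
background_correct <- function(pface_density, eface_density) {
  stopifnot(all(pface_density >= 0), all(eface_density >= 0))
  corrected <- pmax(pface_density - eface_density, 0)
  list(corrected = corrected, flag = eface_density > pface_density)
}

#' Split presynaptic particles into active-zone and extrasynaptic pools
#'
#' @param particles particle table (one terminal's particles or a table with
#'   `profile_id` matching the terminal).
#' @param profile a `gq_profile` with `subregions$active_zone`.
#' @return list with `partition` (counts and percentages) and `densities`
#'   (per-subregion density records using subregion areas).
#' @export
split_presynaptic <- function(particles, profile) {
  az <- profile$subregions$active_zone
  if (is.null(az)) stop("profile has no active_zone subregion")
  a_az <- polygon_area_um2(az)
  if (a_az <= 0) stop("active zone has zero area")
  a_ex <- profile$area_um2 - a_az
  sel <- particles[particles$profile_id == profile$id |
                     is.na(particles$profile_id), , drop = FALSE]
  in_az <- point_in_polygon(sel$x_nm, sel$y_nm, az, eps = 1)
  n_az <- sum(in_az); n_ex <- nrow(sel) - n_az
  total <- n_az + n_ex
  partition <- data.frame(
    profile_id = profile$id,
    region = c("az", "extrasynaptic"),
    n = c(n_az, n_ex),
    percent = if (total) 100 * c(n_az, n_ex) / total else NA_real_)
  densities <- data.frame(
    profile_id = profile$id,
    region = c("az", "extrasynaptic"),
    n_particles = c(n_az, n_ex),
    area_um2 = c(a_az, a_ex),
    density_per_um2 = c(n_az / a_az, n_ex / a_ex))
  list(partition = partition, densities = densities)
}

#' Classify pre-embedding particles as membrane or intracellular
#'
#' A particle is membrane-associated iff its distance to the membrane
#' contour is at most `d_mem_nm` (a particle exactly on the contour is
#' membrane). The threshold is configurable; the default 25 nm reflects the
#' reach of silver-enhanced pre-embedding particles around the membrane.
#'
#' @param particles particle table with `x_nm`, `y_nm`.
#' @param profile a `gq_profile` with `membrane_contour`.
#' @param d_mem_nm distance threshold (> 0).
#' @return list: `partition` (counts + percentages; percentages `NA`-flagged
#'   when the profile is empty) and `distances` (per-particle distance, nm).
#' @export
classify_membrane <- function(particles, profile, d_mem_nm = 25) {
  contour <- profile$membrane_contour
  if (is.null(contour)) stop("profile has no membrane contour")
  if (nrow(contour) < 2 ||
      sum(sqrt(diff(contour[, 1])^2 + diff(contour[, 2])^2)) <= 0) {
    stop("degenerate membrane contour")
  }
  stopifnot(d_mem_nm > 0)
  sel <- particles[particles$profile_id == profile$id |
                     is.na(particles$profile_id), , drop = FALSE]
  d <- if (nrow(sel)) dist_to_polyline(sel$x_nm, sel$y_nm, contour) else numeric(0)
  mem <- d <= d_mem_nm
  n_mem <- sum(mem); n_int <- sum(!mem); total <- n_mem + n_int
  partition <- data.frame(
    profile_id = profile$id,
    region = c("membrane", "intracellular"),
    n = c(n_mem, n_int),
    percent = if (total) 100 * c(n_mem, n_int) / total else NA_real_)
  list(partition = partition, distances = d)
}

#' Per-compartment density table (mean +/- SEM between animals)
#'
#' Two-stage aggregation: profile densities are averaged within each animal,
#' then the group mean and SEM are computed across animal means (the
#' "between animals" convention). Rows are ordered soma -> apical -> oblique
#' -> spine within each layer.
#'
#' @param records density records (rows from [compute_density()]) carrying
#'   `animal_id` and grouping columns `genotype`, `layer`, `klass`.
#' @return data.frame: genotype, layer, klass, n_animals, n_profiles,
#'   mean_density, sem (NA-flagged with < 2 animals).
#' @export
density_gradient_table <- function(records) {
  stopifnot(all(c("animal_id", "genotype", "layer", "klass",
                  "density_per_um2") %in% names(records)))
  key <- interaction(records$genotype, records$layer, records$klass, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, key), function(g) {
    am <- tapply(g$density_per_um2, g$animal_id, mean)
    n_animals <- length(am)
    data.frame(genotype = g$genotype[1], layer = g$layer[1], klass = g$klass[1],
               n_animals = n_animals, n_profiles = nrow(g),
               mean_density = mean(am),
               sem = if (n_animals >= 2) stats::sd(am) / sqrt(n_animals)
                     else NA_real_)
  }))
  klass_order <- c("soma", "apical_dendrite", "oblique_dendrite", "spine")
  layer_order <- c("so", "sp", "sr", "sr_prox", "sr_dist", "slm")
  out <- out[order(out$genotype, match(out$layer, layer_order),
                   match(out$klass, klass_order)), ]
  rownames(out) <- NULL
  out
}
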