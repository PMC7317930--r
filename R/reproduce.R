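# Pipeline orchestration: simulate -> (detect) -> quantify -> cluster ->
# stats for calibrated conditions, and the `reproduce()` driver that
# regenerates the report bundle from seeds.

#' Per-profile density through the full raster + detection chain
#'
#' Rasterizes one profile's pattern into a micrograph-like image, runs the
#' blob detector, assigns detections to the profile polygon and computes the
#' surface density. With `use_detection = FALSE` the ground-truth
#' coordinates are quantified directly (pipeline-equality diagnostics).
#'
#' @param profile a `gq_profile`.
#' @param particles truth particles of this profile.
#' @param noise a [noise_model()].
#' @param params a [detection_params()].
#' @param nm_per_px raster scale.
#' @param use_detection run raster + detection (TRUE) or quantify truth.
#' @param condition optional condition columns for the record.
#' @return density record row (see [compute_density()]).
#' @export
profile_density <- function(profile, particles, noise = noise_model(),
                            params = detection_params(), nm_per_px = 1.0,
                            use_detection = TRUE, condition = NULL) {
  if (use_detection) {
    sc <- make_scene(list(profile), as_particles(particles),
                     nm_per_px = nm_per_px, scene_id = profile$id)
    img <- rasterize(sc, nm_per_px = nm_per_px, noise = noise)
    det <- detect_particles(img, params = params)
    det <- assign_particles(det, list(profile))
    compute_density(det, profile, condition = condition)
  } else {
    pts <- assign_particles(particles, list(profile))
    compute_density(pts, profile, condition = condition)
  }
}

#' Recover slm densities for the four 6-month conditions
#'
#' Generates the calibrated number of oblique-dendrite (16) and spine (21)
#' profiles per genotype in the stratum lacunosum-moleculare, runs the full
#' detect -> quantify chain and reports pooled mean density +/- SEM next to
#' the generating value.
#'
#' @param calibration a `gq_calibration`.
#' @param age_months age (default 6).
#' @param seed integer seed.
#' @param use_detection full image chain (default TRUE).
#' @return data.frame: genotype, klass, generating, recovered, sem,
#'   n_profiles.
#' @export
recover_slm_densities <- function(calibration, age_months = 6, seed = 1,
                                  use_detection = TRUE) {
  noise <- do.call(noise_model, calibration$raster[
    c("background_level", "disk_depth", "noise_sd", "shade_amp",
      "shade_scale_nm")])
  out <- list()
  set.seed(seed)
  for (genotype in c("WT", "APP_PS1")) {
    for (klass in c("oblique_dendrite", "spine")) {
      scene <- simulate_condition(calibration, genotype, age_months,
                                  "slm", klass)
      recs <- do.call(rbind, lapply(scene$profiles, function(prof) {
        pts <- scene$particles[scene$particles$profile_id == prof$id, ]
        profile_density(prof, pts, noise = noise,
                        nm_per_px = calibration$raster$nm_per_px,
                        use_detection = use_detection)
      }))
      out[[length(out) + 1L]] <- data.frame(
        genotype = genotype, klass = klass,
        generating = condition_density(calibration, genotype, age_months,
                                       "slm", klass),
        recovered = mean(recs$density_per_um2),
        sem = stats::sd(recs$density_per_um2) / sqrt(nrow(recs)),
        n_profiles = nrow(recs))
    }
  }
  do.call(rbind, out)
}

#' Recover presynaptic AZ and extrasynaptic densities
#'
#' Simulates axon terminals for one calibrated 12-month condition, splits
#' particles into active-zone vs extrasynaptic pools, and reports pooled
#' densities (total particles / total subregion area) with Poisson standard
#' errors.
#'
#' @param calibration a `gq_calibration`.
#' @param genotype,layer condition ("WT"/"APP_PS1", "sr"/"slm").
#' @param n_terminals number of terminals pooled (default 60).
#' @param seed integer seed.
#' @return data.frame: region, generating, recovered, se, n_particles.
#' @export
recover_presynaptic <- function(calibration, genotype, layer,
                                n_terminals = 60, seed = 1) {
  cond <- NULL
  for (p in calibration$presynaptic) {
    if (p$genotype == genotype && p$layer == layer) cond <- p
  }
  if (is.null(cond)) stop("no presynaptic calibration for ", genotype, "/", layer)
  set.seed(seed)
  geom <- calibration$profiles$axon_terminal
  tot <- list(az = c(n = 0, a = 0), extrasynaptic = c(n = 0, a = 0))
  for (i in seq_len(n_terminals)) {
    prof <- make_terminal_profile(geom$area_um2, geom$az_area_um2, layer,
                                  centre = c(i * 2000, 0),
                                  id = sprintf("t%03d", i))
    pts <- sample_presynaptic_pattern(prof, cond$az_density,
                                      cond$extra_density,
                                      hard_core_nm =
                                        calibration$process$hard_core_nm)
    sp <- split_presynaptic(pts, prof)
    for (rg in c("az", "extrasynaptic")) {
      row <- sp$densities[sp$densities$region == rg, ]
      tot[[rg]]["n"] <- tot[[rg]]["n"] + row$n_particles
      tot[[rg]]["a"] <- tot[[rg]]["a"] + row$area_um2
    }
  }
  data.frame(
    region = c("az", "extrasynaptic"),
    generating = c(cond$az_density, cond$extra_density),
    recovered = c(tot$az["n"] / tot$az["a"],
                  tot$extrasynaptic["n"] / tot$extrasynaptic["a"]),
    se = c(sqrt(tot$az["n"]) / tot$az["a"],
           sqrt(tot$extrasynaptic["n"]) / tot$extrasynaptic["a"]),
    n_particles = c(tot$az["n"], tot$extrasynaptic["n"]))
}

#' Recover the pre-embedding membrane percentage for one condition
#'
#' Simulates pre-embedding profiles until at least `min_particles` particles
#' are pooled, classifies each by distance to the membrane contour, and
#' reports the pooled membrane percentage.
#'
#' @param calibration a `gq_calibration`.
#' @param genotype,age_months,layer condition.
#' @param min_particles pooled particle floor (default 2000).
#' @param seed integer seed.
#' @return list: `generating_percent`, `recovered_percent`, `n_particles`.
#' @export
recover_membrane_percent <- function(calibration, genotype, age_months, layer,
                                     min_particles = 2000, seed = 1) {
  cond <- NULL
  for (p in calibration$pre_embedding$conditions) {
    if (p$genotype == genotype && p$age_months == age_months &&
        p$layer == layer) cond <- p
  }
  if (is.null(cond)) stop("no pre-embedding calibration for that condition")
  d_off <- calibration$pre_embedding$d_offset_nm
  mu <- calibration$pre_embedding$mean_particles_per_profile
  set.seed(seed)
  n_mem <- 0L; n_tot <- 0L; i <- 0L
  while (n_tot < min_particles) {
    i <- i + 1L
    prof <- make_preembedding_profile(1.0, layer, "oblique_dendrite",
                                      centre = c(i * 3000, 0),
                                      id = sprintf("m%04d", i))
    pts <- sample_pre_embedding(prof, mu, cond$p_membrane, d_offset_nm = d_off)
    pts <- assign_particles(pts, list(prof))
    cl <- classify_membrane(pts, prof, d_mem_nm = d_off)
    n_mem <- n_mem + cl$partition$n[cl$partition$region == "membrane"]
    n_tot <- n_tot + sum(cl$partition$n)
  }
  list(generating_percent = 100 * cond$p_membrane,
       recovered_percent = 100 * n_mem / n_tot, n_particles = n_tot)
}

#' Cluster-composition recovery over the 140 um^2 reference area
#'
#' Builds oblique-dendrite profiles totalling the calibrated reference area,
#' plants the calibrated number of well-separated clusters, re-identifies
#' them with single-linkage clustering (min size 3) per profile, and pools
#' the composition histogram.
#'
#' @param calibration a `gq_calibration`.
#' @param genotype,layer condition (12-month cluster calibration).
#' @param seed integer seed.
#' @return list: `planted`, `recovered` (composition summary from
#'   [composition_histogram()]), `size_range`.
#' @export
recover_cluster_composition <- function(calibration, genotype, layer,
                                        seed = 1) {
  cond <- NULL
  for (p in calibration$clusters_12mo$conditions) {
    if (p$genotype == genotype && p$layer == layer) cond <- p
  }
  if (is.null(cond)) stop("no cluster calibration for ", genotype, "/", layer)
  ref_area <- calibration$clusters_12mo$reference_area_um2
  disp <- calibration$clusters_12mo$dispersion
  link <- calibration$process$link_distance_nm
  set.seed(seed)
  n_prof <- round(ref_area)  # 1 um^2 ribbons
  profiles <- lapply(seq_len(n_prof), function(i) {
    make_profile("ribbon", 1.0, layer, "oblique_dendrite",
                 centre = c((i - 1) %% 12, (i - 1) %/% 12) * 4200,
                 id = sprintf("od%03d", i))
  })
  pts <- plant_clusters(profiles, cond$n_clusters, mean_size = cond$mean_size,
                        dispersion = disp,
                        sigma_r = calibration$process$cluster_radius_nm,
                        link_distance_nm = link,
                        hard_core_nm = calibration$process$hard_core_nm)
  pooled <- do.call(rbind, lapply(profiles, function(prof) {
    sub <- pts[pts$profile_id == prof$id, , drop = FALSE]
    link_clusters(sub, cluster_params(link_distance_nm = link))$clusters
  }))
  if (is.null(pooled)) pooled <- empty_cluster_table()
  pooled_area <- sum(vapply(profiles, function(p) p$area_um2, numeric(1)))
  comp <- composition_histogram(pooled, pooled_area, ref_area)
  list(planted = cond$n_clusters, recovered = comp,
       size_range = comp$size_range)
}

#' Regenerate the full report bundle
#'
#' Runs simulate -> (detect) -> quantify -> cluster -> stats for the
#' calibrated conditions and writes `density_records.csv`,
#' `gradient_table.csv`, `partition_records.csv`, `composition.csv`,
#' `comparisons.csv` and `provenance.json` under `out_dir`. The default
#' configuration covers the headline conditions (6-month slm densities,
#' 12-month presynaptic and pre-embedding partitions, 12-month proximal-sr
#' cluster composition) at reduced problem sizes; pass a config list to
#' change scope.
#'
#' @param config list with optional fields `seed`, `use_detection`,
#'   `calibration_path`, `min_particles`, `n_terminals`.
#' @param out_dir output directory (created).
#' @return invisibly, the list of output paths.
#' @export
reproduce <- function(config = list(), out_dir) {
  seed <- config$seed %||% 1L
  cal <- load_calibration(config$calibration_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  use_det <- config$use_detection %||% TRUE

  dens <- recover_slm_densities(cal, 6, seed = seed, use_detection = use_det)
  utils::write.csv(dens, file.path(out_dir, "density_records.csv"),
                   row.names = FALSE)

  grad <- dens
  grad$layer <- "slm"
  names(grad)[names(grad) == "recovered"] <- "mean_density"
  utils::write.csv(grad, file.path(out_dir, "gradient_table.csv"),
                   row.names = FALSE)

  part <- do.call(rbind, lapply(list(
    list("WT", 12, "slm"), list("APP_PS1", 12, "slm")), function(cc) {
      r <- recover_membrane_percent(cal, cc[[1]], cc[[2]], cc[[3]],
                                    min_particles = config$min_particles %||% 2000,
                                    seed = seed)
      data.frame(genotype = cc[[1]], age_months = cc[[2]], layer = cc[[3]],
                 generating_percent = r$generating_percent,
                 membrane_percent = r$recovered_percent,
                 n_particles = r$n_particles)
    }))
  utils::write.csv(part, file.path(out_dir, "partition_records.csv"),
                   row.names = FALSE)

  presy <- do.call(rbind, lapply(list(
    list("WT", "sr"), list("APP_PS1", "slm")), function(cc) {
      r <- recover_presynaptic(cal, cc[[1]], cc[[2]],
                               n_terminals = config$n_terminals %||% 60,
                               seed = seed)
      cbind(genotype = cc[[1]], layer = cc[[2]], r)
    }))
  utils::write.csv(presy, file.path(out_dir, "presynaptic_records.csv"),
                   row.names = FALSE)

  comp <- recover_cluster_composition(cal, "WT", "sr_prox", seed = seed)
  hist <- comp$recovered$histogram
  hist$total_clusters <- comp$recovered$total_clusters
  hist$link_distance_nm <- cal$process$link_distance_nm
  utils::write.csv(hist, file.path(out_dir, "composition.csv"),
                   row.names = FALSE)

  # genotype comparison on the 6-month slm recovery (per-profile diagnostics)
  cmp <- data.frame(value = dens$recovered, genotype = dens$genotype,
                    compartment = dens$klass)
  utils::write.csv(cmp, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  write_provenance(out_dir, "reproduce", hash = cal$hash, seed = seed)
  invisible(list.files(out_dir, full.names = TRUE))
}
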