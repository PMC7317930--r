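# Synthetic immunogold point patterns with known ground truth.
#
# Clustered labeling is generated by a Thomas-type parent-offspring process:
# cluster centres are homogeneous Poisson at intensity lambda_c inside the
# profile polygon; each centre receives 3 + NegBin(mu = mu_k - 3, size =
# dispersion) offspring (so every planted cluster satisfies the minimum-size-
# three rule; dispersion = Inf gives the shifted-Poisson limit), displaced
# isotropically with Gaussian scale sigma_r (truncated at 3 sigma_r and
# resampled until inside the polygon, so expected counts are exactly
# area * (lambda_c * mu_k + lambda_s)). A homogeneous scattered process at
# lambda_s is superposed. All particles respect a hard-core minimum
# centre-to-centre distance (gold conjugates are solid and carry an antibody
# shell); positions are resampled, never dropped, so counts are unaffected.

offspring_count <- function(n, mu_k, dispersion) {
  stopifnot(mu_k >= 3)
  if (is.infinite(dispersion)) 3L + stats::rpois(n, mu_k - 3)
  else 3L + stats::rnbinom(n, size = dispersion, mu = mu_k - 3)
}

# Sequential hard-core placement: propose via `propose(m)` (matrix m x 2),
# accept points at least `hard_core` nm from all previously accepted ones,
# resampling rejected proposals (bounded tries; the packing fractions used
# here are far below jamming so exhaustion is not seen in practice).
place_hard_core <- function(n, propose, hard_core, xs = numeric(0),
                            ys = numeric(0), max_tries = 200L) {
  out_x <- numeric(n); out_y <- numeric(n)
  hc2 <- hard_core * hard_core
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- propose(1L)
      if (length(xs)) {
        d2 <- (xs - p[1])^2 + (ys - p[2])^2
        if (min(d2) < hc2) next
      }
      ok <- TRUE
      break
    }
    # extremely dense packing: accept the last proposal rather than fail
    out_x[i] <- p[1]; out_y[i] <- p[2]
    xs <- c(xs, p[1]); ys <- c(ys, p[2])
  }
  cbind(x = out_x, y = out_y)
}

# Gaussian displacement truncated at 3 sigma, conditioned inside the polygon.
propose_offspring <- function(cx, cy, sigma_r, ring) {
  function(m) {
    for (t in 1:500) {
      r <- abs(stats::rnorm(1, 0, sigma_r))
      if (r > 3 * sigma_r) next
      a <- stats::runif(1, 0, 2 * pi)
      x <- cx + r * cos(a); y <- cy + r * sin(a)
      if (point_in_polygon(x, y, ring, eps = 0)) return(c(x, y))
    }
    c(cx, cy)  # pathological polygon: fall back to the parent location
  }
}

#' Sample a clustered + scattered particle pattern on a P-face profile
#'
#' @param profile a `gq_profile` with `face == "P"`.
#' @param cfg a [condition_record()] (fields `lambda_c`, `mu_k`,
#'   `dispersion`, `sigma_r`, `lambda_s`, `hard_core_nm`), or any list with
#'   those fields.
#' @param seed optional integer seed (set only when non-NULL, so callers can
#'   manage one RNG stream across many profiles).
#' @return `gq_particles` with labels `"cluster"` (with `cluster_id`) and
#'   `"scattered"`.
#' @export
sample_point_pattern <- function(profile, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!identical(profile$face, "P")) stop("clustered labeling is sampled on P-face profiles")
  lam_c <- cfg$lambda_c; lam_s <- cfg$lambda_s
  if (!is.finite(lam_c) || !is.finite(lam_s) || lam_c < 0 || lam_s < 0) {
    stop("intensities must be finite and non-negative")
  }
  a <- profile$area_um2
  if (a <= 0) stop("zero-area profile")
  hc <- if (is.null(cfg$hard_core_nm)) 0 else cfg$hard_core_nm
  ring <- profile$ring

  n_parents <- stats::rpois(1, lam_c * a)
  parents <- runif_in_polygon(n_parents, ring)
  xs <- numeric(0); ys <- numeric(0); labs <- character(0); cids <- integer(0)
  if (n_parents > 0) {
    ks <- offspring_count(n_parents, cfg$mu_k, cfg$dispersion)
    for (i in seq_len(n_parents)) {
      pts <- place_hard_core(ks[i],
                             propose_offspring(parents[i, 1], parents[i, 2],
                                               cfg$sigma_r, ring),
                             hc, xs, ys)
      xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
      labs <- c(labs, rep("cluster", ks[i])); cids <- c(cids, rep(i, ks[i]))
    }
  }
  n_s <- stats::rpois(1, lam_s * a)
  if (n_s > 0) {
    pts <- place_hard_core(n_s, function(m) runif_in_polygon(1L, ring)[1, ],
                           hc, xs, ys)
    xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
    labs <- c(labs, rep("scattered", n_s)); cids <- c(cids, rep(NA_integer_, n_s))
  }
  out <- empty_particles(length(xs))
  out$profile_id <- rep(profile$id, length(xs))
  out$x_nm <- xs; out$y_nm <- ys; out$label <- labs; out$cluster_id <- cids
  out
}

#' Sample an E-face background pattern
#'
#' Nonspecific background labeling measured on E-face structures: a sparse
#' homogeneous process at the calibrated background intensity.
#'
#' @param profile `gq_profile` with `face == "E"`.
#' @param lambda_bg background intensity (particles/um^2).
#' @param seed optional seed.
#' @return `gq_particles` with label `"background"`.
#' @export
sample_background_pattern <- function(profile, lambda_bg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(lambda_bg >= 0)
  n <- stats::rpois(1, lambda_bg * profile$area_um2)
  pts <- runif_in_polygon(n, profile$ring)
  out <- empty_particles(n)
  out$profile_id <- rep(profile$id, n)
  if (n) { out$x_nm <- pts[, 1]; out$y_nm <- pts[, 2] }
  out$label <- rep("background", n)
  out
}

#' Sample a presynaptic pattern: active zone vs extrasynaptic membrane
#'
#' Independent homogeneous processes inside the active zone and in the
#' remainder of the terminal outline.
#'
#' @param profile `gq_profile` with `subregions$active_zone`.
#' @param az_intensity,extra_intensity particles/um^2 (>= 0).
#' @param seed optional seed.
#' @param hard_core_nm minimum centre separation (default 15).
#' @return `gq_particles` with labels `"az"` and `"extrasynaptic"`.
#' @export
sample_presynaptic_pattern <- function(profile, az_intensity, extra_intensity,
                                       seed = NULL, hard_core_nm = 15) {
  if (!is.null(seed)) set.seed(seed)
  az <- profile$subregions$active_zone
  if (is.null(az)) stop("profile has no active_zone subregion")
  stopifnot(az_intensity >= 0, extra_intensity >= 0)
  if (!all(point_in_polygon(az[, 1], az[, 2], profile$ring, eps = 0))) {
    stop("active zone not contained in the terminal outline")
  }
  a_az <- polygon_area_um2(az)
  a_ex <- profile$area_um2 - a_az
  stopifnot(a_az > 0, a_ex > 0)
  n_az <- stats::rpois(1, az_intensity * a_az)
  n_ex <- stats::rpois(1, extra_intensity * a_ex)
  prop_az <- function(m) runif_in_polygon(1L, az)[1, ]
  prop_ex <- function(m) {
    for (t in 1:1000) {
      p <- runif_in_polygon(1L, profile$ring)[1, ]
      if (!point_in_polygon(p[1], p[2], az, eps = 0)) return(p)
    }
    stop("could not place extrasynaptic particle outside the active zone")
  }
  xs <- numeric(0); ys <- numeric(0)
  p1 <- place_hard_core(n_az, prop_az, hard_core_nm)
  xs <- p1[, 1]; ys <- p1[, 2]
  p2 <- place_hard_core(n_ex, prop_ex, hard_core_nm, xs, ys)
  out <- empty_particles(n_az + n_ex)
  out$profile_id <- rep(profile$id, n_az + n_ex)
  out$x_nm <- c(xs, p2[, 1]); out$y_nm <- c(ys, p2[, 2])
  out$label <- c(rep("az", n_az), rep("extrasynaptic", n_ex))
  out
}

#' Sample a pre-embedding pattern: membrane vs intracellular particles
#'
#' Each particle is independently membrane-associated with probability
#' `p_membrane`, in which case it is placed inside the profile within
#' `d_offset_nm` of the membrane contour; otherwise it is placed uniformly in
#' the interior beyond that band. Keeping the two placement regions disjoint
#' makes the distance-threshold classifier identifiable from the geometry.
#'
#' @param profile `gq_profile` with a `membrane_contour`.
#' @param total_count_mean Poisson mean of the particle count per profile.
#' @param p_membrane membrane fraction in [0, 1].
#' @param d_offset_nm membrane band width (nm).
#' @param seed optional seed.
#' @return `gq_particles` with labels `"membrane"` and `"intracellular"`.
#' @export
sample_pre_embedding <- function(profile, total_count_mean, p_membrane,
                                 d_offset_nm = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profile$membrane_contour)) stop("profile has no membrane contour")
  stopifnot(p_membrane >= 0, p_membrane <= 1, d_offset_nm > 0)
  contour <- profile$membrane_contour
  n <- stats::rpois(1, total_count_mean)
  on_mem <- stats::runif(n) < p_membrane
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    for (t in 1:2000) {
      p <- runif_in_polygon(1L, profile$ring)[1, ]
      d <- dist_to_polyline(p[1], p[2], contour)
      if (on_mem[i] == (d <= d_offset_nm)) break
    }
    xs[i] <- p[1]; ys[i] <- p[2]
  }
  out <- empty_particles(n)
  out$profile_id <- rep(profile$id, n)
  out$x_nm <- xs; out$y_nm <- ys
  out$label <- ifelse(on_mem, "membrane", "intracellular")
  out
}

#' Plant a fixed number of well-separated clusters over pooled profiles
#'
#' Used for cluster-composition analyses over a matched reference area:
#' exactly `n_clusters` cluster centres are distributed over the profiles
#' (multinomially, proportional to area) and placed by dart-throwing with a
#' minimum centre separation of `2 * 3 sigma_r + link_distance_nm` plus a
#' margin, and each cluster's offspring set is resampled until it is
#' single-linkage connected at `link_distance_nm`. Well-separated connected
#' planting makes cluster-count recovery exact at any seed.
#'
#' @param profiles list of `gq_profile` (pooled reference area).
#' @param n_clusters total number of clusters to plant.
#' @param mean_size,dispersion shifted-negative-binomial size law.
#' @param sigma_r cluster radius (nm).
#' @param link_distance_nm linkage radius the downstream analysis will use.
#' @param hard_core_nm minimum particle separation (nm).
#' @param lambda_s optional scattered intensity (default 0).
#' @param seed optional seed.
#' @return `gq_particles` across all profiles; `cluster_id` numbers planted
#'   clusters globally.
#' @export
plant_clusters <- function(profiles, n_clusters, mean_size = 8,
                           dispersion = 1.5, sigma_r = 20,
                           link_distance_nm = 50, hard_core_nm = 15,
                           lambda_s = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  areas <- vapply(profiles, function(p) p$area_um2, numeric(1))
  alloc <- as.integer(stats::rmultinom(1, n_clusters, areas / sum(areas)))
  min_sep <- 2 * 3 * sigma_r + link_distance_nm + 10
  out <- empty_particles(0)
  cid0 <- 0L
  for (pi in seq_along(profiles)) {
    prof <- profiles[[pi]]
    k <- alloc[pi]
    if (k == 0 && lambda_s == 0) next
    # dart-throwing inhibition for cluster centres, margin 3 sigma from edge
    centres <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centres) < k && tries < 20000L) {
      tries <- tries + 1L
      p <- runif_in_polygon(1L, prof$ring)[1, ]
      if (dist_to_ring(p[1], p[2], prof$ring) < 3 * sigma_r) next
      if (nrow(centres) &&
          min((centres[, 1] - p[1])^2 + (centres[, 2] - p[2])^2) < min_sep^2) next
      centres <- rbind(centres, p)
    }
    if (nrow(centres) < k) stop("could not place well-separated cluster centres; reduce n_clusters or profile packing")
    sizes <- offspring_count(k, mean_size, dispersion)
    xs <- numeric(0); ys <- numeric(0); labs <- character(0); cids <- integer(0)
    for (i in seq_len(k)) {
      for (t in 1:100) {
        pts <- place_hard_core(sizes[i],
                               propose_offspring(centres[i, 1], centres[i, 2],
                                                 sigma_r, prof$ring),
                               hard_core_nm)
        comp <- single_linkage_components(pts[, 1], pts[, 2], link_distance_nm)
        if (max(comp) == 1L) break
      }
      xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
      labs <- c(labs, rep("cluster", sizes[i]))
      cids <- c(cids, rep(cid0 + i, sizes[i]))
    }
    if (lambda_s > 0) {
      n_s <- stats::rpois(1, lambda_s * prof$area_um2)
      if (n_s > 0) {
        pts <- place_hard_core(n_s, function(m) runif_in_polygon(1L, prof$ring)[1, ],
                               hard_core_nm, xs, ys)
        xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
        labs <- c(labs, rep("scattered", n_s))
        cids <- c(cids, rep(NA_integer_, n_s))
      }
    }
    add <- empty_particles(length(xs))
    add$profile_id <- rep(prof$id, length(xs))
    add$x_nm <- xs; add$y_nm <- ys; add$label <- labs; add$cluster_id <- cids
    out <- rbind(out, add)
    cid0 <- cid0 + k
  }
  as_particles(out)
}

#' Simulate all profiles of one experimental condition
#'
#' Generates `n_profiles` P-face profiles of the compartment's default
#' geometry at well-separated positions, samples the calibrated clustered +
#' scattered pattern on each, and (optionally) adds an E-face companion
#' profile carrying only background labeling.
#'
#' @param calibration a `gq_calibration`.
#' @param genotype,age_months,layer,klass the condition.
#' @param n_profiles number of profiles (default: calibrated per-class n).
#' @param include_eface add one E-face companion per P-face profile.
#' @param seed optional seed (one stream for the whole condition).
#' @return a `gq_scene`.
#' @export
simulate_condition <- function(calibration, genotype, age_months, layer, klass,
                               n_profiles = NULL, include_eface = FALSE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- condition_record(calibration, genotype, age_months, layer, klass)
  geom <- calibration$profiles[[klass]]
  if (is.null(geom)) stop("no profile geometry calibrated for class ", klass)
  if (is.null(n_profiles)) n_profiles <- geom$n_profiles
  pitch <- sqrt(geom$area_um2 * 1e6) * 4
  profiles <- list(); particles <- empty_particles(0)
  for (i in seq_len(n_profiles)) {
    ctr <- c((i - 1) %% 8, (i - 1) %/% 8) * pitch
    prof <- make_profile(geom$shape, geom$area_um2, layer, klass,
                         face = "P", centre = ctr, id = sprintf("p%03d", i))
    profiles[[length(profiles) + 1L]] <- prof
    particles <- rbind(particles, sample_point_pattern(prof, cfg))
    if (include_eface) {
      ectr <- ctr + c(pitch / 2, pitch / 2)
      eprof <- make_profile("blob", geom$area_um2, layer, klass,
                            face = "E", centre = ectr,
                            id = sprintf("e%03d", i))
      profiles[[length(profiles) + 1L]] <- eprof
      particles <- rbind(particles,
                         sample_background_pattern(eprof, cfg$eface_background))
    }
  }
  make_scene(profiles, as_particles(particles), mode = "sds_frl",
             nm_per_px = calibration$raster$nm_per_px, seed = seed %||% NA,
             scene_id = sprintf("%s_%dmo_%s_%s", genotype, age_months, layer, klass))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
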