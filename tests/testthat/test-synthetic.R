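# Synthetic scene generator: point processes, pre-embedding split,
# rasterization, conservation / containment / reproducibility invariants.

test_that("zero intensities give an empty pattern", {
  prof <- square_profile()
  pts <- sample_point_pattern(prof, flat_config(0, 0), seed = 1)
  expect_s3_class(pts, "gq_particles")
  expect_equal(nrow(pts), 0)
})

test_that("scattered process recovers the Poisson mean lambda * area", {
  prof <- square_profile(side_nm = sqrt(2) * 1000)  # 2.0 um^2
  set.seed(42)
  counts <- replicate(400, nrow(sample_point_pattern(prof, flat_config(0, 10))))
  # mean 20, se = sqrt(20/400)
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 400))
})

test_that("clustered process recovers area * (lambda_c mu_k + lambda_s)", {
  prof <- square_profile()
  cfg <- flat_config(lambda_c = 5, lambda_s = 8, mu_k = 6, hard_core_nm = 15)
  set.seed(43)
  counts <- replicate(150, nrow(sample_point_pattern(prof, cfg)))
  expected <- 5 * 6 + 8
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("every generated particle is labelled, inside, and conserved", {
  cal <- load_calibration()
  cfg <- condition_record(cal, "WT", 6, "slm", "oblique_dendrite")
  set.seed(5)
  prof <- make_profile("ribbon", 1.0, "slm", "oblique_dendrite", id = "r1")
  pts <- sample_point_pattern(prof, cfg)
  expect_true(all(pts$label %in% c("cluster", "scattered")))
  # conservation: per-label counts sum to the total
  expect_equal(sum(pts$label == "cluster") + sum(pts$label == "scattered"),
               nrow(pts))
  # containment oracle: all particles inside the polygon
  expect_true(all(oracle_ray_cast(pts$x_nm, pts$y_nm, prof$ring)))
  # hard core respected
  if (nrow(pts) > 1) {
    expect_gte(min(stats::dist(cbind(pts$x_nm, pts$y_nm))), cfg$hard_core_nm)
  }
  # cluster ids are only on cluster particles
  expect_true(all(is.na(pts$cluster_id[pts$label == "scattered"])))
  expect_true(all(!is.na(pts$cluster_id[pts$label == "cluster"])))
})

test_that("identical config and seed reproduce particle tables and images", {
  cal <- load_calibration()
  s1 <- simulate_condition(cal, "WT", 6, "slm", "spine", n_profiles = 3,
                           seed = 99)
  s2 <- simulate_condition(cal, "WT", 6, "slm", "spine", n_profiles = 3,
                           seed = 99)
  expect_identical(s1$particles, s2$particles)
  i1 <- rasterize(s1, seed = 7); i2 <- rasterize(s2, seed = 7)
  expect_identical(i1, i2)
})

test_that("invalid generator inputs are rejected", {
  prof <- square_profile()
  expect_error(sample_point_pattern(prof, flat_config(-1, 0), seed = 1),
               "non-negative")
  eface <- square_profile(face = "E", id = "e1")
  expect_error(sample_point_pattern(eface, flat_config(1, 1), seed = 1),
               "P-face")
})

test_that("presynaptic sampler labels AZ and extrasynaptic pools correctly", {
  set.seed(12)
  prof <- make_terminal_profile(0.3, 0.05, "sr")
  az <- prof$subregions$active_zone
  pts <- sample_presynaptic_pattern(prof, az_intensity = 100,
                                    extra_intensity = 30)
  expect_true(all(pts$label %in% c("az", "extrasynaptic")))
  in_az <- oracle_ray_cast(pts$x_nm, pts$y_nm, az)
  expect_true(all(in_az[pts$label == "az"]))
  expect_true(!any(in_az[pts$label == "extrasynaptic"]))
  # mean AZ count = lambda * area (0.05 um^2 at 100/um^2 -> 5)
  set.seed(13)
  n_az <- replicate(300, {
    p <- sample_presynaptic_pattern(prof, 100, 0)
    nrow(p)
  })
  expect_lt(abs(mean(n_az) - 5), 3 * sd(n_az) / sqrt(300))
})

test_that("equal AZ and extrasynaptic intensities give a homogeneous pool", {
  set.seed(14)
  prof <- make_terminal_profile(0.3, 0.05, "sr")
  a_az <- polygon_area_um2(prof$subregions$active_zone)
  frac_az <- a_az / prof$area_um2
  pooled <- replicate(200, {
    p <- sample_presynaptic_pattern(prof, 80, 80)
    c(sum(p$label == "az"), nrow(p))
  })
  # AZ share of the pooled pattern ~ AZ share of the area
  expect_lt(abs(sum(pooled[1, ]) / sum(pooled[2, ]) - frac_az), 0.02)
})

test_that("pre-embedding sampler honours the membrane fraction", {
  set.seed(15)
  prof <- make_preembedding_profile(1.0)
  # degenerate fraction: all particles within the offset band
  pts <- sample_pre_embedding(prof, 40, p_membrane = 1, d_offset_nm = 25)
  d <- dist_to_polyline(pts$x_nm, pts$y_nm, prof$membrane_contour)
  expect_true(all(d <= 25))
  # Bernoulli mean at p = 0.5 over pooled draws
  set.seed(16)
  tot <- c(mem = 0, all = 0)
  while (tot["all"] < 10000) {
    p <- sample_pre_embedding(prof, 200, 0.5, d_offset_nm = 25)
    tot["mem"] <- tot["mem"] + sum(p$label == "membrane")
    tot["all"] <- tot["all"] + nrow(p)
  }
  phat <- tot[["mem"]] / tot[["all"]]
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / tot[["all"]]))
  expect_error(sample_pre_embedding(square_profile(), 10, 0.5),
               "membrane contour")
})

test_that("rasterization draws particles as dark disks with clean metadata", {
  prof <- square_profile(1000, id = "sq")
  # empty scene: pure background, no pixel at disk depth
  sc0 <- make_scene(list(prof), empty_particles())
  img0 <- rasterize(sc0, noise = noise_model(noise_sd = 0, shade_amp = 0))
  expect_true(min(img0) > 0.8)
  # single particle at a known position: darkest pixel within 1 px
  p1 <- empty_particles(1)
  p1$profile_id <- "sq"; p1$x_nm <- 120; p1$y_nm <- -80
  p1$label <- "scattered"
  sc1 <- make_scene(list(prof), p1)
  img1 <- rasterize(sc1, noise = noise_model(noise_sd = 0, shade_amp = 0))
  origin <- attr(img1, "origin_nm")
  # the disk interior is a plateau at the minimum; its centroid marks the
  # particle centre
  ij <- arrayInd(which(img1 <= min(img1) + 1e-9), dim(img1))
  hit <- c(origin["x"] + (mean(ij[, 2]) - 0.5),
           origin["y"] + (mean(ij[, 1]) - 0.5))
  expect_lt(max(abs(hit - c(120, -80))), 1)
  # undersampled particles warn
  expect_warning(rasterize(sc1, nm_per_px = 5, particle_diameter_nm = 9),
                 "unreliable")
})

test_that("planted clusters always satisfy the minimum-size rule", {
  set.seed(17)
  profiles <- lapply(1:4, function(i) {
    make_profile("ribbon", 1.0, "sr_prox", "oblique_dendrite",
                 centre = c(i * 4500, 0), id = paste0("od", i))
  })
  pts <- plant_clusters(profiles, 10, mean_size = 6, dispersion = 1.5)
  sizes <- table(pts$cluster_id)
  expect_equal(length(sizes), 10L)
  expect_true(all(sizes >= 3))
  expect_true(all(oracle_ray_cast(pts$x_nm, pts$y_nm, profiles[[1]]$ring) |
                    pts$profile_id != "od1"))
})
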