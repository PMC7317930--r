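# Blob detector: delta recovery, determinism, threshold monotonicity,
# translation equivariance, seeded refinement, and truth matching.

make_planted_image <- function(xy, side_nm = 800, noise = noise_model(
                                 noise_sd = 0, shade_amp = 0)) {
  prof <- square_profile(side_nm, centre = c(side_nm / 2, side_nm / 2))
  pts <- empty_particles(nrow(xy))
  pts$profile_id <- "sq"
  pts$x_nm <- xy[, 1]; pts$y_nm <- xy[, 2]
  pts$label <- "scattered"
  sc <- make_scene(list(prof), pts)
  rasterize(sc, noise = noise)
}

test_that("blank and constant images give zero detections with a warning", {
  img <- matrix(0.85, 200, 200)
  attr(img, "nm_per_px") <- 1
  expect_warning(d <- detect_particles(img), "constant")
  expect_equal(nrow(d), 0)
  set.seed(2)
  noisy_blank <- matrix(0.85 + rnorm(200 * 200, 0, 0.05), 200, 200)
  attr(noisy_blank, "nm_per_px") <- 1
  expect_equal(nrow(detect_particles(noisy_blank)), 0)
})

test_that("well-separated particles are each recovered within 3 nm", {
  xy <- cbind(c(100, 300, 500, 650, 200), c(120, 380, 150, 600, 650))
  img <- make_planted_image(xy)
  det <- detect_particles(img)
  expect_equal(nrow(det), 5)
  for (k in seq_len(5)) {
    d <- sqrt((det$x_nm - xy[k, 1])^2 + (det$y_nm - xy[k, 2])^2)
    expect_lt(min(d), 3)
  }
})

test_that("detection is deterministic and monotone in the threshold", {
  set.seed(33)
  xy <- cbind(runif(30, 50, 750), runif(30, 50, 750))
  img <- make_planted_image(xy, noise = noise_model())
  d1 <- detect_particles(img)
  d2 <- detect_particles(img)
  expect_identical(d1, d2)
  n_by_thr <- vapply(c(0.1, 0.2, 0.3, 0.5, 0.7), function(thr) {
    nrow(detect_particles(img, params = detection_params(
      response_threshold = thr)))
  }, numeric(1))
  expect_true(all(diff(n_by_thr) <= 0))
})

test_that("whole-pixel image translation translates detections identically", {
  xy <- cbind(c(200, 400, 550), c(250, 500, 300))
  img <- make_planted_image(xy)
  attr_nm <- attr(img, "nm_per_px")
  shift <- 7L
  img2 <- img[, c((shift + 1):ncol(img), 1:shift)]  # shift left by 7 px
  attr(img2, "nm_per_px") <- attr_nm
  attr(img2, "origin_nm") <- attr(img, "origin_nm")
  d1 <- detect_particles(img)
  d2 <- detect_particles(img2)
  keep <- d1$x_nm - attr(img, "origin_nm")["x"] > (shift + 10)  # interior
  d1k <- d1[keep, ]
  expect_equal(nrow(d2), nrow(d1k) + sum(!keep))
  for (k in which(keep)) {
    d <- sqrt((d2$x_nm - (d1$x_nm[k] - shift))^2 + (d2$y_nm - d1$y_nm[k])^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("seeded refinement snaps to the response peak", {
  xy <- cbind(c(300), c(400))
  img <- make_planted_image(xy)
  # seed exactly on the particle: agrees with automated detection
  auto <- detect_particles(img)
  s1 <- refine_seeded(img, data.frame(x_nm = 300, y_nm = 400))
  expect_equal(nrow(s1), 1)
  expect_lt(sqrt((s1$x_nm - auto$x_nm)^2 + (s1$y_nm - auto$y_nm)^2), 1)
  # seed offset by 4 nm: snapped within 1 nm of truth on a noiseless image
  s2 <- refine_seeded(img, data.frame(x_nm = 304, y_nm = 397))
  expect_lt(sqrt((s2$x_nm - 300)^2 + (s2$y_nm - 400)^2), 1)
  # empty seed list and flat-region seeds
  expect_equal(nrow(refine_seeded(img, data.frame(x_nm = numeric(0),
                                                  y_nm = numeric(0)))), 0)
  expect_message(s3 <- refine_seeded(img, data.frame(x_nm = 700, y_nm = 700)),
                 "flat region")
  expect_equal(nrow(s3), 0)
  # two seeds on one particle merge by the min-separation rule
  s4 <- refine_seeded(img, data.frame(x_nm = c(297, 303), y_nm = c(400, 401)))
  expect_equal(nrow(s4), 1)
})

test_that("truth matching reports exact metrics on known configurations", {
  tru <- data.frame(x_nm = c(10, 50, 90), y_nm = c(10, 50, 90))
  m0 <- match_to_truth(tru, tru)
  expect_equal(m0$recall, 1); expect_equal(m0$precision, 1)
  expect_equal(m0$rmse_nm, 0)
  det <- rbind(tru, data.frame(x_nm = 500, y_nm = 500))
  m1 <- match_to_truth(det, tru)
  expect_equal(m1$tp, 3); expect_equal(m1$fp, 1); expect_equal(m1$fn, 0)
  expect_equal(m1$precision, 0.75)
})

test_that("gate matching equals the exhaustive optimal assignment", {
  set.seed(44)
  for (rep in 1:25) {
    nd <- sample(3:8, 1); nt <- sample(3:8, 1)
    det <- data.frame(x_nm = runif(nd, 0, 60), y_nm = runif(nd, 0, 60))
    tru <- data.frame(x_nm = runif(nt, 0, 60), y_nm = runif(nt, 0, 60))
    m <- match_to_truth(det, tru, gate_nm = 15)
    expect_equal(m$tp, oracle_max_matching(det, tru, 15))
  }
})

test_that("detection stays accurate at calibrated densities under noise", {
  cal <- load_calibration()
  cfg <- condition_record(cal, "WT", 6, "slm", "oblique_dendrite")
  set.seed(55)
  rec <- prec <- numeric(8)
  for (s in seq_len(8)) {
    prof <- make_profile("ribbon", 0.5, "slm", "oblique_dendrite",
                         id = "od")
    pts <- sample_point_pattern(prof, cfg)
    sc <- make_scene(list(prof), pts)
    img <- rasterize(sc, noise = noise_model())
    det <- detect_particles(img)
    m <- match_to_truth(det, pts, gate_nm = 10)
    rec[s] <- m$recall; prec[s] <- m$precision
  }
  expect_gte(mean(rec), 0.95)
  expect_gte(mean(prec), 0.95)
})
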