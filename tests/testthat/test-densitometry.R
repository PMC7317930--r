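# Histoblot / immunoblot densitometry: ROI readout, background subtraction,
# band normalization, and the linearity / offset-invariance properties.

test_that("ROI density inverts pixel values exactly on uniform images", {
  img <- matrix(0.3, 200, 200)
  r <- roi_density(img, roi_spec(c(1, 1), 0.10), mm_per_px = 0.01)
  expect_equal(r$raw_density, 0.7)
  dark <- matrix(1, 200, 200); dark[80:120, 80:120] <- 0
  r2 <- roi_density(dark, roi_spec(c(1, 1), 0.10), mm_per_px = 0.01)
  expect_equal(r2$raw_density, 1)  # disk fully inside the dark region
  expect_error(roi_density(img, roi_spec(c(0.02, 1), 0.10), 0.01), "bounds")
})

test_that("background subtraction enforces the configured ROI count", {
  rec <- background_subtract(100, rep(20, 8), label = "CA1_slm")
  expect_equal(rec$corrected, 80)
  expect_equal(background_subtract(15, rep(15, 8))$corrected, 0)
  neg <- background_subtract(10, rep(15, 8))
  expect_equal(neg$corrected, -5)
  expect_true(neg$negative_flag)
  expect_error(background_subtract(10, rep(15, 5)), "expected 8")
  expect_warning(background_subtract(10, rep(15, 5), strict = FALSE),
                 "expected 8")
})

test_that("raw densities are linear in stain darkness", {
  set.seed(91)
  base <- matrix(runif(100 * 100, 0.5, 1), 100, 100)
  roi <- roi_spec(c(0.5, 0.5), 0.2)
  r1 <- roi_density(base, roi, 0.01)$raw_density
  darker <- 1 - 2 * (1 - base)  # darkness doubled
  r2 <- roi_density(darker, roi, 0.01)$raw_density
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
})

test_that("corrected densities are invariant to a constant image offset", {
  set.seed(92)
  img <- matrix(runif(200 * 200, 0.4, 0.9), 200, 200)
  rois <- lapply(1:3, function(k) roi_spec(c(k * 0.4, 0.6), 0.10, paste0("r", k)))
  bg_rois <- lapply(1:8, function(k) roi_spec(c(k * 0.2, 1.5), 0.10))
  corrected <- function(im) {
    bg <- vapply(bg_rois, function(r) roi_density(im, r, 0.01)$raw_density,
                 numeric(1))
    vapply(rois, function(r) {
      background_subtract(roi_density(im, r, 0.01)$raw_density, bg)$corrected
    }, numeric(1))
  }
  expect_equal(corrected(img), corrected(img - 0.08), tolerance = 1e-9)
})

test_that("synthetic blot corrected densities preserve the generating order", {
  ring_at <- function(cx, cy, w = 0.8, h = 0.4) {
    cbind(cx + c(-w, w, w, -w) / 2, cy + c(-h, -h, h, h) / 2)
  }
  regions <- list(
    list(ring = ring_at(1, 1), intensity = 0.2, label = "weak"),
    list(ring = ring_at(3, 1), intensity = 0.5, label = "mid"),
    list(ring = ring_at(5, 1), intensity = 0.8, label = "strong"))
  scan <- simulate_blot(regions, seed = 93)
  bg <- vapply(1:8, function(k) {
    roi_density(scan, roi_spec(c(0.3 + k * 0.6, 3.2), 0.10), 0.01)$raw_density
  }, numeric(1))
  cor <- vapply(c(1, 3, 5), function(cx) {
    background_subtract(
      roi_density(scan, roi_spec(c(cx, 1), 0.10), 0.01)$raw_density, bg)$corrected
  }, numeric(1))
  expect_true(all(diff(cor) > 0))
})

test_that("band quantification recovers planted lane ratios", {
  lane <- matrix(1, 300, 80)
  lane[60:80, 20:60] <- 1 - 0.6    # target band
  lane[200:220, 20:60] <- 1 - 0.8  # reference band
  b <- list(rows = 50:90, cols = 15:65)
  r <- list(rows = 190:230, cols = 15:65)
  q <- band_quantify(lane, b, r)
  expect_equal(q$ratio, 0.75, tolerance = 1e-6)
  expect_equal(band_quantify(lane, b, b2 <- r)$ratio, 0.75, tolerance = 1e-6)
  # identical windows' content -> ratio 1
  lane2 <- lane; lane2[200:220, 20:60] <- 1 - 0.6
  expect_equal(band_quantify(lane2, b, r)$ratio, 1, tolerance = 1e-6)
  expect_error(band_quantify(lane, b, list(rows = 80:120, cols = 15:65)),
               "overlap")
  blank <- matrix(1, 300, 80)
  expect_error(band_quantify(blank, b, r), "reference")
  # blurred + noisy planted ratio
  set.seed(94)
  regions <- list(
    list(ring = cbind(c(0.5, 2.5, 2.5, 0.5), c(0.8, 0.8, 1.2, 1.2)),
         intensity = 0.45, label = "band"),
    list(ring = cbind(c(0.5, 2.5, 2.5, 0.5), c(2.8, 2.8, 3.2, 3.2)),
         intensity = 0.60, label = "ref"))
  scan <- simulate_blot(regions, width_mm = 3, height_mm = 4, seed = 95)
  q2 <- band_quantify(scan, list(rows = 60:140, cols = 40:260),
                      list(rows = 260:340, cols = 40:260))
  expect_equal(q2$ratio, 0.75, tolerance = 0.02)
})

test_that("equal-intensity groups rarely test significant", {
  # synthetic blots generated with identical WT/APP region intensities:
  # the genotype comparison should be non-significant in >= 95% of seeds
  ring_at <- function(cx, cy) cbind(cx + c(-0.4, 0.4, 0.4, -0.4),
                                    cy + c(-0.2, -0.2, 0.2, 0.2))
  read_region <- function(seed) {
    regions <- list(list(ring = ring_at(1, 1), intensity = 0.5, label = "r"))
    scan <- simulate_blot(regions, width_mm = 2, height_mm = 2,
                          mm_per_px = 0.02, seed = seed)
    roi_density(scan, roi_spec(c(1, 1), 0.3), 0.02)$raw_density
  }
  set.seed(96)
  seeds <- matrix(sample.int(1e6, 60 * 8), nrow = 60)
  p_vals <- apply(seeds, 1, function(ss) {
    wt <- vapply(ss[1:4], read_region, numeric(1))
    app <- vapply(ss[5:8], read_region, numeric(1))
    stats::t.test(wt, app)$p.value
  })
  expect_gte(mean(p_vals > 0.05), 0.95)
})
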