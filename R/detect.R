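# Gold-particle detection: multi-scale Laplacian-of-Gaussian blob detector
# for dark disks on a bright background, with non-maximum suppression,
# sub-pixel localization and a seeded (semi-automated) refinement mode.
#
# The response is normalized so that an ideal noiseless disk of full contrast
# (depth 1) at the matched scale scores 1.0; `response_threshold` is a
# fraction of that ideal contrast. The normalization constants are
# self-calibrated by rendering analytic disks at each scale.

#' Detection parameters
#'
#' @param expected_diameter_nm nominal particle diameter (default 10 nm).
#' @param diameter_tolerance relative half-width of the scale band searched
#'   around the nominal diameter (default 0.4, i.e. +/-40%).
#' @param response_threshold relative blob-response cutoff in (0, 1); the
#'   fraction of the ideal full-contrast disk response a candidate must reach.
#' @param min_separation_nm non-maximum suppression radius (default: one
#'   particle diameter).
#' @param n_scales number of LoG scales spanning the band.
#' @return list of class `gq_detection_params`.
#' @export
detection_params <- function(expected_diameter_nm = 10,
                             diameter_tolerance = 0.4,
                             response_threshold = 0.3,
                             min_separation_nm = expected_diameter_nm,
                             n_scales = 4) {
  stopifnot(expected_diameter_nm > 0,
            diameter_tolerance > 0, diameter_tolerance < 1,
            response_threshold > 0, response_threshold < 1,
            min_separation_nm > 0, n_scales >= 1)
  structure(as.list(environment()), class = "gq_detection_params")
}

# discrete 5-point Laplacian with replicated borders
laplacian <- function(m) {
  h <- nrow(m); w <- ncol(m)
  up <- m[c(1, seq_len(h - 1)), ]; dn <- m[c(seq_len(h - 1) + 1, h), ]
  lf <- m[, c(1, seq_len(w - 1))]; rt <- m[, c(seq_len(w - 1) + 1, w)]
  up + dn + lf + rt - 4 * m
}

# scale-normalized dark-blob response at one radius (pixels)
log_response <- function(img, r_px) {
  sigma <- r_px / sqrt(2)
  sm <- EBImage::gblur(img, sigma = sigma)
  sigma^2 * laplacian(sm)  # positive at the centre of a dark blob
}

# peak response of an ideal depth-1 disk of radius r_px (memoised per scale)
.disk_cal <- new.env(parent = emptyenv())
ideal_disk_response <- function(r_px) {
  key <- sprintf("%.4f", r_px)
  if (!is.null(.disk_cal[[key]])) return(.disk_cal[[key]])
  n <- ceiling(r_px * 8) + 9L
  cx <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, `+`))
  disk <- 1 - pmin(pmax(r_px + 0.5 - d, 0), 1)  # bright bg 1, dark disk 0
  val <- max(log_response(disk, r_px))
  .disk_cal[[key]] <- val
  val
}

detection_scales <- function(params, nm_per_px) {
  r0 <- params$expected_diameter_nm / 2 / nm_per_px
  r0 * seq(1 - params$diameter_tolerance, 1 + params$diameter_tolerance,
           length.out = params$n_scales)
}

#' Detect gold particles in a grayscale image
#'
#' Multi-scale LoG dark-blob detection over the diameter band, thresholded
#' on normalized response, greedily non-maximum-suppressed at
#' `min_separation_nm`, with sub-pixel localization by local centre of mass
#' of the response. Deterministic for fixed input.
#'
#' @param image numeric matrix in [0, 1] (rows = y); attributes `nm_per_px`
#'   and `origin_nm` are honoured when present.
#' @param nm_per_px raster scale; defaults to the image attribute.
#' @param params a [detection_params()].
#' @return data.frame of class `gq_detections`: `x_nm, y_nm, radius_nm,
#'   response`.
#' @export
detect_particles <- function(image, nm_per_px = NULL,
                             params = detection_params()) {
  nm_per_px <- nm_per_px %||% attr(image, "nm_per_px")
  if (is.null(nm_per_px)) stop("nm_per_px unknown")
  origin <- attr(image, "origin_nm") %||% c(x = 0, y = 0)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      radius_nm = numeric(0), response = numeric(0))
  class(empty) <- c("gq_detections", "data.frame")
  if (diff(range(image)) < 1e-6) {
    warning("constant or saturated image; no detections")
    return(empty)
  }
  radii <- detection_scales(params, nm_per_px)
  h <- nrow(image); w <- ncol(image)
  best <- matrix(-Inf, h, w); best_r <- matrix(radii[1], h, w)
  for (r in radii) {
    resp <- log_response(image, r) / ideal_disk_response(r)
    upd <- resp > best
    best[upd] <- resp[upd]; best_r[upd] <- r
  }
  # 3x3 local maxima above threshold (image borders excluded)
  cand <- which(best >= params$response_threshold)
  cand <- cand[{
    ij <- arrayInd(cand, dim(best))
    ij[, 1] > 1 & ij[, 1] < h & ij[, 2] > 1 & ij[, 2] < w
  }]
  if (!length(cand)) return(empty)
  ij <- arrayInd(cand, dim(best))
  is_max <- vapply(seq_along(cand), function(k) {
    i <- ij[k, 1]; j <- ij[k, 2]
    best[i, j] >= max(best[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, logical(1))
  ij <- ij[is_max, , drop = FALSE]
  if (!nrow(ij)) return(empty)
  resp_v <- best[ij]
  # greedy NMS, strongest first; ties broken by position for determinism
  ord <- order(-resp_v, ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]; resp_v <- resp_v[ord]
  min_sep_px2 <- (params$min_separation_nm / nm_per_px)^2
  keep <- logical(nrow(ij))
  ky <- numeric(0); kx <- numeric(0)
  for (k in seq_len(nrow(ij))) {
    if (length(ky) &&
        min((ky - ij[k, 1])^2 + (kx - ij[k, 2])^2) < min_sep_px2) next
    keep[k] <- TRUE; ky <- c(ky, ij[k, 1]); kx <- c(kx, ij[k, 2])
  }
  ij <- ij[keep, , drop = FALSE]; resp_v <- resp_v[keep]
  # sub-pixel localization: centre of mass of the response in a 5x5 window
  out <- data.frame(x_nm = numeric(nrow(ij)), y_nm = numeric(nrow(ij)),
                    radius_nm = best_r[ij] * nm_per_px, response = resp_v)
  for (k in seq_len(nrow(ij))) {
    i <- ij[k, 1]; j <- ij[k, 2]
    ii <- max(1, i - 2):min(h, i + 2); jj <- max(1, j - 2):min(w, j + 2)
    win <- best[ii, jj, drop = FALSE]
    win <- win - min(win)
    if (sum(win) <= 0) { ci <- i; cj <- j } else {
      ci <- sum(row(win) * win) / sum(win) + ii[1] - 1
      cj <- sum(col(win) * win) / sum(win) + jj[1] - 1
    }
    out$x_nm[k] <- origin["x"] + (cj - 0.5) * nm_per_px
    out$y_nm[k] <- origin["y"] + (ci - 0.5) * nm_per_px
  }
  out <- out[order(out$x_nm, out$y_nm), ]
  rownames(out) <- NULL
  class(out) <- c("gq_detections", "data.frame")
  out
}

#' Semi-automated detection: snap seed points to response maxima
#'
#' Each approximate seed is snapped to the strongest response pixel within
#' one expected diameter; seeds in flat regions (below threshold) are
#' dropped with a notice, and duplicates are merged by the minimum-
#' separation rule.
#'
#' @param image grayscale matrix.
#' @param seeds data.frame or matrix with columns x_nm, y_nm.
#' @param nm_per_px raster scale; defaults to the image attribute.
#' @param params a [detection_params()].
#' @return `gq_detections` data.frame.
#' @export
refine_seeded <- function(image, seeds, nm_per_px = NULL,
                          params = detection_params()) {
  nm_per_px <- nm_per_px %||% attr(image, "nm_per_px")
  origin <- attr(image, "origin_nm") %||% c(x = 0, y = 0)
  seeds <- as.data.frame(seeds)
  empty <- data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      radius_nm = numeric(0), response = numeric(0))
  class(empty) <- c("gq_detections", "data.frame")
  if (!nrow(seeds)) return(empty)
  r_mid <- mean(detection_scales(params, nm_per_px))
  resp <- log_response(image, r_mid) / ideal_disk_response(r_mid)
  h <- nrow(image); w <- ncol(image)
  rad_px <- params$expected_diameter_nm / nm_per_px
  hits <- empty
  for (k in seq_len(nrow(seeds))) {
    j <- (seeds$x_nm[k] - origin["x"]) / nm_per_px + 0.5
    i <- (seeds$y_nm[k] - origin["y"]) / nm_per_px + 0.5
    if (i < 1 || i > h || j < 1 || j > w) stop("seed outside the image")
    ii <- max(1, round(i - rad_px)):min(h, round(i + rad_px))
    jj <- max(1, round(j - rad_px)):min(w, round(j + rad_px))
    win <- resp[ii, jj, drop = FALSE]
    if (max(win) < params$response_threshold) {
      message("seed ", k, " in flat region; dropped")
      next
    }
    am <- arrayInd(which.max(win), dim(win))
    pi_ <- ii[am[1]]; pj <- jj[am[2]]
    i2 <- max(1, pi_ - 2):min(h, pi_ + 2); j2 <- max(1, pj - 2):min(w, pj + 2)
    wv <- resp[i2, j2, drop = FALSE]; wv <- wv - min(wv)
    if (sum(wv) <= 0) { ci <- pi_; cj <- pj } else {
      ci <- sum(row(wv) * wv) / sum(wv) + i2[1] - 1
      cj <- sum(col(wv) * wv) / sum(wv) + j2[1] - 1
    }
    hits <- rbind(hits, data.frame(
      x_nm = unname(origin["x"] + (cj - 0.5) * nm_per_px),
      y_nm = unname(origin["y"] + (ci - 0.5) * nm_per_px),
      radius_nm = r_mid * nm_per_px, response = max(win)))
  }
  if (nrow(hits) > 1) {  # merge duplicates snapped to the same particle
    ord <- order(-hits$response)
    hits <- hits[ord, ]
    keep <- logical(nrow(hits)); kx <- numeric(0); ky <- numeric(0)
    for (k in seq_len(nrow(hits))) {
      if (length(kx) && min((kx - hits$x_nm[k])^2 + (ky - hits$y_nm[k])^2) <
          params$min_separation_nm^2) next
      keep[k] <- TRUE; kx <- c(kx, hits$x_nm[k]); ky <- c(ky, hits$y_nm[k])
    }
    hits <- hits[keep, ]
  }
  rownames(hits) <- NULL
  class(hits) <- c("gq_detections", "data.frame")
  hits
}

#' Score detections against ground truth
#'
#' One-to-one matching between detections and truth particles that maximizes
#' the number of matches under a distance gate (augmenting-path bipartite
#' matching; neighbours tried nearest-first so ties resolve to close pairs).
#'
#' @param detections data.frame with `x_nm`, `y_nm`.
#' @param truth data.frame with `x_nm`, `y_nm`.
#' @param gate_nm maximum match distance (default 10 nm).
#' @return list: `tp`, `fp`, `fn`, `recall`, `precision`, `rmse_nm`,
#'   `matches` (data.frame detection/truth row indices and distance).
#' @export
match_to_truth <- function(detections, truth, gate_nm = 10) {
  nd <- nrow(detections); nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(tp = 0L, fp = nd, fn = nt,
                recall = if (nt) 0 else NA_real_,
                precision = if (nd) 0 else NA_real_,
                rmse_nm = NA_real_,
                matches = data.frame(detection = integer(0),
                                     truth = integer(0), dist_nm = numeric(0))))
  }
  g2 <- gate_nm^2
  adj <- vector("list", nd)
  for (i in seq_len(nd)) {
    d2 <- (truth$x_nm - detections$x_nm[i])^2 +
          (truth$y_nm - detections$y_nm[i])^2
    nb <- which(d2 <= g2)
    adj[[i]] <- nb[order(d2[nb])]
  }
  match_t <- rep(0L, nt)  # truth j -> detection i
  try_kuhn <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_t[j] == 0L || Recall(match_t[j], seen)) {
        match_t[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  for (i in seq_len(nd)) try_kuhn(i, logical(nt))
  mt <- which(match_t > 0L)
  md <- match_t[mt]
  dist_nm <- sqrt((truth$x_nm[mt] - detections$x_nm[md])^2 +
                  (truth$y_nm[mt] - detections$y_nm[md])^2)
  tp <- length(mt)
  list(tp = tp, fp = nd - tp, fn = nt - tp,
       recall = tp / nt, precision = tp / nd,
       rmse_nm = if (tp) sqrt(mean(dist_nm^2)) else NA_real_,
       matches = data.frame(detection = md, truth = mt, dist_nm = dist_nm))
}
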