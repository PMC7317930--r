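# Packaged generating calibration: per-condition intensities transcribed from
# the study's printed results, plus raster/process defaults.

#' Load the packaged (or a user) calibration
#'
#' The calibration holds, per experimental condition (genotype x age x
#' compartment), the generating surface densities of the synthetic scenes,
#' plus raster and point-process defaults. Densities carry a `source` tag:
#' values printed in the source study's text (`body_text`), figure-legend
#' variants (`alternates`), and plausible fill-ins (`assumed`) for
#' compartments whose absolute densities were shown only graphically.
#'
#' @param path optional path to a calibration YAML; default is the packaged
#'   file under `inst/extdata/calibration.yaml`.
#' @return A list of class `gq_calibration`.
#' @export
#' @examples
#' cal <- load_calibration()
#' condition_density(cal, "WT", 6, "slm", "oblique_dendrite")  # 64.34
load_calibration <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibration.yaml", package = "goldquant")
  }
  if (!nzchar(path) || !file.exists(path)) stop("calibration file not found: ", path)
  cal <- yaml::read_yaml(path)
  stopifnot(is.list(cal$gradient), is.list(cal$process), is.list(cal$raster))
  cal$path <- path
  cal$hash <- unname(tools::md5sum(path))
  class(cal) <- "gq_calibration"
  cal
}

#' @export
print.gq_calibration <- function(x, ...) {
  cat("<gq_calibration>", length(x$gradient$baseline), "gradient compartments;",
      length(x$pre_embedding$conditions), "pre-embedding conditions;",
      length(x$clusters_12mo$conditions), "cluster conditions\n")
  invisible(x)
}

#' Enumerate the 11 somato-dendritic compartment classes
#'
#' The somato-dendritic compartments used for the density-gradient analysis:
#' soma (stratum pyramidale only), apical and oblique dendrites, and spines
#' across the strata of CA1. Ordered soma -> apical -> oblique -> spine
#' within each layer for report tables.
#'
#' @param calibration a `gq_calibration` (default: packaged).
#' @return data.frame with columns `layer`, `klass`.
#' @export
compartment_classes <- function(calibration = load_calibration()) {
  b <- calibration$gradient$baseline
  df <- data.frame(
    layer = vapply(b, `[[`, "", "layer"),
    klass = vapply(b, `[[`, "", "klass"),
    stringsAsFactors = FALSE
  )
  klass_order <- c("soma", "apical_dendrite", "oblique_dendrite", "spine")
  layer_order <- c("so", "sp", "sr_prox", "sr_dist", "slm")
  df <- df[order(match(df$layer, layer_order), match(df$klass, klass_order)), ]
  rownames(df) <- NULL
  stopifnot(all(df$layer[df$klass == "soma"] == "sp"))
  df
}

#' Generating mean density for one condition
#'
#' @param calibration a `gq_calibration`.
#' @param genotype "WT" or "APP_PS1".
#' @param age_months 1, 6 or 12.
#' @param layer,klass compartment class.
#' @return density in particles/um^2.
#' @export
condition_density <- function(calibration, genotype, age_months, layer, klass) {
  genotype <- match.arg(genotype, c("WT", "APP_PS1"))
  stopifnot(age_months %in% c(1, 6, 12))
  base <- NULL
  for (b in calibration$gradient$baseline) {
    if (b$layer == layer && b$klass == klass) base <- b$density
  }
  if (is.null(base)) stop("unknown compartment: ", layer, "/", klass)
  for (ov in calibration$gradient$overrides) {
    if (ov$age_months == age_months && ov$genotype == genotype &&
        ov$layer == layer && ov$klass == klass) {
      return(ov$density)
    }
  }
  if (genotype == "APP_PS1" && age_months == 12) {
    return(base * calibration$gradient$app_12mo_fraction)
  }
  base
}

#' Full per-condition generator record
#'
#' Combines the condition density with the shared point-process parameters
#' into the record consumed by [sample_point_pattern()]: cluster-centre
#' intensity `lambda_c`, mean offspring count `mu_k`, offspring dispersion,
#' cluster radius `sigma_r`, scattered intensity `lambda_s`, and the E-face
#' background intensity.
#'
#' @inheritParams condition_density
#' @return list of class `gq_condition`.
#' @export
condition_record <- function(calibration, genotype, age_months, layer, klass) {
  d <- condition_density(calibration, genotype, age_months, layer, klass)
  p <- calibration$process
  lambda_s <- p$frac_scattered * d
  lambda_c <- (1 - p$frac_scattered) * d / p$mean_cluster_size
  structure(list(
    genotype = genotype, age_months = age_months, layer = layer, klass = klass,
    density = d,
    lambda_c = lambda_c,
    mu_k = p$mean_cluster_size,
    dispersion = p$offspring_dispersion,
    sigma_r = p$cluster_radius_nm,
    lambda_s = lambda_s,
    hard_core_nm = p$hard_core_nm,
    eface_background = p$eface_background_per_um2
  ), class = "gq_condition")
}
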