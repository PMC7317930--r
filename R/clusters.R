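# Cluster statistics for immunogold point patterns: single-linkage grouping
# with the minimum-size-three membership rule, convex-hull area,
# nearest-cluster distance and composition histograms.

#' Clustering parameters
#'
#' @param link_distance_nm maximum centre-to-centre distance joining two
#'   particles into the same cluster (single linkage). The source procedure
#'   fixes only the minimum cluster size; the default linkage radius of 50 nm
#'   (~3 particle diameters) is this package's choice and is surfaced in
#'   every report header.
#' @param min_cluster_size minimum number of member particles; components
#'   below this size are reported as scattered. Default 3: clusters of one or
#'   two particles are discarded.
#' @return list of class `gq_cluster_params`.
#' @export
cluster_params <- function(link_distance_nm = 50, min_cluster_size = 3) {
  stopifnot(link_distance_nm > 0, min_cluster_size >= 1)
  structure(list(link_distance_nm = link_distance_nm,
                 min_cluster_size = min_cluster_size),
            class = "gq_cluster_params")
}

# Union-find with path compression; single-linkage components of the graph
# joining particle pairs at centre distance <= link. O(n^2) pair scan is fine
# at per-profile particle counts (hundreds).
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

single_linkage_components <- function(x, y, link) {
  n <- length(x)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  link2 <- link * link
  for (i in seq_len(max(n - 1L, 0L))) {
    dx <- x[(i + 1L):n] - x[i]
    dy <- y[(i + 1L):n] - y[i]
    hits <- which(dx * dx + dy * dy <= link2)
    for (j in hits + i) {
      ri <- uf_find(parent, i); rj <- uf_find(parent, j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  match(roots, unique(roots))
}

#' Group particles of one profile into clusters
#'
#' Connected components of the graph joining particle pairs at centre
#' distance at most `link_distance_nm` (single linkage). Components smaller
#' than `min_cluster_size` are returned as scattered particles, following the
#' rule that clusters of one or two particles are discarded. Cluster ids are
#' assigned by lexicographic order of the cluster centroids so the labelling
#' is deterministic and independent of the input row order.
#'
#' @param particles data.frame with `x_nm`, `y_nm` (one profile's particles).
#' @param params a [cluster_params()].
#' @return list with `clusters` (data.frame: cluster_id, size, centroid_x_nm,
#'   centroid_y_nm, hull_area_nm2, nearest_cluster_nm), `membership` (integer
#'   vector: cluster id per particle, NA when scattered) and `scattered`
#'   (indices of scattered particles).
#' @export
link_clusters <- function(particles, params = cluster_params()) {
  n <- nrow(particles)
  if (n == 0) {
    return(list(clusters = empty_cluster_table(), membership = integer(0),
                scattered = integer(0)))
  }
  comp <- single_linkage_components(particles$x_nm, particles$y_nm,
                                    params$link_distance_nm)
  sizes <- tabulate(comp)
  keep <- which(sizes >= params$min_cluster_size)
  if (!length(keep)) {
    return(list(clusters = empty_cluster_table(),
                membership = rep(NA_integer_, n), scattered = seq_len(n)))
  }
  cl <- lapply(keep, function(k) which(comp == k))
  cx <- vapply(cl, function(ix) mean(particles$x_nm[ix]), numeric(1))
  cy <- vapply(cl, function(ix) mean(particles$y_nm[ix]), numeric(1))
  ord <- order(cx, cy)
  cl <- cl[ord]; cx <- cx[ord]; cy <- cy[ord]
  hulls <- vapply(cl, function(ix) {
    if (length(ix) < 3) return(0)
    hull_area(cbind(particles$x_nm[ix], particles$y_nm[ix]))
  }, numeric(1))
  membership <- rep(NA_integer_, n)
  for (i in seq_along(cl)) membership[cl[[i]]] <- i
  tab <- data.frame(cluster_id = seq_along(cl),
                    size = lengths(cl),
                    centroid_x_nm = cx, centroid_y_nm = cy,
                    hull_area_nm2 = hulls,
                    nearest_cluster_nm = NA_real_)
  if (nrow(tab) >= 2) tab$nearest_cluster_nm <- nearest_cluster_distance(tab)
  list(clusters = tab, membership = membership,
       scattered = which(is.na(membership)))
}

empty_cluster_table <- function() {
  data.frame(cluster_id = integer(0), size = integer(0),
             centroid_x_nm = numeric(0), centroid_y_nm = numeric(0),
             hull_area_nm2 = numeric(0), nearest_cluster_nm = numeric(0))
}

#' Centroid distance to the nearest other cluster
#'
#' @param clusters cluster table with `centroid_x_nm`, `centroid_y_nm`.
#' @return numeric vector of nearest-cluster centroid distances (nm); with a
#'   single cluster the distance is undefined and returned as `NA` with a
#'   warning flag attribute.
#' @export
nearest_cluster_distance <- function(clusters) {
  k <- nrow(clusters)
  if (k < 2) {
    out <- rep(NA_real_, k)
    attr(out, "flag") <- "single_cluster"
    return(out)
  }
  d <- as.matrix(stats::dist(clusters[, c("centroid_x_nm", "centroid_y_nm")]))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Cluster-composition histogram over a fixed pooled reference area
#'
#' Pools clusters from profiles whose areas sum to a configured reference
#' area (the source analysis used a matched total area per condition so that
#' compositions are comparable across genotypes), then tabulates counts and
#' percentages of clusters per size.
#'
#' @param clusters pooled cluster table (rows from [link_clusters()]).
#' @param pooled_area_um2 total area of the pooled profiles.
#' @param reference_area_um2 configured reference area (default 140).
#' @param area_tolerance relative tolerance on the pooled area (default 0.05).
#' @return list with `histogram` (size, n, percent), `total_clusters`,
#'   `size_range`, `pooled_area_um2`.
#' @export
composition_histogram <- function(clusters, pooled_area_um2,
                                  reference_area_um2 = 140,
                                  area_tolerance = 0.05) {
  if (abs(pooled_area_um2 - reference_area_um2) >
      area_tolerance * reference_area_um2) {
    stop(sprintf(paste0("pooled area %.2f um^2 outside %.0f%% of the ",
                        "reference area %.2f um^2; re-sample profiles to ",
                        "match the reference area"),
                 pooled_area_um2, 100 * area_tolerance, reference_area_um2))
  }
  if (nrow(clusters) == 0) {
    return(list(histogram = data.frame(size = integer(0), n = integer(0),
                                       percent = numeric(0)),
                total_clusters = 0L, size_range = c(NA_integer_, NA_integer_),
                pooled_area_um2 = pooled_area_um2))
  }
  tab <- table(clusters$size)
  hist <- data.frame(size = as.integer(names(tab)), n = as.integer(tab))
  hist$percent <- 100 * hist$n / sum(hist$n)
  list(histogram = hist, total_clusters = nrow(clusters),
       size_range = range(clusters$size),
       pooled_area_um2 = pooled_area_um2)
}
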