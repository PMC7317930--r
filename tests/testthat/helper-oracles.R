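# Independent oracles used by the property tests. These deliberately avoid
# the package's own implementations: ray casting instead of winding numbers,
# boolean transitive closure instead of union-find, exhaustive assignment
# instead of augmenting paths, brute-force extreme-edge hulls instead of
# grDevices::chull, and hand-written sum-of-squares arithmetic instead of lm.

# even-odd ray casting point-in-polygon
oracle_ray_cast <- function(x, y, ring) {
  n <- nrow(ring)
  px <- ring[, 1]; py <- ring[, 2]
  qx <- px[c(2:n, 1)]; qy <- py[c(2:n, 1)]
  vapply(seq_along(x), function(i) {
    crosses <- ((py > y[i]) != (qy > y[i])) &
      (x[i] < (qx - px) * (y[i] - py) / (qy - py) + px)
    sum(crosses) %% 2 == 1
  }, logical(1))
}

# connected components of the <=link graph by boolean matrix closure
oracle_components <- function(x, y, link) {
  n <- length(x)
  if (n == 0) return(integer(0))
  a <- as.matrix(stats::dist(cbind(x, y))) <= link
  diag(a) <- TRUE
  reach <- a
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

# brute-force convex hull area: an ordered pair (i, j) is a hull edge iff
# all other points lie on one side; assemble edges and apply the shoelace.
oracle_hull_area <- function(xy) {
  n <- nrow(xy)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (xy[j, 1] - xy[i, 1]) * (xy[, 2] - xy[i, 2]) -
          (xy[j, 2] - xy[i, 2]) * (xy[, 1] - xy[i, 1])
    if (all(cr <= 1e-9)) edges[[length(edges) + 1L]] <- c(i, j)
  }
  if (!length(edges)) return(0)  # all collinear
  em <- do.call(rbind, edges)
  # walk the edge cycle
  start <- em[1, 1]; cur <- em[1, 2]; ord <- c(start, cur)
  while (cur != start) {
    nxt <- em[em[, 1] == cur, 2]
    nxt <- nxt[!(nxt %in% ord[-1])][1]
    if (is.na(nxt)) break
    if (nxt != start) ord <- c(ord, nxt)
    cur <- nxt
  }
  ring <- xy[ord, , drop = FALSE]
  m <- nrow(ring)
  if (m < 3) return(0)
  k <- c(m, seq_len(m - 1))
  abs(sum(ring[k, 1] * ring[, 2] - ring[, 1] * ring[k, 2]) / 2)
}

# maximum matching under a gate by exhaustive assignment (n <= 10)
oracle_max_matching <- function(det, tru, gate) {
  nd <- nrow(det); nt <- nrow(tru)
  ok <- outer(seq_len(nd), seq_len(nt), function(i, j) {
    sqrt((det$x_nm[i] - tru$x_nm[j])^2 + (det$y_nm[i] - tru$y_nm[j])^2) <= gate
  })
  best <- 0L
  rec <- function(i, used) {
    if (i > nd) return(0L)
    m <- rec(i + 1L, used)  # leave detection i unmatched
    for (j in seq_len(nt)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        m <- max(m, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    m
  }
  rec(1L, logical(nt))
}

# classical balanced two-way ANOVA from explicit sums of squares
oracle_anova_balanced <- function(value, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  a <- nlevels(f1); b <- nlevels(f2)
  n <- length(value) / (a * b)
  gm <- mean(value)
  m1 <- tapply(value, f1, mean); m2 <- tapply(value, f2, mean)
  m12 <- tapply(value, interaction(f1, f2), mean)
  ss1 <- n * b * sum((m1 - gm)^2)
  ss2 <- n * a * sum((m2 - gm)^2)
  cell <- m12[interaction(f1, f2)]
  sse <- sum((value - cell)^2)
  ssi <- sum((cell - m1[f1] - m2[f2] + gm)^2)
  df1 <- a - 1; df2 <- b - 1; dfi <- df1 * df2; dfe <- a * b * (n - 1)
  data.frame(
    factor = c("genotype", "compartment", "interaction"),
    F = c((ss1 / df1) / (sse / dfe), (ss2 / df2) / (sse / dfe),
          (ssi / dfi) / (sse / dfe)),
    p = c(stats::pf((ss1 / df1) / (sse / dfe), df1, dfe, lower.tail = FALSE),
          stats::pf((ss2 / df2) / (sse / dfe), df2, dfe, lower.tail = FALSE),
          stats::pf((ssi / dfi) / (sse / dfe), dfi, dfe, lower.tail = FALSE)))
}

# compact fixtures
square_profile <- function(side_nm = 1000, centre = c(0, 0), id = "sq",
                           layer = "slm", klass = "oblique_dendrite",
                           face = "P") {
  h <- side_nm / 2
  ring <- cbind(centre[1] + c(-h, h, h, -h), centre[2] + c(-h, -h, h, h))
  goldquant:::new_profile(id, ring, face, layer, klass)
}

flat_config <- function(lambda_c = 0, lambda_s = 0, mu_k = 6, sigma_r = 20,
                        dispersion = 2, hard_core_nm = 0) {
  list(lambda_c = lambda_c, lambda_s = lambda_s, mu_k = mu_k,
       sigma_r = sigma_r, dispersion = dispersion,
       hard_core_nm = hard_core_nm)
}

balanced_toy <- function(effect_genotype = 0, effect_inter = 0, n = 3,
                         seed = 1) {
  set.seed(seed)
  grid <- expand.grid(genotype = c("WT", "APP"),
                      compartment = c("oDen", "spine"),
                      animal = seq_len(n))
  grid$value <- stats::rnorm(nrow(grid), 20, 3) +
    effect_genotype * (grid$genotype == "APP") +
    effect_inter * (grid$genotype == "APP") * (grid$compartment == "spine")
  grid
}
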