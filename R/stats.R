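# Group comparison layer: two-way ANOVA (genotype x compartment) on
# per-animal densities, Bonferroni-adjusted per-compartment pairwise tests,
# and mean +/- SEM report formatting. The experimental unit is the animal
# (profile densities are averaged per animal first), per the "between
# animals" convention.

#' Two-way ANOVA on a per-animal density table
#'
#' Balanced designs use the classical sequential sum-of-squares
#' decomposition (`stats::lm` + `stats::anova`, exact for balanced data);
#' unbalanced designs fall back to Type-II sums of squares via
#' [car::Anova()] and are flagged.
#'
#' @param table data.frame with columns `value`, `genotype`, `compartment`
#'   (and optionally `animal_id`; one row per animal x cell).
#' @return list of class `gq_anova`: `table` (factor, F, p), `balanced`,
#'   `zero_variance` flag, and the fitted `lm`.
#' @export
two_way_anova <- function(table) {
  stopifnot(all(c("value", "genotype", "compartment") %in% names(table)))
  table$genotype <- factor(table$genotype)
  table$compartment <- factor(table$compartment)
  if (nlevels(table$genotype) < 2 || nlevels(table$compartment) < 2) {
    stop("each factor needs at least two levels")
  }
  counts <- table(table$genotype, table$compartment)
  if (any(counts < 2)) stop("need >= 2 animals per genotype x compartment cell")
  if (stats::var(table$value) < .Machine$double.eps) {
    out <- data.frame(factor = c("genotype", "compartment", "interaction"),
                      F = NA_real_, p = NA_real_)
    return(structure(list(table = out, balanced = all(counts == counts[1]),
                          zero_variance = TRUE, fit = NULL),
                     class = "gq_anova"))
  }
  balanced <- all(counts == counts[1])
  fit <- stats::lm(value ~ genotype * compartment, data = table)
  if (balanced) {
    a <- stats::anova(fit)
    rows <- c("genotype", "compartment", "genotype:compartment")
    out <- data.frame(factor = c("genotype", "compartment", "interaction"),
                      df = a[rows, "Df"],
                      F = a[rows, "F value"], p = a[rows, "Pr(>F)"])
  } else {
    a <- car::Anova(fit, type = 2)
    rows <- c("genotype", "compartment", "genotype:compartment")
    out <- data.frame(factor = c("genotype", "compartment", "interaction"),
                      df = a[rows, "Df"],
                      F = a[rows, "F value"], p = a[rows, "Pr(>F)"])
  }
  rownames(out) <- NULL
  structure(list(table = out, balanced = balanced, zero_variance = FALSE,
                 fit = fit), class = "gq_anova")
}

#' @export
print.gq_anova <- function(x, ...) {
  cat("Two-way ANOVA (", if (x$balanced) "balanced" else "unbalanced, Type II",
      ")\n", sep = "")
  if (x$zero_variance) cat("  zero-variance data; F undefined\n")
  else print(x$table, row.names = FALSE)
  invisible(x)
}

significance_stars <- function(p_adj) {
  ifelse(p_adj < 1e-4, "****", ifelse(p_adj < 0.05, "*", ""))
}

#' Per-compartment pairwise comparisons with Bonferroni adjustment
#'
#' Raw two-sample t tests (animal means, pooled variance) of WT vs APP/PS1
#' within each compartment; adjusted p = min(1, m * p_raw) with m the number
#' of compartment-wise comparisons (default: the number of compartments in
#' the table, 11 for gradient tables). Stars follow the convention
#' * p < 0.05, **** p < 0.0001 on adjusted p-values.
#'
#' @param table as in [two_way_anova()].
#' @param m Bonferroni multiplier (default: number of compartments).
#' @return data.frame: compartment, n1, n2, t, p_raw, p_adj, stars.
#' @export
bonferroni_pairwise <- function(table, m = NULL) {
  stopifnot(all(c("value", "genotype", "compartment") %in% names(table)))
  comps <- unique(as.character(table$compartment))
  if (is.null(m)) m <- length(comps)
  if (m == 0 || !length(comps)) {
    return(data.frame(compartment = character(0), n1 = integer(0),
                      n2 = integer(0), t = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), stars = character(0)))
  }
  gl <- unique(as.character(table$genotype))
  stopifnot(length(gl) == 2)
  out <- do.call(rbind, lapply(comps, function(cc) {
    x <- table$value[table$compartment == cc & table$genotype == gl[1]]
    y <- table$value[table$compartment == cc & table$genotype == gl[2]]
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(compartment = cc, n1 = length(x), n2 = length(y),
               t = unname(tt$statistic), p_raw = tt$p.value)
  }))
  out$p_adj <- pmin(1, m * out$p_raw)
  out$stars <- significance_stars(out$p_adj)
  out
}

#' Format mean +/- SEM report strings
#'
#' @param values per-animal values of one condition.
#' @param unit unit string appended to the report (default
#'   "immunoparticles/um^2").
#' @param n_label label for the sampling unit in the "n = " clause.
#' @return list: `mean`, `sem` (NA-flagged for a single animal), `text`.
#' @export
summarize_condition <- function(values, unit = "immunoparticles/um^2",
                                n_label = "animals") {
  stopifnot(length(values) >= 1)
  m <- mean(values)
  sem <- if (length(values) >= 2) stats::sd(values) / sqrt(length(values)) else NA_real_
  txt <- if (is.na(sem)) {
    sprintf("%.2f %s, n = %d %s (SEM undefined)", m, unit, length(values), n_label)
  } else {
    sprintf("%.2f ± %.2f %s, n = %d %s", m, sem, unit, length(values), n_label)
  }
  list(mean = m, sem = sem, text = txt)
}
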