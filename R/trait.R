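# Quantitative-trait layer. One additive trait whose allele effects follow a
# Finlay-Wilkinson regression on an environmental covariate w:
#
#   a_i(w) = b_i + m_i * w
#
# so an individual's genetic value is Sum_i x_i (b_i + m_i w) = g0 + s * w,
# exactly linear in w with genotype-specific intercept g0 (main effect) and
# slope s. Intercepts are scaled so the base population's variance of g0
# equals var_G; slopes are scaled to unit slope variance in the base
# population, after which the year and location covariate variances equal
# var_GxY and var_GxL directly.

#' Trait variance-component targets
#'
#' @param var_G main (intercept) genetic variance target; default 1.
#' @param var_GxY genotype-by-year interaction variance; default 2.
#' @param var_GxL genotype-by-location interaction variance; default 1.
#' @return An object of class `variance_components` with the derived
#'   `var_GxYxL = var_GxY + var_GxL` (3 at the defaults).
#' @export
variance_components <- function(var_G = 1, var_GxY = 2, var_GxL = 1) {
  stopifnot(var_G > 0, var_GxY >= 0, var_GxL >= 0)
  structure(list(var_G = var_G, var_GxY = var_GxY, var_GxL = var_GxL,
                 var_GxYxL = var_GxY + var_GxL),
            class = "variance_components")
}

pop_var <- function(x) mean((x - mean(x))^2)  # denominator n

#' Sample a QTN trait architecture and calibrate it on a base population
#'
#' Draws `n_qtn_per_chrom` QTN per chromosome from the sites segregating in
#' the base population, samples intercepts and slopes from a standard normal,
#' and rescales them on the base population's actual genotypes: intercepts so
#' that the population variance of genetic values at w = 0 equals `var_G`,
#' and slopes to unit slope-value variance (so covariate variances map
#' one-to-one onto the GxY and GxL targets; see
#' [sample_env_covariates()]).
#'
#' @param founders a `founder_set` from [simulate_founders()], or a
#'   `population` (then `map` must be given). This population is the
#'   calibration base.
#' @param vc a [variance_components()].
#' @param n_qtn_per_chrom QTN sampled per chromosome (default 100).
#' @param map `genetic_map` when `founders` is a bare `population`.
#' @return An object of class `trait_architecture`: QTN site indices `qtn`,
#'   intercepts `b`, slopes `m`, and the variance targets `vc`.
#' @export
sample_architecture <- function(founders, vc = variance_components(),
                                n_qtn_per_chrom = 100L, map = NULL) {
  if (inherits(founders, "founder_set")) {
    map <- founders$map
    pop <- founders$founders
  } else {
    pop <- founders
    stopifnot(inherits(map, "genetic_map"))
  }
  stopifnot(inherits(pop, "population"), is_count(n_qtn_per_chrom, 1))
  X_all <- dosages(pop)
  seg <- which(segregating_cols(X_all))
  qtn <- integer(0)
  for (c in seq_along(map$chr_len)) {
    sites <- seq.int(map$chr_start[c], map$chr_end[c])
    sites <- intersect(sites, seg)
    if (length(sites) < n_qtn_per_chrom) {
      abort_breedsim(sprintf(
        "insufficient variation: chromosome %d has %d segregating sites but %d QTN were requested",
        c, length(sites), n_qtn_per_chrom),
        "breedsim_insufficient_variation_error")
    }
    qtn <- c(qtn, sort(sample(sites, n_qtn_per_chrom)))
  }
  b <- rnorm(length(qtn))
  m <- rnorm(length(qtn))
  X <- X_all[, qtn, drop = FALSE]
  g0 <- as.vector(X %*% b)
  v0 <- pop_var(g0)
  if (v0 <= 0) {
    abort_breedsim("base population has zero genetic variance at the sampled QTN",
                   "breedsim_insufficient_variation_error")
  }
  b <- b * sqrt(vc$var_G / v0)
  s <- as.vector(X %*% m)
  vs <- pop_var(s)
  if (vs <= 0) {
    abort_breedsim("base population has zero slope variance at the sampled QTN",
                   "breedsim_insufficient_variation_error")
  }
  m <- m / sqrt(vs)
  structure(list(qtn = qtn, chrom = map$table$chrom[qtn], b = b, m = m,
                 vc = vc, n_base = n_ind(pop)),
            class = "trait_architecture")
}

# segregating = not all 0 and not all 2 in the dosage matrix
segregating_cols <- function(X) {
  cs <- colSums(X)
  cs > 0 & cs < 2 * nrow(X)
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture> %d QTN on %d chromosomes; targets var_G=%g, var_GxY=%g, var_GxL=%g\n",
              length(x$qtn), length(unique(x$chrom)), x$vc$var_G, x$vc$var_GxY,
              x$vc$var_GxL))
  invisible(x)
}

#' Allele effect of one QTN at a covariate value
#'
#' Finlay-Wilkinson allele effect `b_i + m_i * w`.
#'
#' @param arch a [trait_architecture()].
#' @param i QTN index.
#' @param w environmental covariate value.
#' @return Numeric effect.
#' @export
allele_effect <- function(arch, i, w) {
  stopifnot(i >= 1, i <= length(arch$b))
  arch$b[i] + arch$m[i] * w
}

#' Genetic main effects (genetic values at w = 0)
#' @param pop a `population`.
#' @param arch a `trait_architecture`.
#' @return Numeric vector, one value per individual.
#' @export
main_effect <- function(pop, arch) {
  as.vector(dosages(pop, arch$qtn) %*% arch$b)
}

#' Genetic slopes on the environmental covariate
#' @inheritParams main_effect
#' @return Numeric vector, one slope per individual.
#' @export
slope_value <- function(pop, arch) {
  as.vector(dosages(pop, arch$qtn) %*% arch$m)
}

#' Genetic values of a population at covariate value(s) w
#'
#' `g(w) = sum_i x_i (b_i + m_i w)`, computed exactly; linear in `w`.
#'
#' @param pop a `population`.
#' @param arch a `trait_architecture`.
#' @param w a single covariate value or a vector of values.
#' @return A numeric vector (one `w`) or an individuals x `length(w)` matrix.
#' @export
genetic_value <- function(pop, arch, w = 0) {
  if (!is.null(pop$g0) && !is.null(pop$s)) {
    g0 <- pop$g0
    s <- pop$s
  } else {
    X <- dosages(pop, arch$qtn)
    g0 <- as.vector(X %*% arch$b)
    s <- as.vector(X %*% arch$m)
  }
  if (length(w) == 1) g0 + s * w else g0 + outer(s, as.numeric(w))
}

# Cache per-individual genetic intercept (g0) and slope (s) on the cohort;
# both are invariant over an individual's life, so the engine computes them
# once per cohort instead of re-extracting dosages every year.
attach_genetics <- function(pop, arch) {
  gs <- .genetic_values_cpp(pop$H, arch$qtn - 1L, arch$b, arch$m)
  pop$g0 <- gs$g0
  pop$s <- gs$s
  pop
}

#' Sample the year x location environmental-covariate matrix
#'
#' Covariates decompose as `w[j, l] = u[j] + v[j, l]` with `u` (year effects,
#' shared across locations) and `v` (year-by-location effects) independent
#' zero-mean normals. Because slopes are calibrated to unit variance in the
#' base population, `Var(u) = var_GxY` and `Var(v) = var_GxL` make the
#' realized genotype-by-year and genotype-by-location interaction variances
#' hit their targets.
#'
#' @param n_years number of years covered (rows).
#' @param n_locations_max maximum locations phenotyped in any stage (columns).
#' @param vc a [variance_components()].
#' @param arch optional [trait_architecture()]; when given, its stored
#'   variance targets are used (and must match `vc` if both are supplied).
#' @return An object of class `env_covariates`: matrix `w` plus its `u`, `v`
#'   parts.
#' @export
sample_env_covariates <- function(n_years, n_locations_max,
                                  vc = NULL, arch = NULL) {
  if (is.null(vc)) vc <- arch$vc
  stopifnot(inherits(vc, "variance_components"), is_count(n_years, 1),
            is_count(n_locations_max, 1))
  u <- rnorm(n_years, 0, sqrt(vc$var_GxY))
  v <- matrix(rnorm(n_years * n_locations_max, 0, sqrt(vc$var_GxL)),
              nrow = n_years)
  structure(list(w = u + v, u = u, v = v, vc = vc), class = "env_covariates")
}

#' Plot error variance implied by a target plot heritability
#'
#' Plot heritability is defined on a single-plot basis as
#' `h2 = var_G / (var_G + var_GxYxL + var_e)`, so
#' `var_e = (var_G + var_GxYxL) * (1 - h2) / h2`.
#'
#' @param vc a [variance_components()].
#' @param h2 target plot heritability in (0, 1].
#' @return Error variance `var_e`.
#' @export
#' @examples
#' error_variance_from_h2(variance_components(1, 2, 1), 0.2)  # 16
error_variance_from_h2 <- function(vc, h2) {
  if (!is_scalar_number(h2) || h2 <= 0 || h2 > 1) {
    abort_breedsim("plot heritability must lie in (0, 1]",
                   "breedsim_invalid_noise_error")
  }
  (vc$var_G + vc$var_GxYxL) * (1 - h2) / h2
}

#' Default stage plot heritabilities
#'
#' Package defaults (configurable, not estimates from any particular
#' program): unreplicated early stages get lower plot heritability.
#'
#' @return Named numeric vector of plot h2 by stage name.
#' @export
default_stage_h2 <- function() {
  c(CE = 0.2, PYT = 0.3, AYT = 0.4, UYT1 = 0.45, UYT2 = 0.45)
}

#' Phenotype a cohort at one stage in one year
#'
#' Each plot value is the individual's genetic value at that location's
#' covariate `w[year, loc]` plus independent normal noise with variance
#' `var_e`; the entry mean averages an individual's `n_locations x reps`
#' plots.
#'
#' @param pop the cohort (`population`).
#' @param arch a `trait_architecture`.
#' @param env an `env_covariates` whose `w` covers `year` and the locations.
#' @param year row of `env$w` to use.
#' @param n_locations,reps_per_location the stage's evaluation decisions.
#' @param var_e plot error variance (see [error_variance_from_h2()]).
#' @return A list with `entry_mean` (numeric vector) and `plots` (matrix,
#'   individuals x plots, locations varying fastest).
#' @export
phenotype_cohort <- function(pop, arch, env, year, n_locations,
                             reps_per_location, var_e) {
  stopifnot(inherits(env, "env_covariates"), var_e >= 0,
            year >= 1, year <= nrow(env$w), n_locations <= ncol(env$w))
  w_loc <- env$w[year, seq_len(n_locations)]
  g <- genetic_value(pop, arch, w_loc)           # n x L (or vector if L = 1)
  if (is.null(dim(g))) g <- matrix(g, ncol = 1)
  n <- n_ind(pop)
  plots <- g[, rep(seq_len(n_locations), times = reps_per_location),
             drop = FALSE]
  noise <- matrix(rnorm(length(plots), 0, sqrt(var_e)), nrow = n)
  plots <- plots + noise
  list(entry_mean = rowMeans(plots), plots = plots)
}
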