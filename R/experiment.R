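# Treatment-grid experiment: enumerate resource allocations at fixed F1 size,
# run them over replicated founder/burn-in realizations (paired within
# replicate), and summarize genetic gain.

#' Enumerate the treatment grid at fixed total F1 size
#'
#' All (n_parents, n_crosses) combinations with `n_crosses <= n_parents *
#' (n_parents - 1) / 2` (the half-diallel cap), each with `n_progeny_per_cross
#' = total_F1 / n_crosses`, ordered by parents then crosses. The defaults
#' reproduce the 24-treatment grid of a 1,632-individual program over parent
#' levels 4-64 and cross levels 6-816.
#'
#' @param parent_levels candidate crossing-block sizes.
#' @param cross_levels candidate numbers of crosses; each must divide
#'   `total_F1`.
#' @param total_F1 fixed number of F1 individuals per year.
#' @param policy [recycling_policy()] attached to every treatment.
#' @return A list of [treatment()] objects; see [treatments_table()] for a
#'   tabular view.
#' @export
#' @examples
#' length(enumerate_treatments())  # 24
enumerate_treatments <- function(parent_levels = c(4, 8, 16, 32, 64),
                                 cross_levels = c(6, 12, 24, 48, 96, 204, 408, 816),
                                 total_F1 = 1632,
                                 policy = recycling_policy(PYT = 0.5, AYT = 0.5)) {
  bad <- cross_levels[total_F1 %% cross_levels != 0]
  if (length(bad) > 0) {
    abort_breedsim(sprintf("cross level(s) %s do not divide total_F1 = %d",
                           paste(bad, collapse = ", "), total_F1),
                   "breedsim_config_error")
  }
  out <- list()
  for (np in sort(parent_levels)) {
    cap <- np * (np - 1) / 2
    for (nc in sort(cross_levels)) {
      if (nc > cap) next
      out[[length(out) + 1L]] <- treatment(np, nc, total_F1 / nc,
                                           policy = policy,
                                           allow_reciprocals = FALSE)
    }
  }
  out
}

#' Tabulate a list of treatments
#'
#' @param treatments list of [treatment()] objects.
#' @return Tibble with columns `id`, `n_parents`, `n_crosses`,
#'   `n_progeny_per_cross`, `total_F1`, `policy`.
#' @export
treatments_table <- function(treatments) {
  dplyr::bind_rows(lapply(treatments, function(tr) {
    tibble(id = tr$id, n_parents = tr$n_parents, n_crosses = tr$n_crosses,
           n_progeny_per_cross = tr$n_progeny_per_cross,
           total_F1 = tr$n_crosses * tr$n_progeny_per_cross,
           policy = paste(sprintf("%s:%g", names(tr$policy),
                                  unclass(tr$policy)), collapse = ","))
  }))
}

#' Run a treatment grid over replicated simulations
#'
#' For each replicate, one founder realization and burn-in segment is shared
#' by all treatments (common fork), so contrasts between treatments are
#' paired within replicate.
#'
#' @inheritParams run_replicate
#' @param treatments list of [treatment()] objects.
#' @param n_replicates number of independent replicates.
#' @param master_seed master seed; every sub-stream seed derives from it.
#' @param verbose print per-replicate progress to stderr.
#' @return A tidy results tibble (see [run_replicate()]) over all replicates
#'   and treatments, with parent-age logs in the `"parent_ages"` attribute.
#' @export
run_grid <- function(treatments, scheme, n_replicates, n_years,
                     burn_in_years = 20L, cfg = genome_config(),
                     vc = variance_components(), h2 = default_stage_h2(),
                     n_qtn_per_chrom = 100L, n_founders = 4L, master_seed = 1L,
                     verbose = FALSE) {
  stopifnot(is_count(n_replicates, 1))
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    if (verbose) {
      message(sprintf("replicate %d/%d (%d treatments)", r, n_replicates,
                      length(treatments)))
    }
    out[[r]] <- run_replicate(scheme, treatments, n_years, burn_in_years,
                              cfg, vc, h2, n_qtn_per_chrom, n_founders,
                              master_seed = master_seed, replicate = r)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "parent_ages") <- dplyr::bind_rows(lapply(out, attr, "parent_ages"))
  res
}

#' Summarize genetic gain by treatment and year
#'
#' Gain is the mean genetic value at a stage minus the same replicate's mean
#' at `baseline_year` (typically the last burn-in year), averaged over
#' replicates with its standard error.
#'
#' @param results tidy results from [run_grid()] / [run_replicate()].
#' @param stage stage name to summarize (e.g. `"AYT"`).
#' @param baseline_year year whose mean defines zero gain.
#' @param relative if `TRUE`, gains are divided by the absolute baseline mean
#'   (gain relative to the mean).
#' @return Tibble: `treatment_id`, `year`, `stage`, `gain`, `se`,
#'   `n_replicates`. `se` is `NA` for a single replicate.
#' @export
summarize_gain <- function(results, stage, baseline_year, relative = FALSE) {
  stopifnot(stage %in% results$stage)
  res <- results[results$stage == stage, ]
  base <- res[res$year == baseline_year, c("replicate", "treatment_id",
                                           "genetic_mean")]
  names(base)[names(base) == "genetic_mean"] <- "baseline_mean"
  res <- dplyr::left_join(res, base, by = c("replicate", "treatment_id"))
  res$gain <- res$genetic_mean - res$baseline_mean
  if (relative) res$gain <- res$gain / abs(res$baseline_mean)
  out <- dplyr::summarise(
    dplyr::group_by(res, .data$treatment_id, .data$year, .data$stage),
    mean_gain = mean(.data$gain),
    se = if (dplyr::n() > 1) stats::sd(.data$gain) / sqrt(dplyr::n()) else NA_real_,
    n_replicates = dplyr::n(),
    .groups = "drop")
  names(out)[names(out) == "mean_gain"] <- "gain"
  dplyr::arrange(out, .data$treatment_id, .data$year)
}

#' Contrast mean gain between two sets of treatments
#'
#' The paired, within-replicate difference in mean gain at a horizon year:
#' for each replicate, the mean gain over `treatments_a` minus that over
#' `treatments_b`; the difference and its standard error are taken across
#' replicates. The direction label is assigned when the difference exceeds
#' twice its standard error.
#'
#' @param results tidy results from [run_grid()].
#' @param stage stage whose genetic mean defines gain.
#' @param baseline_year year of zero gain.
#' @param horizon_year year at which treatments are contrasted.
#' @param treatments_a,treatments_b character vectors of treatment ids.
#' @return A list: `difference` (a minus b), `se`, `direction` (one of
#'   `"first_higher"`, `"second_higher"`, `"indistinguishable"`), and the
#'   per-replicate differences.
#' @export
compare_gain <- function(results, stage, baseline_year, horizon_year,
                         treatments_a, treatments_b) {
  stopifnot(length(treatments_a) >= 1, length(treatments_b) >= 1)
  gain_at <- function(ids) {
    res <- results[results$stage == stage & results$treatment_id %in% ids, ]
    if (nrow(res) == 0) {
      abort_breedsim("no results rows match the requested treatment set",
                     "breedsim_config_error")
    }
    base <- res[res$year == baseline_year, ]
    hor <- res[res$year == horizon_year, ]
    g <- hor$genetic_mean -
      base$genetic_mean[match(paste(hor$replicate, hor$treatment_id),
                              paste(base$replicate, base$treatment_id))]
    tapply(g, hor$replicate, mean)   # mean over the treatment set
  }
  ga <- gain_at(treatments_a)
  gb <- gain_at(treatments_b)
  reps <- intersect(names(ga), names(gb))
  d <- ga[reps] - gb[reps]
  diff <- mean(d)
  se <- if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_
  direction <- if (!is.na(se) && abs(diff) > 2 * se) {
    if (diff > 0) "first_higher" else "second_higher"
  } else {
    "indistinguishable"
  }
  list(difference = diff, se = se, direction = direction, per_replicate = d)
}
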