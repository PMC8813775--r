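# Stage-gate breeding engine: overlapping cohorts advance one stage per
# simulated year; each year the crossing block is rebuilt from the currently
# phenotyped recycling-source cohorts and a new F1 cohort enters the nursery.
# Genetic means and variances are recorded at w = 0 (main-effect scale) so
# gain is comparable across years despite GxE.

#' Define a parent-recycling policy
#'
#' Named proportions of the crossing block drawn from each recycling-source
#' stage.
#'
#' @param ... named numeric proportions (e.g. `PYT = 0.5, AYT = 0.5`); must be
#'   in `[0, 1]` and sum to 1.
#' @return An object of class `recycling_policy`.
#' @export
#' @examples
#' recycling_policy(PYT = 0.5, AYT = 0.5)
recycling_policy <- function(...) {
  p <- c(...)
  stopifnot(is.numeric(p), length(p) >= 1, !is.null(names(p)),
            all(nzchar(names(p))), all(p >= 0), all(p <= 1))
  if (abs(sum(p) - 1) > 1e-8) {
    abort_breedsim("recycling proportions must sum to 1",
                   "breedsim_policy_error")
  }
  structure(p, class = "recycling_policy")
}

#' Define a simulation treatment
#'
#' One point of the resource-allocation grid: numbers of parents and crosses,
#' progeny per cross, and the recycling policy, at fixed total F1 size.
#'
#' @param n_parents crossing-block size.
#' @param n_crosses crosses made per year; at most `n_parents * (n_parents -
#'   1) / 2` without reciprocals (twice that with).
#' @param n_progeny_per_cross progeny per cross.
#' @param policy a [recycling_policy()].
#' @param allow_reciprocals whether reciprocal (ordered) crosses count as
#'   distinct.
#' @param id treatment identifier; generated from the factors by default.
#' @return An object of class `treatment`.
#' @export
#' @examples
#' treatment(16, 24, 68)
treatment <- function(n_parents, n_crosses, n_progeny_per_cross,
                      policy = recycling_policy(PYT = 0.5, AYT = 0.5),
                      allow_reciprocals = FALSE, id = NULL) {
  stopifnot(is_count(n_parents, 2), is_count(n_crosses, 1),
            is_count(n_progeny_per_cross, 1),
            inherits(policy, "recycling_policy"))
  cap <- n_parents * (n_parents - 1) / 2
  if (allow_reciprocals) cap <- 2 * cap
  if (n_crosses > cap) {
    abort_breedsim(sprintf("n_crosses (%d) exceeds the %s cap of %d for %d parents",
                           n_crosses,
                           if (allow_reciprocals) "full-diallel" else "half-diallel",
                           as.integer(cap), n_parents),
                   "breedsim_constraint_error")
  }
  id <- id %||% sprintf("p%02d_c%03d_%s", n_parents, n_crosses,
                        paste(tolower(names(policy)), collapse = ""))
  structure(list(id = id, n_parents = as.integer(n_parents),
                 n_crosses = as.integer(n_crosses),
                 n_progeny_per_cross = as.integer(n_progeny_per_cross),
                 policy = policy, allow_reciprocals = isTRUE(allow_reciprocals)),
            class = "treatment")
}

#' The treatment a scheme's own crossing stage encodes
#'
#' @param s a valid [breeding_scheme()].
#' @param policy recycling policy to attach (default: equal mix of the
#'   scheme's recycling-source stages).
#' @return A [treatment()].
#' @export
baseline_treatment <- function(s, policy = NULL) {
  cb <- crossing_stage(s)
  if (is.null(policy)) {
    rs <- recycling_stages(s)
    policy <- do.call(recycling_policy,
                      as.list(setNames(rep(1 / length(rs), length(rs)), rs)))
  }
  treatment(cb$crossing$n_parents, cb$crossing$n_crosses,
            cb$crossing$n_progeny_per_cross, policy = policy,
            allow_reciprocals = isTRUE(cb$crossing$allow_reciprocals),
            id = paste0("baseline_", s$id))
}

#' Plan the crosses of one crossing block
#'
#' Samples distinct parent pairs (unordered unless reciprocals are allowed),
#' never selfing, uniformly without replacement. Whenever `n_crosses >=
#' ceiling(n_parents / 2)`, every parent is guaranteed at least one cross: a
#' random disjoint pairing of all parents seeds the plan before the remaining
#' pairs are sampled.
#'
#' @param parents vector of parent indices (or ids).
#' @param n_crosses number of crosses to plan.
#' @param n_progeny progeny per cross.
#' @param allow_reciprocals whether (i, j) and (j, i) are distinct crosses.
#' @return An object of class `cross_plan`: a tibble with columns `mother`,
#'   `father` and attribute `n_progeny`.
#' @export
#' @examples
#' plan_crosses(1:4, 6, 272)   # forced half-diallel
plan_crosses <- function(parents, n_crosses, n_progeny,
                         allow_reciprocals = FALSE) {
  np <- length(parents)
  stopifnot(np >= 2, is_count(n_crosses, 1), is_count(n_progeny, 1))
  cap <- np * (np - 1) / 2
  if (allow_reciprocals) cap <- 2 * cap
  if (n_crosses > cap) {
    abort_breedsim(sprintf("n_crosses (%d) exceeds the %s cap of %d for %d parents",
                           n_crosses,
                           if (allow_reciprocals) "full-diallel" else "half-diallel",
                           as.integer(cap), np),
                   "breedsim_constraint_error")
  }
  pair_key <- function(i, j) {
    if (allow_reciprocals) (i - 1) * np + j
    else (pmin(i, j) - 1) * np + pmax(i, j)
  }
  chosen_i <- integer(0); chosen_j <- integer(0)
  if (n_crosses >= ceiling(np / 2)) {
    perm <- sample.int(np)
    k <- floor(np / 2)
    chosen_i <- perm[seq_len(k) * 2 - 1]
    chosen_j <- perm[seq_len(k) * 2]
    if (np %% 2 == 1) {
      chosen_i <- c(chosen_i, perm[np])
      chosen_j <- c(chosen_j, sample(perm[-np], 1))
    }
  }
  # remaining pairs, sampled uniformly without replacement
  all_i <- rep(seq_len(np), each = np)
  all_j <- rep(seq_len(np), times = np)
  keep <- if (allow_reciprocals) all_i != all_j else all_i < all_j
  all_i <- all_i[keep]; all_j <- all_j[keep]
  used <- pair_key(chosen_i, chosen_j)
  avail <- which(!(pair_key(all_i, all_j) %in% used))
  n_more <- n_crosses - length(chosen_i)
  if (n_more > 0) {
    pick <- if (length(avail) == 1) avail else sample(avail, n_more)
    chosen_i <- c(chosen_i, all_i[pick])
    chosen_j <- c(chosen_j, all_j[pick])
  } else if (n_more < 0) {
    chosen_i <- chosen_i[seq_len(n_crosses)]
    chosen_j <- chosen_j[seq_len(n_crosses)]
  }
  plan <- tibble(mother = parents[chosen_i], father = parents[chosen_j])
  attr(plan, "n_progeny") <- as.integer(n_progeny)
  class(plan) <- c("cross_plan", class(plan))
  plan
}

#' Advance the best entries of a phenotyped cohort
#'
#' Truncation selection on entry-mean phenotype: the `n_select` entries with
#' the highest means, ties broken by ascending id, returned in descending
#' merit order.
#'
#' @param cohort a `population` with entry means in `$pheno`.
#' @param n_select number of entries to advance.
#' @return The selected `population`.
#' @export
advance <- function(cohort, n_select) {
  stopifnot(inherits(cohort, "population"), is_count(n_select, 0))
  if (is.null(cohort$pheno) || anyNA(cohort$pheno)) {
    abort_breedsim("cohort has missing entry-mean phenotypes",
                   "breedsim_state_error")
  }
  if (n_select > n_ind(cohort)) {
    abort_breedsim(sprintf("n_select (%d) exceeds cohort size (%d)",
                           n_select, n_ind(cohort)),
                   "breedsim_state_error")
  }
  ord <- order(-cohort$pheno, cohort$id)
  cohort[ord[seq_len(n_select)]]
}

#' Apportion crossing-block quotas across recycling stages
#'
#' Largest-remainder apportionment of `n_parents` by the policy proportions;
#' remainder ties go to the earlier stage (first in the policy's stage
#' order).
#'
#' @param policy a [recycling_policy()].
#' @param n_parents crossing-block size to fill.
#' @return Named integer vector of per-stage quotas summing to `n_parents`.
#' @export
#' @examples
#' policy_quotas(recycling_policy(PYT = 0.5, AYT = 0.5), 5)  # PYT 3, AYT 2
policy_quotas <- function(policy, n_parents) {
  p <- unclass(policy)
  exact <- p * n_parents
  base <- floor(exact)
  rem <- exact - base
  left <- n_parents - sum(base)
  if (left > 0) {
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(base), names(p))
}

#' Select crossing-block parents from phenotyped cohorts under a policy
#'
#' Per-stage quotas come from [policy_quotas()]; within each stage the
#' top-merit entries by entry mean are taken (ties by ascending id).
#'
#' @param cohorts named list of phenotyped `population` cohorts, keyed by
#'   stage name.
#' @param policy a [recycling_policy()] whose stages all appear in `cohorts`.
#' @param n_parents total number of parents to select.
#' @return A `population` of parents (stage blocks concatenated in policy
#'   order).
#' @export
select_parents <- function(cohorts, policy, n_parents) {
  quotas <- policy_quotas(policy, n_parents)
  picked <- list()
  for (stage in names(quotas)) {
    q <- quotas[[stage]]
    if (q == 0) next
    coh <- cohorts[[stage]]
    if (is.null(coh)) {
      abort_breedsim(sprintf("no cohort available for policy stage '%s'", stage),
                     "breedsim_state_error")
    }
    if (q > n_ind(coh)) {
      abort_breedsim(sprintf("quota %d for stage '%s' exceeds its cohort size %d",
                             q, stage, n_ind(coh)),
                     "breedsim_constraint_error")
    }
    picked[[stage]] <- advance(coh, q)
  }
  pop_concat(picked)
}

# --- program state ----------------------------------------------------------

eval_stage_names <- function(s) {
  nm <- stage_names(s)
  keep <- vapply(s$stages, function(st) identical(st$role, "evaluation"),
                 logical(1))
  nm[keep]
}

noncrossing_stage_names <- function(s) {
  nm <- stage_names(s)
  roles <- vapply(s$stages, `[[`, character(1), "role")
  nm[roles != "crossing"]
}

stage_by_name <- function(s, name) s$stages[[match(name, stage_names(s))]]

# Noise table: named h2 vector -> per-stage var_e
stage_var_e <- function(s, vc, h2) {
  out <- numeric(0)
  for (nm in eval_stage_names(s)) {
    h <- h2[[nm]] %||% NA_real_
    if (is.na(h)) {
      abort_breedsim(sprintf("no plot heritability supplied for stage '%s'", nm),
                     "breedsim_invalid_noise_error")
    }
    out[nm] <- error_variance_from_h2(vc, h)
  }
  out
}

#' Initialize a program state with a full cohort ladder
#'
#' Builds the starting state for [run_year()]: every non-crossing stage is
#' occupied with a scheme-conformant cohort derived from founder crosses
#' (later stages are random subsets of an extra founder F1 batch, with birth
#' years staggered so cohort ages are consistent). Burn-in years are expected
#' to wash out this initialization.
#'
#' @param scheme a valid [breeding_scheme()].
#' @param fs a `founder_set`.
#' @param tr the [treatment()] used for the initial crossing blocks (usually
#'   the baseline).
#' @param arch optional `trait_architecture`; when given, genetic intercepts
#'   and slopes are cached on every initial cohort (the engine does this for
#'   all cohorts it creates later).
#' @return An object of class `program_state`.
#' @export
init_program <- function(scheme, fs, tr, arch = NULL) {
  assert_valid_scheme(scheme)
  founders <- fs$founders
  map <- fs$map
  state <- list(year = 0L, map = map, next_id = max(founders$id) + 1L,
                cohorts = list(), records = list(), parent_ages = list())
  make_f1 <- function(birth_year) {
    if (tr$n_parents > n_ind(founders)) {
      # draw parents with replacement across crossing blocks of the ramp-up
      idx <- sample.int(n_ind(founders), tr$n_parents, replace = TRUE)
    } else {
      idx <- sample.int(n_ind(founders), tr$n_parents)
    }
    block <- founders[idx]
    plan <- plan_crosses(seq_len(n_ind(block)), tr$n_crosses,
                         tr$n_progeny_per_cross, tr$allow_reciprocals)
    n_prog <- attr(plan, "n_progeny")
    mo <- rep(plan$mother, each = n_prog)
    fa <- rep(plan$father, each = n_prog)
    f1 <- cross_batch(block, mo, fa, map, first_id = state$next_id,
                      birth_year = birth_year)
    state$next_id <<- state$next_id + n_ind(f1)
    if (!is.null(arch)) f1 <- attach_genetics(f1, arch)
    f1
  }
  nc <- noncrossing_stage_names(scheme)
  # in year 1, the k-th non-crossing stage holds a cohort born in year 2 - k;
  # the first (nursery) slot is a placeholder replaced by year 1's own F1
  pool <- make_f1(0L)  # reservoir for the downstream stages
  for (k in seq_along(nc)) {
    st <- stage_by_name(scheme, nc[k])
    size <- st$selection$n_entries_in
    if (k == 1) {
      coh <- pool
    } else if (k == 2) {
      coh <- make_f1(0L)
    } else {
      if (size > n_ind(pool)) {
        abort_breedsim("initial founder F1 batch smaller than a stage cohort",
                       "breedsim_state_error")
      }
      coh <- pool[sample.int(n_ind(pool), size)]
      coh$birth_year <- rep(2L - k, size)
    }
    if (n_ind(coh) != size) {
      abort_breedsim(sprintf("initial cohort for '%s' has %d entries, scheme expects %d",
                             nc[k], n_ind(coh), size),
                     "breedsim_state_error")
    }
    state$cohorts[[nc[k]]] <- coh
  }
  structure(state, class = "program_state")
}

record_year <- function(state, scheme, tr, arch) {
  rows <- lapply(noncrossing_stage_names(scheme), function(nm) {
    coh <- state$cohorts[[nm]]
    g0 <- coh$g0 %||% main_effect(coh, arch)
    tibble(year = state$year, stage = nm, n = n_ind(coh),
           genetic_mean = mean(g0), genetic_var = pop_var(g0))
  })
  state$records[[length(state$records) + 1L]] <- dplyr::bind_rows(rows)
  state
}

#' Run one simulated year of a breeding program
#'
#' In one year: every evaluation cohort is phenotyped at its stage's
#' locations/reps and error variance; per-stage genetic means and variances
#' (at w = 0) are recorded; crossing-block parents are selected from the
#' policy stages and crossed into a new F1 cohort (this year's nursery); and
#' all cohorts advance one stage by truncation selection on entry means.
#'
#' @param state a `program_state` from [init_program()].
#' @param scheme the [breeding_scheme()] being executed.
#' @param tr the active [treatment()].
#' @param arch a `trait_architecture`.
#' @param env an `env_covariates` covering the new year.
#' @param var_e named per-stage plot error variances (see
#'   [error_variance_from_h2()]); internally derived from `h2` by
#'   [run_program()].
#' @return The updated `program_state`.
#' @export
run_year <- function(state, scheme, tr, arch, env, var_e) {
  year <- state$year + 1L
  state$year <- year
  nc <- noncrossing_stage_names(scheme)
  ev <- eval_stage_names(scheme)
  # phenotype evaluation cohorts
  for (nm in ev) {
    st <- stage_by_name(scheme, nm)
    ph <- phenotype_cohort(state$cohorts[[nm]], arch, env, year,
                           st$evaluation$n_locations,
                           st$evaluation$reps_per_location, var_e[[nm]])
    state$cohorts[[nm]]$pheno <- ph$entry_mean
  }
  # select parents and build the new F1 (this year's nursery output)
  parents <- select_parents(state$cohorts, tr$policy, tr$n_parents)
  state$parent_ages[[length(state$parent_ages) + 1L]] <-
    tibble(year = year, age = year - parents$birth_year + 1L)
  plan <- plan_crosses(seq_len(n_ind(parents)), tr$n_crosses,
                       tr$n_progeny_per_cross, tr$allow_reciprocals)
  n_prog <- attr(plan, "n_progeny")
  f1 <- cross_batch(parents, rep(plan$mother, each = n_prog),
                    rep(plan$father, each = n_prog), state$map,
                    first_id = state$next_id, birth_year = year)
  f1 <- attach_genetics(f1, arch)
  state$next_id <- state$next_id + n_ind(f1)
  # this year's occupancy: the new F1 sits in the first (nursery) stage
  state$cohorts[[nc[1]]] <- f1
  state <- record_year(state, scheme, tr, arch)
  # advance the ladder: this year's stage k occupant feeds stage k+1
  new_cohorts <- list()
  new_cohorts[[nc[1]]] <- f1   # placeholder; replaced by next year's F1
  for (k in seq_along(nc)[-1]) {
    prev <- stage_by_name(scheme, nc[k - 1])
    out_n <- prev$selection$n_selected_out
    src <- state$cohorts[[nc[k - 1]]]
    new_cohorts[[nc[k]]] <- if (identical(prev$role, "evaluation") &&
                                out_n < n_ind(src)) {
      advance(src, out_n)
    } else {
      src
    }
  }
  state$cohorts <- new_cohorts
  state
}

records_table <- function(state, replicate, treatment_id) {
  out <- dplyr::bind_rows(state$records)
  out$replicate <- as.integer(replicate)
  out$treatment_id <- treatment_id
  out[, c("replicate", "treatment_id", "year", "stage", "n", "genetic_mean",
          "genetic_var")]
}

#' Run one replicate of a breeding program under one or more treatments
#'
#' One founder realization and one burn-in segment (the scheme's own baseline
#' crossing decisions) are shared by all treatments: the state at the end of
#' burn-in is forked, so treatment contrasts are paired within replicate and
#' burn-in records are identical across treatments.
#'
#' @param scheme a valid [breeding_scheme()].
#' @param treatments a [treatment()] or list of treatments.
#' @param n_years treatment years simulated after burn-in.
#' @param burn_in_years baseline years before the fork (default 20).
#' @param cfg a [genome_config()].
#' @param vc a [variance_components()].
#' @param h2 named per-stage plot heritabilities (default
#'   [default_stage_h2()]).
#' @param n_qtn_per_chrom QTN per chromosome (default 100).
#' @param n_founders founder individuals (default 4).
#' @param master_seed integer master seed.
#' @param replicate replicate number (used in sub-stream seeding and the
#'   output).
#' @return A tidy tibble: `replicate`, `treatment_id`, `year`, `stage`, `n`,
#'   `genetic_mean`, `genetic_var`. Years `1..burn_in_years` are the shared
#'   burn-in; treatment years follow.
#' @export
run_replicate <- function(scheme, treatments, n_years, burn_in_years = 20L,
                          cfg = genome_config(), vc = variance_components(),
                          h2 = default_stage_h2(), n_qtn_per_chrom = 100L,
                          n_founders = 4L, master_seed = 1L, replicate = 1L) {
  assert_valid_scheme(scheme)
  if (inherits(treatments, "treatment")) treatments <- list(treatments)
  f1_total <- n_f1(scheme)
  for (tr in treatments) {
    if (tr$n_crosses * tr$n_progeny_per_cross != f1_total) {
      abort_breedsim(sprintf(
        "treatment '%s' produces %d F1 individuals; the scheme is sized for %d",
        tr$id, tr$n_crosses * tr$n_progeny_per_cross, f1_total),
        "breedsim_constraint_error")
    }
  }
  set.seed(derive_seed(master_seed, "founders", replicate))
  fs <- simulate_founders(cfg, n_founders = n_founders)
  arch <- sample_architecture(fs, vc, n_qtn_per_chrom)
  n_loc_max <- max(vapply(scheme$stages, function(st) {
    as.integer(st$evaluation$n_locations %||% 1L)
  }, integer(1)))
  env <- sample_env_covariates(burn_in_years + n_years, n_loc_max, vc)
  var_e <- stage_var_e(scheme, vc, h2)
  base_tr <- baseline_treatment(scheme)
  state <- init_program(scheme, fs, base_tr, arch)
  set.seed(derive_seed(master_seed, "burnin", replicate))
  for (y in seq_len(burn_in_years)) {
    state <- run_year(state, scheme, base_tr, arch, env, var_e)
  }
  out <- lapply(treatments, function(tr) {
    st <- state
    set.seed(derive_seed(master_seed, "treatment", replicate, tr$id))
    for (y in seq_len(n_years)) {
      st <- run_year(st, scheme, tr, arch, env, var_e)
    }
    tab <- records_table(st, replicate, tr$id)
    ages <- dplyr::bind_rows(st$parent_ages)
    ages$replicate <- as.integer(replicate)
    ages$treatment_id <- tr$id
    attr(tab, "parent_ages") <- ages
    tab
  })
  res <- dplyr::bind_rows(out)
  attr(res, "parent_ages") <- dplyr::bind_rows(lapply(out, attr, "parent_ages"))
  res
}

#' Simulate a breeding program for one treatment
#'
#' Convenience wrapper around [run_replicate()] for a single treatment:
#' founder simulation, burn-in under the scheme's baseline crossing
#' decisions, then `n_years` under `tr`.
#'
#' @inheritParams run_replicate
#' @param tr a [treatment()].
#' @param seed master seed.
#' @return A tidy results tibble (see [run_replicate()]).
#' @export
run_program <- function(scheme, tr, n_years, burn_in_years = 20L,
                        cfg = genome_config(), vc = variance_components(),
                        h2 = default_stage_h2(), n_qtn_per_chrom = 100L,
                        n_founders = 4L, seed = 1L) {
  run_replicate(scheme, list(tr), n_years, burn_in_years, cfg, vc, h2,
                n_qtn_per_chrom, n_founders, master_seed = seed,
                replicate = 1L)
}
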