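# Shared small-scale fixtures, built in code.

# compact genome: 4 chromosomes x 120 candidate sites, short burn-in
small_cfg <- function(...) {
  genome_config(n_chromosomes = 4L, sites_per_chromosome = 120L,
                burn_in_generations = 300L, ...)
}

# one founder realization reused across tests (built once per test run)
small_fs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_founders(small_cfg(), n_founders = 6,
                                                    seed = 101)
    cache
  }
})

small_arch <- function(vc = variance_components(), n_qtn = 30L, seed = 202) {
  set.seed(seed)
  sample_architecture(small_fs(), vc, n_qtn)
}

# a compact but structurally complete scheme for engine tests
mini_scheme <- function() {
  breeding_scheme(
    id = "mini", pipeline_id = "test",
    stages = list(
      stage_definition("X", 1, "crossing",
                       crossing = list(n_parents = 4L, n_crosses = 4L,
                                       n_progeny_per_cross = 25L,
                                       coupling_method = "random mating",
                                       allow_reciprocals = FALSE)),
      stage_definition("N", 1, "multiplication",
                       evaluation = list(n_locations = 1L, reps_per_location = 1L),
                       selection = list(n_entries_in = 100L, n_selected_out = 100L,
                                        selection_method = "none",
                                        surrogate_of_merit = "none",
                                        recycling_source = FALSE)),
      stage_definition("S1", 2, "evaluation",
                       evaluation = list(n_locations = 1L, reps_per_location = 1L),
                       selection = list(n_entries_in = 100L, n_selected_out = 20L,
                                        selection_method = "phenotypic truncation",
                                        surrogate_of_merit = "entry mean",
                                        recycling_source = FALSE)),
      stage_definition("S2", 3, "evaluation",
                       evaluation = list(n_locations = 2L, reps_per_location = 2L),
                       selection = list(n_entries_in = 20L, n_selected_out = 10L,
                                        selection_method = "phenotypic truncation",
                                        surrogate_of_merit = "entry mean",
                                        recycling_source = TRUE)),
      stage_definition("S3", 4, "evaluation",
                       evaluation = list(n_locations = 2L, reps_per_location = 2L),
                       selection = list(n_entries_in = 10L, n_selected_out = 6L,
                                        selection_method = "phenotypic truncation",
                                        surrogate_of_merit = "entry mean",
                                        recycling_source = TRUE))))
}

mini_h2 <- function() c(S1 = 0.25, S2 = 0.4, S3 = 0.5)

# a genetic map with fully specified positions, for exact meiosis tests
manual_map <- function(pos_list, chr_len = vapply(pos_list, max, numeric(1))) {
  chrom <- rep(seq_along(pos_list), lengths(pos_list))
  pos_m <- unlist(pos_list)
  tab <- tibble::tibble(chrom = chrom, site = seq_along(pos_m),
                        id = sprintf("c%02d_s%04d", chrom, seq_along(pos_m)),
                        pos_m = pos_m, pos_bp = pmax(1, round(pos_m * 1e8)))
  structure(list(table = tab, chr_len = as.numeric(chr_len),
                 chr_start = vapply(seq_along(pos_list),
                                    function(c) min(which(chrom == c)), integer(1)),
                 chr_end = vapply(seq_along(pos_list),
                                  function(c) max(which(chrom == c)), integer(1)),
                 n_sites = length(pos_m)),
            class = "genetic_map")
}

# a population with fully specified haplotypes, for exact-value tests
manual_population <- function(haps, ids = NULL) {
  H <- do.call(cbind, haps)   # each element: one haplotype (sites vector)
  new_pop <- breedsim:::new_population
  new_pop(H, id = ids %||% seq_len(ncol(H) / 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
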