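# Genome configuration, genetic map and founder simulation.
#
# The genome is site-based: a fixed panel of candidate biallelic sites per
# chromosome with positions in Morgans (physical positions derived through
# the constant per-bp recombination rate). Founders carry standing variation
# generated by a discrete-generation Wright-Fisher burn-in at small effective
# size: random mating, symmetric two-state mutation per site, and Poisson
# recombination. Each candidate site stands for its surrounding window of
# sequence, so its mutation rate is the per-bp rate times the bp spacing
# between sites.

#' Genome and burn-in configuration
#'
#' Defaults describe a cassava-like outbred genome: 18 chromosomes of 1.43
#' Morgans and 8e8 bp each, per-bp mutation rate 2e-9, and an effective
#' population size of 30 standing in for a history of natural and artificial
#' selection.
#'
#' @param n_chromosomes number of chromosome pairs.
#' @param morgans_per_chromosome genetic length of each chromosome (Morgans).
#' @param bp_per_chromosome physical length of each chromosome (base pairs).
#' @param mutation_rate_per_bp mutation rate per base pair per generation.
#' @param effective_population_size Wright-Fisher burn-in population size.
#' @param sites_per_chromosome candidate segregating sites simulated per
#'   chromosome (must cover the QTN demanded downstream).
#' @param burn_in_generations Wright-Fisher generations run to reach
#'   mutation-drift equilibrium.
#' @param seed optional integer seed used by [simulate_founders()] when no
#'   explicit seed is given there.
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(n_chromosomes = 18L,
                          morgans_per_chromosome = 1.43,
                          bp_per_chromosome = 8e8,
                          mutation_rate_per_bp = 2e-9,
                          effective_population_size = 30L,
                          sites_per_chromosome = 500L,
                          burn_in_generations = 1000L,
                          seed = NULL) {
  stopifnot(is_count(n_chromosomes, 1), morgans_per_chromosome > 0,
            bp_per_chromosome > 0, mutation_rate_per_bp > 0,
            is_count(effective_population_size, 1),
            is_count(sites_per_chromosome, 2),
            is_count(burn_in_generations, 1))
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 morgans_per_chromosome = morgans_per_chromosome,
                 bp_per_chromosome = bp_per_chromosome,
                 mutation_rate_per_bp = mutation_rate_per_bp,
                 effective_population_size = as.integer(effective_population_size),
                 sites_per_chromosome = as.integer(sites_per_chromosome),
                 burn_in_generations = as.integer(burn_in_generations),
                 seed = seed),
            class = "genome_config")
}

#' Recombination rate per base pair implied by a genome configuration
#'
#' The constant rate `morgans_per_chromosome / bp_per_chromosome` used to
#' convert between genetic and physical positions. At the defaults this is
#' 1.43 / 8e8 = 1.7875e-9, displayed as 1.8e-9 (2 significant figures).
#'
#' @param cfg a [genome_config()].
#' @param display if `TRUE`, round to 2 significant figures for display.
#' @return Rate in Morgans per base pair.
#' @export
#' @examples
#' recombination_rate_per_bp(genome_config())                  # 1.7875e-09
#' recombination_rate_per_bp(genome_config(), display = TRUE)  # 1.8e-09
recombination_rate_per_bp <- function(cfg, display = FALSE) {
  r <- cfg$morgans_per_chromosome / cfg$bp_per_chromosome
  if (display) signif(r, 2) else r
}

new_genetic_map <- function(chrom, pos_m, cfg) {
  ord <- order(chrom, pos_m)
  chrom <- chrom[ord]; pos_m <- pos_m[ord]
  rate <- recombination_rate_per_bp(cfg)
  tab <- tibble(chrom = chrom,
                site = seq_along(chrom),
                id = sprintf("c%02d_s%04d", as.integer(chrom),
                             as.integer(stats::ave(chrom, chrom, FUN = seq_along))),
                pos_m = pos_m,
                pos_bp = pmax(1, round(pos_m / rate)))
  chr_ids <- seq_len(cfg$n_chromosomes)
  chr_start <- vapply(chr_ids, function(c) min(which(chrom == c)), integer(1))
  chr_end <- vapply(chr_ids, function(c) max(which(chrom == c)), integer(1))
  structure(list(table = tab,
                 chr_len = rep(cfg$morgans_per_chromosome, cfg$n_chromosomes),
                 chr_start = chr_start, chr_end = chr_end,
                 n_sites = nrow(tab)),
            class = "genetic_map")
}

subset_map <- function(map, keep) {
  keep <- sort(keep)
  tab <- map$table[keep, , drop = FALSE]
  tab$site <- seq_len(nrow(tab))
  chr_ids <- seq_along(map$chr_len)
  chr_start <- integer(length(chr_ids)); chr_end <- integer(length(chr_ids))
  for (c in chr_ids) {
    idx <- which(tab$chrom == c)
    if (length(idx) == 0) {
      abort_breedsim(sprintf("no segregating sites retained on chromosome %d", c),
                     "breedsim_insufficient_variation_error")
    }
    chr_start[c] <- min(idx); chr_end[c] <- max(idx)
  }
  structure(list(table = tab, chr_len = map$chr_len,
                 chr_start = chr_start, chr_end = chr_end,
                 n_sites = nrow(tab)),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d sites on %d chromosomes (%.2f Morgans each)\n",
              x$n_sites, length(x$chr_len), x$chr_len[1]))
  invisible(x)
}

# --- population container ---------------------------------------------------

# H is sites x haplotypes: columns 2i - 1 and 2i hold individual i's two
# haplotypes (contiguous columns keep meiosis and dosage extraction fast).
new_population <- function(H, id, mother = NA_integer_, father = NA_integer_,
                           birth_year = NA_integer_, pheno = NULL) {
  n <- ncol(H) / 2
  structure(list(H = H,
                 id = as.integer(rep_len(id, n)),
                 mother = as.integer(rep_len(mother, n)),
                 father = as.integer(rep_len(father, n)),
                 birth_year = as.integer(rep_len(birth_year, n)),
                 pheno = pheno),
            class = "population")
}

#' Number of individuals in a population
#' @param pop a `population` object.
#' @return Integer count.
#' @export
n_ind <- function(pop) length(pop$id)

#' Subset a population by individual index
#' @param x a `population`.
#' @param i integer indices of individuals to keep.
#' @param ... unused.
#' @return A `population` with the selected individuals, in the given order.
#' @export
`[.population` <- function(x, i, ...) {
  cols <- as.vector(rbind(2L * i - 1L, 2L * i))
  out <- new_population(x$H[, cols, drop = FALSE], x$id[i], x$mother[i],
                        x$father[i], x$birth_year[i],
                        if (!is.null(x$pheno)) x$pheno[i])
  if (!is.null(x$g0)) out$g0 <- x$g0[i]
  if (!is.null(x$s)) out$s <- x$s[i]
  out
}

#' @export
print.population <- function(x, ...) {
  cat(sprintf("<population> %d diploid individuals x %d sites\n",
              n_ind(x), nrow(x$H)))
  invisible(x)
}

pop_concat <- function(pops) {
  all_have <- function(f) all(vapply(pops, function(p) !is.null(p[[f]]), logical(1)))
  out <- new_population(do.call(cbind, lapply(pops, `[[`, "H")),
                        unlist(lapply(pops, `[[`, "id")),
                        unlist(lapply(pops, `[[`, "mother")),
                        unlist(lapply(pops, `[[`, "father")),
                        unlist(lapply(pops, `[[`, "birth_year")),
                        if (all_have("pheno")) unlist(lapply(pops, `[[`, "pheno")))
  if (all_have("g0")) out$g0 <- unlist(lapply(pops, `[[`, "g0"))
  if (all_have("s")) out$s <- unlist(lapply(pops, `[[`, "s"))
  out
}

#' Allele dosages of a population
#'
#' @param pop a `population`.
#' @param sites optional site indices to extract.
#' @return Integer matrix, individuals x sites, entries in 0:2.
#' @export
dosages <- function(pop, sites = NULL) {
  n <- n_ind(pop)
  odd <- seq.int(1L, 2L * n, by = 2L)
  D <- if (is.null(sites)) {
    pop$H[, odd, drop = FALSE] + pop$H[, odd + 1L, drop = FALSE]
  } else {
    pop$H[sites, odd, drop = FALSE] + pop$H[sites, odd + 1L, drop = FALSE]
  }
  t(D)
}

# --- founder simulation -----------------------------------------------------

#' Simulate founder individuals with neutral standing variation
#'
#' Runs a Wright-Fisher burn-in of `cfg$burn_in_generations` generations at
#' population size `cfg$effective_population_size`, with Poisson-crossover
#' recombination on the configured genetic map and symmetric per-site
#' mutation at rate `mutation_rate_per_bp * (bp_per_chromosome /
#' sites_per_chromosome)` per transmitted gamete, then samples `n_founders`
#' diploids from the final generation. Sites monomorphic in the sampled
#' founders are pruned from both haplotypes and map.
#'
#' @param cfg a [genome_config()].
#' @param n_founders number of founder individuals to sample (at most the
#'   effective population size).
#' @param seed optional integer seed; defaults to `cfg$seed`, or to the
#'   current RNG stream when both are `NULL`.
#' @return An object of class `founder_set`: a list with elements `founders`
#'   (a `population`), `map` (a `genetic_map` of retained segregating sites),
#'   `het` (mean expected heterozygosity per burn-in generation),
#'   `n_candidate_sites` and `n_retained`.
#' @export
#' @examples
#' cfg <- genome_config(n_chromosomes = 2, sites_per_chromosome = 50,
#'                      burn_in_generations = 100)
#' fs <- simulate_founders(cfg, n_founders = 4, seed = 1)
#' fs$founders
simulate_founders <- function(cfg, n_founders = 4L, seed = NULL) {
  stopifnot(inherits(cfg, "genome_config"), is_count(n_founders, 1))
  ne <- cfg$effective_population_size
  if (n_founders > ne) {
    abort_breedsim(sprintf("n_founders (%d) exceeds the burn-in population size (%d)",
                           n_founders, ne),
                   "breedsim_config_error")
  }
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n_cand <- cfg$n_chromosomes * cfg$sites_per_chromosome
  chrom <- rep(seq_len(cfg$n_chromosomes), each = cfg$sites_per_chromosome)
  pos_m <- runif(n_cand, 0, cfg$morgans_per_chromosome)
  map <- new_genetic_map(chrom, pos_m, cfg)
  mu_site <- cfg$mutation_rate_per_bp *
    (cfg$bp_per_chromosome / cfg$sites_per_chromosome)
  res <- .wf_burnin_cpp(ne, cfg$burn_in_generations, map$table$pos_m,
                        map$chr_start - 1L, map$chr_end - 1L, map$chr_len,
                        mu_site)
  pick <- sort(sample.int(ne, n_founders))
  cols <- as.vector(rbind(2L * pick - 1L, 2L * pick))
  H <- res$H[, cols, drop = FALSE]
  counts <- rowSums(H)
  seg <- which(counts > 0 & counts < ncol(H))
  map2 <- subset_map(map, seg)
  founders <- new_population(H[sort(seg), , drop = FALSE],
                             id = seq_len(n_founders), birth_year = 0L)
  structure(list(founders = founders, map = map2, het = res$het,
                 n_candidate_sites = n_cand, n_retained = length(seg),
                 mu_site = mu_site, config = cfg),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("<founder_set> %d founders; %d of %d candidate sites segregating\n",
              n_ind(x$founders), x$n_retained, x$n_candidate_sites))
  invisible(x)
}

# --- meiosis and crossing ---------------------------------------------------

#' Simulate meiosis for one individual
#'
#' Produces gametes under the no-interference Poisson crossover model: per
#' chromosome the crossover count is Poisson with mean equal to the map
#' length in Morgans, crossover positions are uniform, and the starting
#' haplotype is chosen with probability 1/2.
#'
#' @param pop a `population` holding the parent.
#' @param map the `genetic_map` the population's sites are aligned to.
#' @param which index of the parent within `pop`.
#' @param n_gametes number of independent gametes to draw.
#' @return Integer matrix, sites x `n_gametes`, one gamete per column.
#' @export
meiosis <- function(pop, map, which = 1L, n_gametes = 1L) {
  stopifnot(inherits(pop, "population"), inherits(map, "genetic_map"),
            nrow(pop$H) == map$n_sites, is_count(n_gametes, 1),
            which >= 1, which <= n_ind(pop))
  hapA <- rep.int(2L * as.integer(which) - 2L, n_gametes)
  .gametes_cpp(pop$H, hapA, hapA + 1L, map$table$pos_m, map$chr_start - 1L,
               map$chr_end - 1L, map$chr_len, 0)
}

# One maternal and one paternal gamete per progeny; mother_idx/father_idx are
# per-progeny indices into pop. No mutation during the breeding phase.
cross_batch <- function(pop, mother_idx, father_idx, map, first_id,
                        birth_year) {
  n <- length(mother_idx)
  stopifnot(length(father_idx) == n)
  mo <- 2L * as.integer(mother_idx) - 2L
  fa <- 2L * as.integer(father_idx) - 2L
  H <- .progeny_cpp(pop$H, mo, mo + 1L, fa, fa + 1L, map$table$pos_m,
                    map$chr_start - 1L, map$chr_end - 1L, map$chr_len)
  new_population(H, id = seq.int(first_id, length.out = n),
                 mother = pop$id[mother_idx], father = pop$id[father_idx],
                 birth_year = birth_year)
}

#' Cross two individuals
#'
#' Each progeny is formed from one maternal and one paternal meiosis;
#' pedigree (mother and father ids) is recorded and progeny ids are unique
#' within the returned population.
#'
#' @param mother,father single-individual `population` objects (e.g.
#'   `pop[3]`) sharing one genetic map.
#' @param n_progeny number of progeny to produce.
#' @param map the shared `genetic_map`.
#' @param first_id id assigned to the first progeny.
#' @param birth_year birth year recorded for the progeny.
#' @return A `population` of `n_progeny` individuals.
#' @export
make_cross <- function(mother, father, n_progeny, map, first_id = 1L,
                       birth_year = NA_integer_) {
  stopifnot(inherits(mother, "population"), inherits(father, "population"),
            n_ind(mother) == 1, n_ind(father) == 1, is_count(n_progeny, 1))
  pair <- pop_concat(list(mother, father))
  cross_batch(pair, rep.int(1L, n_progeny), rep.int(2L, n_progeny), map,
              first_id = first_id, birth_year = birth_year)
}
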