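test_that("recombination rate per bp is the exact genome-length ratio", {
  cfg <- genome_config()
  expect_equal(recombination_rate_per_bp(cfg), 1.43 / 8e8)  # 1.7875e-9 exactly
  expect_equal(recombination_rate_per_bp(cfg, display = TRUE), 1.8e-9)
  cfg2 <- genome_config(morgans_per_chromosome = 1, bp_per_chromosome = 1e8)
  expect_equal(recombination_rate_per_bp(cfg2), 1e-8)
})

test_that("founder simulation is deterministic and structurally sound", {
  cfg <- small_cfg()
  a <- simulate_founders(cfg, n_founders = 4, seed = 33)
  b <- simulate_founders(cfg, n_founders = 4, seed = 33)
  expect_identical(a$founders$H, b$founders$H)
  expect_identical(a$map$table, b$map$table)

  expect_identical(n_ind(a$founders), 4L)
  expect_identical(a$n_candidate_sites, 4L * 120L)
  expect_identical(a$map$n_sites, a$n_retained)
  # every retained site segregates in the founder sample
  D <- dosages(a$founders)
  expect_true(all(D %in% 0:2))
  cs <- colSums(D)
  expect_true(all(cs > 0 & cs < 2 * 8))
  # map positions strictly increasing within chromosomes, one bp conversion rate
  tab <- a$map$table
  for (c in unique(tab$chrom)) {
    p <- tab$pos_m[tab$chrom == c]
    expect_true(all(diff(p) > 0))
  }
  expect_equal(tab$pos_bp, pmax(1, round(tab$pos_m / recombination_rate_per_bp(cfg))))
  # heterozygosity is positive and roughly stable over the last 20% of burn-in
  tail_het <- a$het[seq(0.8 * length(a$het), length(a$het))]
  expect_true(all(tail_het > 0))
  trend <- coef(lm(tail_het ~ seq_along(tail_het)))[2]
  expect_lt(abs(trend * length(tail_het)), 0.25 * mean(tail_het))
})

test_that("a founder sample too large for the burn-in population is rejected", {
  expect_error(simulate_founders(small_cfg(), n_founders = 1000, seed = 1),
               class = "breedsim_config_error")
})

test_that("meiosis on a zero-length chromosome returns a whole parental haplotype", {
  map <- manual_map(list(seq(0, 1, length.out = 10), rep(0, 5)),
                    chr_len = c(1, 0))
  h1 <- rep(0L, 15); h2 <- rep(1L, 15)
  pop <- manual_population(list(h1, h2))
  set.seed(9)
  g <- meiosis(pop, map, n_gametes = 200)
  chr2 <- g[11:15, ]
  expect_true(all(chr2 == 0 | chr2 == 1))
  expect_true(all(apply(chr2, 2, function(x) length(unique(x))) == 1))
  # both parental haplotypes transmitted at ~1/2
  frac <- mean(chr2[1, ])
  expect_gt(frac, 0.35); expect_lt(frac, 0.65)
})

test_that("crossover counts are Poisson with mean equal to the map length", {
  L <- 1.43
  n_sites <- 200
  map <- manual_map(list(seq(0, L, length.out = n_sites)), chr_len = L)
  pop <- manual_population(list(rep(0L, n_sites), rep(1L, n_sites)))
  set.seed(17)
  g <- meiosis(pop, map, n_gametes = 10000)
  switches <- colSums(g[-1, , drop = FALSE] != g[-n_sites, , drop = FALSE])
  expect_equal(mean(switches), L, tolerance = 0.05 / L)
  # goodness of fit against Poisson(1.43)
  classes <- pmin(switches, 5)
  obs <- tabulate(classes + 1L, nbins = 6L)
  p <- c(dpois(0:4, L), 1 - ppois(4, L))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("two-point recombination fraction follows the Haldane map function", {
  d <- 0.01
  map <- manual_map(list(c(0, d)), chr_len = d)
  pop <- manual_population(list(c(0L, 0L), c(1L, 1L)))
  set.seed(23)
  g <- meiosis(pop, map, n_gametes = 20000)
  r_obs <- mean(g[1, ] != g[2, ])
  r_exp <- (1 - exp(-2 * d)) / 2   # Haldane, no interference
  expect_equal(r_obs, r_exp, tolerance = 3e-3 / r_exp)
})

test_that("crosses record pedigree and respect Mendelian transmission", {
  fs <- small_fs()
  pop <- fs$founders
  set.seed(5)
  prog <- make_cross(pop[1], pop[2], 136, fs$map, first_id = 100L,
                     birth_year = 3L)
  expect_identical(n_ind(prog), 136L)
  expect_true(all(prog$mother == pop$id[1]))
  expect_true(all(prog$father == pop$id[2]))
  expect_identical(prog$id, seq.int(100L, length.out = 136L))
  expect_true(all(prog$birth_year == 3L))
  # every transmitted allele exists in the transmitting parent
  mo_alleles <- pop$H[, 1:2]; fa_alleles <- pop$H[, 3:4]
  mat_g <- prog$H[, seq(1, 271, by = 2)]
  pat_g <- prog$H[, seq(2, 272, by = 2)]
  expect_true(all(mat_g == mo_alleles[, 1] | mat_g == mo_alleles[, 2]))
  expect_true(all(pat_g == fa_alleles[, 1] | pat_g == fa_alleles[, 2]))
  expect_true(all(dosages(prog) %in% 0:2))
})

test_that("selfing a fully homozygous parent yields genetically identical progeny", {
  map <- manual_map(list(seq(0, 1, length.out = 20)))
  hom <- rep(c(0L, 1L), 10)
  pop <- manual_population(list(hom, hom))
  set.seed(2)
  prog <- make_cross(pop[1], pop[1], 10, map)
  expect_true(all(prog$H == hom))
})

test_that("the folded founder SFS is decreasing and matches a linkage-free drift oracle", {
  ne <- 20L; gens <- 400L; n_hap <- 8L
  # moderate per-site mutation (theta ~ 0.2) so the neutral folded SFS is
  # strictly decreasing rather than flattened by recurrent mutation
  cfg <- genome_config(n_chromosomes = 2L, sites_per_chromosome = 80L,
                       bp_per_chromosome = 1e8,
                       effective_population_size = ne,
                       burn_in_generations = gens)
  mu <- cfg$mutation_rate_per_bp * cfg$bp_per_chromosome / cfg$sites_per_chromosome

  counts <- integer(n_hap / 2)
  for (seed in 1:25) {
    fs <- simulate_founders(cfg, n_founders = 4, seed = 3000 + seed)
    mac <- colSums(dosages(fs$founders))
    mac <- pmin(mac, n_hap - mac)
    counts <- counts + tabulate(mac, nbins = n_hap / 2)
  }
  sfs <- counts / sum(counts)
  expect_true(all(diff(sfs) < 0))

  # oracle: independent-site Wright-Fisher allele-frequency drift with the
  # same mutation model, then a sample of 8 haplotypes per site
  set.seed(77)
  n_loci <- 4000
  p <- rep(0, n_loci)
  for (g in seq_len(gens)) {
    p_mut <- p * (1 - mu) + (1 - p) * mu
    p <- rbinom(n_loci, 2 * ne, p_mut) / (2 * ne)
  }
  k <- rbinom(n_loci, n_hap, p)
  k <- pmin(k, n_hap - k)
  k <- k[k > 0]
  oracle <- tabulate(k, nbins = n_hap / 2) / length(k)
  expect_true(all(diff(oracle) < 0))
  expect_lt(max(abs(sfs - oracle)), 0.08)
})
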