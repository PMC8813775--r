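test_that("recycling policies are validated", {
  expect_s3_class(recycling_policy(PYT = 0.5, AYT = 0.5), "recycling_policy")
  expect_error(recycling_policy(PYT = 0.6, AYT = 0.6),
               class = "breedsim_policy_error")
  expect_error(recycling_policy(0.5, 0.5))
})

test_that("cross plans cover forced designs, caps and parent coverage", {
  # 4 parents, 6 crosses without reciprocals: the full half-diallel is forced
  set.seed(1)
  plan <- plan_crosses(1:4, 6, 272)
  expect_identical(nrow(plan), 6L)
  pairs <- paste(pmin(plan$mother, plan$father), pmax(plan$mother, plan$father))
  expect_setequal(pairs, c("1 2", "1 3", "1 4", "2 3", "2 4", "3 4"))
  expect_identical(attr(plan, "n_progeny"), 272L)

  # the baseline: 4 parents, 12 reciprocal crosses, 136 progeny each
  plan <- plan_crosses(1:4, 12, 136, allow_reciprocals = TRUE)
  expect_identical(nrow(plan), 12L)
  expect_identical(anyDuplicated(paste(plan$mother, plan$father)), 0L)
  expect_identical(nrow(plan) * attr(plan, "n_progeny"), 1632L)

  # exceeding the half-diallel cap is a constraint error naming the cap
  err <- tryCatch(plan_crosses(1:4, 7, 10), error = identity)
  expect_s3_class(err, "breedsim_constraint_error")
  expect_match(conditionMessage(err), "cap of 6")

  # never selfing, never duplicated pairs, full coverage when feasible
  for (rep in 1:50) {
    np <- sample(3:12, 1)
    nc <- sample(ceiling(np / 2):(np * (np - 1) / 2), 1)
    plan <- plan_crosses(seq_len(np), nc, 5)
    expect_true(all(plan$mother != plan$father))
    key <- paste(pmin(plan$mother, plan$father), pmax(plan$mother, plan$father))
    expect_identical(anyDuplicated(key), 0L)
    expect_setequal(unique(c(plan$mother, plan$father)), seq_len(np))
  }
})

test_that("advance equals brute-force top-k with deterministic tie-breaking", {
  map <- manual_map(list(c(0, 0.5, 1)))
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    H <- matrix(sample(0:1, 3 * 2 * n, TRUE), nrow = 3)
    pop <- breedsim:::new_population(H, id = sample(n))
    pop$pheno <- sample(round(rnorm(n), 1), n, TRUE)  # ties likely
    sel <- advance(pop, k)
    ord <- order(-pop$pheno, pop$id)
    expect_identical(sel$id, pop$id[ord][seq_len(k)])
    if (k > 1) expect_true(all(diff(sel$pheno) <= 0))
  }
  # n_select = cohort size returns the whole cohort (sorted by merit)
  pop <- breedsim:::new_population(matrix(0L, 2, 8), id = 1:4)
  pop$pheno <- c(3, 1, 4, 2)
  expect_setequal(advance(pop, 4)$id, 1:4)
  expect_error(advance(pop, 5), class = "breedsim_state_error")
  pop$pheno <- NULL
  expect_error(advance(pop, 2), class = "breedsim_state_error")
})

test_that("parent selection apportions quotas by largest remainder and takes per-stage top merit", {
  expect_identical(policy_quotas(recycling_policy(PYT = 0.5, AYT = 0.5), 4),
                   c(PYT = 2L, AYT = 2L))
  expect_identical(policy_quotas(recycling_policy(PYT = 0.5, AYT = 0.5), 5),
                   c(PYT = 3L, AYT = 2L))  # tie goes to the earlier stage
  expect_identical(policy_quotas(recycling_policy(A = 0.34, B = 0.33, C = 0.33), 10),
                   c(A = 4L, B = 3L, C = 3L))

  mk <- function(ids, pheno) {
    p <- breedsim:::new_population(matrix(0L, 2, 2 * length(ids)), id = ids)
    p$pheno <- pheno
    p
  }
  cohorts <- list(PYT = mk(1:10, 10:1), AYT = mk(11:20, seq(5, 50, by = 5)))
  sel <- select_parents(cohorts, recycling_policy(PYT = 0.5, AYT = 0.5), 4)
  expect_setequal(sel$id, c(1, 2, 20, 19))
  sel <- select_parents(cohorts, recycling_policy(AYT = 1), 8)
  expect_identical(sel$id, 20:13)
  expect_error(select_parents(cohorts, recycling_policy(AYT = 1), 11),
               class = "breedsim_constraint_error")
  expect_error(select_parents(cohorts, recycling_policy(UYT = 1), 2),
               class = "breedsim_state_error")
})

test_that("each simulated year preserves the scheme's cohort ladder", {
  s <- mini_scheme()
  res <- run_program(s, baseline_treatment(s), n_years = 4, burn_in_years = 2,
                     cfg = small_cfg(), h2 = mini_h2(), n_qtn_per_chrom = 25L,
                     n_founders = 6L, seed = 11)
  sizes <- unique(res[, c("stage", "n")])
  expect_identical(nrow(sizes), 4L)  # one fixed size per stage, every year
  expect_identical(sizes$n[match(c("N", "S1", "S2", "S3"), sizes$stage)],
                   c(100L, 100L, 20L, 10L))
  expect_identical(sort(unique(res$year)), 1:6)
})

test_that("the baseline cassava ladder reproduces the program's stage sizes", {
  s <- baseline_cassava_scheme()
  res <- run_program(s, baseline_treatment(s), n_years = 1, burn_in_years = 1,
                     cfg = small_cfg(), n_qtn_per_chrom = 40L, seed = 4)
  yr <- res[res$year == 2, ]
  expect_identical(yr$n[match(c("Seedling nursery", "CE", "PYT", "AYT",
                                "UYT1", "UYT2"), yr$stage)],
                   c(1632L, 1632L, 120L, 64L, 24L, 24L))
})

test_that("runs are deterministic under the master seed and share burn-in across treatments", {
  s <- mini_scheme()
  trs <- list(treatment(4, 4, 25, recycling_policy(S2 = 0.5, S3 = 0.5)),
              treatment(6, 4, 25, recycling_policy(S3 = 1)))
  args <- list(s, trs, n_years = 3, burn_in_years = 2, cfg = small_cfg(),
               h2 = mini_h2(), n_qtn_per_chrom = 25L, n_founders = 6L,
               master_seed = 99L)
  r1 <- do.call(run_replicate, args)
  r2 <- do.call(run_replicate, args)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  burn <- r1[r1$year <= 2, ]
  split_burn <- lapply(split(burn[, c("year", "stage", "n", "genetic_mean",
                                      "genetic_var")], burn$treatment_id),
                       function(d) { rownames(d) <- NULL; as.data.frame(d) })
  expect_identical(split_burn[[1]], split_burn[[2]])
})

test_that("realized parental ages match the policy's expected cycle time", {
  s <- mini_scheme()
  res_mixed <- run_program(s, treatment(4, 4, 25,
                                        recycling_policy(S2 = 0.5, S3 = 0.5)),
                           n_years = 4, burn_in_years = 0, cfg = small_cfg(),
                           h2 = mini_h2(), n_qtn_per_chrom = 25L,
                           n_founders = 6L, seed = 7)
  ages <- attr(res_mixed, "parent_ages")
  expect_true(all(tapply(ages$age, ages$year, mean) == 3.5))
  res_s3 <- run_program(s, treatment(4, 4, 25, recycling_policy(S3 = 1)),
                        n_years = 4, burn_in_years = 0, cfg = small_cfg(),
                        h2 = mini_h2(), n_qtn_per_chrom = 25L,
                        n_founders = 6L, seed = 7)
  expect_true(all(attr(res_s3, "parent_ages")$age == 4))
})

test_that("a treatment whose F1 output mismatches the scheme size is rejected", {
  s <- mini_scheme()
  expect_error(run_program(s, treatment(4, 5, 25, recycling_policy(S3 = 1)),
                           n_years = 1, burn_in_years = 0, cfg = small_cfg(),
                           h2 = mini_h2(), n_qtn_per_chrom = 25L,
                           n_founders = 6L, seed = 1),
               class = "breedsim_constraint_error")
})

test_that("selection increases the genetic mean while pure-noise selection drifts around zero", {
  s <- mini_scheme()
  gains <- function(h2) {
    vapply(1:6, function(r) {
      res <- run_program(s, baseline_treatment(s), n_years = 8,
                         burn_in_years = 0, cfg = small_cfg(), h2 = h2,
                         n_qtn_per_chrom = 25L, n_founders = 6L, seed = 100 + r)
      m <- res$genetic_mean[res$stage == "S1"]
      m[length(m)] - m[1]
    }, numeric(1))
  }
  gain_sel <- gains(mini_h2())
  # h2 -> 0 limit: phenotypes are almost pure noise, expected trend ~ 0
  gain_null <- gains(c(S1 = 1e-4, S2 = 1e-4, S3 = 1e-4))
  expect_gt(mean(gain_sel), 0)
  expect_gt(mean(gain_sel), mean(gain_null) + 2 * sd(gain_null) / sqrt(6))
})
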