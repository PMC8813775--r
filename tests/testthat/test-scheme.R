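baseline <- baseline_cassava_scheme()

test_that("bundled baseline scheme has the documented structure", {
  expect_s3_class(baseline, "breeding_scheme")
  expect_length(baseline$stages, 7)
  expect_identical(vapply(baseline$stages, `[[`, character(1), "name"),
                   c("Crossing block", "Seedling nursery", "CE", "PYT", "AYT",
                     "UYT1", "UYT2"))
  expect_identical(nrow(validate_scheme(baseline)), 0L)
  expect_identical(n_f1(baseline), 1632L)
})

test_that("selected percentages reproduce the baseline advancement table", {
  pct <- selected_percentages(baseline)
  expect_equal(pct[["PYT"]], 7.35)
  expect_equal(pct[["AYT"]], 53.3)
  expect_equal(pct[["UYT1"]], 37.5)
  expect_equal(pct[["Seedling nursery"]], 100)
  expect_equal(pct[["CE"]], 100)
})

test_that("selected percentages error on a degenerate (zero-entry) stage", {
  s <- mini_scheme()
  s$stages[[3]]$selection$n_entries_in <- 0L
  s$stages[[3]]$selection$n_selected_out <- 0L
  s$stages[[2]]$selection$n_selected_out <- 0L  # keep chain consistent
  s$stages[[2]]$selection$n_entries_in <- 100L
  s$stages[[4]]$selection$n_entries_in <- 0L
  s$stages[[4]]$selection$n_selected_out <- 0L
  s$stages[[5]]$selection$n_entries_in <- 0L
  s$stages[[5]]$selection$n_selected_out <- 0L
  expect_error(selected_percentages(s), class = "breedsim_degenerate_stage_error")
})

test_that("validation reports each invariant breach as data", {
  s <- mini_scheme()
  expect_identical(nrow(validate_scheme(s)), 0L)

  # selection exceeding entries
  bad <- mini_scheme()
  bad$stages[[3]]$selection$n_selected_out <- 200L
  v <- validate_scheme(bad)
  expect_true("select_exceeds_entries" %in% v$rule)
  expect_true(any(v$stage == "S1"))

  # broken cohort chain
  bad <- mini_scheme()
  bad$stages[[4]]$selection$n_entries_in <- 21L
  expect_true("cohort_chain" %in% validate_scheme(bad)$rule)

  # no recycling source
  bad <- mini_scheme()
  bad$stages[[4]]$selection$recycling_source <- FALSE
  bad$stages[[5]]$selection$recycling_source <- FALSE
  expect_true("no_recycling_source" %in% validate_scheme(bad)$rule)

  # empty stage list
  empty <- breeding_scheme("x", stages = list())
  expect_true("empty_stages" %in% validate_scheme(empty)$rule)

  # decreasing years
  bad <- mini_scheme()
  bad$stages[[5]]$year <- c(2L, 2L)
  expect_true("years_decreasing" %in% validate_scheme(bad)$rule)

  # crossing stage not at head
  bad <- mini_scheme()
  bad$stages <- bad$stages[c(2, 1, 3, 4, 5)]
  expect_true("crossing_head" %in% validate_scheme(bad)$rule)
})

test_that("market segment and product profile validation uses the controlled vocabularies", {
  s <- mini_scheme()
  s$market_segments <- list(market_segment(
    "seg1", client_features = list(geographical_region = "x", favourite_color = "blue")))
  v <- validate_scheme(s)
  expect_true("unknown_feature_key" %in% v$rule)
  expect_identical(sum(v$rule == "unknown_feature_key"), 1L)

  s$market_segments <- list(market_segment("seg1"))
  s$product_profiles <- list(product_profile("nonexistent", list(
    trait_requirement("yield", "output", "at_least", NA_real_, "t/ha"))))
  v <- validate_scheme(s)
  expect_true("unresolved_reference" %in% v$rule)
  expect_true("missing_bound" %in% v$rule)
})

test_that("canonical JSON round-trips byte-identically and CSV preserves the stage table", {
  path <- system.file("extdata", "cassava_baseline_scheme.json",
                      package = "breedsim")
  tmp <- withr::local_tempfile(fileext = ".json")
  save_scheme(load_scheme(path), tmp)
  expect_identical(readLines(tmp), readLines(path))
  # idempotence on the re-saved file too
  tmp2 <- withr::local_tempfile(fileext = ".json")
  save_scheme(load_scheme(tmp), tmp2)
  expect_identical(readLines(tmp2), readLines(tmp))

  csv <- withr::local_tempfile(fileext = ".csv")
  save_scheme(baseline, csv)
  s2 <- load_scheme(csv, id = baseline$id)
  expect_identical(selected_percentages(s2), selected_percentages(baseline))
  expect_identical(plots_per_stage(s2), plots_per_stage(baseline))
  # free-form evaluation decisions survive the CSV round trip
  expect_identical(s2$stages[[3]]$evaluation$other$plant_portion,
                   baseline$stages[[3]]$evaluation$other$plant_portion)
})

test_that("malformed files raise format errors; invalid schemes raise validation errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", bad)
  expect_error(load_scheme(bad), class = "breedsim_format_error")
  expect_error(load_scheme("/nonexistent/file.json"),
               class = "breedsim_format_error")

  invalid <- withr::local_tempfile(fileext = ".json")
  s <- mini_scheme()
  s$stages[[3]]$selection$n_selected_out <- 200L
  save_scheme(s, invalid)
  err <- tryCatch(load_scheme(invalid), error = identity)
  expect_s3_class(err, "breedsim_validation_error")
  expect_match(conditionMessage(err), "n_selected_out")
})

test_that("expected cycle time is the policy-weighted mean of recycling years", {
  expect_equal(expected_cycle_time(baseline, recycling_policy(PYT = 0.5, AYT = 0.5)),
               3.5)
  expect_equal(expected_cycle_time(baseline, recycling_policy(AYT = 1)), 4)
  expect_equal(expected_cycle_time(baseline, recycling_policy(PYT = 1)), 3)
  # linear in the policy weights, bounded by the recycling-stage years
  for (a in seq(0, 1, by = 0.25)) {
    ct <- expected_cycle_time(baseline, recycling_policy(PYT = a, AYT = 1 - a))
    expect_equal(ct, a * 3 + (1 - a) * 4)
    expect_gte(ct, 3); expect_lte(ct, 4)
  }
  expect_error(expected_cycle_time(baseline, recycling_policy(CE = 1)),
               class = "breedsim_policy_error")
  expect_error(expected_cycle_time(baseline, recycling_policy(Nowhere = 1)),
               class = "breedsim_policy_error")
})

test_that("a recycling stage with a year range contributes its final year", {
  s <- mini_scheme()
  s$stages[[5]]$year <- c(4L, 5L)
  expect_equal(expected_cycle_time(s, recycling_policy(S3 = 1)), 5)
})

test_that("plot counts are entries x locations x reps, checks excluded", {
  plots <- plots_per_stage(baseline)
  expect_equal(plots[["PYT"]], 480)    # 120 x 2 x 2
  expect_equal(plots[["AYT"]], 384)    # 64 x 2 x 3
  expect_equal(plots[["CE"]], 1632)    # 1 location, 1 rep
  expect_equal(plots[["UYT1"]], 144)   # 24 x 2 x 3
})

test_that("flowchart export has one node per stage, forward edges, and dashed recycling back-edges", {
  dot <- to_flowchart(baseline)
  expect_match(dot, "^digraph")
  node_lines <- grep("\\[label=", strsplit(dot, "\n")[[1]], value = TRUE)
  expect_length(node_lines[!grepl("style=dashed", node_lines)], 7)
  edges <- grep("->", strsplit(dot, "\n")[[1]], value = TRUE)
  expect_length(edges[!grepl("dashed", edges)], 6)
  expect_length(grep("dashed", edges, value = TRUE), 2)
  # property: node count equals stage count on other schemes
  mini_dot <- strsplit(to_flowchart(mini_scheme()), "\n")[[1]]
  expect_length(grep("\\[label=", mini_dot), 5)
})
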