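# Breeding schemes as data: an ordered table of stages, each carrying the
# crossing, evaluation and selection (CES) decisions made at that stage.
# Decision fields beyond the fixed schema are preserved in a free-form
# `other` map so a program's full decision vocabulary stays representable.

eval_fields <- c("n_locations", "reps_per_location", "design_label",
                 "plot_width", "plot_length", "plot_units", "n_checks")
sel_fields <- c("n_entries_in", "n_selected_out", "selection_method",
                "surrogate_of_merit", "recycling_source")
cross_fields <- c("n_parents", "n_crosses", "n_progeny_per_cross",
                  "coupling_method", "allow_reciprocals")
stage_roles <- c("crossing", "multiplication", "evaluation")

#' Define one stage of a breeding scheme
#'
#' @param name short stage name, unique within the scheme (e.g. `"PYT"`).
#' @param year integer year, or length-2 vector `(start, end)` for stages that
#'   span several years.
#' @param role one of `"crossing"`, `"multiplication"`, `"evaluation"`.
#' @param evaluation list with `n_locations`, `reps_per_location`,
#'   `design_label`, `plot_width`, `plot_length`, `plot_units`, `n_checks`,
#'   and optionally `other` (a free-form named list of further evaluation
#'   decisions).
#' @param selection list with `n_entries_in`, `n_selected_out`,
#'   `selection_method`, `surrogate_of_merit`, `recycling_source`.
#' @param crossing list with `n_parents`, `n_crosses`, `n_progeny_per_cross`,
#'   `coupling_method`, `allow_reciprocals` (crossing stages only).
#' @param label optional display label (e.g. `"Stage 2 (PYT)"`).
#' @return An object of class `stage_definition`.
#' @export
stage_definition <- function(name, year, role, evaluation = NULL,
                             selection = NULL, crossing = NULL, label = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  year <- as.integer(year)
  if (length(year) == 1) year <- c(year, year)
  stopifnot(length(year) == 2)
  if (!is.null(evaluation)) {
    evaluation$other <- as.list(evaluation$other %||% list())
    evaluation <- evaluation[c(intersect(eval_fields, names(evaluation)), "other")]
  }
  if (!is.null(selection)) selection <- selection[intersect(sel_fields, names(selection))]
  if (!is.null(crossing)) crossing <- crossing[intersect(cross_fields, names(crossing))]
  structure(list(name = name, label = label %||% name, year = year,
                 role = role, evaluation = evaluation, selection = selection,
                 crossing = crossing),
            class = "stage_definition")
}

#' Define a breeding scheme
#'
#' A breeding scheme is the ordered list of stage-wise CES decisions a
#' pipeline executes, optionally linked to the market segments it serves.
#'
#' @param id scheme identifier.
#' @param pipeline_id identifier of the owning breeding pipeline.
#' @param stages list of [stage_definition()] objects in stage order; the
#'   first stage must be the (single) crossing stage.
#' @param segment_ids character vector of market-segment ids served.
#' @param market_segments list of [market_segment()] objects (optional).
#' @param product_profiles list of [product_profile()] objects (optional).
#' @return An object of class `breeding_scheme`.
#' @seealso [load_scheme()], [validate_scheme()], [selected_percentages()]
#' @export
breeding_scheme <- function(id, pipeline_id = "", stages = list(),
                            segment_ids = character(),
                            market_segments = list(),
                            product_profiles = list()) {
  structure(list(id = id, pipeline_id = pipeline_id,
                 segment_ids = as.character(segment_ids),
                 market_segments = market_segments,
                 product_profiles = product_profiles,
                 stages = stages),
            class = "breeding_scheme")
}

#' @export
print.breeding_scheme <- function(x, ...) {
  cat(sprintf("<breeding_scheme> %s (pipeline: %s)\n", x$id,
              if (nzchar(x$pipeline_id)) x$pipeline_id else "<none>"))
  for (st in x$stages) {
    n <- if (!is.null(st$selection)) st$selection$n_entries_in
         else if (!is.null(st$crossing)) with(st$crossing, n_crosses * n_progeny_per_cross)
         else NA
    yr <- if (st$year[1] == st$year[2]) st$year[1]
          else paste(st$year[1], st$year[2], sep = "-")
    rec <- if (isTRUE(st$selection$recycling_source)) " [recycling source]" else ""
    cat(sprintf("  %-18s year %-4s %-14s n=%s%s\n", st$name, yr, st$role, n, rec))
  }
  invisible(x)
}

stage_names <- function(s) vapply(s$stages, `[[`, character(1), "name")

crossing_stage <- function(s) {
  i <- which(vapply(s$stages, function(st) identical(st$role, "crossing"), logical(1)))
  if (length(i) == 0) NULL else s$stages[[i[1]]]
}

#' Total F1 size of a scheme's crossing stage
#'
#' @param s a [breeding_scheme()].
#' @return `n_crosses * n_progeny_per_cross` of the crossing stage.
#' @export
n_f1 <- function(s) {
  cb <- crossing_stage(s)
  if (is.null(cb)) abort_breedsim("scheme has no crossing stage",
                                  "breedsim_validation_error")
  cb$crossing$n_crosses * cb$crossing$n_progeny_per_cross
}

recycling_stages <- function(s) {
  nm <- stage_names(s)
  keep <- vapply(s$stages, function(st) isTRUE(st$selection$recycling_source),
                 logical(1))
  nm[keep]
}

empty_violations <- function() {
  tibble(stage = character(), field = character(), rule = character(),
         message = character())
}

add_violation <- function(v, stage, field, rule, message) {
  rbind(v, tibble(stage = stage, field = field, rule = rule, message = message))
}

#' Validate a breeding scheme
#'
#' Checks every structural invariant of the scheme data model and returns the
#' violations as data (an empty table means the scheme is valid). Rules
#' checked include: non-empty stage list; exactly one crossing stage, at the
#' head; `n_selected_out <= n_entries_in` within each stage; entries of each
#' stage equal to the selected-out count of its predecessor; at least one
#' recycling-source stage; non-decreasing years; positive location/rep
#' counts; market-segment feature keys restricted to the controlled
#' vocabularies; product-profile references and bounds.
#'
#' @param s a [breeding_scheme()].
#' @return A tibble with columns `stage`, `field`, `rule`, `message`; zero
#'   rows iff the scheme is valid.
#' @export
validate_scheme <- function(s) {
  v <- empty_violations()
  if (length(s$stages) == 0) {
    return(add_violation(v, "<scheme>", "stages", "empty_stages",
                         "scheme has no stages"))
  }
  roles <- vapply(s$stages, `[[`, character(1), "role")
  nm <- stage_names(s)
  if (anyDuplicated(nm)) {
    v <- add_violation(v, nm[duplicated(nm)][1], "name", "duplicate_stage_name",
                       "stage names must be unique")
  }
  n_cross <- sum(roles == "crossing")
  if (n_cross != 1 || roles[1] != "crossing") {
    v <- add_violation(v, "<scheme>", "stages", "crossing_head",
                       "scheme must have exactly one crossing stage, at the head")
  }
  bad_role <- which(!(roles %in% stage_roles))
  for (i in bad_role) {
    v <- add_violation(v, nm[i], "role", "invalid_role",
                       sprintf("role '%s' not one of: %s", roles[i],
                               paste(stage_roles, collapse = ", ")))
  }
  # per-stage checks
  for (st in s$stages) {
    if (st$year[1] > st$year[2] || st$year[1] < 1) {
      v <- add_violation(v, st$name, "year", "invalid_year",
                         "year range must be positive with start <= end")
    }
    if (identical(st$role, "crossing")) {
      cr <- st$crossing
      if (is.null(cr)) {
        v <- add_violation(v, st$name, "crossing", "missing_block",
                           "crossing stage lacks a crossing decision block")
      } else {
        for (f in c("n_parents", "n_crosses", "n_progeny_per_cross")) {
          if (!is_count(cr[[f]] %||% NA, 1)) {
            v <- add_violation(v, st$name, f, "invalid_count",
                               sprintf("%s must be a positive integer", f))
          }
        }
        if (is_count(cr$n_parents %||% NA, 1) && is_count(cr$n_crosses %||% NA, 1)) {
          cap <- cr$n_parents * (cr$n_parents - 1) / 2
          if (isTRUE(cr$allow_reciprocals)) cap <- 2 * cap
          if (cr$n_crosses > cap) {
            v <- add_violation(v, st$name, "n_crosses", "cross_cap",
                               sprintf("n_crosses (%d) exceeds the %s cap of %d for %d parents",
                                       cr$n_crosses,
                                       if (isTRUE(cr$allow_reciprocals)) "full-diallel" else "half-diallel",
                                       as.integer(cap), cr$n_parents))
          }
        }
      }
    } else {
      se <- st$selection
      if (is.null(se)) {
        v <- add_violation(v, st$name, "selection", "missing_block",
                           "non-crossing stage lacks a selection block")
      } else {
        if (!is_count(se$n_entries_in %||% NA, 0) ||
            !is_count(se$n_selected_out %||% NA, 0)) {
          v <- add_violation(v, st$name, "selection", "invalid_count",
                             "n_entries_in and n_selected_out must be non-negative integers")
        } else if (se$n_selected_out > se$n_entries_in) {
          v <- add_violation(v, st$name, "n_selected_out", "select_exceeds_entries",
                             sprintf("n_selected_out (%d) exceeds n_entries_in (%d)",
                                     se$n_selected_out, se$n_entries_in))
        }
      }
      ev <- st$evaluation
      if (!is.null(ev)) {
        if (!is_count(ev$n_locations %||% NA, 1) ||
            !is_count(ev$reps_per_location %||% NA, 1)) {
          v <- add_violation(v, st$name, "evaluation", "invalid_count",
                             "n_locations and reps_per_location must be positive integers")
        }
        if (!is.null(ev$n_checks) && !is_count(ev$n_checks, 0)) {
          v <- add_violation(v, st$name, "n_checks", "invalid_count",
                             "n_checks must be a non-negative integer")
        }
      }
    }
  }
  # chain: entries of stage k equal output of stage k-1
  prev_out <- NULL
  for (st in s$stages) {
    if (identical(st$role, "crossing")) {
      cr <- st$crossing
      prev_out <- if (is.null(cr)) NULL else cr$n_crosses * cr$n_progeny_per_cross
      next
    }
    this_in <- st$selection$n_entries_in
    if (!is.null(prev_out) && !is.null(this_in) && !is.na(prev_out) &&
        is_count(this_in, 0) && this_in != prev_out) {
      v <- add_violation(v, st$name, "n_entries_in", "cohort_chain",
                         sprintf("n_entries_in (%d) differs from predecessor's output (%d)",
                                 this_in, as.integer(prev_out)))
    }
    prev_out <- st$selection$n_selected_out
  }
  if (length(recycling_stages(s)) == 0) {
    v <- add_violation(v, "<scheme>", "recycling_source", "no_recycling_source",
                       "at least one stage must be flagged recycling_source")
  }
  yr <- vapply(s$stages, function(st) st$year[1], integer(1))
  if (is.unsorted(yr)) {
    v <- add_violation(v, "<scheme>", "year", "years_decreasing",
                       "stage start years must be non-decreasing in stage order")
  }
  # segments and profiles
  seg_ids <- vapply(s$market_segments, `[[`, character(1), "id")
  if (anyDuplicated(seg_ids)) {
    v <- add_violation(v, "<scheme>", "market_segments", "duplicate_segment_id",
                       "market segment ids must be unique")
  }
  for (seg in s$market_segments) v <- rbind(v, validate_segment(seg))
  for (ref in s$segment_ids) {
    if (length(seg_ids) > 0 && !(ref %in% seg_ids)) {
      v <- add_violation(v, "<scheme>", "segment_ids", "unresolved_reference",
                         sprintf("segment_id '%s' does not match any market segment", ref))
    }
  }
  for (i in seq_along(s$product_profiles)) {
    v <- rbind(v, validate_profile(s$product_profiles[[i]], seg_ids,
                                   sprintf("<profile %d>", i)))
  }
  v
}

assert_valid_scheme <- function(s) {
  v <- validate_scheme(s)
  if (nrow(v) > 0) {
    abort_breedsim(paste0("invalid breeding scheme:\n",
                          paste(sprintf("- [%s/%s] %s", v$stage, v$field,
                                        v$message), collapse = "\n")),
                   "breedsim_validation_error")
  }
  invisible(s)
}
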