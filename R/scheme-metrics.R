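# Derived program metrics computed from a validated breeding scheme.

stage_entries <- function(st) {
  if (identical(st$role, "crossing")) {
    st$crossing$n_crosses * st$crossing$n_progeny_per_cross
  } else {
    st$selection$n_entries_in
  }
}

#' Percentage of material retained at each stage
#'
#' For stage k, the percentage is `100 * entries(k) / entries(k - 1)`, where
#' the crossing stage's entry count is its total F1 output. Values are
#' reported to 3 significant digits, matching the display precision of
#' program summary tables (e.g. 7.35, 53.3, 37.5).
#'
#' @param s a valid [breeding_scheme()].
#' @return Named numeric vector (one entry per non-crossing stage).
#' @export
#' @examples
#' selected_percentages(baseline_cassava_scheme())
selected_percentages <- function(s) {
  assert_valid_scheme(s)
  entries <- vapply(s$stages, stage_entries, numeric(1))
  nm <- stage_names(s)
  out <- numeric(0)
  for (k in 2:length(entries)) {
    if (entries[k - 1] == 0) {
      abort_breedsim(sprintf("degenerate stage: '%s' has zero entries, cannot compute %% selected for '%s'",
                             nm[k - 1], nm[k]),
                     "breedsim_degenerate_stage_error")
    }
    out[nm[k]] <- signif(100 * entries[k] / entries[k - 1], 3)
  }
  out
}

#' Expected parent-recycling cycle time of a scheme under a policy
#'
#' The proportion-weighted mean of the year indices at which the policy's
#' recycling stages feed parents back into the crossing block. A stage
#' spanning a year range contributes its final year.
#'
#' @param s a valid [breeding_scheme()].
#' @param policy a [recycling_policy()]; every policy stage must be flagged
#'   `recycling_source` in `s`.
#' @return Expected cycle time in years.
#' @export
#' @examples
#' expected_cycle_time(baseline_cassava_scheme(),
#'                     recycling_policy(PYT = 0.5, AYT = 0.5))
expected_cycle_time <- function(s, policy) {
  assert_valid_scheme(s)
  stopifnot(inherits(policy, "recycling_policy"))
  nm <- stage_names(s)
  rec <- recycling_stages(s)
  for (stage in names(policy)) {
    if (!(stage %in% nm)) {
      abort_breedsim(sprintf("policy stage '%s' is absent from the scheme", stage),
                     "breedsim_policy_error")
    }
    if (!(stage %in% rec)) {
      abort_breedsim(sprintf("policy stage '%s' is not flagged recycling_source", stage),
                     "breedsim_policy_error")
    }
  }
  years <- vapply(names(policy), function(stage) {
    st <- s$stages[[match(stage, nm)]]
    as.numeric(st$year[2])
  }, numeric(1))
  sum(unclass(policy) * years)
}

#' Number of plots handled per stage
#'
#' `entries x n_locations x reps_per_location` for each stage that defines an
#' evaluation block. Check plots are excluded: program accounting here tracks
#' entries only.
#'
#' @param s a valid [breeding_scheme()].
#' @return Named numeric vector of plot counts.
#' @export
#' @examples
#' plots_per_stage(baseline_cassava_scheme())
plots_per_stage <- function(s) {
  assert_valid_scheme(s)
  out <- numeric(0)
  for (st in s$stages) {
    if (is.null(st$evaluation)) next
    out[st$name] <- st$selection$n_entries_in * st$evaluation$n_locations *
      st$evaluation$reps_per_location
  }
  out
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

#' Export a breeding scheme as a DOT flowchart
#'
#' One node per stage (labeled with name, year and entry count), solid edges
#' in stage order, and dashed back-edges from each recycling-source stage to
#' the crossing stage.
#'
#' @param s a valid [breeding_scheme()].
#' @return A single string of DOT (graphviz) source.
#' @export
#' @examples
#' cat(to_flowchart(baseline_cassava_scheme()))
to_flowchart <- function(s) {
  stopifnot(inherits(s, "breeding_scheme"), length(s$stages) > 0)
  nm <- stage_names(s)
  lines <- c("digraph breeding_scheme {", "  rankdir=TB;",
             "  node [shape=box];")
  for (st in s$stages) {
    yr <- if (st$year[1] == st$year[2]) sprintf("year %d", st$year[1])
          else sprintf("years %d-%d", st$year[1], st$year[2])
    label <- sprintf("%s\\n%s\\n%d entries", st$label, yr,
                     as.integer(stage_entries(st)))
    lines <- c(lines, sprintf("  %s [label=%s];", dot_quote(st$name),
                              dot_quote(label)))
  }
  if (length(nm) > 1) {
    for (k in 2:length(nm)) {
      lines <- c(lines, sprintf("  %s -> %s;", dot_quote(nm[k - 1]),
                                dot_quote(nm[k])))
    }
  }
  head_name <- nm[1]
  for (rs in recycling_stages(s)) {
    lines <- c(lines, sprintf("  %s -> %s [style=dashed];", dot_quote(rs),
                              dot_quote(head_name)))
  }
  paste(c(lines, "}"), collapse = "\n")
}
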