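# Scheme serialization. JSON is the canonical format: a versioned, fixed
# key-order document so that save(load(f)) is byte-identical for canonical
# files. CSV is accepted as the flat stage x decision table (stages in rows,
# decisions in columns) with a fixed header vocabulary; extra columns are
# preserved in the stage's free-form `other` map.

scheme_format_version <- 1L

canonical_stage <- function(st) {
  out <- list(name = st$name, label = st$label,
              year = I(as.integer(st$year)), role = st$role)
  if (!is.null(st$crossing)) {
    cr <- st$crossing
    out$crossing <- list(
      n_parents = as.integer(cr$n_parents),
      n_crosses = as.integer(cr$n_crosses),
      n_progeny_per_cross = as.integer(cr$n_progeny_per_cross),
      coupling_method = cr$coupling_method %||% "random mating",
      allow_reciprocals = isTRUE(cr$allow_reciprocals))
  }
  if (!is.null(st$evaluation)) {
    ev <- st$evaluation
    out$evaluation <- list(
      n_locations = as.integer(ev$n_locations),
      reps_per_location = as.integer(ev$reps_per_location),
      design_label = ev$design_label %||% "",
      plot_width = as.numeric(ev$plot_width %||% NA),
      plot_length = as.numeric(ev$plot_length %||% NA),
      plot_units = ev$plot_units %||% "m",
      n_checks = as.integer(ev$n_checks %||% 0L),
      other = if (length(ev$other)) ev$other[order(names(ev$other))]
              else stats::setNames(list(), character()))
  }
  if (!is.null(st$selection)) {
    se <- st$selection
    out$selection <- list(
      n_entries_in = as.integer(se$n_entries_in),
      n_selected_out = as.integer(se$n_selected_out),
      selection_method = se$selection_method %||% "",
      surrogate_of_merit = se$surrogate_of_merit %||% "",
      recycling_source = isTRUE(se$recycling_source))
  }
  out
}

canonical_segment <- function(seg) {
  ord <- function(x) if (length(x)) x[order(names(x))] else stats::setNames(list(), character())
  list(id = seg$id,
       client_features = ord(seg$client_features),
       environment_features = ord(seg$environment_features),
       product_features = ord(seg$product_features))
}

canonical_profile <- function(pp) {
  list(segment_id = pp$segment_id,
       traits = lapply(pp$traits, function(tr) {
         list(name = tr$name, category = tr$category, direction = tr$direction,
              bounds = I(as.numeric(tr$bounds)), unit = tr$unit %||% "")
       }))
}

#' Save a breeding scheme
#'
#' JSON output is canonical (versioned, fixed key order) so that loading and
#' re-saving a canonical file reproduces it byte for byte. CSV output writes
#' the stage table only (segments and profiles are JSON-only).
#'
#' @param s a validated [breeding_scheme()].
#' @param path output file path.
#' @param format `"json"` or `"csv"`; guessed from the file extension by
#'   default.
#' @return `path`, invisibly.
#' @export
save_scheme <- function(s, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "csv") return(save_scheme_csv(s, path))
  doc <- list(format_version = scheme_format_version,
              id = s$id, pipeline_id = s$pipeline_id,
              segment_ids = I(as.character(s$segment_ids)),
              market_segments = lapply(s$market_segments, canonical_segment),
              product_profiles = lapply(s$product_profiles, canonical_profile),
              stages = lapply(s$stages, canonical_stage))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

csv_columns <- c("name", "label", "year_start", "year_end", "role",
                 "n_entries_in", "n_selected_out", "selection_method",
                 "surrogate_of_merit", "recycling_source",
                 "n_locations", "reps_per_location", "design_label",
                 "plot_width", "plot_length", "plot_units", "n_checks",
                 "n_parents", "n_crosses", "n_progeny_per_cross",
                 "coupling_method", "allow_reciprocals")

save_scheme_csv <- function(s, path) {
  rows <- lapply(s$stages, function(st) {
    base <- list(name = st$name, label = st$label, year_start = st$year[1],
                 year_end = st$year[2], role = st$role)
    se <- st$selection; ev <- st$evaluation; cr <- st$crossing
    base$n_entries_in <- se$n_entries_in %||% NA
    base$n_selected_out <- se$n_selected_out %||% NA
    base$selection_method <- se$selection_method %||% NA
    base$surrogate_of_merit <- se$surrogate_of_merit %||% NA
    base$recycling_source <- se$recycling_source %||% NA
    base$n_locations <- ev$n_locations %||% NA
    base$reps_per_location <- ev$reps_per_location %||% NA
    base$design_label <- ev$design_label %||% NA
    base$plot_width <- ev$plot_width %||% NA
    base$plot_length <- ev$plot_length %||% NA
    base$plot_units <- ev$plot_units %||% NA
    base$n_checks <- ev$n_checks %||% NA
    base$n_parents <- cr$n_parents %||% NA
    base$n_crosses <- cr$n_crosses %||% NA
    base$n_progeny_per_cross <- cr$n_progeny_per_cross %||% NA
    base$coupling_method <- cr$coupling_method %||% NA
    base$allow_reciprocals <- cr$allow_reciprocals %||% NA
    extras <- ev$other %||% list()
    c(base, extras)
  })
  extra_cols <- unique(unlist(lapply(rows, function(r) setdiff(names(r), csv_columns))))
  cols <- c(csv_columns, extra_cols)
  df <- do.call(rbind, lapply(rows, function(r) {
    vals <- lapply(cols, function(cn) r[[cn]] %||% NA)
    as.data.frame(setNames(vals, cols), stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Load a breeding scheme from JSON or CSV
#'
#' The loaded scheme is validated; any invariant violation raises an error
#' listing each breach (use [validate_scheme()] directly to inspect
#' violations as data).
#'
#' @param path file path.
#' @param format `"json"` or `"csv"`; guessed from the extension by default.
#' @param id scheme id to use for CSV input (CSV carries no scheme metadata);
#'   defaults to the file name without extension.
#' @return A validated [breeding_scheme()].
#' @export
#' @examples
#' s <- load_scheme(system.file("extdata", "cassava_baseline_scheme.json",
#'                              package = "breedsim"))
#' selected_percentages(s)
load_scheme <- function(path, format = c("auto", "json", "csv"), id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_breedsim(sprintf("scheme file not found: %s", path),
                   "breedsim_format_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  s <- if (format == "csv") load_scheme_csv(path, id = id) else load_scheme_json(path)
  assert_valid_scheme(s)
  s
}

load_scheme_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort_breedsim(sprintf("cannot parse '%s' as JSON: %s",
                                           path, conditionMessage(e)),
                                   "breedsim_format_error")
                  })
  stages <- lapply(doc$stages, function(st) {
    ev <- st$evaluation
    if (!is.null(ev)) ev$other <- lapply(ev$other %||% list(), identity)
    stage_definition(name = st$name, year = unlist(st$year), role = st$role,
                     evaluation = ev, selection = st$selection,
                     crossing = st$crossing, label = st$label)
  })
  segs <- lapply(doc$market_segments %||% list(), function(seg) {
    market_segment(seg$id, seg$client_features %||% list(),
                   seg$environment_features %||% list(),
                   seg$product_features %||% list())
  })
  profs <- lapply(doc$product_profiles %||% list(), function(pp) {
    product_profile(pp$segment_id, lapply(pp$traits %||% list(), function(tr) {
      trait_requirement(tr$name, tr$category, tr$direction,
                        unlist(tr$bounds), tr$unit %||% "")
    }))
  })
  breeding_scheme(id = doc$id %||% "", pipeline_id = doc$pipeline_id %||% "",
                  stages = stages,
                  segment_ids = unlist(doc$segment_ids) %||% character(),
                  market_segments = segs, product_profiles = profs)
}

load_scheme_csv <- function(path, id = NULL) {
  df <- tryCatch(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
                 error = function(e) {
                   abort_breedsim(sprintf("cannot parse '%s' as CSV: %s",
                                          path, conditionMessage(e)),
                                  "breedsim_format_error")
                 })
  need <- c("name", "year_start", "year_end", "role")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    abort_breedsim(sprintf("CSV scheme table lacks required column(s): %s",
                           paste(missing, collapse = ", ")),
                   "breedsim_format_error")
  }
  extra_cols <- setdiff(names(df), csv_columns)
  get <- function(row, col) {
    if (!(col %in% names(df))) return(NULL)
    val <- df[[col]][row]
    if (is.na(val) || (is.character(val) && !nzchar(val))) NULL else val
  }
  stages <- lapply(seq_len(nrow(df)), function(i) {
    role <- df$role[i]
    crossing <- if (identical(role, "crossing")) {
      list(n_parents = get(i, "n_parents"), n_crosses = get(i, "n_crosses"),
           n_progeny_per_cross = get(i, "n_progeny_per_cross"),
           coupling_method = get(i, "coupling_method") %||% "random mating",
           allow_reciprocals = isTRUE(as.logical(get(i, "allow_reciprocals"))))
    }
    selection <- if (!identical(role, "crossing")) {
      list(n_entries_in = get(i, "n_entries_in"),
           n_selected_out = get(i, "n_selected_out"),
           selection_method = get(i, "selection_method") %||% "",
           surrogate_of_merit = get(i, "surrogate_of_merit") %||% "",
           recycling_source = isTRUE(as.logical(get(i, "recycling_source"))))
    }
    other <- Filter(Negate(is.null), setNames(lapply(extra_cols, get, row = i),
                                              extra_cols))
    evaluation <- if (!identical(role, "crossing")) {
      list(n_locations = get(i, "n_locations"),
           reps_per_location = get(i, "reps_per_location"),
           design_label = get(i, "design_label") %||% "",
           plot_width = get(i, "plot_width"),
           plot_length = get(i, "plot_length"),
           plot_units = get(i, "plot_units") %||% "m",
           n_checks = get(i, "n_checks") %||% 0L,
           other = other)
    }
    stage_definition(name = df$name[i],
                     year = c(df$year_start[i], df$year_end[i]), role = role,
                     evaluation = evaluation, selection = selection,
                     crossing = crossing, label = get(i, "label"))
  })
  breeding_scheme(id = id %||% sub("\\.[^.]*$", "", basename(path)),
                  stages = stages)
}

#' The bundled baseline cassava breeding scheme
#'
#' Loads the packaged seven-stage East-African cassava pipeline: crossing
#' block (4 parents, 12 crosses, 136 progeny per cross), seedling nursery,
#' clonal evaluation (CE, 1,632 entries), preliminary yield trial (PYT, 120),
#' advanced yield trial (AYT, 64), and two years of uniform yield trial
#' (UYT, 24), with PYT and AYT flagged as parent-recycling sources.
#'
#' @return A validated [breeding_scheme()].
#' @export
baseline_cassava_scheme <- function() {
  load_scheme(system.file("extdata", "cassava_baseline_scheme.json",
                          package = "breedsim", mustWork = TRUE))
}
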