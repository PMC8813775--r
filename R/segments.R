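# Market segments and product profiles: the "design" layer a breeding scheme
# serves. Feature keys are drawn from three controlled vocabularies (client,
# environment, product); unknown keys are validation errors rather than being
# silently carried along, so segment records stay comparable across pipelines.

#' Controlled feature vocabularies for market segments
#'
#' @return A named list with character vectors `client`, `environment` and
#'   `product`: the admissible feature keys for each feature group of a
#'   [market_segment()].
#' @export
segment_feature_vocabulary <- function() {
  list(
    client = c("geographical_region", "income", "education", "farm_size"),
    environment = c("temperature", "humidity", "vegetation",
                    "water_availability", "soil_fertility", "altitude",
                    "soil_ph", "production_system",
                    "prevailing_biotic_stresses"),
    product = c("mode_of_reproduction", "maturity", "color", "shape",
                "biofortification", "end_use")
  )
}

#' Define a market segment
#'
#' A market segment is the combination of the client served, the target
#' population of environments, and the characteristics of the final product.
#'
#' @param id unique segment identifier (string).
#' @param client_features named list of client features (see
#'   [segment_feature_vocabulary()]).
#' @param environment_features named list of environment features.
#' @param product_features named list of product features.
#' @return An object of class `market_segment`.
#' @export
#' @examples
#' market_segment("ea-fresh",
#'   client_features = list(geographical_region = "East Africa"),
#'   environment_features = list(water_availability = "high rainfall"),
#'   product_features = list(end_use = "fresh consumption"))
market_segment <- function(id, client_features = list(),
                           environment_features = list(),
                           product_features = list()) {
  stopifnot(is.character(id), length(id) == 1, nzchar(id))
  structure(list(id = id,
                 client_features = as.list(client_features),
                 environment_features = as.list(environment_features),
                 product_features = as.list(product_features)),
            class = "market_segment")
}

trait_categories <- c("quality", "survival", "output", "agronomic")
trait_directions <- c("at_least", "at_most", "target_range")

#' Define a product-profile trait requirement
#'
#' @param name trait name.
#' @param category one of `"quality"`, `"survival"`, `"output"`,
#'   `"agronomic"`.
#' @param direction one of `"at_least"`, `"at_most"`, `"target_range"`.
#' @param bounds numeric vector: one finite bound for `at_least`/`at_most`,
#'   two (low, high) for `target_range`.
#' @param unit unit string for the bounds.
#' @return An object of class `trait_requirement`.
#' @export
trait_requirement <- function(name, category, direction, bounds, unit = "") {
  stopifnot(is.character(name), length(name) == 1)
  structure(list(name = name, category = category, direction = direction,
                 bounds = as.numeric(bounds), unit = unit),
            class = "trait_requirement")
}

#' Define a product profile for a market segment
#'
#' A product profile lists, trait by trait, the thresholds a released variety
#' must meet for one market segment.
#'
#' @param segment_id id of the [market_segment()] the profile serves.
#' @param traits list of [trait_requirement()] objects.
#' @return An object of class `product_profile`.
#' @export
product_profile <- function(segment_id, traits = list()) {
  stopifnot(is.character(segment_id), length(segment_id) == 1)
  structure(list(segment_id = segment_id, traits = traits),
            class = "product_profile")
}

validate_segment <- function(seg, where = seg$id %||% "<segment>") {
  v <- empty_violations()
  vocab <- segment_feature_vocabulary()
  groups <- c(client_features = "client", environment_features = "environment",
              product_features = "product")
  for (field in names(groups)) {
    keys <- names(seg[[field]]) %||% character()
    bad <- setdiff(keys, vocab[[groups[[field]]]])
    for (k in bad) {
      v <- add_violation(v, where, field, "unknown_feature_key",
                         sprintf("feature key '%s' is not in the %s vocabulary",
                                 k, groups[[field]]))
    }
  }
  v
}

validate_profile <- function(pp, segment_ids, where) {
  v <- empty_violations()
  if (!(pp$segment_id %in% segment_ids)) {
    v <- add_violation(v, where, "segment_id", "unresolved_reference",
                       sprintf("segment_id '%s' does not match any market segment",
                               pp$segment_id))
  }
  for (tr in pp$traits) {
    if (!(tr$category %in% trait_categories)) {
      v <- add_violation(v, where, tr$name, "invalid_category",
                         sprintf("category '%s' not one of: %s", tr$category,
                                 paste(trait_categories, collapse = ", ")))
    }
    if (!(tr$direction %in% trait_directions)) {
      v <- add_violation(v, where, tr$name, "invalid_direction",
                         sprintf("direction '%s' not one of: %s", tr$direction,
                                 paste(trait_directions, collapse = ", ")))
    }
    nb <- sum(is.finite(tr$bounds))
    need <- if (identical(tr$direction, "target_range")) 2L else 1L
    if (nb < need) {
      v <- add_violation(v, where, tr$name, "missing_bound",
                         sprintf("trait '%s' needs %d finite bound(s), has %d",
                                 tr$name, need, nb))
    }
  }
  v
}
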