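`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Hashes the master seed together with an arbitrary sequence of labels
#' (replicate number, module name, treatment id, ...) into an integer seed
#' below 2^31, so that distinct units of a simulation experiment get distinct,
#' reproducible random streams from one master seed.
#'
#' @param master integer master seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "founders", 3)
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1)
  m <- 2147483647
  h <- abs(as.double(master)) %% m
  for (part in c(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(part)))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h %% (m - 1)) + 1L
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == round(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1 && !is.na(x)
}

abort_breedsim <- function(message, class) {
  stop(structure(class = c(class, "breedsim_error", "error", "condition"),
                 list(message = message, call = NULL)))
}
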