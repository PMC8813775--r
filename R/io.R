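# Plain-text interchange: trait architecture and covariate matrices as CSV,
# founder genotypes as phased VCF, genetic map as 3-column text.

#' Export / import a trait architecture as CSV
#'
#' Columns: `chrom`, `site_id`, `b` (intercept), `m` (slope). Import restores
#' effects against a map by matching site ids.
#'
#' @param arch a `trait_architecture`.
#' @param map the `genetic_map` the architecture indexes into.
#' @param path CSV file path.
#' @return `path` (write) or a `trait_architecture` (read), whose variance
#'   targets are taken from `vc`.
#' @export
write_architecture_csv <- function(arch, map, path) {
  df <- data.frame(chrom = arch$chrom, site_id = map$table$id[arch$qtn],
                   b = arch$b, m = arch$m)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_architecture_csv
#' @param vc a [variance_components()] recorded on the imported object.
#' @export
read_architecture_csv <- function(path, map, vc = variance_components()) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  idx <- match(df$site_id, map$table$id)
  if (anyNA(idx)) {
    abort_breedsim("architecture CSV contains site ids absent from the map",
                   "breedsim_format_error")
  }
  structure(list(qtn = idx, chrom = df$chrom, b = df$b, m = df$m, vc = vc,
                 n_base = NA_integer_),
            class = "trait_architecture")
}

#' Export an environmental-covariate matrix as CSV
#'
#' Years in rows, locations in columns.
#'
#' @param env an `env_covariates`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(env, path) {
  w <- env$w
  df <- data.frame(year = seq_len(nrow(w)), w)
  names(df) <- c("year", sprintf("loc%d", seq_len(ncol(w))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export founder genotypes as a phased VCF
#'
#' Biallelic sites; contig = chromosome, POS = the site's derived physical
#' position, GT phased (`0|1` style) from the two stored haplotypes.
#'
#' @param fs a `founder_set` (or a list with `founders` and `map`).
#' @param path output `.vcf` path (uncompressed text).
#' @return `path`, invisibly.
#' @export
write_founders_vcf <- function(fs, path) {
  pop <- fs$founders
  map <- fs$map
  n <- n_ind(pop)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=breedsim",
               sprintf("##contig=<ID=%d>", seq_along(map$chr_len)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sprintf("ind%d", pop$id)),
                   collapse = "\t"), con)
  odd <- seq.int(1L, 2L * n, by = 2L)
  for (s in seq_len(map$n_sites)) {
    gt <- paste(pop$H[s, odd], pop$H[s, odd + 1L], sep = "|")
    writeLines(paste(c(map$table$chrom[s], map$table$pos_bp[s],
                       map$table$id[s], "A", "T", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Export a genetic map as 3-column text
#'
#' Columns: chromosome, site id, position in centiMorgans.
#'
#' @param map a `genetic_map`.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  df <- data.frame(chrom = map$table$chrom, id = map$table$id,
                   cM = 100 * map$table$pos_m)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a tidy results table as CSV
#'
#' @param results tibble from [run_grid()] / [run_replicate()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
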