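#' Read and write pipeline tables
#'
#' Readers and writers for the delimited-text formats the pipeline
#' exchanges: comma-separated, header row mandatory, UTF-8, `"."` for
#' missing values.  Locus tables are written as tab-separated text in the
#' column order of [scan_repeats()] (1-based inclusive coordinates, the
#' dialect of the tandem-repeat tool ecosystem).
#'
#' @param path File path.
#' @return A tibble (readers) or `path` invisibly (writers).
#' @name msat_io
NULL

msat_na <- c("", ".", "NA")

#' @rdname msat_io
#' @export
read_genotypes <- function(path) {
  g <- readr::read_csv(path, na = msat_na, col_types = readr::cols(
    marker_id = readr::col_character(),
    line_id = readr::col_character(),
    allele_bp = readr::col_integer()
  ))
  if (!all(c("marker_id", "line_id", "allele_bp") %in% names(g))) {
    abort("Genotype file needs columns marker_id, line_id, allele_bp.")
  }
  g
}

#' @rdname msat_io
#' @param genotypes Genotype tibble to write.
#' @export
write_genotypes <- function(genotypes, path) {
  readr::write_csv(genotypes, path, na = ".")
  invisible(path)
}

#' @rdname msat_io
#' @export
read_markers <- function(path) {
  m <- readr::read_csv(path, na = msat_na, show_col_types = FALSE)
  need <- c("marker_id", "unit", "progenitor_bp")
  if (!all(need %in% names(m))) {
    abort("Marker file needs at least columns marker_id, unit, progenitor_bp.")
  }
  m
}

#' @rdname msat_io
#' @param markers Marker tibble to write.
#' @export
write_markers <- function(markers, path) {
  readr::write_csv(markers, path, na = ".")
  invisible(path)
}

#' @rdname msat_io
#' @param loci Locus tibble from [scan_repeats()].
#' @export
write_loci <- function(loci, path) {
  readr::write_tsv(loci, path, na = ".")
  invisible(path)
}

#' @rdname msat_io
#' @export
read_loci <- function(path) {
  readr::read_tsv(path, na = msat_na, col_types = readr::cols(
    seq_id = readr::col_character(),
    start = readr::col_integer(),
    end = readr::col_integer(),
    unit_length = readr::col_integer(),
    copy_number = readr::col_double(),
    percent_match = readr::col_integer(),
    percent_indels = readr::col_integer(),
    score = readr::col_integer(),
    unit = readr::col_character(),
    canonical_class = readr::col_character(),
    is_perfect = readr::col_logical()
  ))
}

#' @rdname msat_io
#' @param calls Calls tibble from [call_mutations()].
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(calls, path, na = ".")
  invisible(path)
}

#' @rdname msat_io
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, na = msat_na, col_types = readr::cols(
    marker_id = readr::col_character(),
    line_id = readr::col_character(),
    delta_units = readr::col_integer(),
    kind = readr::col_character(),
    step = readr::col_character()
  ))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
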