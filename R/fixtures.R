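#' Packaged MA microsatellite marker panel
#'
#' Loads the marker panel shipped with the package: 41 microsatellite
#' markers (19 perfect, 22 imperfect; units of 2-6 bp and 3-64 repeat
#' copies) assayed in 82 selfing mutation-accumulation lines over 142
#' generations, together with the observed mutation events at each marker.
#' The per-marker `magnitudes` column of the source sheet (e.g.
#' `"+1(2);-9(1)"`, meaning a one-unit insertion in two lines and a
#' nine-unit deletion in one) is expanded into one call per affected line.
#'
#' Fragment sizes are not part of the panel; the progenitor allele is
#' represented by the array length `unit_length * repeat_count` in bp,
#' which is sufficient because mutation calls depend only on size
#' differences.  Line identities of mutated lines are not recorded in the
#' source, so calls are assigned to lines `L001`, `L002`, ... within each
#' marker; no line carries two events at the same marker in this panel.
#'
#' @return A list with `markers` (tibble: `marker_id`, `chromosome`,
#'   `unit`, `repeat_count`, `percent_match`, `progenitor_bp`) and `calls`
#'   (tibble as returned by [call_mutations()]), plus `n_lines` (82) and
#'   `t` (142) as attributes of the list.
#' @examples
#' fx <- fixture_ma_markers()
#' nrow(fx$markers)
#' nrow(fx$calls)
#' @export
fixture_ma_markers <- function() {
  path <- system.file("extdata", "ma_marker_panel.csv", package = "msatma",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chromosome = readr::col_character(),
    unit = readr::col_character(),
    repeat_count = readr::col_double(),
    percent_match = readr::col_integer(),
    magnitudes = readr::col_character()
  ))
  markers <- raw |>
    dplyr::mutate(
      progenitor_bp = as.integer(nchar(.data$unit) * .data$repeat_count)
    ) |>
    dplyr::select("marker_id", "chromosome", "unit", "repeat_count",
                  "percent_match", "progenitor_bp")
  calls <- raw |>
    dplyr::filter(!is.na(.data$magnitudes), nzchar(.data$magnitudes)) |>
    dplyr::mutate(parsed = purrr::map(.data$magnitudes, parse_magnitudes)) |>
    dplyr::select("marker_id", "parsed") |>
    tidyr::unnest("parsed") |>
    dplyr::group_by(.data$marker_id) |>
    dplyr::mutate(line_id = sprintf("L%03d", dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      marker_id = .data$marker_id,
      line_id = .data$line_id,
      delta_units = .data$delta_units,
      kind = ifelse(.data$delta_units > 0, "insertion", "deletion"),
      step = ifelse(abs(.data$delta_units) == 1L, "single", "multi")
    )
  out <- list(markers = markers, calls = calls)
  attr(out, "n_lines") <- 82L
  attr(out, "t") <- 142L
  out
}

# "+1(2);-9(1)" -> tibble(delta_units = c(1, 1, -9))
parse_magnitudes <- function(x) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*([+-]?\\d+)\\((\\d+)\\)\\s*$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    abort(sprintf("Cannot parse magnitude entry '%s'.", parts[bad][1]))
  }
  delta <- vapply(m, function(g) as.integer(g[2]), integer(1))
  n <- vapply(m, function(g) as.integer(g[3]), integer(1))
  if (any(delta == 0L)) abort("Magnitude entries must be nonzero.")
  tibble::tibble(delta_units = rep(delta, n))
}

#' Reconstruct a full genotype table from the packaged marker panel
#'
#' Expands the packaged panel into a long-format genotype table over
#' `n_lines` lines: every line carries the progenitor allele except the
#' lines recorded as mutated, whose allele is shifted by the recorded
#' number of repeat units.  Per-marker assessed-line counts in the original
#' assay are not published, so all lines are treated as assessed at every
#' marker; rates computed from this table therefore use `l = n_lines`
#' throughout.
#'
#' @param n_lines Number of lines (default 82).
#' @return A genotype tibble (`marker_id`, `line_id`, `allele_bp`) suitable
#'   for [call_mutations()] and [estimate_rates()].
#' @examples
#' geno <- fixture_genotypes()
#' nrow(geno)
#' @export
fixture_genotypes <- function(n_lines = 82) {
  fx <- fixture_ma_markers()
  line_ids <- sprintf("L%03d", seq_len(n_lines))
  grid <- tidyr::expand_grid(marker_id = fx$markers$marker_id,
                             line_id = line_ids)
  grid |>
    dplyr::left_join(
      dplyr::select(fx$markers, "marker_id", "unit", "progenitor_bp"),
      by = "marker_id"
    ) |>
    dplyr::left_join(
      dplyr::select(fx$calls, "marker_id", "line_id", "delta_units"),
      by = c("marker_id", "line_id")
    ) |>
    dplyr::transmute(
      marker_id = .data$marker_id,
      line_id = .data$line_id,
      allele_bp = as.integer(.data$progenitor_bp +
        nchar(.data$unit) * dplyr::coalesce(.data$delta_units, 0L))
    )
}

#' Packaged perfect-locus counts from a strict genome screen
#'
#' Per-motif counts of perfect dinucleotide and trinucleotide loci observed
#' in a strict tandem-repeat screen of an AT-rich nematode genome, as
#' shipped with the package.  Used to illustrate composition statistics
#' ([tally_at_richness()]) and missing-class detection
#' ([missing_classes()]) without re-running a genome-scale scan.
#'
#' @return A tibble with columns `unit` and `n_loci`.
#' @examples
#' counts <- fixture_strict_perfect_counts()
#' missing_classes(dplyr::filter(counts, nchar(unit) == 2), 2)
#' @export
fixture_strict_perfect_counts <- function() {
  tibble::tibble(
    unit = c("AC", "AG", "AT", "CG",
             "AAC", "AAG", "AAT", "ACC", "ACG", "ACT", "AGC", "AGG", "ATC",
             "CCG"),
    n_loci = c(21, 265, 97, 0,
               32, 3, 57, 2, 2, 3, 3, 3, 28, 0)
  )
}
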