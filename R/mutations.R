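#' Convert an allele-size difference to signed repeat units
#'
#' Microsatellite genotypes are read as PCR fragment sizes in bp; a mutation
#' at a locus with unit length `u` changes the fragment by a multiple of
#' `u`.  `delta_units()` converts the difference between a line's allele and
#' the progenitor allele into a signed number of repeat units (positive =
#' insertion, negative = deletion, 0 = no mutation).
#'
#' A size difference that is not a whole multiple of the unit length cannot
#' be a clean repeat-number change ("off-ladder" allele, typically a
#' genotyping artifact that would be re-checked by independent
#' amplification).  By default this raises an error; batch callers suppress
#' the call instead and report it.
#'
#' @param allele_bp,progenitor_bp Positive integer allele sizes in bp.
#' @param unit_length Repeat unit length in bp (1-6).
#' @param off_ladder `"error"` (default) or `"na"` to return `NA` for
#'   non-divisible differences.
#' @return Integer vector of signed repeat-unit changes.
#' @examples
#' delta_units(204, 200, 4)
#' delta_units(164, 200, 4)
#' @export
delta_units <- function(allele_bp, progenitor_bp, unit_length,
                        off_ladder = c("error", "na")) {
  off_ladder <- match.arg(off_ladder)
  if (any(allele_bp <= 0 | progenitor_bp <= 0, na.rm = TRUE)) {
    abort("Allele sizes must be positive.")
  }
  if (any(unit_length < 1 | unit_length > 6, na.rm = TRUE)) {
    abort("`unit_length` must be within 1..6.")
  }
  diff <- allele_bp - progenitor_bp
  bad <- !is.na(diff) & diff %% unit_length != 0
  if (any(bad)) {
    if (off_ladder == "error") {
      abort(sprintf(
        "Off-ladder allele: size difference %d bp is not a multiple of the %d bp unit.",
        diff[bad][1], unit_length[bad][1]
      ))
    }
    diff[bad] <- NA_integer_
  }
  as.integer(diff %/% unit_length)
}

#' Call mutations from progenitor-versus-line allele sizes
#'
#' Compares every genotyped (marker, line) allele against the marker's
#' progenitor allele and emits one mutation call per nonzero difference,
#' expressed in signed repeat units.  Because MA lines descend from a single
#' homozygous selfing progenitor through single-offspring bottlenecks, each
#' line carries one allele per marker, and any size difference from the
#' progenitor is a fixed accumulated mutation.
#'
#' Genotypes missing from `genotypes` (or with `NA` allele sizes) produce no
#' call; they reduce the marker's assessed-line count used downstream by the
#' rate estimator.  Off-ladder alleles (size difference not a multiple of
#' the unit length) are suppressed with a warning and returned in the
#' `"off_ladder"` attribute for inspection.
#'
#' @param genotypes Long-format data frame with columns `marker_id`,
#'   `line_id`, `allele_bp`.
#' @param markers Marker sheet with columns `marker_id`, `unit`,
#'   `progenitor_bp` (and optionally `chromosome`, `repeat_count`,
#'   `percent_match`).
#'
#' @return A tibble of calls: `marker_id`, `line_id`, `delta_units`, `kind`
#'   (`"insertion"`/`"deletion"`), `step` (`"single"`/`"multi"`).
#'
#' @examples
#' markers <- data.frame(marker_id = "M1", unit = "ACAT", progenitor_bp = 144)
#' geno <- data.frame(marker_id = "M1", line_id = c("L1", "L2"),
#'                    allele_bp = c(148, 144))
#' call_mutations(geno, markers)
#' @export
call_mutations <- function(genotypes, markers) {
  genotypes <- tibble::as_tibble(genotypes)
  markers <- tibble::as_tibble(markers)
  need_g <- c("marker_id", "line_id", "allele_bp")
  need_m <- c("marker_id", "unit", "progenitor_bp")
  if (!all(need_g %in% names(genotypes))) {
    abort("`genotypes` needs columns marker_id, line_id, allele_bp.")
  }
  if (!all(need_m %in% names(markers))) {
    abort("`markers` needs columns marker_id, unit, progenitor_bp.")
  }
  unknown <- setdiff(unique(genotypes$marker_id), markers$marker_id)
  if (length(unknown) > 0) {
    abort(sprintf("Genotypes reference markers without a definition: %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  joined <- genotypes |>
    dplyr::filter(!is.na(.data$allele_bp)) |>
    dplyr::inner_join(
      dplyr::transmute(markers, marker_id = .data$marker_id,
                       unit_length = nchar(.data$unit),
                       progenitor_bp = .data$progenitor_bp),
      by = "marker_id"
    ) |>
    dplyr::mutate(delta_units = delta_units(
      .data$allele_bp, .data$progenitor_bp, .data$unit_length,
      off_ladder = "na"
    ))
  off <- joined |>
    dplyr::filter(is.na(.data$delta_units)) |>
    dplyr::select("marker_id", "line_id", "allele_bp", "progenitor_bp")
  if (nrow(off) > 0) {
    warn(sprintf(
      "%d off-ladder allele(s) suppressed (size difference not a multiple of the unit); see attr(, \"off_ladder\").",
      nrow(off)
    ))
  }
  calls <- joined |>
    dplyr::filter(!is.na(.data$delta_units), .data$delta_units != 0L) |>
    dplyr::transmute(
      marker_id = .data$marker_id,
      line_id = .data$line_id,
      delta_units = .data$delta_units,
      kind = ifelse(.data$delta_units > 0, "insertion", "deletion"),
      step = ifelse(abs(.data$delta_units) == 1L, "single", "multi")
    )
  attr(calls, "off_ladder") <- off
  calls
}

#' Summarize a set of mutation calls into a mutation spectrum
#'
#' Tallies mutation calls into the statistics that characterise a
#' microsatellite mutation spectrum: total events and mutated loci,
#' single-step versus multistep events (a single-step event changes the
#' repeat number by exactly one unit, the change predicted to dominate under
#' the stepwise mutation model), insertion versus deletion events, and the
#' per-locus net change with its direction (growth, decrease, or none).
#'
#' @param calls A calls tibble from [call_mutations()] (columns `marker_id`,
#'   `line_id`, `delta_units`).
#' @param markers Optional marker sheet; markers absent from `calls` are
#'   then reported with zero events.
#'
#' @return An object of class `"msat_spectrum"`: tallies plus a `per_locus`
#'   tibble (`marker_id`, `n_events`, `n_lines_mutated`, `net_units`,
#'   `trend`).  `glance()` returns the tallies as a one-row tibble;
#'   `tidy()` the per-locus tibble.
#' @examples
#' calls <- data.frame(marker_id = "M1", line_id = c("L1", "L2"),
#'                     delta_units = c(1, -9))
#' mutation_spectrum(calls)
#' @export
mutation_spectrum <- function(calls, markers = NULL) {
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) > 0 &&
      !all(c("marker_id", "line_id", "delta_units") %in% names(calls))) {
    abort("`calls` needs columns marker_id, line_id, delta_units.")
  }
  if (!is.null(markers)) {
    markers <- tibble::as_tibble(markers)
    unknown <- setdiff(unique(calls$marker_id), markers$marker_id)
    if (length(unknown) > 0) {
      abort(sprintf("Calls reference unknown markers: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
  }
  if (nrow(calls) == 0L) {
    per_locus <- tibble::tibble(marker_id = character(), n_events = integer(),
                                n_lines_mutated = integer(),
                                net_units = integer(), trend = character())
  } else {
    per_locus <- calls |>
      dplyr::group_by(marker_id = .data$marker_id) |>
      dplyr::summarise(
        n_events = dplyr::n(),
        n_lines_mutated = dplyr::n_distinct(.data$line_id),
        net_units = sum(.data$delta_units),
        .groups = "drop"
      ) |>
      dplyr::mutate(trend = dplyr::case_when(
        .data$net_units > 0 ~ "growth",
        .data$net_units < 0 ~ "decrease",
        TRUE ~ "none"
      ))
  }
  if (!is.null(markers)) {
    zero <- setdiff(markers$marker_id, per_locus$marker_id)
    if (length(zero) > 0) {
      per_locus <- dplyr::bind_rows(
        per_locus,
        tibble::tibble(marker_id = zero, n_events = 0L, n_lines_mutated = 0L,
                       net_units = 0L, trend = "none")
      )
    }
    per_locus <- per_locus[match(markers$marker_id, per_locus$marker_id), ]
  }
  d <- calls$delta_units
  step_sizes <- if (nrow(calls) > 0) {
    dplyr::count(calls, delta_units = .data$delta_units, name = "n_events")
  } else {
    tibble::tibble(delta_units = integer(), n_events = integer())
  }
  structure(list(
    total_events = length(d),
    n_loci_mutated = length(unique(calls$marker_id)),
    single_step_total = sum(abs(d) == 1),
    single_step_insertions = sum(d == 1),
    single_step_deletions = sum(d == -1),
    multi_step_total = sum(abs(d) > 1),
    insertion_events_total = sum(d > 0),
    deletion_events_total = sum(d < 0),
    net_units_total = sum(d),
    per_locus = per_locus,
    step_sizes = step_sizes
  ), class = "msat_spectrum")
}

#' @export
print.msat_spectrum <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<msat_spectrum> %d events at %d loci\n",
      "  single-step: %d (%d insertions, %d deletions); multistep: %d\n",
      "  insertions vs deletions (events): %d vs %d; net change %+d units\n"
    ),
    x$total_events, x$n_loci_mutated, x$single_step_total,
    x$single_step_insertions, x$single_step_deletions, x$multi_step_total,
    x$insertion_events_total, x$deletion_events_total, x$net_units_total
  ))
  invisible(x)
}

#' @method tidy msat_spectrum
#' @export
tidy.msat_spectrum <- function(x, ...) x$per_locus

#' @method glance msat_spectrum
#' @export
glance.msat_spectrum <- function(x, ...) {
  tibble::tibble(
    total_events = x$total_events,
    n_loci_mutated = x$n_loci_mutated,
    single_step_total = x$single_step_total,
    single_step_insertions = x$single_step_insertions,
    single_step_deletions = x$single_step_deletions,
    multi_step_total = x$multi_step_total,
    insertion_events_total = x$insertion_events_total,
    deletion_events_total = x$deletion_events_total,
    net_units_total = x$net_units_total
  )
}

#' Stratify mutation events by marker properties
#'
#' Partitions markers into strata and counts mutation events (and markers)
#' in each.  Three stratifiers are available: `"perfection"` (perfect loci,
#' percent match 100, versus imperfect), `"repeat_count"` (repeat count
#' above versus at-or-below a threshold — long versus short loci), and
#' `"perfect_long"` (perfect AND long versus everything else; the stratum
#' where stepwise slippage mutations concentrate).
#'
#' @param calls Calls tibble from [call_mutations()].
#' @param markers Marker sheet with `marker_id`, `percent_match`,
#'   `repeat_count`.
#' @param by One of `"perfection"`, `"repeat_count"`, `"perfect_long"`.
#' @param repeat_count_threshold Threshold for the long/short split
#'   (required for `"repeat_count"` and `"perfect_long"`).
#' @return A tibble with columns `stratum`, `n_markers`, `n_events`.
#' @examples
#' fx <- fixture_ma_markers()
#' stratify_events(fx$calls, fx$markers, by = "perfect_long",
#'                 repeat_count_threshold = 3)
#' @export
stratify_events <- function(calls, markers,
                            by = c("perfection", "repeat_count", "perfect_long"),
                            repeat_count_threshold = NULL) {
  by <- match.arg(by)
  markers <- tibble::as_tibble(markers)
  calls <- tibble::as_tibble(calls)
  if (by %in% c("repeat_count", "perfect_long") &&
      is.null(repeat_count_threshold)) {
    abort(sprintf("`repeat_count_threshold` is required for by = \"%s\".", by))
  }
  stratum <- switch(by,
    perfection = ifelse(markers$percent_match == 100, "perfect", "imperfect"),
    repeat_count = ifelse(markers$repeat_count > repeat_count_threshold,
                          "long", "short"),
    perfect_long = ifelse(markers$percent_match == 100 &
                            markers$repeat_count > repeat_count_threshold,
                          "perfect_long", "other")
  )
  mk <- tibble::tibble(marker_id = markers$marker_id, stratum = stratum)
  ev <- calls |>
    dplyr::count(.data$marker_id, name = "n_events") |>
    dplyr::right_join(mk, by = "marker_id") |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L))
  ev |>
    dplyr::group_by(stratum = .data$stratum) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     n_events = sum(.data$n_events), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$stratum))
}
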