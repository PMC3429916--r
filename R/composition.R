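#' Summarize the tandem-repeat composition of a genome
#'
#' Aggregates a table of scanned repeat loci into genome-level composition
#' statistics: per-class locus tallies (split by perfect/imperfect), the
#' locus frequency per megabase, the fraction of the genome covered by
#' repeats (overlapping loci are collapsed before summing so shared bases
#' are not double-counted), and the AT-rich share of loci per unit length.
#' A class is counted as AT-rich when its unit has at most one C/G base
#' (e.g. `[(A/T)_2, X_1]` trimers).
#'
#' @param loci A tibble of repeat loci as returned by [scan_repeats()].
#' @param genome_length_bp Total length of the scanned sequence in bp.
#'
#' @return An object of class `"msat_composition"`: a list with
#'   `class_counts` (tibble: `unit_length`, `canonical_class`, `n_loci`,
#'   `n_perfect`, `n_imperfect`), `at_rich_share` (tibble per unit length),
#'   `n_loci`, `loci_per_megabase`, `genome_fraction_percent` and
#'   `genome_length_bp`.  `tidy()` returns the per-class tibble; `glance()`
#'   the one-row genome summary.
#'
#' @examples
#' loci <- scan_repeats(c(chr = strrep("AG", 40)), scan_params("strict"))
#' summarize_composition(loci, 80)
#' @export
summarize_composition <- function(loci, genome_length_bp) {
  if (length(genome_length_bp) != 1L || is.na(genome_length_bp) ||
      genome_length_bp < 0) {
    abort("`genome_length_bp` must be a single non-negative number.")
  }
  if (nrow(loci) > 0 &&
      (any(loci$start < 1L) || any(loci$end > genome_length_bp))) {
    abort("Locus coordinates fall outside the stated genome length.")
  }
  class_counts <- loci |>
    dplyr::group_by(.data$unit_length, canonical_class = .data$canonical_class) |>
    dplyr::summarise(
      n_loci = dplyr::n(),
      n_perfect = sum(.data$is_perfect),
      n_imperfect = sum(!.data$is_perfect),
      .groups = "drop"
    )
  covered <- 0L
  if (nrow(loci) > 0) {
    by_seq <- split(IRanges::IRanges(loci$start, loci$end), loci$seq_id)
    covered <- sum(vapply(by_seq, function(r) sum(IRanges::width(IRanges::reduce(r))),
                          numeric(1)))
  }
  at_share <- tally_at_richness(
    dplyr::select(class_counts, unit = "canonical_class", n_loci = "n_loci")
  )
  structure(list(
    class_counts = class_counts,
    at_rich_share = at_share,
    n_loci = nrow(loci),
    loci_per_megabase = if (genome_length_bp > 0)
      nrow(loci) / (genome_length_bp / 1e6) else 0,
    genome_fraction_percent = if (genome_length_bp > 0)
      100 * covered / genome_length_bp else 0,
    genome_length_bp = genome_length_bp
  ), class = "msat_composition")
}

#' @export
print.msat_composition <- function(x, ...) {
  cat(sprintf(
    "<msat_composition> %d loci over %.3g Mb: %.2f loci/Mb, %.3f%% of the genome\n",
    x$n_loci, x$genome_length_bp / 1e6, x$loci_per_megabase,
    x$genome_fraction_percent
  ))
  print(x$class_counts, ...)
  invisible(x)
}

#' @method tidy msat_composition
#' @export
tidy.msat_composition <- function(x, ...) x$class_counts

#' @method glance msat_composition
#' @export
glance.msat_composition <- function(x, ...) {
  tibble::tibble(
    n_loci = x$n_loci,
    loci_per_megabase = x$loci_per_megabase,
    genome_fraction_percent = x$genome_fraction_percent,
    genome_length_bp = x$genome_length_bp
  )
}

#' AT-richness tallies for a table of per-class locus counts
#'
#' Given per-motif locus counts, computes for each unit length the share of
#' loci whose repeat unit is AT-rich (at most one C or G base, i.e.
#' `[(A/T)_k, X_0]` or `[(A/T)_k-1, X_1]`).  This is the composition
#' statistic used to describe AT-dominated repeat landscapes.
#'
#' @param counts A data frame with columns `unit` (motif strings) and
#'   `n_loci` (locus counts).
#' @return A tibble with one row per unit length: `unit_length`, `n_loci`,
#'   `n_at_rich` and `at_rich_percent`.
#' @examples
#' tally_at_richness(data.frame(unit = c("AAC", "CCG"), n_loci = c(9, 1)))
#' @export
tally_at_richness <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!all(c("unit", "n_loci") %in% names(counts))) {
    abort("`counts` needs columns `unit` and `n_loci`.")
  }
  if (nrow(counts) == 0L) {
    return(tibble::tibble(unit_length = integer(), n_loci = double(),
                          n_at_rich = double(), at_rich_percent = double()))
  }
  ar <- at_richness(counts$unit)
  counts |>
    dplyr::mutate(
      unit_length = nchar(.data$unit),
      at_rich = ar$at_count >= .data$unit_length - 1L
    ) |>
    dplyr::group_by(.data$unit_length) |>
    dplyr::summarise(
      n_at_rich = sum(.data$n_loci[.data$at_rich]),
      n_loci = sum(.data$n_loci),
      at_rich_percent = 100 * .data$n_at_rich / .data$n_loci,
      .groups = "drop"
    ) |>
    dplyr::relocate("n_loci", .after = "unit_length")
}

#' Motif classes absent from an observed set of perfect loci
#'
#' Compares the observed perfect-locus classes of one unit length against
#' the complete enumeration from [enumerate_motif_classes()] and returns the
#' classes with no perfect locus.  In AT-rich genomes the CG-richest classes
#' (pure CG dimers, CCG trimers) are typically the missing ones.
#'
#' @param observed Either an `"msat_composition"` object or a data frame
#'   with columns `unit` and `n_loci` giving perfect-locus counts.
#' @param unit_length Unit length to check (1-6).
#' @return Character vector of canonical motifs with zero perfect loci.
#' @examples
#' missing_classes(
#'   data.frame(unit = c("AC", "AG", "AT", "CG"), n_loci = c(21, 265, 97, 0)),
#'   unit_length = 2
#' )
#' @export
missing_classes <- function(observed, unit_length) {
  if (inherits(observed, "msat_composition")) {
    obs <- observed$class_counts |>
      dplyr::filter(.data$n_perfect > 0) |>
      dplyr::pull("canonical_class")
  } else {
    observed <- tibble::as_tibble(observed)
    if (!all(c("unit", "n_loci") %in% names(observed))) {
      abort("`observed` needs columns `unit` and `n_loci`.")
    }
    obs <- canonical_motif(observed$unit[observed$n_loci > 0])
  }
  all_classes <- enumerate_motif_classes(unit_length)$canonical
  obs <- unique(obs[nchar(obs) == unit_length])
  setdiff(all_classes, obs)
}
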