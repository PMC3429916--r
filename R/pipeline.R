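#' Scan a FASTA file and write the locus table and composition summary
#'
#' File-level wrapper around [scan_repeats()] and
#' [summarize_composition()]: reads a (possibly gzip-compressed) multi-record
#' FASTA, scans it under `params`, and writes `<out_prefix>_loci.tsv` (the
#' locus table), `<out_prefix>_composition.json` (the genome composition
#' summary) and `<out_prefix>_provenance.json` (the parameters and package
#' version that produced them).  Outputs are deterministic: re-running with
#' the same inputs gives byte-identical files.
#'
#' @param fasta_path Path to a FASTA file.
#' @param out_prefix Path prefix for the output files.
#' @param params A [scan_params()] object.
#' @return Invisibly, a list with `loci`, `composition` and `files`.
#' @export
run_scan <- function(fasta_path, out_prefix,
                     params = scan_params("strict")) {
  if (!file.exists(fasta_path)) {
    abort(sprintf("FASTA file not found: %s", fasta_path))
  }
  seqs <- tryCatch(
    as.character(Biostrings::readDNAStringSet(fasta_path)),
    error = function(e) abort(sprintf("Cannot read FASTA '%s': %s",
                                      fasta_path, conditionMessage(e)))
  )
  loci <- scan_repeats(seqs, params)
  comp <- summarize_composition(loci, sum(nchar(seqs)))
  files <- list(
    loci = paste0(out_prefix, "_loci.tsv"),
    composition = paste0(out_prefix, "_composition.json"),
    provenance = paste0(out_prefix, "_provenance.json")
  )
  write_loci(loci, files$loci)
  write_json_file(list(
    n_loci = comp$n_loci,
    genome_length_bp = comp$genome_length_bp,
    loci_per_megabase = comp$loci_per_megabase,
    genome_fraction_percent = comp$genome_fraction_percent,
    class_counts = comp$class_counts,
    at_rich_share = comp$at_rich_share
  ), files$composition)
  write_json_file(provenance_block(
    step = "scan", input = fasta_path,
    params = unclass(params)
  ), files$provenance)
  invisible(list(loci = loci, composition = comp, files = files))
}

#' Run the calling, spectrum and rate-estimation stages and write reports
#'
#' File-level wrapper for the downstream half of the pipeline: reads a
#' genotype table and marker sheet (or takes them as data frames), calls
#' mutations against the progenitor, summarises the mutation spectrum and
#' estimates per-marker rates, then writes `<out_prefix>_calls.tsv`,
#' `<out_prefix>_rates.tsv`, `<out_prefix>_spectrum.json`,
#' `<out_prefix>_report.txt` (a human-readable narrative of the spectrum
#' and rates) and `<out_prefix>_provenance.json`.
#'
#' @param genotypes Genotype table (path to CSV or data frame), long format.
#' @param markers Marker sheet (path to CSV or data frame).
#' @param t Number of generations.
#' @param out_prefix Path prefix for the output files.
#' @param confidence Confidence level for rate intervals.
#' @return Invisibly, a list with `calls`, `spectrum`, `rates` and `files`.
#' @export
run_report <- function(genotypes, markers, t, out_prefix,
                       confidence = 0.95) {
  if (length(t) != 1L || is.na(t) || t <= 0) {
    abort("`t` must be a single positive number of generations.")
  }
  geno_in <- if (is.character(genotypes)) genotypes else "<data frame>"
  mark_in <- if (is.character(markers)) markers else "<data frame>"
  if (is.character(genotypes)) genotypes <- read_genotypes(genotypes)
  if (is.character(markers)) markers <- read_markers(markers)
  calls <- call_mutations(genotypes, markers)
  spec <- mutation_spectrum(calls, markers)
  rates <- estimate_rates(genotypes, markers, t, confidence)
  files <- list(
    calls = paste0(out_prefix, "_calls.tsv"),
    rates = paste0(out_prefix, "_rates.tsv"),
    spectrum = paste0(out_prefix, "_spectrum.json"),
    report = paste0(out_prefix, "_report.txt"),
    provenance = paste0(out_prefix, "_provenance.json")
  )
  write_calls(calls, files$calls)
  readr::write_tsv(tidy(rates), files$rates, na = ".")
  write_json_file(c(
    as.list(glance(spec)),
    list(per_locus = spec$per_locus, step_sizes = spec$step_sizes)
  ), files$spectrum)
  writeLines(report_text(spec, rates), files$report)
  write_json_file(provenance_block(
    step = "report", input = c(genotypes = geno_in, markers = mark_in),
    params = list(t = t, confidence = confidence)
  ), files$provenance)
  invisible(list(calls = calls, spectrum = spec, rates = rates,
                 files = files))
}

provenance_block <- function(step, input, params) {
  list(
    tool = "msatma",
    version = as.character(utils::packageVersion("msatma")),
    step = step,
    input = input,
    params = params
  )
}

report_text <- function(spec, rates) {
  g <- glance(spec)
  perfect_n <- if ("percent_match" %in% names(rates)) {
    sum(rates$percent_match == 100, na.rm = TRUE)
  } else NA_integer_
  informative <- rates[!rates$uninformative & !rates$saturated &
                         rates$l > 0, , drop = FALSE]
  lines <- c(
    "Microsatellite mutation report",
    "==============================",
    sprintf("Markers assayed: %d%s", nrow(rates),
            if (!is.na(perfect_n)) sprintf(" (%d perfect, %d imperfect)",
                                           perfect_n, nrow(rates) - perfect_n)
            else ""),
    sprintf("Mutation events: %d at %d loci", g$total_events,
            g$n_loci_mutated),
    sprintf("Single-step events: %d (%d insertions, %d deletions); multistep: %d",
            g$single_step_total, g$single_step_insertions,
            g$single_step_deletions, g$multi_step_total),
    sprintf("Insertion vs deletion events: %d vs %d (net %+d repeat units)",
            g$insertion_events_total, g$deletion_events_total,
            g$net_units_total),
    "",
    "Per-marker rate estimates (zero-class estimator):"
  )
  if (nrow(informative) > 0) {
    lines <- c(lines, sprintf(
      "  %s: n = %d of l = %d lines, mu = %.3g [%.3g, %.3g]%s",
      informative$marker_id, informative$n, informative$l, informative$mu,
      informative$ci_low, informative$ci_high,
      ifelse(informative$single_event, " (single event)", "")
    ))
  } else {
    lines <- c(lines, "  (no informative markers)")
  }
  gr <- glance(rates)
  if (!is.na(gr$suggested_rate)) {
    lines <- c(lines, "", sprintf(
      "Suggested aggregate rate (perfect loci, >= 30 units, n >= 2; %d markers): %.3g per allele per generation",
      gr$n_markers_in_guide, gr$suggested_rate
    ))
  }
  lines
}
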