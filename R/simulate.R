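#' Simulate mutation-accumulation lines under a stepwise mutation model
#'
#' Generates the genotype table produced by an MA experiment on
#' microsatellite loci: a set of selfing lines descends from a single
#' homozygous progenitor through single-offspring bottlenecks for
#' `n_generations`, so every new mutation fixes immediately and each line
#' carries one allele per locus.  Each line x locus mutates independently
#' with per-generation probability `mu`; a mutation changes the repeat
#' number by +/-1 with probability `p_single_step`, otherwise by a
#' multistep magnitude drawn as `1 + Geometric(multistep_q)` truncated to at
#' least 2; the sign is an insertion with probability `p_insertion`,
#' independent of magnitude.  Repeat counts are floored at `floor_copies`
#' (a deletion that would shrink the array below the floor is redrawn), so
#' loci never die during a run.
#'
#' The defaults describe a typical nematode MA design: 82 surviving selfing
#' lines propagated for 142 generations, with 26/31 of observed events
#' single-step and 23/31 insertions.
#'
#' @param loci Data frame with columns `unit` (motif), `repeat_count`
#'   (initial copies, >= 3) and `mu` (true per-allele per-generation
#'   mutation rate); an optional `marker_id` column names the loci.
#' @param n_lines Number of surviving lines genotyped (default 82).
#' @param n_generations Number of generations of propagation (default 142).
#' @param p_single_step Probability that an event is single-step
#'   (default 26/31).
#' @param p_insertion Probability that an event is an insertion
#'   (default 23/31).
#' @param multistep_q Geometric parameter for the multistep magnitude tail
#'   (default 0.357, giving a mean multistep magnitude of about 3.8 units).
#' @param floor_copies Minimum repeat count (default 3).
#' @param n_founding Optional number of founded lines; when given, only a
#'   random subset of `n_lines` survivors is genotyped (line attrition).
#' @param seed Integer seed for reproducibility; identical seeds give
#'   identical output.
#'
#' @return A list with `genotypes` (long tibble: `marker_id`, `line_id`,
#'   `allele_bp`), `markers` (marker sheet usable by [call_mutations()] and
#'   [estimate_rates()]), and `truth` (event log tibble: `marker_id`,
#'   `line_id`, `generation`, `delta_units`).
#' @examples
#' sim <- simulate_ma_lines(
#'   data.frame(unit = "AC", repeat_count = 40, mu = 5e-4),
#'   n_lines = 82, n_generations = 142, seed = 1
#' )
#' head(sim$genotypes)
#' @export
simulate_ma_lines <- function(loci, n_lines = 82, n_generations = 142,
                              p_single_step = 26 / 31,
                              p_insertion = 23 / 31,
                              multistep_q = 0.357,
                              floor_copies = 3,
                              n_founding = NULL,
                              seed = NULL) {
  loci <- tibble::as_tibble(loci)
  if (!all(c("unit", "repeat_count", "mu") %in% names(loci))) {
    abort("`loci` needs columns unit, repeat_count, mu.")
  }
  check_dna(loci$unit, max_len = 6L, arg = "unit")
  if (any(loci$repeat_count < floor_copies)) {
    abort(sprintf("Initial repeat counts must be at least %g.", floor_copies))
  }
  if (any(loci$mu < 0 | loci$mu > 1)) abort("`mu` must lie in [0, 1].")
  for (p in c(p_single_step, p_insertion)) {
    if (p < 0 || p > 1) abort("Probabilities must lie in [0, 1].")
  }
  if (n_lines < 1 || n_generations < 1) {
    abort("`n_lines` and `n_generations` must be positive.")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (!is.null(n_founding)) {
    if (n_founding < n_lines) abort("`n_founding` must be >= `n_lines`.")
    founders <- sort(sample.int(n_founding, n_lines))
  } else {
    founders <- seq_len(n_lines)
  }
  line_ids <- sprintf("L%03d", founders)

  if (!"marker_id" %in% names(loci)) {
    loci$marker_id <- sprintf("S%02d", seq_len(nrow(loci)))
  }
  unit_len <- nchar(loci$unit)
  markers <- tibble::tibble(
    marker_id = loci$marker_id,
    chromosome = "synthetic",
    unit = loci$unit,
    repeat_count = loci$repeat_count,
    percent_match = 100L,
    progenitor_bp = as.integer(unit_len * loci$repeat_count)
  )

  n_loci <- nrow(loci)
  cells <- n_loci * n_lines
  n_events <- rbinom(cells, n_generations, rep(loci$mu, each = n_lines))
  locus_idx <- rep(seq_len(n_loci), each = n_lines)
  line_idx <- rep(seq_len(n_lines), times = n_loci)

  truth <- vector("list", sum(n_events > 0))
  final_delta <- integer(cells)
  k <- 0L
  for (c_i in which(n_events > 0)) {
    li <- locus_idx[c_i]
    gens <- sort(sample.int(n_generations, n_events[c_i]))
    count <- loci$repeat_count[li]
    deltas <- integer(length(gens))
    for (e in seq_along(gens)) {
      repeat {
        d <- draw_step(p_single_step, p_insertion, multistep_q)
        if (count + d >= floor_copies) break
      }
      count <- count + d
      deltas[e] <- d
    }
    final_delta[c_i] <- sum(deltas)
    k <- k + 1L
    truth[[k]] <- tibble::tibble(
      marker_id = loci$marker_id[li],
      line_id = line_ids[line_idx[c_i]],
      generation = gens,
      delta_units = deltas
    )
  }
  truth <- if (k > 0) dplyr::bind_rows(truth) else
    tibble::tibble(marker_id = character(), line_id = character(),
                   generation = integer(), delta_units = integer())

  genotypes <- tibble::tibble(
    marker_id = loci$marker_id[locus_idx],
    line_id = line_ids[line_idx],
    allele_bp = as.integer(markers$progenitor_bp[locus_idx] +
                             unit_len[locus_idx] * final_delta)
  ) |>
    dplyr::arrange(.data$marker_id, .data$line_id)

  list(genotypes = genotypes, markers = markers, truth = truth)
}

draw_step <- function(p_single, p_insertion, q) {
  mag <- if (runif(1) < p_single) 1L else {
    m <- 1L + rgeom(1, q)
    while (m < 2L) m <- 1L + rgeom(1, q)
    m
  }
  if (runif(1) < p_insertion) mag else -mag
}

#' Generate a synthetic genome with planted tandem repeats
#'
#' Builds an i.i.d. random background sequence with a given A+T fraction
#' (default 0.58, a typical AT-rich nematode genome) and inserts the
#' requested tandem arrays at non-overlapping positions, returning both the
#' sequence and a ground-truth table of the planted intervals.  The base
#' immediately flanking each planted array on either side is forced to
#' break the repeat period, so the truth intervals are exact.
#'
#' Imperfect arrays are produced by substituting each base with probability
#' `(100 - percent_match) / 200` (one substitution breaks two adjacent-copy
#' comparisons, so the realised copy-to-copy match percentage is
#' approximately the target); no indels are introduced.
#'
#' @param genome_length Total sequence length in bp (0 gives an empty
#'   genome).
#' @param loci_spec Data frame with columns `unit` and `copies`, optional
#'   `percent_match` (default 100) and `start` (1-based; placed evenly when
#'   omitted).
#' @param background_at_fraction Background A+T fraction (default 0.58).
#' @param seed Integer seed.
#' @param seq_id Name of the generated sequence.
#'
#' @return A list with `sequences` (named character vector, scannable by
#'   [scan_repeats()]) and `truth` (tibble: `seq_id`, `start`, `end`,
#'   `unit`, `copies`, `percent_match_target`).
#' @examples
#' g <- plant_repeats(2000, data.frame(unit = "AG", copies = 20), seed = 1)
#' g$truth
#' @export
plant_repeats <- function(genome_length, loci_spec = NULL,
                          background_at_fraction = 0.58, seed = NULL,
                          seq_id = "synthetic") {
  if (genome_length < 0) abort("`genome_length` must be non-negative.")
  if (!is.null(seed)) set.seed(as.integer(seed))
  empty_truth <- tibble::tibble(
    seq_id = character(), start = integer(), end = integer(),
    unit = character(), copies = double(), percent_match_target = integer()
  )
  if (genome_length == 0) {
    return(list(sequences = setNames(character(0), character(0)),
                truth = empty_truth))
  }
  p_at <- background_at_fraction / 2
  p_cg <- (1 - background_at_fraction) / 2
  chars <- sample(c("A", "T", "C", "G"), genome_length, replace = TRUE,
                  prob = c(p_at, p_at, p_cg, p_cg))

  if (is.null(loci_spec) || nrow(loci_spec) == 0) {
    return(list(
      sequences = setNames(paste(chars, collapse = ""), seq_id),
      truth = empty_truth
    ))
  }
  loci_spec <- tibble::as_tibble(loci_spec)
  if (!all(c("unit", "copies") %in% names(loci_spec))) {
    abort("`loci_spec` needs columns unit and copies.")
  }
  check_dna(loci_spec$unit, max_len = 6L, arg = "unit")
  if (!"percent_match" %in% names(loci_spec)) loci_spec$percent_match <- 100L
  spans <- ceiling(nchar(loci_spec$unit) * loci_spec$copies)

  if (!"start" %in% names(loci_spec)) {
    # even placement: one array per equal-width chunk, centred with jitter
    n <- nrow(loci_spec)
    chunk <- genome_length %/% n
    if (any(spans + 2 > chunk)) {
      abort("Planted loci do not fit the genome without overlap.")
    }
    offsets <- vapply(seq_len(n), function(i) {
      room <- chunk - spans[i] - 2L
      1L + sample.int(room, 1)
    }, integer(1))
    loci_spec$start <- (seq_len(n) - 1L) * chunk + offsets + 1L
  }
  ends <- loci_spec$start + spans - 1L
  if (any(loci_spec$start < 1) || any(ends > genome_length)) {
    abort("Planted loci fall outside the genome.")
  }
  ord <- order(loci_spec$start)
  if (any(loci_spec$start[ord][-1] <= ends[ord][-length(ord)])) {
    abort("Planted loci overlap.")
  }

  for (i in seq_len(nrow(loci_spec))) {
    u <- strsplit(loci_spec$unit[i], "", fixed = TRUE)[[1]]
    p <- length(u)
    arr <- rep(u, length.out = spans[i])
    pm <- loci_spec$percent_match[i]
    if (pm < 100) {
      r <- (100 - pm) / 200
      hit <- runif(spans[i]) < r
      arr[hit] <- vapply(arr[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    s <- loci_spec$start[i]; e <- ends[i]
    chars[s:e] <- arr
    # break the period just outside the array so truth intervals are exact
    if (s > 1) {
      exp_left <- u[((-1) %% p) + 1L]
      if (chars[s - 1L] == exp_left) {
        chars[s - 1L] <- setdiff(c("A", "C", "G", "T"), exp_left)[1]
      }
    }
    if (e < genome_length) {
      exp_right <- u[(spans[i] %% p) + 1L]
      if (chars[e + 1L] == exp_right) {
        chars[e + 1L] <- setdiff(c("A", "C", "G", "T"), exp_right)[1]
      }
    }
  }
  truth <- tibble::tibble(
    seq_id = seq_id,
    start = as.integer(loci_spec$start),
    end = as.integer(ends),
    unit = loci_spec$unit,
    copies = loci_spec$copies,
    percent_match_target = as.integer(loci_spec$percent_match)
  )
  list(sequences = setNames(paste(chars, collapse = ""), seq_id),
       truth = truth)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector of DNA sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
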