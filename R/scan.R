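#' Scanning parameter presets
#'
#' Bundles the alignment weights and thresholds that control tandem-repeat
#' detection.  Two presets mirror the screening regimes commonly used with
#' Tandem Repeats Finder-style scans: `"strict"` (weights
#' match/mismatch/indel = 2/3/5, minimum score 50), which favours short,
#' near-perfect loci, and `"loose"` (weights 2/7/7, minimum score 20), which
#' admits longer and more imperfect loci.
#'
#' @param preset `"strict"`, `"loose"`, or `NULL` to supply weights manually.
#' @param match_weight,mismatch_weight,indel_weight Positive integer
#'   alignment weights (reward per matched base, penalty per mismatched or
#'   inserted/deleted base).
#' @param min_score Minimum alignment score for a locus to be reported.
#' @param min_copies Minimum number of repeat-unit copies (default 3).
#' @param unit_lengths Integer vector of unit lengths to scan, within 1..6
#'   (default 2:6; homopolymers are excluded from the default screen).
#'
#' @return A list of class `"scan_params"`.
#' @examples
#' scan_params("strict")
#' scan_params(match_weight = 2, mismatch_weight = 7, indel_weight = 7,
#'             min_score = 20)
#' @export
scan_params <- function(preset = NULL,
                        match_weight = NULL, mismatch_weight = NULL,
                        indel_weight = NULL, min_score = NULL,
                        min_copies = 3, unit_lengths = 2:6) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("strict", "loose"))
    defaults <- switch(preset,
      strict = list(match_weight = 2L, mismatch_weight = 3L,
                    indel_weight = 5L, min_score = 50L),
      loose  = list(match_weight = 2L, mismatch_weight = 7L,
                    indel_weight = 7L, min_score = 20L)
    )
    match_weight    <- match_weight    %||% defaults$match_weight
    mismatch_weight <- mismatch_weight %||% defaults$mismatch_weight
    indel_weight    <- indel_weight    %||% defaults$indel_weight
    min_score       <- min_score       %||% defaults$min_score
  }
  p <- list(
    regime_name = preset %||% "custom",
    match_weight = as.integer(match_weight),
    mismatch_weight = as.integer(mismatch_weight),
    indel_weight = as.integer(indel_weight),
    min_score = as.integer(min_score),
    min_copies = as.numeric(min_copies),
    unit_lengths = sort(unique(as.integer(unit_lengths)))
  )
  ok <- function(x) length(x) == 1L && !is.na(x) && x > 0
  if (!ok(p$match_weight) || !ok(p$mismatch_weight) || !ok(p$indel_weight) ||
      !ok(p$min_score)) {
    abort("Alignment weights and `min_score` must be single positive numbers.")
  }
  if (!ok(p$min_copies) || p$min_copies < 3) {
    abort("`min_copies` must be at least 3.")
  }
  if (length(p$unit_lengths) == 0L || any(p$unit_lengths < 1L) ||
      any(p$unit_lengths > 6L)) {
    abort("`unit_lengths` must lie within 1..6.")
  }
  structure(p, class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat(sprintf(
    "<scan_params: %s> weights {%d,%d,%d}, min score %d, min copies %g, units %s\n",
    x$regime_name, x$match_weight, x$mismatch_weight, x$indel_weight,
    x$min_score, x$min_copies, paste(x$unit_lengths, collapse = ",")
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect short tandem repeats in DNA sequences
#'
#' Scans sequences for tandem arrays of 1-6 bp units with at least
#' `min_copies` copies, using a deterministic seed-extend-score procedure:
#' positions where a `p`-mer recurs at distance `p` seed a candidate array,
#' which is extended left and right against the periodic extension of the
#' seed unit; extension stops once the running score falls two full units'
#' worth of mismatch penalty below its best value, and the array is clipped
#' at the best-scoring endpoints.  The score of an array is
#' `match_weight * matched bases - mismatch_weight * mismatched bases`
#' against the periodic pattern (a perfect array of span `L` scores
#' `match_weight * L`), and only arrays reaching `min_score` are reported.
#' The extension is gap-free, so reported loci have `percent_indels = 0`;
#' interrupted arrays are modelled through mismatches.
#'
#' Overlapping candidates sharing at least half of the shorter span are
#' resolved in favour of the higher score, with ties broken toward the
#' smaller unit length and then the leftmost start.  Runs of `N` are never
#' crossed.  Non-primitive seed units are reduced to their primitive unit
#' before reporting, so an `ACAC`-seeded hit is classified as an `AC` locus.
#'
#' @param sequences A named character vector of DNA sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param params A [scan_params()] object (default: the strict preset).
#'
#' @return A tibble with one row per locus: `seq_id`, `start`, `end`
#'   (1-based, inclusive), `unit_length`, `copy_number`, `percent_match`,
#'   `percent_indels`, `score`, `unit` (pattern at the locus start),
#'   `canonical_class`, and `is_perfect`.
#'
#' @examples
#' scan_repeats(c(chr = paste0(strrep("AG", 30), "TTTT")),
#'              scan_params("strict"))
#' @export
scan_repeats <- function(sequences, params = scan_params("strict")) {
  if (!inherits(params, "scan_params")) {
    abort("`params` must be created with scan_params().")
  }
  sequences <- as_dna_chars(sequences)
  res <- purrr::imap(sequences, function(s, id) scan_one(s, id, params))
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0L) {
    return(tibble::tibble(
      seq_id = character(), start = integer(), end = integer(),
      unit_length = integer(), copy_number = double(),
      percent_match = integer(), percent_indels = integer(),
      score = integer(), unit = character(), canonical_class = character(),
      is_perfect = logical()
    ))
  }
  dplyr::arrange(out, .data$seq_id, .data$start, .data$unit_length)
}

# Scan a single sequence (character scalar) for one id.
scan_one <- function(seq, seq_id, params) {
  n <- nchar(seq)
  if (n == 0L) return(NULL)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c("A", "C", "G", "T", "N"))
  if (any(bad)) {
    abort(sprintf("Sequence '%s' contains non-ACGTN characters.", seq_id))
  }
  valid <- chars != "N"
  mw <- params$match_weight
  mm <- params$mismatch_weight

  cands <- list()
  for (p in params$unit_lengths) {
    if (n < 2L * p) next
    i <- seq_len(n - p)
    msk <- valid[i] & valid[i + p] & (chars[i] == chars[i + p])
    r <- rle(msk)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seeds <- starts[r$values & r$lengths >= p]
    covered_until <- 0L
    for (seed in seeds) {
      if (seed <= covered_until) next
      loc <- extend_seed(chars, valid, seed, p, mw, mm)
      covered_until <- loc$end
      span <- loc$end - loc$start + 1L
      if (loc$score < params$min_score) next
      unit <- paste(loc$pattern, collapse = "")
      prim <- primitive_unit(unit)
      plen <- nchar(prim)
      copy <- span / plen
      if (copy < params$min_copies) next
      pm <- percent_match_at(chars, loc$start, loc$end, plen)
      cands[[length(cands) + 1L]] <- list(
        start = loc$start, end = loc$end, unit_length = plen,
        copy_number = copy, percent_match = pm$pm,
        score = loc$score, unit = prim
      )
    }
  }
  if (length(cands) == 0L) return(NULL)
  tbl <- dplyr::bind_rows(lapply(cands, tibble::as_tibble))
  tbl <- dplyr::distinct(tbl, .data$start, .data$end, .data$unit_length,
                         .keep_all = TRUE)
  tbl <- resolve_overlaps(tbl)
  tibble::tibble(
    seq_id = seq_id,
    start = as.integer(tbl$start),
    end = as.integer(tbl$end),
    unit_length = as.integer(tbl$unit_length),
    copy_number = round(tbl$copy_number, 1),
    percent_match = as.integer(tbl$percent_match),
    percent_indels = 0L,
    score = as.integer(tbl$score),
    unit = tbl$unit,
    canonical_class = canonical_motif(tbl$unit),
    is_perfect = tbl$percent_match == 100L
  )
}

# Gap-free extension of a seeded candidate array.  Returns clipped
# coordinates, the periodic pattern phased to the clipped start, and the
# whole-array score.
extend_seed <- function(chars, valid, seed, p, mw, mm) {
  n <- length(chars)
  u <- chars[seed:(seed + p - 1L)]
  expected <- function(j) u[((j - seed) %% p) + 1L]
  drop_limit <- 2L * p * mm

  cur <- 0L; best <- 0L; best_r <- seed + 2L * p - 1L
  j <- seed + 2L * p
  while (j <= n && valid[j]) {
    cur <- cur + if (chars[j] == expected(j)) mw else -mm
    if (cur > best) { best <- cur; best_r <- j }
    if (best - cur > drop_limit) break
    j <- j + 1L
  }
  gain_r <- best

  cur <- 0L; best <- 0L; best_l <- seed
  j <- seed - 1L
  while (j >= 1L && valid[j]) {
    cur <- cur + if (chars[j] == expected(j)) mw else -mm
    if (cur > best) { best <- cur; best_l <- j }
    if (best - cur > drop_limit) break
    j <- j - 1L
  }
  gain_l <- best

  span <- best_r - best_l + 1L
  exp_all <- u[((best_l:best_r - seed) %% p) + 1L]
  n_match <- sum(chars[best_l:best_r] == exp_all)
  score <- mw * n_match - mm * (span - n_match)
  list(start = best_l, end = best_r, score = score,
       pattern = exp_all[seq_len(p)])
}

# Percent match from adjacent-copy comparisons at lag `p` over [start, end].
percent_match_at <- function(chars, start, end, p) {
  idx <- start:(end - p)
  if (length(idx) < 1L || end - p < start) {
    return(list(pm = 100L))
  }
  hits <- sum(chars[idx] == chars[idx + p])
  list(pm = as.integer(round(100 * hits / length(idx))))
}

# Keep the best-scoring locus among candidates sharing >= 50% of the
# shorter span; ties to smaller unit length, then leftmost start.
resolve_overlaps <- function(tbl) {
  ord <- order(-tbl$score, tbl$unit_length, tbl$start)
  tbl <- tbl[ord, , drop = FALSE]
  keep <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(tbl$end[i], tbl$end[j]) - max(tbl$start[i], tbl$start[j]) + 1L
      if (ov <= 0L) next
      shorter <- min(tbl$end[i] - tbl$start[i], tbl$end[j] - tbl$start[j]) + 1L
      if (ov / shorter >= 0.5) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  tbl <- tbl[keep, , drop = FALSE]
  tbl[order(tbl$start, tbl$unit_length), , drop = FALSE]
}

# Accept character vector, DNAStringSet, or FASTA path.
as_dna_chars <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) {
    out <- as.character(sequences)
  } else if (is.character(sequences) && length(sequences) == 1L &&
             !grepl("^[ACGTNacgtn]*$", sequences) && file.exists(sequences)) {
    out <- as.character(Biostrings::readDNAStringSet(sequences))
  } else if (is.character(sequences)) {
    out <- sequences
  } else {
    abort("`sequences` must be a character vector, DNAStringSet, or FASTA path.")
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    names(out) <- paste0("seq", seq_along(out))
  }
  # FASTA headers may carry descriptions; keep the first token as the id
  names(out) <- sub("\\s.*$", "", names(out))
  out
}
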