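#' Poisson zero-class mutation-rate estimator
#'
#' Estimates the per-allele per-generation mutation rate of a locus from the
#' fraction of MA lines that show at least one visible mutation after `t`
#' generations.  Under a Poisson mutation process with rate `mu`, a line is
#' unmutated with probability `exp(-mu * t)`, so
#' `mu = -log(1 - n / l) / t`, where `n` is the number of mutated lines and
#' `l` the number of lines assessed.  Using the zero-class fraction rather
#' than the raw event count corrects for multiple hits in the same line.
#'
#' @param n Number of mutated lines (0 <= n < l).
#' @param l Number of lines assessed (>= 1).
#' @param t Number of generations (>= 1).
#' @return The rate estimate `mu` (per allele per generation).  `n = 0`
#'   gives 0; `n = l` (every line mutated) leaves the estimator undefined
#'   and raises an error.
#' @examples
#' estimate_rate(6, 82, 142)
#' @export
estimate_rate <- function(n, l, t) {
  check_nlt(n, l, t)
  if (any(n == l)) {
    abort("Estimator saturated: every assessed line mutated (n = l); the zero-class estimator is undefined.")
  }
  -log(1 - n / l) / t
}

check_nlt <- function(n, l, t) {
  if (any(is.na(n) | is.na(l) | is.na(t))) abort("n, l, t must not be NA.")
  if (any(l < 1) || any(t < 1)) abort("`l` and `t` must be at least 1.")
  if (any(n < 0)) abort("`n` must be non-negative.")
  if (any(n > l)) abort("`n` cannot exceed the number of assessed lines `l`.")
  invisible(TRUE)
}

#' Exact binomial confidence interval for the mutation rate
#'
#' Clopper-Pearson interval on the mutated-line fraction `n / l`,
#' transformed through the zero-class estimator `mu = -log(1 - f) / t`
#' (monotone in `f`, so the interval endpoints map directly).  The interval
#' always contains the point estimate; `n = 0` gives a lower bound of 0 and
#' `n = l` an infinite upper bound.
#'
#' @inheritParams estimate_rate
#' @param confidence Coverage level in (0, 1); default 0.95.
#' @return A tibble with columns `ci_low` and `ci_high`.
#' @examples
#' rate_ci(6, 82, 142)
#' @export
rate_ci <- function(n, l, t, confidence = 0.95) {
  check_nlt(n, l, t)
  if (length(confidence) != 1L || is.na(confidence) ||
      confidence <= 0 || confidence >= 1) {
    abort("`confidence` must be a single number in (0, 1).")
  }
  alpha <- 1 - confidence
  f_low <- ifelse(n == 0, 0, qbeta(alpha / 2, n, l - n + 1))
  f_high <- ifelse(n == l, 1, qbeta(1 - alpha / 2, n + 1, l - n))
  tibble::tibble(
    ci_low = -log(1 - f_low) / t,
    ci_high = ifelse(f_high >= 1, Inf, -log(1 - f_high) / t)
  )
}

#' Per-marker mutation-rate estimates from a genotype table
#'
#' Runs the full estimation pipeline for every marker: calls mutations
#' against the progenitor ([call_mutations()]), counts the mutated lines `n`
#' and the assessed lines `l` (lines with a non-missing genotype at that
#' marker — assessed-line counts may differ between markers), and applies
#' the zero-class estimator with exact binomial confidence bounds.
#'
#' Markers with no mutated line get `mu = 0` and are flagged
#' `uninformative`; single-event markers are flagged `single_event` (one
#' mutation is too little to pin down a rate and such estimates are best
#' reported parenthetically); a saturated marker (`n = l`) gets `mu = NA`
#' and `saturated = TRUE` rather than aborting the batch.
#'
#' @inheritParams call_mutations
#' @param t Number of generations of MA propagation.
#' @param confidence Confidence level for the interval (default 0.95).
#'
#' @return A tibble of class `"msat_rates"` with one row per marker:
#'   `marker_id`, `n`, `l`, `t`, `mu`, `ci_low`, `ci_high`,
#'   `single_event`, `uninformative`, `saturated`, plus `repeat_count`,
#'   `percent_match` and `unit` carried over from the marker sheet when
#'   present.  `glance()` adds the aggregate suggested rate (mean `mu` over
#'   perfect markers with at least two mutated lines and at least 30 repeat
#'   units — the marker population recommended for divergence dating).
#' @examples
#' fx <- fixture_ma_markers()
#' geno <- fixture_genotypes(n_lines = 82)
#' estimate_rates(geno, fx$markers, t = 142)
#' @export
estimate_rates <- function(genotypes, markers, t, confidence = 0.95) {
  if (length(t) != 1L || is.na(t) || t < 1) {
    abort("`t` must be a single positive number of generations.")
  }
  markers <- tibble::as_tibble(markers)
  genotypes <- tibble::as_tibble(genotypes)
  calls <- call_mutations(genotypes, markers)
  l_tbl <- genotypes |>
    dplyr::filter(!is.na(.data$allele_bp)) |>
    dplyr::group_by(marker_id = .data$marker_id) |>
    dplyr::summarise(l = dplyr::n_distinct(.data$line_id), .groups = "drop")
  n_tbl <- calls |>
    dplyr::group_by(marker_id = .data$marker_id) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$line_id), .groups = "drop")
  res <- markers |>
    dplyr::select(dplyr::any_of(c("marker_id", "unit", "repeat_count",
                                  "percent_match"))) |>
    dplyr::left_join(l_tbl, by = "marker_id") |>
    dplyr::left_join(n_tbl, by = "marker_id") |>
    dplyr::mutate(
      l = dplyr::coalesce(.data$l, 0L),
      n = dplyr::coalesce(.data$n, 0L),
      t = t,
      saturated = .data$l > 0 & .data$n == .data$l,
      mu = dplyr::case_when(
        .data$l == 0L ~ NA_real_,
        saturated ~ NA_real_,
        TRUE ~ -log(1 - .data$n / .data$l) / t
      ),
      single_event = .data$n == 1L,
      uninformative = .data$n == 0L
    )
  ci <- purrr::pmap_dfr(
    list(res$n, res$l, res$saturated),
    function(n, l, sat, ...) {
      if (l == 0L) return(tibble::tibble(ci_low = NA_real_, ci_high = NA_real_))
      rate_ci(n, l, t, confidence)
    }
  )
  out <- dplyr::bind_cols(res, ci) |>
    dplyr::relocate("marker_id", "n", "l", "t", "mu", "ci_low", "ci_high")
  class(out) <- c("msat_rates", class(out))
  attr(out, "confidence") <- confidence
  out
}

#' @method tidy msat_rates
#' @export
tidy.msat_rates <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "msat_rates")
  out
}

#' @method glance msat_rates
#' @export
glance.msat_rates <- function(x, ...) {
  informative <- !x$uninformative & !x$saturated & x$l > 0
  guide <- informative & x$n >= 2
  if (all(c("percent_match", "repeat_count") %in% names(x))) {
    guide <- guide & x$percent_match == 100 & x$repeat_count >= 30
  }
  tibble::tibble(
    n_markers = nrow(x),
    n_markers_mutated = sum(x$n > 0),
    total_mutated_lines = sum(x$n),
    suggested_rate = if (any(guide)) mean(x$mu[guide]) else NA_real_,
    n_markers_in_guide = sum(guide),
    confidence = attr(x, "confidence") %||% NA_real_
  )
}
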