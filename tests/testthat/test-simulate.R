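sim_loci <- function(n = 1, mu = 5e-4, unit = "AC", copies = 40) {
  data.frame(unit = unit, repeat_count = copies, mu = mu)
}

test_that("a zero mutation rate leaves every line at the progenitor allele", {
  sim <- simulate_ma_lines(sim_loci(mu = 0), n_lines = 20, seed = 1)
  expect_true(all(sim$genotypes$allele_bp == sim$markers$progenitor_bp))
  expect_equal(nrow(sim$truth), 0L)
  expect_equal(nrow(call_mutations(sim$genotypes, sim$markers)), 0L)
})

test_that("identical seeds reproduce identical simulator output", {
  cfg <- list(loci = sim_loci(n = 3, mu = 1e-3), n_lines = 30, seed = 77)
  a <- simulate_ma_lines(cfg$loci, n_lines = cfg$n_lines, seed = cfg$seed)
  b <- simulate_ma_lines(cfg$loci, n_lines = cfg$n_lines, seed = cfg$seed)
  expect_identical(a, b)
  g <- plant_repeats(5000, data.frame(unit = "AG", copies = 20), seed = 5)
  h <- plant_repeats(5000, data.frame(unit = "AG", copies = 20), seed = 5)
  expect_identical(g, h)
})

test_that("the mutated-line fraction matches the zero-class expectation", {
  loci <- do.call(rbind, replicate(500, sim_loci(), simplify = FALSE))
  sim <- simulate_ma_lines(loci, n_lines = 82, n_generations = 142,
                           p_single_step = 1, seed = 2024)
  cells <- nrow(loci) * 82
  p_expect <- 1 - (1 - 5e-4)^142
  mutated <- nrow(dplyr::distinct(sim$truth, marker_id, line_id))
  se <- sqrt(p_expect * (1 - p_expect) / cells)
  expect_lte(abs(mutated / cells - p_expect), 3 * se)
})

test_that("genotypes are the progenitor plus the summed truth deltas", {
  sim <- simulate_ma_lines(sim_loci(n = 5, mu = 2e-3), n_lines = 40,
                           seed = 31)
  truth_sum <- sim$truth |>
    dplyr::group_by(marker_id, line_id) |>
    dplyr::summarise(net = sum(delta_units), .groups = "drop")
  joined <- dplyr::left_join(sim$genotypes, truth_sum,
                             by = c("marker_id", "line_id")) |>
    dplyr::left_join(sim$markers, by = "marker_id") |>
    dplyr::mutate(net = dplyr::coalesce(net, 0L))
  expect_true(all(joined$allele_bp ==
                    joined$progenitor_bp + nchar(joined$unit) * joined$net))
})

test_that("pipeline spectrum equals truth tallies absent homoplasy, never exceeds with it", {
  sim <- simulate_ma_lines(sim_loci(n = 200, mu = 1e-3), n_lines = 82,
                           seed = 404)
  calls <- call_mutations(sim$genotypes, sim$markers)
  sp <- mutation_spectrum(calls, sim$markers)
  # cells with a single truth event must be recovered exactly
  single_hit <- sim$truth |>
    dplyr::group_by(marker_id, line_id) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup()
  recovered <- dplyr::semi_join(calls, single_hit,
                                by = c("marker_id", "line_id"))
  expect_equal(nrow(recovered), nrow(single_hit))
  expect_equal(
    sort(recovered$delta_units),
    sort(single_hit$delta_units)
  )
  # overall the pipeline can only lose events to cancellation, never gain
  expect_lte(sp$total_events,
             nrow(dplyr::distinct(sim$truth, marker_id, line_id)))
})

test_that("repeat counts never fall below the floor", {
  sim <- simulate_ma_lines(sim_loci(n = 50, mu = 5e-2, copies = 3),
                           n_lines = 20, n_generations = 50,
                           p_single_step = 0.5, p_insertion = 0.2, seed = 8)
  expect_true(all(sim$genotypes$allele_bp >= 3L * 2L))
})

test_that("line attrition genotypes only the surviving subset", {
  sim <- simulate_ma_lines(sim_loci(), n_lines = 82, n_founding = 100,
                           seed = 15)
  expect_equal(dplyr::n_distinct(sim$genotypes$line_id), 82L)
  ids <- as.integer(sub("L", "", unique(sim$genotypes$line_id)))
  expect_true(all(ids >= 1 & ids <= 100))
})

test_that("background base composition honours the AT fraction", {
  g <- plant_repeats(1e5, seed = 99)
  chars <- strsplit(g$sequences[[1]], "")[[1]]
  at <- mean(chars %in% c("A", "T"))
  se <- sqrt(0.58 * 0.42 / 1e5)
  expect_lte(abs(at - 0.58), 3 * se)
})

test_that("planting validates geometry and handles the empty genome", {
  empty <- plant_repeats(0)
  expect_length(empty$sequences, 0L)
  expect_equal(nrow(empty$truth), 0L)
  expect_error(
    plant_repeats(100, data.frame(unit = "AG", copies = 30,
                                  start = c(1, 20)), seed = 1),
    "overlap"
  )
  expect_error(
    plant_repeats(50, data.frame(unit = "TTCAA", copies = 64), seed = 1),
    "fit|outside"
  )
})
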