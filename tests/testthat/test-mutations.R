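test_that("allele-size differences convert to signed repeat units", {
  expect_equal(delta_units(204, 200, 4), 1L)
  expect_equal(delta_units(164, 200, 4), -9L)
  expect_equal(delta_units(200, 200, 4), 0L)
  expect_error(delta_units(203, 200, 2), "Off-ladder")
  expect_error(delta_units(-1, 200, 2), "positive")
})

test_that("delta_units is antisymmetric in allele and progenitor", {
  set.seed(21)
  for (i in 1:50) {
    u <- sample(2:6, 1)
    a <- 100L + u * sample(-10:10, 1)
    expect_equal(delta_units(a, 100L, u), -delta_units(100L, a, u))
  }
})

test_that("calling returns one call per nonzero difference and honours missing data", {
  markers <- data.frame(marker_id = c("M1", "M2"), unit = c("ACAT", "AG"),
                        progenitor_bp = c(144L, 80L))
  geno <- data.frame(
    marker_id = c("M1", "M1", "M1", "M2", "M2"),
    line_id = c("L1", "L2", "L3", "L1", "L2"),
    allele_bp = c(148L, 144L, NA, 80L, 80L)
  )
  calls <- call_mutations(geno, markers)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$marker_id, "M1")
  expect_equal(calls$delta_units, 1L)
  expect_equal(calls$kind, "insertion")
  expect_equal(calls$step, "single")

  same <- geno; same$allele_bp <- c(144L, 144L, 144L, 80L, 80L)
  expect_equal(nrow(call_mutations(same, markers)), 0L)

  expect_error(call_mutations(data.frame(marker_id = "MX", line_id = "L1",
                                         allele_bp = 100L), markers),
               "without a definition")
})

test_that("off-ladder alleles are suppressed with a warning and reported", {
  markers <- data.frame(marker_id = "M1", unit = "AG", progenitor_bp = 80L)
  geno <- data.frame(marker_id = "M1", line_id = c("L1", "L2"),
                     allele_bp = c(83L, 82L))
  expect_warning(calls <- call_mutations(geno, markers), "off-ladder")
  expect_equal(nrow(calls), 1L)
  expect_equal(nrow(attr(calls, "off_ladder")), 1L)
  expect_equal(attr(calls, "off_ladder")$line_id, "L1")
})

test_that("spectrum conservation identities hold for random call sets", {
  set.seed(33)
  for (i in 1:25) {
    calls <- random_calls(sample(1:40, 1))
    sp <- mutation_spectrum(calls)
    expect_equal(sp$single_step_total + sp$multi_step_total, sp$total_events)
    expect_equal(sp$insertion_events_total + sp$deletion_events_total,
                 sp$total_events)
    net <- tapply(calls$delta_units, calls$marker_id, sum)
    expect_equal(sp$per_locus$net_units[order(sp$per_locus$marker_id)],
                 as.integer(net[order(names(net))]), ignore_attr = TRUE)
    expect_equal(sum(sp$per_locus$n_events), sp$total_events)
  }
})

test_that("per-locus net change and trend follow the signed sum", {
  calls <- tibble::tibble(
    marker_id = "M82",
    line_id = paste0("L", 1:6),
    delta_units = c(-3L, -1L, 1L, 1L, 2L, 3L)
  )
  sp <- mutation_spectrum(calls)
  expect_equal(sp$per_locus$net_units, 3L)
  expect_equal(sp$per_locus$trend, "growth")
  balanced <- calls; balanced$delta_units <- c(-1L, 1L, -2L, 2L, -3L, 3L)
  expect_equal(mutation_spectrum(balanced)$per_locus$trend, "none")
})

test_that("empty call sets yield an all-zero spectrum", {
  sp <- mutation_spectrum(tibble::tibble(marker_id = character(),
                                         line_id = character(),
                                         delta_units = integer()))
  g <- glance(sp)
  expect_true(all(unlist(g) == 0))
})

test_that("the packaged panel expands to the recorded event set", {
  fx <- fixture_ma_markers()
  expect_equal(nrow(fx$markers), 41L)
  expect_equal(nrow(fx$calls), 31L)
  expect_equal(sum(fx$calls$marker_id == "M79"), 4L)
  expect_true(all(fx$calls$delta_units[fx$calls$marker_id == "M79"] == 1L))
  expect_equal(sum(fx$markers$percent_match == 100), 19L)
  # no line is recorded twice at one marker, so mutated-line counts equal
  # event counts per marker
  sp <- mutation_spectrum(fx$calls, fx$markers)
  expect_equal(sp$per_locus$n_events, sp$per_locus$n_lines_mutated)
})

test_that("stratification partitions markers and assigns events to strata", {
  fx <- fixture_ma_markers()
  pl <- stratify_events(fx$calls, fx$markers, by = "perfect_long",
                        repeat_count_threshold = 3)
  expect_equal(sum(pl$n_markers), 41L)
  expect_equal(sum(pl$n_events), 31L)
  expect_equal(pl$n_events[pl$stratum == "perfect_long"], 29L)

  pf <- stratify_events(fx$calls, fx$markers, by = "perfection")
  expect_equal(pf$n_events[pf$stratum == "imperfect"], 1L)
  expect_equal(pf$n_markers[pf$stratum == "perfect"], 19L)

  expect_error(stratify_events(fx$calls, fx$markers, by = "repeat_count"),
               "threshold")
  expect_error(stratify_events(fx$calls, fx$markers, by = "nonsense"))
})
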