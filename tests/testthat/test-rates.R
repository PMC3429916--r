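test_that("the zero-class estimator matches its closed form and edge cases", {
  expect_equal(estimate_rate(0, 82, 142), 0)
  expect_equal(estimate_rate(1, 80, 142), -log(1 - 1 / 80) / 142)
  expect_equal(estimate_rate(6, 82, 142), -log(1 - 6 / 82) / 142)
  expect_equal(signif(estimate_rate(6, 82, 142), 3), 5.35e-4)
  expect_error(estimate_rate(82, 82, 142), "saturated")
  expect_error(estimate_rate(83, 82, 142), "cannot exceed")
  expect_error(estimate_rate(-1, 82, 142), "non-negative")
})

test_that("small mutated fractions keep the estimator near n/(l*t)", {
  for (l in c(50, 82, 200)) {
    for (n in 1:floor(0.05 * l)) {
      mu <- estimate_rate(n, l, 142)
      naive <- n / (l * 142)
      expect_lte(abs(mu - naive) / mu, 0.03)
    }
  }
})

test_that("the estimator is monotone in n and in t", {
  mus <- vapply(0:20, estimate_rate, numeric(1), l = 82, t = 142)
  expect_true(all(diff(mus) > 0))
  ts <- vapply(c(50, 100, 142, 300), function(t) estimate_rate(5, 82, t),
               numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("exact binomial intervals agree with binom.test and contain the estimate", {
  for (n in c(0, 1, 2, 6, 40)) {
    ci <- rate_ci(n, 82, 142, confidence = 0.95)
    ref <- stats::binom.test(n, 82, conf.level = 0.95)$conf.int
    expect_equal(ci$ci_low, -log(1 - ref[1]) / 142, tolerance = 1e-10)
    expect_equal(ci$ci_high, -log(1 - ref[2]) / 142, tolerance = 1e-10)
    if (n < 82) {
      mu <- estimate_rate(n, 82, 142)
      expect_lte(ci$ci_low, mu)
      expect_gte(ci$ci_high, mu)
    }
  }
  expect_equal(rate_ci(0, 82, 142)$ci_low, 0)
})

test_that("interval coverage is close to nominal over simulated loci", {
  set.seed(404)
  mu_true <- 5e-4; l <- 82; t <- 142
  p_mut <- 1 - exp(-mu_true * t)
  n <- rbinom(1000, l, p_mut)
  ci <- rate_ci(n, l, t, confidence = 0.95)
  cover <- mean(ci$ci_low <= mu_true & ci$ci_high >= mu_true)
  expect_gte(cover, 0.90)
  expect_lte(cover, 1.00)
})

test_that("batch estimation flags uninformative, single-event and saturated markers", {
  markers <- data.frame(
    marker_id = c("A", "B", "C"),
    unit = c("AG", "AG", "AG"),
    repeat_count = c(40, 40, 40),
    percent_match = c(100L, 100L, 100L),
    progenitor_bp = c(80L, 80L, 80L)
  )
  geno <- tidyr::expand_grid(marker_id = markers$marker_id,
                             line_id = paste0("L", 1:10)) |>
    dplyr::mutate(allele_bp = 80L)
  geno$allele_bp[geno$marker_id == "B" & geno$line_id == "L1"] <- 82L
  geno$allele_bp[geno$marker_id == "C"] <- 82L
  r <- estimate_rates(geno, markers, t = 100)
  expect_true(r$uninformative[r$marker_id == "A"])
  expect_equal(r$mu[r$marker_id == "A"], 0)
  expect_true(r$single_event[r$marker_id == "B"])
  expect_true(r$saturated[r$marker_id == "C"])
  expect_true(is.na(r$mu[r$marker_id == "C"]))
})

test_that("missing genotypes reduce the assessed-line count l per marker", {
  markers <- data.frame(marker_id = "A", unit = "AG", progenitor_bp = 80L)
  geno <- data.frame(marker_id = "A", line_id = paste0("L", 1:10),
                     allele_bp = c(rep(80L, 7), 82L, NA, NA))
  r <- estimate_rates(geno, markers, t = 100)
  expect_equal(r$l, 8L)
  expect_equal(r$n, 1L)
  expect_equal(r$mu, -log(1 - 1 / 8) / 100)
})

test_that("rates over the packaged panel match the closed form per marker", {
  fx <- fixture_ma_markers()
  geno <- fixture_genotypes()
  r <- estimate_rates(geno, fx$markers, t = 142)
  expect_equal(nrow(r), 41L)
  expect_true(all(r$l == 82L))
  m82 <- r[r$marker_id == "M82", ]
  expect_equal(m82$n, 6L)
  expect_equal(m82$mu, -log(1 - 6 / 82) / 142)
  expect_equal(sum(r$n > 0), 11L)
  expect_equal(sum(r$single_event), 4L)
  g <- glance(r)
  expect_equal(g$n_markers_in_guide, 7L)
  expect_true(g$suggested_rate > 1e-4 && g$suggested_rate < 1e-3)
})
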