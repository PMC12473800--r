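test_that("the default two-zone spec mirrors the built-in descriptive statistics", {
  spec <- default_cunas_spec()
  expect_equal(nrow(spec$sites), 6)
  expect_equal(as.vector(table(spec$sites$zone)[c("upper", "lower")]),
               c(3L, 3L))
  zs <- spec$zone_stats
  expect_equal(zs$mean[zs$zone == "lower" & zs$element == "Zn"], 101.3)
  expect_equal(zs$mean[zs$zone == "upper" & zs$element == "As"], 7.7)
  expect_equal(zs$mean[zs$zone == "lower" & zs$element == "Cd"], 0.4)
  expect_equal(nrow(zs), 2 * 13)
})

test_that("generation is deterministic under a fixed seed and strictly positive", {
  spec <- default_cunas_spec()
  a <- generate_samples(spec, seed = 99)
  b <- generate_samples(spec, seed = 99)
  expect_identical(a, b)
  c <- generate_samples(spec, seed = 100)
  expect_false(identical(a, c))
  vals <- unlist(a[sample_elements(a)])
  expect_true(all(vals > 0))
})

test_that("a zero target SD degenerates to the exact mean", {
  spec <- zone_generator_spec(
    zone_stats = tibble::tibble(zone = "lower", element = "Zn",
                                mean = 101.3, sd = 0),
    sites = tibble::tibble(site = "L1", zone = "lower"),
    replicates_per_site = 5)
  s <- generate_samples(spec, seed = 1)
  expect_true(all(s$Zn == 101.3))
})

test_that("lognormal moment matching recovers the target moments at n = 10,000", {
  spec <- zone_generator_spec(
    zone_stats = tibble::tibble(zone = "lower", element = "Zn",
                                mean = 101.3, sd = 58.7),
    sites = tibble::tibble(site = "L1", zone = "lower"),
    replicates_per_site = 5000,
    months = c("February", "March"))
  s <- generate_samples(spec, seed = 20260901)
  expect_equal(nrow(s), 10000)
  expect_equal(mean(s$Zn), 101.3, tolerance = 0.02)
  expect_equal(sd(s$Zn), 58.7, tolerance = 0.05)
})

test_that("the generator preserves the downstream enrichment ordering", {
  spec <- default_cunas_spec(replicates_per_site = 250, months = "February",
                             site_effect_sd = 0)
  s <- generate_samples(spec, seed = 7)
  z <- summarize_by_zone(s)
  stats <- cunas_zone_stats()
  up <- stats[stats$zone == "upper", ]
  lo <- stats[stats$zone == "lower", ]
  gradient <- up$element[lo$mean[match(up$element, lo$element)] > up$mean]
  for (el in gradient) {
    expect_gt(z$mean[z$zone == "lower" & z$element == el],
              z$mean[z$zone == "upper" & z$element == el])
  }
})

test_that("site effects perturb sites multiplicatively without changing the seed contract", {
  spec <- default_cunas_spec(site_effect_sd = 0.3)
  a <- generate_samples(spec, seed = 5)
  b <- generate_samples(spec, seed = 5)
  expect_identical(a, b)
  expect_true(all(unlist(a[sample_elements(a)]) > 0))
})

test_that("the worked fixture reproduces its hand-computed quantities", {
  fx <- generate_worked_fixture()
  expect_equal(nrow(fx), 3)

  idx <- compute_indices(fx)
  # Cf by construction: As 1, 2, 4 x background; Cd 2, 4, 8; Pb 1, 1, 2
  expect_equal(idx$cf[idx$element == "As"], c(1, 2, 4))
  expect_equal(idx$cf[idx$element == "Cd"], c(2, 4, 8))
  expect_equal(idx$cf[idx$element == "Pb"], c(1, 1, 2))

  eco <- assess_ecological_risk(fx)
  # Er with T = {As 10, Cd 30, Pb 5}: site sums 75, 145, 290
  expect_equal(eco$sites$ri[match(c("S1", "S2", "S3"), eco$sites$site)],
               c(75, 145, 290))
  expect_equal(eco$sites$ri_category[match(c("S1", "S2", "S3"),
                                           eco$sites$site)],
               c("low", "moderate", "considerable"))

  hh <- assess_health_risk(fx)
  shares <- split(hh$by_element, interaction(hh$by_element$site,
                                             hh$by_element$receptor))
  for (g in shares) {
    expect_equal(sum(g$hi_share), 100, tolerance = 1e-9)
    expect_equal(sum(g$tcr_share), 100, tolerance = 1e-9)
  }
})
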