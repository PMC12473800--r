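test_that("contamination factor reproduces worked ratios and bands", {
  cd <- contamination_factor(0.4, 0.1)
  expect_equal(cd$value, 4)
  expect_equal(cd$category, "high")

  as_ <- contamination_factor(15.4, 1.5)
  expect_equal(as_$value, 15.4 / 1.5)
  expect_gt(as_$value, 10)
  expect_equal(as_$category, "very high")

  same <- contamination_factor(2.7, 2.7)
  expect_equal(same$value, 1)
  expect_equal(same$category, "moderate") # left-closed band at Cf = 1

  expect_error(contamination_factor(1, 0), "positive")
  expect_error(contamination_factor(-1, 1), "non-negative")
})

test_that("contamination factor is linear in the sample concentration", {
  set.seed(1)
  c0 <- runif(20, 0.1, 50); b <- runif(20, 0.1, 100); k <- runif(20, 0.1, 9)
  expect_equal(contamination_factor(k * c0, b)$value,
               k * contamination_factor(c0, b)$value)
})

test_that("geoaccumulation index matches closed forms and the Muller classes", {
  expect_equal(geoaccumulation_index(1.5 * 0.7, 0.7)$value, 0)
  expect_equal(geoaccumulation_index(1.5 * 0.7, 0.7)$category, "unpolluted")

  g <- geoaccumulation_index(0.4, 0.1)
  expect_equal(g$value, log2(0.4 / 0.15), tolerance = 1e-12)
  expect_equal(round(g$value, 3), 1.415)
  expect_equal(g$category, "moderately polluted")

  expect_equal(geoaccumulation_index(0.75, 1.0)$value, -1)
  expect_equal(geoaccumulation_index(0.75, 1.0)$category, "unpolluted")

  expect_equal(geoaccumulation_index(0, 1)$category, "below scale")
  expect_equal(geoaccumulation_index(0, 1)$value, -Inf)
})

test_that("Igeo equals log2(Cf / 1.5) on random inputs", {
  set.seed(42)
  cs <- runif(200, 1e-3, 1e3); bg <- runif(200, 1e-3, 1e3)
  cf <- contamination_factor(cs, bg)$value
  ig <- geoaccumulation_index(cs, bg)$value
  expect_equal(ig, log2(cf / 1.5), tolerance = 1e-12)
})

test_that("enrichment factor double ratio and strict 1.5 threshold", {
  ef1 <- enrichment_factor(10, 500, 10, 500)
  expect_equal(ef1$value, 1)
  expect_false(ef1$anthropogenic)

  ef <- enrichment_factor(15.4, 9986, 1.5, 47200)
  expect_equal(ef$value, (15.4 / 9986) / (1.5 / 47200), tolerance = 1e-12)
  expect_equal(ef$value, 48.5, tolerance = 1e-3)
  expect_true(ef$anthropogenic)

  # EF exactly 1.5 is not flagged (strict inequality)
  ef_edge <- enrichment_factor(1.5, 1, 1, 1)
  expect_equal(ef_edge$value, 1.5)
  expect_false(ef_edge$anthropogenic)

  expect_error(enrichment_factor(1, 0, 1, 1), "positive")
})

test_that("pollution load index is the geometric mean of Cf", {
  expect_equal(pollution_load_index(c(1, 1, 1))$value, 1)
  expect_equal(pollution_load_index(c(1, 4))$value, 2)
  expect_error(pollution_load_index(c(1, 0)), "degenerate")
  expect_error(pollution_load_index(numeric(0)), "nonempty")

  set.seed(3)
  v <- runif(12, 0.05, 12)
  expect_equal(pollution_load_index(v)$value, oracle_geomean(v),
               tolerance = 1e-12)
  # duplication invariance of the geometric mean
  expect_equal(pollution_load_index(c(v, v))$value,
               pollution_load_index(v)$value, tolerance = 1e-12)
})

test_that("lower-zone mean Cf vector gives the expected PLI against the log-mean oracle", {
  stats <- cunas_zone_stats()
  tm <- builtin_references()$taylor_mclennan_1995
  lower <- stats[stats$zone == "lower" &
                   stats$element %in% default_index_elements(), ]
  cf <- lower$mean / tm$background[lower$element]
  pli <- pollution_load_index(cf)
  expect_equal(pli$value, oracle_geomean(cf), tolerance = 1e-12)
  expect_equal(pli$value, 0.655, tolerance = 1e-3)
})

test_that("modified contamination degree is the arithmetic mean with doubling bands", {
  expect_equal(modified_contamination_degree(c(1, 1, 1))$value, 1)
  expect_equal(modified_contamination_degree(c(2, 4))$value, 3)
  expect_equal(modified_contamination_degree(c(2, 4))$category, "moderate")
  expect_equal(modified_contamination_degree(0.5)$category, "nil to very low")
  expect_equal(modified_contamination_degree(40)$category, "ultra high")
})

test_that("mCd >= PLI for any positive Cf vector (AM-GM)", {
  set.seed(7)
  for (i in 1:50) {
    v <- rlnorm(sample(2:15, 1), meanlog = runif(1, -2, 2), sdlog = 1)
    expect_gte(modified_contamination_degree(v)$value,
               pollution_load_index(v)$value)
  }
})

test_that("band assignment is monotone in the index value", {
  cf_vals <- sort(c(0.2, 0.999, 1, 2.999, 3, 5.999, 6, 50))
  ord <- match(contamination_factor(cf_vals, 1)$category,
               c("low", "moderate", "high", "very high"))
  expect_true(all(diff(ord) >= 0))

  mcd_vals <- sort(c(0.1, 1.49, 1.5, 1.99, 2, 3.99, 4, 7.99, 8, 15.9, 16,
                     31.9, 32, 100))
  ord2 <- match(vapply(mcd_vals,
                       function(v) modified_contamination_degree(v)$category,
                       character(1)),
                c("nil to very low", "low", "moderate", "high", "very high",
                  "extremely high", "ultra high"))
  expect_true(all(diff(ord2) >= 0))
})

test_that("compute_indices assembles per-site indices against a baseline", {
  s <- toy_samples()
  idx <- compute_indices(s, per = "site")
  expect_s3_class(idx, "sedrisk_indices")
  u1_as <- idx[idx$site == "U1" & idx$element == "As", ]
  expect_equal(u1_as$cf, mean(c(1.5, 2.5)) / 1.5)
  expect_equal(u1_as$igeo, log2(u1_as$cf / 1.5))
  # EF cross-check for one cell
  expect_equal(u1_as$ef, (2 / 9200) / (1.5 / 47200), tolerance = 1e-12)
  expect_true(all(is.na(idx$ef[idx$element == "Fe"])))

  per_zone <- compute_indices(s, per = "zone")
  expect_equal(nrow(per_zone), 2 * 5)
  per_sample <- compute_indices(s, per = "sample")
  expect_equal(nrow(per_sample), nrow(s) * 5)
})

test_that("summarize_site_indices reports PLI and mCd per site", {
  s <- toy_samples()
  agg <- summarize_site_indices(compute_indices(s))
  expect_equal(nrow(agg), 4)
  l2 <- agg[agg$site == "L2", ]
  cf_l2 <- compute_indices(s)
  cf_l2 <- cf_l2$cf[cf_l2$site == "L2"]
  expect_equal(l2$pli, oracle_geomean(cf_l2), tolerance = 1e-12)
  expect_equal(l2$mcd, mean(cf_l2), tolerance = 1e-12)
})
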