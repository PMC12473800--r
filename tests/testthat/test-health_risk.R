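adult <- builtin_exposure_profiles()$adult

test_that("ingestion dose matches hand arithmetic under the default adult profile", {
  expect_equal(cdd_ingestion(0, adult), 0)
  d <- cdd_ingestion(15.4, adult, averaging = "nc")
  expect_equal(d, oracle_cdd_ing(15.4, 100, 24, 350, 70, 24 * 365, 1e-6),
               tolerance = 1e-12)
  expect_equal(d, 2.11e-5, tolerance = 1e-3)
})

test_that("non-carcinogenic dose is invariant to ED when AET_nc = ED * 365", {
  p2 <- adult
  p2$ED <- 2 * adult$ED
  p2$AET_nc <- p2$ED * 365
  expect_equal(cdd_ingestion(7.7, p2, "nc"), cdd_ingestion(7.7, adult, "nc"),
               tolerance = 1e-12)
})

test_that("inhalation/ingestion dose ratio is element-independent", {
  set.seed(21)
  cm <- runif(10, 0.01, 500)
  ratio <- cdd_inhalation(cm, adult, "nc") / cdd_ingestion(cm, adult, "nc")
  expect_equal(ratio,
               rep(adult$IHR / (adult$IR * adult$CFU * adult$PEF), 10),
               tolerance = 1e-12)
})

test_that("dermal dose with DAF = 1 is the ingestion formula with IR -> SA x SAF", {
  p <- adult
  p$DAF <- c(default = 1)
  p$IR <- p$SA * p$SAF
  expect_equal(cdd_dermal(3.3, p, "Pb", "nc"), cdd_ingestion(3.3, p, "nc"),
               tolerance = 1e-12)
})

test_that("each dose route matches an independent single-expression oracle", {
  set.seed(123)
  for (i in 1:1000) {
    p <- random_profile()
    cm <- runif(1, 0, 1000)
    for (avg in c("nc", "ca")) {
      aet <- if (avg == "nc") p$AET_nc else p$AET_ca
      expect_equal(cdd_ingestion(cm, p, avg),
                   oracle_cdd_ing(cm, p$IR, p$ED, p$EF_days, p$ABW, aet,
                                  p$CFU),
                   tolerance = 1e-12)
      expect_equal(cdd_inhalation(cm, p, avg),
                   oracle_cdd_inh(cm, p$IHR, p$ED, p$EF_days, p$ABW, aet,
                                  p$PEF),
                   tolerance = 1e-12)
      expect_equal(cdd_dermal(cm, p, "As", avg),
                   oracle_cdd_derm(cm, p$SA, p$SAF, p$DAF[["As"]], p$ED,
                                   p$EF_days, p$ABW, aet, p$CFU),
                   tolerance = 1e-12)
    }
  }
})

test_that("carcinogenic averaging never exceeds non-carcinogenic dosing", {
  set.seed(31)
  for (i in 1:20) {
    p <- random_profile()
    cm <- runif(1, 0, 100)
    expect_lte(cdd_ingestion(cm, p, "ca"), cdd_ingestion(cm, p, "nc"))
    expect_lte(cdd_inhalation(cm, p, "ca"), cdd_inhalation(cm, p, "nc"))
  }
})

test_that("hazard quotient and index follow their definitions and thresholds", {
  expect_equal(hazard_quotient(3e-4, 3e-4), 1)
  expect_equal(hazard_quotient(0, 3e-4), 0)
  expect_error(hazard_quotient(1, 0), "positive")

  hq_as <- hazard_quotient(cdd_ingestion(15.4, adult, "nc"), 3e-4)
  expect_equal(hq_as, 0.0703, tolerance = 1e-3)

  one <- tibble::tibble(element = "As", route = "ing", hq = 0.4)
  hi1 <- hazard_index(one)
  expect_equal(hi1$total$hi, 0.4)
  expect_equal(hi1$total$hi_category, "insignificant")

  expect_equal(hazard_index(tibble::tibble(element = "As", route = "ing",
                                           hq = 0.99))$total$hi_category,
               "insignificant")
  expect_equal(hazard_index(tibble::tibble(element = "As", route = "ing",
                                           hq = 1.01))$total$hi_category,
               "possible chronic adverse effect")

  three <- tibble::tibble(element = "As", route = c("ing", "inh", "derm"),
                          hq = c(0.2, 0.05, 0.1))
  expect_equal(hazard_index(three)$total$hi,
               hazard_index(three[c(3, 1, 2), ])$total$hi)
})

test_that("carcinogenic risk combines routes with the configured slope factors", {
  dr <- dose_response_table()

  zero <- carcinogenic_risk(0, 0, 0, dr, "As")
  expect_equal(zero$tcr, 0)
  expect_equal(zero$tcr_category, "no significant risk")

  d_ing <- cdd_ingestion(15.4, adult, "ca")
  as_only_ing <- carcinogenic_risk(d_ing, 0, 0, dr, "As")
  expect_equal(as_only_ing$cr_ing, d_ing * 1.5, tolerance = 1e-12)
  expect_equal(as_only_ing$cr_ing, 1.08e-5, tolerance = 1e-2)
  expect_equal(as_only_ing$tcr_category, "acceptable")

  # elements without an oral slope factor skip ingestion and dermal
  cd <- carcinogenic_risk(1e-6, 1e-9, 1e-7, dr, "Cd")
  expect_equal(cd$cr_ing, 0)
  expect_equal(cd$cr_derm, 0)
  expect_equal(cd$cr_inh, 1e-9 * dr$iur[dr$element == "Cd"])
  expect_match(cd$routes_skipped, "ingestion")

  # dermal slope factor convention: SF_ing / GIABS vs unadjusted
  cr_g <- carcinogenic_risk(0, 0, 1e-7, dr, "Cr", dermal_sf = "giabs")
  cr_u <- carcinogenic_risk(0, 0, 1e-7, dr, "Cr", dermal_sf = "unadjusted")
  expect_equal(cr_g$cr_derm,
               cr_u$cr_derm / dr$giabs[dr$element == "Cr"],
               tolerance = 1e-12)

  expect_equal(carcinogenic_risk(5e-5 / 1.5, 0, 0, dr, "As")$tcr_category,
               "acceptable")
})

test_that("contribution shares normalise to 100 percent", {
  hi <- tibble::tibble(element = c("As", "Cd"), hi = c(0.3, 0.1))
  tcr <- tibble::tibble(element = c("As", "Cd"), tcr = c(2e-5, 6e-5))
  shares <- risk_contributions(hi, tcr)
  expect_equal(sum(shares$hi_share), 100, tolerance = 1e-9)
  expect_equal(sum(shares$tcr_share), 100, tolerance = 1e-9)
  expect_equal(shares$hi_share[shares$element == "As"], 75)

  single <- risk_contributions(hi[1, ], tcr[1, ])
  expect_equal(single$hi_share, 100)

  four <- tibble::tibble(element = c("As", "Cd", "Cr", "Pb"), hi = rep(2, 4))
  expect_equal(risk_contributions(four, dplyr::rename(four, tcr = hi))$hi_share,
               rep(25, 4))

  none <- risk_contributions(tibble::tibble(element = "As", hi = 0),
                             tibble::tibble(element = "As", tcr = 0))
  expect_true(is.na(none$hi_share) && is.na(none$tcr_share))
})

test_that("the full health assessment is additive and homogeneous in concentration", {
  s <- toy_samples()
  hh <- assess_health_risk(s)

  # HI per element is the sum of its route HQs; totals sum over elements
  hi_check <- tapply(hh$doses$hq,
                     interaction(hh$doses$site, hh$doses$receptor,
                                 hh$doses$element, drop = TRUE), sum)
  for (i in seq_len(nrow(hh$by_element))) {
    key <- paste(hh$by_element$site[i], hh$by_element$receptor[i],
                 hh$by_element$element[i], sep = ".")
    expect_equal(unname(hi_check[key]), hh$by_element$hi[i],
                 tolerance = 1e-12)
  }
  tot <- tapply(hh$by_element$hi,
                interaction(hh$by_element$site, hh$by_element$receptor,
                            drop = TRUE), sum)
  for (i in seq_len(nrow(hh$summary))) {
    key <- paste(hh$summary$site[i], hh$summary$receptor[i], sep = ".")
    expect_equal(unname(tot[key]), hh$summary$hi[i], tolerance = 1e-12)
  }

  # contribution shares sum to 100 within each (site, receptor)
  by_grp <- split(hh$by_element,
                  interaction(hh$by_element$site, hh$by_element$receptor))
  for (g in by_grp) {
    expect_equal(sum(g$hi_share), 100, tolerance = 1e-9)
    expect_equal(sum(g$tcr_share), 100, tolerance = 1e-9)
  }

  # degree-1 homogeneity: scaling all concentrations scales HI and TCR
  s3 <- s
  for (el in sample_elements(s3)) s3[[el]] <- 3 * s3[[el]]
  hh3 <- assess_health_risk(s3)
  expect_equal(hh3$summary$hi, 3 * hh$summary$hi, tolerance = 1e-12)
  expect_equal(hh3$summary$tcr, 3 * hh$summary$tcr, tolerance = 1e-12)
})
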