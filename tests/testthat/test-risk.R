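test_that("exposure concentration applies the EPA time-adjustment factors", {
  cont <- exposure_factors(24, 365, 70, 70)
  expect_equal(exposure_concentration(10, cont), 10)
  expect_equal(exposure_concentration(0, cont), 0)
  ef <- exposure_factors(16, 365, 70, 70)
  expect_equal(exposure_concentration(10, ef), 10 * 16 / 24)
  expect_equal(exposure_concentration(10, ef), 6.667, tolerance = 1e-3)
  expect_error(exposure_factors(0), "hours")
  expect_error(exposure_factors(16, 400), "days")
  expect_error(exposure_factors(16, 365, 80, 70), "exceed")
})

test_that("LCR equals IUR x C under continuous lifetime exposure", {
  tab <- read_risk_table()
  cont <- exposure_factors(24, 365, 70, 70)
  iur_benzene <- tab$iur[tab$voc == "benzene"]
  res <- lifetime_cancer_risk(5, "benzene", tab, cont)
  expect_equal(res$lcr, iur_benzene * 5)
  # unit definition: EC = 1 at IUR 1e-6 sits exactly on the threshold,
  # and "exceeds" is strictly greater
  tab1 <- tab; tab1$iur[tab1$voc == "benzene"] <- 1e-6
  class(tab1) <- class(tab)
  at <- lifetime_cancer_risk(1, "benzene", tab1, cont)
  expect_equal(at$lcr, 1e-6)
  expect_false(at$exceeds_lcr_1e6)
  # zero unit risk: zero risk, no exceedance
  tab0 <- tab; tab0$iur[tab0$voc == "benzene"] <- 0
  expect_false(lifetime_cancer_risk(100, "benzene", tab0, cont)$exceeds_lcr_1e6)
  expect_equal(lifetime_cancer_risk(100, "benzene", tab0, cont)$lcr, 0)
})

test_that("LCR and HQ are linear in concentration and exposure time", {
  tab <- read_risk_table()
  ef8 <- exposure_factors(8, 365, 70, 70)
  ef16 <- exposure_factors(16, 365, 70, 70)
  expect_equal(lifetime_cancer_risk(3, "benzene", tab, ef16)$lcr,
               2 * lifetime_cancer_risk(3, "benzene", tab, ef8)$lcr)
  expect_equal(lifetime_cancer_risk(6, "benzene", tab, ef8)$lcr,
               2 * lifetime_cancer_risk(3, "benzene", tab, ef8)$lcr)
  expect_equal(hazard_quotient(6, "benzene", tab, ef8)$hq,
               2 * hazard_quotient(3, "benzene", tab, ef8)$hq)
  # halving the reference concentration doubles HQ
  tabh <- tab; tabh$rfc[tabh$voc == "benzene"] <- tab$rfc[tab$voc == "benzene"] / 2
  class(tabh) <- class(tab)
  expect_equal(hazard_quotient(3, "benzene", tabh, ef8)$hq,
               2 * hazard_quotient(3, "benzene", tab, ef8)$hq)
})

test_that("HQ uses ED as averaging time and flags strictly above 1", {
  tab <- read_risk_table()
  ef <- exposure_factors(24, 365, 30, 70)  # AT only matters for cancer
  rfc <- tab$rfc[tab$voc == "xylene"]
  res <- hazard_quotient(rfc, "xylene", tab, ef)
  expect_equal(res$hq, 1)          # EC = C because AT collapses to ED
  expect_false(res$exceeds_hq_1)   # boundary is not an exceedance
  expect_equal(hazard_quotient(0, "xylene", tab, ef)$hq, 0)
  expect_true(hazard_quotient(rfc * 1.01, "xylene", tab, ef)$exceeds_hq_1)
})

test_that("missing benchmarks give explicit not-assessable results", {
  tab <- read_risk_table()
  res <- lifetime_cancer_risk(10, "toluene", tab)  # no IUR for toluene
  expect_false(res$assessable)
  expect_true(is.na(res$lcr))
  expect_false(res$exceeds_lcr_1e6)
  res2 <- hazard_quotient(10, "chloroform", tab)   # no RfC
  expect_false(res2$assessable)
  expect_true(is.na(res2$hq))
})

test_that("exceedance fractions match brute-force counting", {
  tab <- read_risk_table()
  cont <- exposure_factors(24, 365, 70, 70)
  iur <- tab$iur[tab$voc == "benzene"]
  conc <- c(2, 2, 2, 0.5) / (iur * 1e6)  # 3 of 4 homes above 1e-6
  res <- lifetime_cancer_risk(conc, rep("benzene", 4), tab, cont,
                              home_id = paste0("h", 1:4))
  sm <- exceedance_summary(lcr_results = res)
  expect_equal(sm$fraction_exceed[sm$metric == "lcr"], 0.75)

  # all below: zero exceedance
  low <- lifetime_cancer_risk(rep(1e-9, 4), rep("benzene", 4), tab, cont)
  expect_equal(exceedance_summary(lcr_results = low)$fraction_exceed, 0)

  # random cohort: summary equals a direct tabulation
  set.seed(21)
  vocs <- sample(c("benzene", "acetaldehyde", "1,3-butadiene"), 60, TRUE)
  cc <- rlnorm(60, 0, 1.5)
  res <- lifetime_cancer_risk(cc, vocs, tab, cont)
  sm <- exceedance_summary(lcr_results = res)
  for (v in unique(vocs)) {
    direct <- mean(res$lcr[res$voc == v] > 1e-6)
    expect_equal(sm$fraction_exceed[sm$voc == v], direct)
  }
  # VOCs without the benchmark never appear in the summary
  res_mix <- lifetime_cancer_risk(c(1, 1), c("benzene", "toluene"), tab, cont)
  expect_false("toluene" %in% exceedance_summary(lcr_results = res_mix)$voc)
})
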