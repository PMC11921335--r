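test_that("season assignment follows the month-based mapping", {
  expect_equal(assign_season(as.Date("2023-06-15")), "summer")
  expect_equal(assign_season(as.Date("2023-12-01")), "winter")
  expect_equal(assign_season(as.Date("2024-02-29")), "winter") # leap day
  months <- as.Date(sprintf("2023-%02d-10", 1:12))
  expect_equal(assign_season(months),
               c("winter", "winter", "spring", "spring", "spring",
                 "summer", "summer", "summer", "autumn", "autumn",
                 "autumn", "winter"))
  expect_error(assign_season("not a date"), "date")
})

test_that("spec validation names the offending field", {
  expect_error(small_spec(urban_fraction = 1.5), "urban_fraction")
  expect_error(small_spec(spike_prob = -0.1), "spike_prob")
  expect_error(small_spec(spike_multiplier = 0.5), "spike_multiplier")
  expect_error(small_spec(volume_range = c(-5, 10)), "volume_range")
  expect_error(small_spec(occupancy_fraction_range = c(0, 2)),
               "occupancy_fraction_range")
  expect_error(cohort_spec(voc_panel = data.frame()), "voc_panel")
  bad_sa <- data.frame(season = "winter", median = 1, gsd = 1.3)
  expect_error(small_spec(seasonal_acr = bad_sa), "seasonal_acr")
})

test_that("generation is deterministic, positive, and empty for n_homes = 0", {
  empty <- generate_cohort(small_spec(n_homes = 0))
  expect_s3_class(empty, "voc_cohort")
  expect_equal(nrow(empty$homes), 0L)
  expect_equal(nrow(empty$concentrations), 0L)

  a <- generate_cohort(small_spec(n_homes = 40, seed = 7))
  b <- generate_cohort(small_spec(n_homes = 40, seed = 7))
  expect_identical(a, b)
  c2 <- generate_cohort(small_spec(n_homes = 40, seed = 8))
  expect_false(identical(a$homes$true_acr, c2$homes$true_acr))

  expect_true(all(a$concentrations$indoor > 0))
  expect_true(all(a$concentrations$outdoor > 0))
  expect_true(all(a$homes$true_acr > 0))
  expect_true(all(a$homes$co2_indoor > 450))
  expect_true(all(a$homes$season == assign_season(a$homes$sample_date)))
})

test_that("generated CO2 is forward-consistent with the stored true ACR", {
  coh <- generate_cohort(small_spec(n_homes = 60, seed = 2))
  back <- infer_acr(coh$homes)
  expect_lt(max(abs(back$acr - coh$homes$true_acr) / coh$homes$true_acr),
            1e-9)
})

test_that("null configuration removes the urban/rural outdoor aromatic shift", {
  coh <- generate_cohort(small_spec(n_homes = 600, seed = 13,
                                    urban_aromatic_multiplier = 1,
                                    spike_prob = 0))
  btex <- coh$concentrations[coh$concentrations$class == "btex", ]
  summed <- tapply(btex$outdoor, btex$home_id, sum)
  urban <- coh$homes$urban[match(names(summed), coh$homes$home_id)]
  res <- brunner_munzel(summed[!urban], summed[urban])
  expect_gt(res$p_raw, 0.05)
  expect_equal(res$effect, 0.5, tolerance = 0.05)
})

test_that("a configured urban aromatic shift is recoverable at scale", {
  coh <- generate_cohort(small_spec(n_homes = 600, seed = 17,
                                    urban_aromatic_multiplier = 2,
                                    urban_fraction = 0.5))
  btex <- coh$concentrations[coh$concentrations$class == "btex", ]
  summed <- tapply(btex$outdoor, btex$home_id, sum)
  urban <- coh$homes$urban[match(names(summed), coh$homes$home_id)]
  ratio <- median(summed[urban]) / median(summed[!urban])
  expect_equal(ratio, 2, tolerance = 0.2)
})

test_that("spiked homes have multiplicatively elevated indoor aromatics", {
  sp <- small_spec(n_homes = 200, seed = 23, spike_prob = 0.05,
                   spike_multiplier = 50)
  coh <- generate_cohort(sp)
  expect_gt(sum(coh$homes$spike), 0)
  xyl <- coh$concentrations[coh$concentrations$voc == "xylene", ]
  spike <- coh$homes$spike[match(xyl$home_id, coh$homes$home_id)]
  expect_gt(median(xyl$indoor[spike]), 10 * median(xyl$indoor[!spike]))
})

test_that("cohort tables round-trip through CSV and specs through YAML", {
  coh <- generate_cohort(small_spec(n_homes = 8, seed = 3))
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$homes$home_id, coh$homes$home_id)
  expect_equal(back$homes$true_acr, coh$homes$true_acr, tolerance = 1e-12)
  expect_equal(back$concentrations$indoor, coh$concentrations$indoor,
               tolerance = 1e-12)
  expect_s3_class(back$homes$sample_date, "Date")

  spec <- read_cohort_spec(system.file("extdata",
                                       "cohort_spec_example.yaml",
                                       package = "ivoc"))
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_homes, 124L)
  expect_equal(spec$seasonal_acr$median[spec$seasonal_acr$season == "winter"],
               0.70)
  expect_equal(spec$acr_params$co2_outdoor, 450)
})
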