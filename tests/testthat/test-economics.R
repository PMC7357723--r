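test_that("total fertilizer cost is product bags plus application labor", {
  cat <- product_catalog_default()
  econ <- econ_params()
  rec0 <- trial_record("f1", "kuruvai", "ffp", 4.5, nutrient_rates(0, 0, 0),
                       n_applications = 0L)
  expect_equal(total_fertilizer_cost(rec0, cat, econ), 0)
  # labor only: four applications
  rec4 <- trial_record("f1", "kuruvai", "bfr", 4.5, nutrient_rates(1, 0, 0),
                       n_applications = 4L)
  expect_equal(total_fertilizer_cost(rec4, cat, econ), 38)
  # one 50-kg bag of urea per ha + one application
  rec1 <- trial_record("f1", "kuruvai", "ffp", 4.5, nutrient_rates(23, 0, 0),
                       products = c(urea = 50), n_applications = 1L)
  expect_equal(total_fertilizer_cost(rec1, cat, econ), 13.8)
  # per-field masses are normalized by area
  rec_half <- trial_record("f1", "kuruvai", "ffp", 4.5, nutrient_rates(23, 0, 0),
                           products = c(urea = 25), n_applications = 1L,
                           field_area = 0.5)
  expect_equal(total_fertilizer_cost(rec_half, cat, econ), 13.8)
  rec_bad <- trial_record("f1", "kuruvai", "ffp", 4.5, nutrient_rates(23, 0, 0),
                          products = c(notafert = 10), n_applications = 1L)
  expect_error(total_fertilizer_cost(rec_bad, cat, econ), "unknown product")
})

test_that("PFP is 1000 GY / FN and undefined without fertilizer N", {
  expect_equal(round(pfp(5.3, 120)), 44)
  expect_equal(round(pfp(3.9, 130)), 30)
  expect_equal(pfp(0, 120), 0)
  expect_error(pfp(5.3, 0), "undefined")
  # strictly monotone: decreasing in FN, increasing in GY
  fn <- seq(60, 180, by = 10)
  expect_true(all(diff(vapply(fn, pfp, numeric(1), grain_yield = 5)) < 0))
  gy <- seq(2, 7, by = 0.5)
  expect_true(all(diff(vapply(gy, pfp, numeric(1), fertilizer_n = 120)) > 0))
})

test_that("gross return above fertilizer cost and added net benefit", {
  expect_equal(gross_return_above_fert(0, 0), 0)
  expect_equal(gross_return_above_fert(5.0, 111), 999)
  expect_equal(gross_return_above_fert(1.0, 222), 0)
  expect_equal(added_net_benefit(1055, 906), 149)
  expect_equal(added_net_benefit(1055, 993), 62)
  expect_equal(added_net_benefit(700, 700), 0)
  # antisymmetry under treatment swap
  set.seed(4)
  a <- rnorm(20, 1000, 100); b <- rnorm(20, 950, 100)
  expect_equal(added_net_benefit(a, b), -added_net_benefit(b, a))
})

test_that("exceedance curves are inclusive, non-increasing, with loss prob", {
  v <- c(-10, 5, 25, 40)
  curve <- exceedance_curve(v, thresholds = c(-20, 0, 25, 50))
  expect_equal(curve$probability, c(1, 0.75, 0.5, 0))
  expect_equal(attr(curve, "loss_probability"), 0.25)
  expect_equal(loss_probability(v), 0.25)
  all_pos <- exceedance_curve(c(10, 20, 30), thresholds = 0)
  expect_equal(all_pos$probability, 1)
  expect_equal(attr(all_pos, "loss_probability"), 0)
  # ties count as exceeding
  expect_equal(exceedance_curve(c(25, 25, 0, 50), thresholds = 25)$probability,
               0.75)
  # property: non-increasing in the threshold for arbitrary samples
  set.seed(9)
  for (i in 1:10) {
    vals <- rnorm(50, 50, 120)
    curve <- exceedance_curve(vals)
    expect_true(all(diff(curve$probability) <= 0))
    expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  }
  expect_error(exceedance_curve(numeric(0)), "non-empty")
})

test_that("percent of target matches the attainment ratios", {
  expect_equal(round(percent_of_target(5.3, 5.4)), 98)
  expect_equal(round(percent_of_target(5.3, 5.8)), 91)
  expect_equal(round(percent_of_target(3.9, 5.8)), 67)
  expect_equal(percent_of_target(5.5, 5.5), 100)
  expect_error(percent_of_target(5.3, 0), "target")
})

test_that("population summaries average per-field values; ANB is linear", {
  pop <- sample_population(default_population_spec(n_fields = 12, seed = 77))
  res <- summarize_trials(pop$trials)
  expect_setequal(unique(res$summary$treatment), c("ssnm", "bfr", "ffp"))
  expect_setequal(unique(res$summary$season),
                  c("kuruvai", "samba", "thaladi"))
  # mean ANB equals the difference of mean GRFs on a balanced population
  per <- res$per_field
  for (s in unique(per$season)) {
    g <- function(tr) mean(per$grf[per$season == s & per$treatment == tr])
    anb <- res$anb
    expect_equal(
      anb$mean_anb[anb$season == s & anb$comparison == "ssnm-ffp"],
      round(g("ssnm") - g("ffp")))
  }
  expect_true(all(res$anb$loss_probability >= 0 & res$anb$loss_probability <= 1))
})
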