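test_that("stage days place panicle initiation from the in-field duration", {
  expect_equal(
    stage_days(make_variety(135), "transplanted", seedling_age = 25)[["pi"]],
    45)  # (135 - 25) - 65
  expect_equal(
    stage_days(make_variety(110), "transplanted", seedling_age = 25)[["pi"]],
    20)  # short-duration transplanted crop: compressed season
  expect_equal(
    stage_days(make_variety(110), "dry_seeded")[["pi"]],
    45)  # direct seeding keeps the full duration in the field
})

test_that("stage days are ordered and the early dose is within 11 days", {
  d <- stage_days(make_variety(135), "transplanted", seedling_age = 25)
  expect_true(all(diff(d) > 0))
  expect_lte(d[["early"]], 11)
  expect_equal(d[["tillering"]], floor((7 + 45) / 2))
  expect_error(stage_days(make_variety(110), "transplanted", seedling_age = 110),
               "seedling_age")
  expect_error(stage_days(make_variety(100), "transplanted", seedling_age = 30),
               "too short")
})

test_that("N splits 24/38/38 normally and into thirds when PI is early", {
  expect_equal(split_n(120, 45), c(29, 45.5, 45.5))  # repaired to sum 120
  expect_equal(split_n(120, 20), c(40, 40, 40))
  expect_equal(split_n(0, 45), c(0, 0, 0))
  # the boundary is strict: PI exactly at 30 keeps the standard split
  expect_equal(split_n(100, 30), c(24, 38, 38))
  expect_equal(split_n(100, 29), split_n(100, 10))
  expect_error(split_n(-5, 45), "non-negative")
})

test_that("N split doses always conserve the total on the half-kg grid", {
  set.seed(11)
  # rates arrive in whole kilograms from the rate equations: exact repair
  for (total in round(runif(50, 0, 200))) {
    for (pi_day in c(20, 45)) {
      doses <- split_n(total, pi_day)
      expect_equal(sum(doses), total, tolerance = 1e-9)
      expect_true(all(doses >= 0))
    }
  }
  # off-grid totals land on the dose grid within a quarter kilogram
  for (total in runif(20, 0, 200)) {
    doses <- split_n(total, 45)
    expect_lte(abs(sum(doses) - total), 0.25)
  }
})

test_that("P goes entirely early and K splits by the early fraction", {
  s <- split_pk(14, 30, 0.55)
  expect_equal(s$early, c(p = 14, k = 16.5))
  expect_equal(s$pi, c(p = 0, k = 13.5))
  s <- split_pk(10, 42, 0.5)
  expect_equal(s$early[["k"]], 21)
  expect_equal(s$pi[["k"]], 21)
  s <- split_pk(14, 0)
  expect_equal(s$early[["k"]] + s$pi[["k"]], 0)
  expect_error(split_pk(14, 30, 1.2), "fraction")
})

test_that("the SSNM schedule has exactly three conserving events", {
  iv <- make_interview(variety = make_variety(135), seedling_age = 25)
  rates <- nutrient_rates(n = 120, p = 14, k = 30)
  sch <- ssnm_schedule(rates, iv, make_params())
  expect_equal(sch$n_applications, 3)
  tot <- schedule_totals(sch)
  expect_equal(tot$n, 120)
  expect_equal(tot$p, 14)
  expect_equal(tot$k, 30)
  expect_equal(sch$events$stage,
               c("early", "active_tillering", "panicle_initiation"))
  expect_lte(sch$events$dae[1], 11)
  expect_true(all(diff(sch$events$dae) > 0))
})

test_that("the blanket recommendation is four equal N and K splits, P basal", {
  sch <- bfr_schedule()
  expect_equal(sch$n_applications, 4)
  expect_equal(sch$events$n, rep(37.5, 4))
  expect_equal(sch$events$k, rep(10.5, 4))
  expect_equal(sch$events$p, c(22, 0, 0, 0))
  tot <- schedule_totals(sch)
  expect_equal(c(tot$n, tot$p, tot$k), c(150, 22, 42))
})
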