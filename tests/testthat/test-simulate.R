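test_that("pyramids follow stratum-specific geometric growth", {
  st <- default_strata()
  st$growth <- 0
  cfg0 <- eas_scenario(strata = st, horizon_year = 2020L)
  pyrs <- simulate_pyramids(cfg0)
  for (p in pyrs) expect_equal(p$count, pyrs[["2015"]]$count)

  # default growth reaches the configured 36-year factors (e.g. 10.13 for
  # women aged 85+), up to integer rounding of yearly counts
  cfg <- eas_scenario()
  pyrs <- simulate_pyramids(cfg)
  ratio <- pyrs[["2051"]]$count / pyrs[["2015"]]$count
  expect_equal(ratio, c(0.76, 1.77, 2.77, 4.20, 0.66, 1.78, 2.91, 10.13),
               tolerance = 1e-4)

  one <- eas_scenario(
    base_year = 2015L, horizon_year = 2017L,
    strata = data.frame(age_band = "0+", sex = "male", base_pop = 1000,
                        growth = 1, c0 = 1, c1 = 0, c2 = 0))
  expect_equal(simulate_pyramids(one)[["2017"]]$count, 4000)
})

test_that("weights recovered from simulated pyramids are exact count ratios", {
  cfg <- small_scenario(horizon_year = 2051L)
  pyrs <- simulate_pyramids(cfg)
  w <- compute_weights(pyrs[["2015"]], pyrs[["2051"]], cfg$scheme)
  for (i in seq_len(nrow(cfg$strata))) {
    expect_identical(
      easproj:::weight_for(w, cfg$strata$age_band[i], cfg$strata$sex[i]),
      pyrs[["2051"]]$count[i] / pyrs[["2015"]]$count[i])
  }
  # and they track the configured ground truth closely
  gt <- ground_truth(cfg, years = 2051)
  expect_equal(w$weight[w$sex != "both"][order(match(
    paste(w$age_band, w$sex)[w$sex != "both"],
    paste(gt$weights$age_band, gt$weights$sex)))],
    gt$weights$weight, tolerance = 1e-3)
})

test_that("the seasonal temperature generator behaves deterministically", {
  cfg <- eas_scenario(temp_amplitude = 0, temp_sd = 0)
  t0 <- simulate_temperature(cfg, 2015)
  expect_equal(nrow(t0), 365L)
  expect_true(all(t0$temp == 23))

  cfg <- eas_scenario(temp_sd = 0)
  t1 <- simulate_temperature(cfg, 2015)
  expect_equal(which.max(t1$temp), 196L)  # warmest at the phase day
  expect_equal(which.min(t1$temp), 13L)   # coldest half a cycle away
  expect_equal(max(t1$temp), 29, tolerance = 1e-4)

  cfg <- eas_scenario()
  means <- vapply(1:20, function(s)
    mean(simulate_temperature(cfg, 2015, seed = 1000L + s)$temp), numeric(1))
  expect_true(all(abs(means - 23) < 0.5))
})

test_that("record volumes follow the configured Poisson rates", {
  none <- eas_scenario(
    base_year = 2015L, horizon_year = 2016L, frac_incomplete = 0,
    strata = data.frame(age_band = "0+", sex = "male", base_pop = 1000,
                        growth = 0, c0 = 0, c1 = 0, c2 = 0))
  expect_equal(nrow(simulate_records(none, 2015)), 0L)

  flat <- eas_scenario(
    base_year = 2015L, horizon_year = 2016L, frac_incomplete = 0,
    strata = data.frame(age_band = "0+", sex = "male", base_pop = 1000,
                        growth = 0, c0 = 10, c1 = 0, c2 = 0))
  n <- nrow(simulate_records(flat, 2015))
  expect_lt(abs(n - 3650), 4 * sqrt(3650))

  # per-day counts show unit Poisson dispersion (rates nearly flat by design)
  rec <- simulate_records(flat, 2015)
  per_day <- table(factor(format(rec$date), levels = format(seq(
    as.Date("2015-01-01"), as.Date("2015-12-31"), 1))))
  disp <- var(as.numeric(per_day)) / mean(per_day)
  expect_gt(disp, 0.75); expect_lt(disp, 1.3)
})

test_that("default scenario regenerates the reference base-year margins", {
  cfg <- eas_scenario()
  rec <- simulate_records(cfg, 2015)
  y <- aggregate_demand(rec, period = "yearly")
  ref <- taipei_reference("demand_2015")
  strata <- ref[ref$age_band != "ALL" & ref$sex != "both", ]
  got <- y$count[match(paste(strata$age_band, strata$sex),
                       paste(y$age_band, y$sex))]
  expect_true(all(abs(got - strata$count) / strata$count < 0.05))
  # incomplete records appear at the configured rate
  expect_equal(attr(y, "n_dropped") / nrow(rec), cfg$frac_incomplete,
               tolerance = 0.05)
  # triage and trauma follow the configured frequencies
  expect_equal(mean(rec$trauma), cfg$p_trauma, tolerance = 0.01)
  expect_equal(as.numeric(prop.table(table(rec$triage))), cfg$triage_probs,
               tolerance = 0.05)
})

test_that("generation is fully deterministic given config and seed", {
  cfg <- small_scenario(seed = 123L)
  r1 <- simulate_records(cfg, 2015)
  r2 <- simulate_records(cfg, 2015)
  expect_identical(r1, r2)

  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_scenario(cfg, d1)
  p2 <- write_scenario(cfg, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))

  r3 <- simulate_records(cfg, 2015, seed = 124L)
  expect_false(identical(r1$age, r3$age))
})

test_that("scenario files round-trip through the package readers", {
  cfg <- small_scenario()
  dir <- tempfile()
  paths <- write_scenario(cfg, dir, years = 2015)
  rec <- read_records(paths$records_2015)
  tmp <- read_temperature(paths$temperature_2015)
  pyr <- read_pyramids(paths$pyramids)
  expect_equal(nrow(tmp), 365L)
  expect_equal(length(pyr), cfg$horizon_year - cfg$base_year + 1L)
  direct <- simulate_records(cfg, 2015)
  expect_equal(nrow(rec), nrow(direct))
  expect_equal(sum(is.na(rec$age)), sum(is.na(direct$age)))
  expect_identical(pyr[["2015"]]$count, simulate_pyramids(cfg)[["2015"]]$count)
})

test_that("ground truth matches an independent direct-summation oracle", {
  cfg <- small_scenario(horizon_year = 2017L)
  gt <- ground_truth(cfg)
  # identity scenario: all true weights are 1
  st0 <- cfg$strata; st0$growth <- 0
  gt0 <- ground_truth(eas_scenario(strata = st0, horizon_year = 2017L))
  expect_true(all(gt0$weights$weight == 1))
  expect_identical(gt$rates$c0, cfg$strata$c0)

  # oracle: explicit loop over noise-free days for one stratum-year
  i <- 4L  # male 85+
  temps <- simulate_temperature(eas_scenario(strata = cfg$strata,
                                             temp_sd = 0), 2017)
  acc <- 0
  for (d in seq_len(nrow(temps))) {
    lam <- cfg$strata$c0[i] + cfg$strata$c1[i] * temps$temp[d] +
      cfg$strata$c2[i] * temps$temp[d]^2
    acc <- acc + max(0, lam)
  }
  acc <- acc * (1 + cfg$strata$growth[i])^2
  expect_equal(gt$expected_yearly$expected[
    gt$expected_yearly$year == 2017 &
      gt$expected_yearly$age_band == "85+" &
      gt$expected_yearly$sex == "male"], acc)

  # sampled records agree with the expectation within Monte-Carlo error
  rec <- simulate_records(cfg, 2015)
  y <- aggregate_demand(rec, cfg$scheme, "yearly")
  exp15 <- gt$expected_yearly[gt$expected_yearly$year == 2015, ]
  got <- y$count[match(paste(exp15$age_band, exp15$sex),
                       paste(y$age_band, y$sex))]
  expect_true(all(abs(got - exp15$expected) <
                    5 * sqrt(exp15$expected) + 0.05 * exp15$expected))
})
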