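dates_2015 <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")

daily_from_quad <- function(c0, b1, b2, temp, dates = dates_2015[seq_along(temp)]) {
  list(daily = data.frame(date = dates, count = c0 + b1 * temp + b2 * temp^2),
       temps = data.frame(date = dates, temp = temp))
}

test_that("the quadratic fit recovers noiseless coefficients exactly", {
  temp <- rep(5:35, length.out = 365)
  d <- daily_from_quad(45.12, -1.48, 0.03, temp)
  # noiseless data: lm warns that the fit is exact, which is the point here
  m <- suppressWarnings(fit_quadratic(d$daily, d$temps))
  expect_equal(m$constant, 45.12, tolerance = 1e-10)
  expect_equal(m$b1, -1.48, tolerance = 1e-10)
  expect_equal(m$b2, 0.03, tolerance = 1e-10)
  expect_equal(m$adj_r2, 1, tolerance = 1e-8)

  # flat response: zero slope and curvature, no explained variance
  d0 <- daily_from_quad(10, 0, 0, temp)
  m0 <- suppressWarnings(fit_quadratic(d0$daily, d0$temps))
  expect_equal(c(m0$constant, m0$b1, m0$b2), c(10, 0, 0), tolerance = 1e-10)

  expect_error(
    fit_quadratic(data.frame(date = dates_2015[1:9], count = 1:9),
                  data.frame(date = dates_2015[1:9], temp = rep(c(10, 20), length.out = 9))),
    "distinct temperature")
})

test_that("OLS agrees with the normal-equations oracle on small instances", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(4:50, 1)
    temp <- runif(n, 0, 35)
    y <- rpois(n, 20) + 0.5 * temp
    d <- data.frame(date = dates_2015[1:n], count = y)
    tm <- data.frame(date = dates_2015[1:n], temp = temp)
    m <- fit_quadratic(d, tm)
    X <- cbind(1, temp, temp^2)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(c(m$constant, m$b1, m$b2), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("fitted coefficients fall inside their own CIs at the nominal rate", {
  # 200 replicate stratum-years of Poisson counts from a known U-shaped rate
  set.seed(20151231)
  truth <- c(45.12, -1.48, 0.03)
  cov_b1 <- cov_b2 <- 0L
  for (r in 1:200) {
    temp <- 23 + 6 * cos(2 * pi * (seq_len(365) - 196) / 365.25) + rnorm(365, 0, 2)
    lam <- pmax(0, truth[1] + truth[2] * temp + truth[3] * temp^2)
    d <- data.frame(date = dates_2015, count = rpois(365, lam))
    m <- fit_quadratic(d, data.frame(date = dates_2015, temp = temp))
    cov_b1 <- cov_b1 + (m$ci_b1[1] <= truth[2] && truth[2] <= m$ci_b1[2])
    cov_b2 <- cov_b2 + (m$ci_b2[1] <= truth[3] && truth[3] <= m$ci_b2[2])
  }
  expect_gte(cov_b1 / 200, 0.90); expect_lte(cov_b1 / 200, 0.99)
  expect_gte(cov_b2 / 200, 0.90); expect_lte(cov_b2 / 200, 0.99)
})

test_that("equation projection scales coefficients, CIs and predictions", {
  f85 <- quad_model(44.25, -1.69, 0.03, ci_b1 = c(-2.34, -1.04),
                    ci_b2 = c(0.02, 0.04), adj_r2 = 0.24)
  p <- project_equation(f85, 10.13)
  expect_equal(c(p$constant, p$b1, p$b2),
               c(448.2525, -17.1197, 0.3039))  # published: 448.17 - 17.11T + 0.29T^2
  expect_equal(p$ci_b1, 10.13 * f85$ci_b1)
  expect_equal(p$adj_r2, 0.24)

  m85 <- quad_model(45.12, -1.48, 0.03)
  p2 <- project_equation(m85, 2.22)
  expect_equal(c(p2$constant, p2$b1, p2$b2),
               c(100.1664, -3.2856, 0.0666))  # published: 100.19 - 3.30T + 0.06T^2

  expect_equal(project_equation(f85, 1)[c("constant", "b1", "b2")],
               f85[c("constant", "b1", "b2")])

  # linearity: projecting then evaluating equals scaling the evaluation
  grid <- seq(-5, 50, by = 2.5)
  expect_equal(predict_demand(p, grid), 10.13 * predict_demand(f85, grid))
})

test_that("combining equations sums coefficients and commutes with evaluation", {
  eqs <- taipei_base_equations()
  comb <- combine_equations(eqs)
  expect_identical(comb$constant, 438.87)  # constants sum exactly
  grid <- seq(0, 50, by = 5)
  ptwise <- Reduce(`+`, lapply(eqs, predict_demand, temp = grid))
  expect_equal(predict_demand(comb, grid), ptwise)

  one <- combine_equations(eqs[1])
  expect_equal(c(one$constant, one$b1, one$b2),
               c(eqs[[1]]$constant, eqs[[1]]$b1, eqs[[1]]$b2))
  expect_error(combine_equations(list()), "no equations")
})

test_that("the vertex locates the temperature of minimum demand", {
  expect_equal(vertex(quad_model(438.87, -6.99, 0.13)), 6.99 / 0.26)  # 26.88 degC
  expect_equal(vertex(quad_model(1064, -29.38, 0.51)), 29.38 / 1.02)  # 28.8 degC
  expect_equal(vertex(quad_model(7, 0, 1)), 0)
  expect_error(vertex(quad_model(10, 1, 0)), "no interior minimum")
})

test_that("curve tables evaluate the quadratic and flag extrapolated negatives", {
  m <- quad_model(438.87, -6.99, 0.13)
  ct <- curve_table(m, 0, 50, 1)
  expect_equal(ct$predicted[ct$temp == 0], 438.87)
  # the grid minimum sits within one step of the analytic vertex
  expect_lte(abs(ct$temp[which.min(ct$predicted)] - vertex(m)), 1)
  expect_false(any(ct$negative))

  neg <- curve_table(quad_model(-5, 0, 0.01), 0, 10, 1)
  expect_true(all(neg$negative[neg$predicted < 0]))
  expect_true(any(neg$negative))

  single <- curve_table(m, 0, 50, 100)
  expect_equal(nrow(single), 1L)
  expect_equal(single$temp, 0)
})

test_that("stratum fits see the steeper old-age response as higher adjusted R2", {
  # a scenario whose temperature sensitivity grows with age, as observed in
  # real ambulance data: flat response below 65, pronounced U above 85
  st <- data.frame(
    age_band = rep(c("0-64", "65-74", "75-84", "85+"), 2),
    sex = rep(c("male", "female"), each = 4),
    base_pop = rep(c(100000, 20000, 10000, 5000), 2),
    growth = 0,
    c0 = rep(c(120, 25, 40, 180), 2),
    c1 = rep(c(0, -0.4, -1.5, -10), 2),
    c2 = rep(c(0, 0.008, 0.03, 0.2), 2))
  cfg <- eas_scenario(base_year = 2015, horizon_year = 2016, strata = st,
                      frac_incomplete = 0, seed = 77L)
  temps <- simulate_temperature(cfg, 2015)
  rec <- simulate_records(cfg, 2015, temps)
  mods <- fit_strata(aggregate_demand(rec, period = "daily"), temps)
  for (sx in c("male", "female")) {
    r2 <- vapply(paste(sx, c("0-64", "65-74", "75-84", "85+")),
                 function(k) mods[[k]]$adj_r2, numeric(1))
    expect_equal(names(which.max(r2)), paste(sx, "85+"))
  }
})
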