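#' Synthetic scenario configuration
#'
#' Bundles everything needed to generate a self-consistent synthetic data
#' set: a base-year population by stratum with stratum-specific annual
#' growth, per-stratum quadratic temperature-demand rates (counts/day as a
#' function of degC, clamped at zero when evaluated), a seasonal
#' temperature model, and record-level nuisance frequencies (triage,
#' trauma, missing fields).
#'
#' The defaults emulate a Taipei-like metropolis: 2.70 million residents
#' in the 2015 base year with about 15% aged 65+, stratum growth rates
#' solved so that the 36-year population-change factors reach the
#' published 2051 weighting factors (e.g. a tenfold increase for women
#' aged 85+), daily demand rates equal to the published base-year
#' equations, and a subtropical temperature cycle (annual mean 23 degC,
#' seasonal amplitude 6 degC, warmest around mid-July, day-to-day noise
#' sd 2 degC).
#'
#' @param base_year,horizon_year Projection span (calendar years).
#' @param strata Data frame with columns `age_band`, `sex`, `base_pop`,
#'   `growth` (annual rate), `c0`, `c1`, `c2` (daily-rate quadratic).
#' @param temp_mean,temp_amplitude,temp_sd Temperature model (degC).
#' @param temp_phase Day-of-year of the seasonal maximum.
#' @param triage_probs Probabilities for triage levels 1-5.
#' @param p_trauma Probability a record is a trauma case.
#' @param frac_incomplete Fraction of all records lacking age or sex.
#'   Stratum rates describe the complete-field records (only those can be
#'   aggregated into strata), so incomplete records are generated on top
#'   of the stratum counts, never by thinning them.
#' @param open_band_cap Upper age used when sampling ages in the open band.
#' @param seed Base random seed; all generator randomness derives from it.
#' @return A list of class `eas_scenario`.
#' @export
eas_scenario <- function(base_year = 2015L, horizon_year = 2051L,
                         strata = default_strata(base_year, horizon_year),
                         temp_mean = 23, temp_amplitude = 6,
                         temp_phase = 196, temp_sd = 2,
                         triage_probs = c(8786, 20914, 59600, 9317, 609) /
                           sum(c(8786, 20914, 59600, 9317, 609)),
                         p_trauma = 0.449,
                         frac_incomplete = 0.116,
                         open_band_cap = 100L, seed = 20150101L) {
  stopifnot(horizon_year >= base_year,
            all(c("age_band", "sex", "base_pop", "growth",
                  "c0", "c1", "c2") %in% names(strata)),
            all(strata$base_pop >= 0), all(is.finite(strata$growth)),
            temp_sd >= 0, length(triage_probs) == 5L,
            abs(sum(triage_probs) - 1) < 1e-8,
            frac_incomplete >= 0, frac_incomplete < 1)
  structure(list(
    base_year = as.integer(base_year), horizon_year = as.integer(horizon_year),
    strata = strata, temp_mean = temp_mean, temp_amplitude = temp_amplitude,
    temp_phase = temp_phase, temp_sd = temp_sd, triage_probs = triage_probs,
    p_trauma = p_trauma, frac_incomplete = frac_incomplete,
    open_band_cap = as.integer(open_band_cap),
    seed = as.integer(seed), scheme = parse_scheme(unique(strata$age_band))
  ), class = "eas_scenario")
}

#' Default Taipei-like strata table
#'
#' Base-year populations give a 2.70-million-resident metropolis with
#' about 15% aged 65+; annual growth rates are solved so the
#' horizon-year population-change factor matches the published 2051
#' weighting factor for each stratum; the daily-rate quadratics take
#' their slope and curvature from the published base-year equations,
#' with the constant calibrated so that the expected yearly stratum
#' demand under the default noise-free seasonal temperature cycle
#' equals the published 2015 stratum demand (the published coefficients
#' are rounded to 2 dp, which for near-zero curvatures loses up to 15%
#' of a stratum's yearly volume; the constant absorbs that rounding).
#'
#' @param base_year,horizon_year Projection span; growth rates are solved
#'   so the horizon-year population-change factor matches the target
#'   factor over `horizon_year - base_year` years.
#' @param yearly_targets Expected yearly demand per stratum used to
#'   calibrate the rate constants (default: the published 2015 values).
#' @return Strata data frame (see [eas_scenario()]).
#' @export
default_strata <- function(base_year = 2015L, horizon_year = 2051L,
                           yearly_targets = c(49554, 7366, 8029, 9387,
                                              32703, 5441, 7373, 7826)) {
  span <- as.integer(horizon_year) - as.integer(base_year)
  bands <- c("0-64", "65-74", "75-84", "85+")
  horizon_factor <- c(0.76, 1.77, 2.77, 4.20,   # male
                      0.66, 1.78, 2.91, 10.13)  # female
  df <- data.frame(
    age_band = rep(bands, 2L),
    sex = rep(c("male", "female"), each = 4L),
    base_pop = c(1130000, 100000, 60000, 20000,
                 1170000, 115000, 75000, 32000),
    growth = horizon_factor^(1 / span) - 1,
    c0 = c(153.31, 25.69, 30.24, 45.12, 91.67, 18.72, 29.87, 44.25),
    c1 = c(-1.88, -0.37, -0.55, -1.48, -0.10, -0.26, -0.65, -1.69),
    c2 = c(0.05, 0.01, 0.01, 0.03, 0.00, 0.00, 0.01, 0.03),
    stringsAsFactors = FALSE
  )
  # noise-free default seasonal cycle over the base year
  dates <- seq(as.Date(sprintf("%d-01-01", base_year)),
               as.Date(sprintf("%d-12-31", base_year)), by = "day")
  d <- as.integer(format(dates, "%j"))
  temp <- 23 + 6 * cos(2 * pi * (d - 196) / 365.25)
  expected <- vapply(seq_len(nrow(df)), function(i)
    sum(pmax(0, df$c0[i] + df$c1[i] * temp + df$c2[i] * temp^2)), numeric(1))
  df$c0 <- df$c0 + (yearly_targets - expected) / length(d)
  df
}

# deterministic per-purpose seed stream, kept well below 2^31
derive_seed <- function(cfg, year, stream) {
  (cfg$seed %% 100000L) * 10000L + (year %% 1000L) * 10L + stream
}

#' Simulate population pyramids for every scenario year
#'
#' Stratum count in year `y` is `base_pop * (1 + growth)^(y - base_year)`,
#' rounded to an integer; generation is deterministic given the
#' configuration.
#'
#' @param cfg An `eas_scenario`.
#' @return Named list of `eas_pyramid` objects, one per year from the base
#'   year to the horizon.
#' @export
simulate_pyramids <- function(cfg) {
  years <- seq(cfg$base_year, cfg$horizon_year)
  out <- lapply(years, function(y) {
    cnt <- round(cfg$strata$base_pop * (1 + cfg$strata$growth)^(y - cfg$base_year))
    new_pyramid_df(y, cfg$strata$sex, cfg$strata$age_band, cnt)
  })
  names(out) <- years
  out
}

#' Simulate a daily mean temperature series for one year
#'
#' `T(d) = mean + amplitude * cos(2 pi (d - phase) / 365.25) + N(0, sd)`
#' over every calendar day of the year; reproducible for a given seed.
#'
#' @param cfg An `eas_scenario`.
#' @param year Calendar year.
#' @param seed Random seed; defaults to a stream derived from `cfg$seed`
#'   and the year.
#' @return Data frame `date`, `temp`.
#' @export
simulate_temperature <- function(cfg, year, seed = derive_seed(cfg, year, 1L)) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  d <- as.integer(format(dates, "%j"))
  set.seed(seed)
  temp <- cfg$temp_mean +
    cfg$temp_amplitude * cos(2 * pi * (d - cfg$temp_phase) / 365.25) +
    stats::rnorm(length(d), 0, cfg$temp_sd)
  data.frame(date = dates, temp = temp)
}

#' Simulate patient-level ambulance records for one year
#'
#' For each stratum and day, the record count is Poisson with mean
#' `max(0, c0 + c1 T + c2 T^2) * scaling`, where the scaling is the
#' stratum's simulated population in `year` divided by its base-year
#' population, so demographic drift propagates to record volume. Counts
#' are expanded to records carrying the date, the stratum sex, an age
#' uniform within the band (open band capped at `open_band_cap`), and
#' triage/trauma drawn from the configured frequencies. Incomplete
#' records (missing age and/or sex, which downstream aggregation drops)
#' are generated on top of the stratum counts so that they make up
#' `frac_incomplete` of all records in expectation.
#'
#' @param cfg An `eas_scenario`.
#' @param year Calendar year.
#' @param temps Optional temperature series (defaults to
#'   [simulate_temperature()] for the year).
#' @param seed Random seed for the record-level draws.
#' @return An `eas_records` data frame (see [read_records()]).
#' @export
simulate_records <- function(cfg, year, temps = NULL,
                             seed = derive_seed(cfg, year, 2L)) {
  if (is.null(temps)) temps <- simulate_temperature(cfg, year)
  pyr <- simulate_pyramids(cfg)
  scaling <- pyr[[as.character(year)]]$count / pyr[[as.character(cfg$base_year)]]$count
  set.seed(seed)
  scheme <- cfg$scheme
  pieces <- vector("list", nrow(cfg$strata))
  for (i in seq_len(nrow(cfg$strata))) {
    st <- cfg$strata[i, ]
    lam <- pmax(0, st$c0 + st$c1 * temps$temp + st$c2 * temps$temp^2) * scaling[i]
    n_day <- stats::rpois(nrow(temps), lam)
    n <- sum(n_day)
    if (n == 0L) next
    bi <- match(st$age_band, scheme$label)
    hi <- if (is.finite(scheme$upper[bi])) scheme$upper[bi] else cfg$open_band_cap
    pieces[[i]] <- data.frame(
      date = rep(temps$date, n_day),
      age = sample(seq.int(scheme$lower[bi], hi), n, replace = TRUE),
      sex = st$sex,
      triage = sample(1:5, n, replace = TRUE, prob = cfg$triage_probs),
      trauma = stats::runif(n) < cfg$p_trauma,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(date = as.Date(character()), age = integer(),
                      sex = character(), triage = integer(), trauma = logical())
  # incomplete records on top: frac_incomplete of all records in expectation
  n_complete <- nrow(out)
  if (n_complete > 0L && cfg$frac_incomplete > 0) {
    n_extra <- stats::rpois(1L, n_complete * cfg$frac_incomplete /
                              (1 - cfg$frac_incomplete))
    if (n_extra > 0L) {
      miss_age <- stats::runif(n_extra) < 0.75
      miss_sex <- stats::runif(n_extra) < 0.5
      miss_age[!miss_age & !miss_sex] <- TRUE
      age <- sample.int(cfg$open_band_cap + 1L, n_extra, replace = TRUE) - 1L
      age[miss_age] <- NA_integer_
      sex <- sample(c("male", "female"), n_extra, replace = TRUE)
      sex[miss_sex] <- NA_character_
      extra <- data.frame(
        date = sample(temps$date, n_extra, replace = TRUE),
        age = age, sex = sex,
        triage = sample(1:5, n_extra, replace = TRUE, prob = cfg$triage_probs),
        trauma = stats::runif(n_extra) < cfg$p_trauma,
        stringsAsFactors = FALSE)
      out <- rbind(out, extra)
    }
  }
  out <- out[order(out$date), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("eas_records", "data.frame"))
}

#' Ground truth implied by a scenario configuration
#'
#' Closed-form quantities with no sampling: the true population-change
#' weights for every year (from the unrounded growth model), the true
#' rate coefficients, and the expected yearly demand per stratum under
#' the noise-free seasonal temperature cycle (sum over days of the
#' zero-clamped quadratic rate times the population scaling).
#'
#' @param cfg An `eas_scenario`.
#' @param years Years to evaluate (default: every scenario year).
#' @return List with `weights` (data frame `year`, `age_band`, `sex`,
#'   `weight`), `rates` (the strata coefficient table) and
#'   `expected_yearly` (data frame `year`, `age_band`, `sex`, `expected`).
#' @export
ground_truth <- function(cfg, years = seq(cfg$base_year, cfg$horizon_year)) {
  wt <- do.call(rbind, lapply(years, function(y) {
    data.frame(year = y, age_band = cfg$strata$age_band, sex = cfg$strata$sex,
               weight = (1 + cfg$strata$growth)^(y - cfg$base_year),
               stringsAsFactors = FALSE)
  }))
  noise_free <- cfg
  noise_free$temp_sd <- 0
  exp_rows <- do.call(rbind, lapply(years, function(y) {
    temps <- simulate_temperature(noise_free, y)
    scale_y <- (1 + cfg$strata$growth)^(y - cfg$base_year)
    expd <- vapply(seq_len(nrow(cfg$strata)), function(i) {
      st <- cfg$strata[i, ]
      sum(pmax(0, st$c0 + st$c1 * temps$temp + st$c2 * temps$temp^2)) * scale_y[i]
    }, numeric(1))
    data.frame(year = y, age_band = cfg$strata$age_band, sex = cfg$strata$sex,
               expected = expd, stringsAsFactors = FALSE)
  }))
  rownames(wt) <- rownames(exp_rows) <- NULL
  list(weights = wt, rates = cfg$strata[, c("age_band", "sex", "c0", "c1", "c2")],
       expected_yearly = exp_rows)
}

#' Write a scenario's data files
#'
#' Emits the file dialects consumed by the readers: one pyramid file
#' covering every scenario year, one temperature file and one records file
#' per requested year, plus a key-value manifest recording the seed and
#' the generator parameters.
#'
#' @param cfg An `eas_scenario`.
#' @param dir Output directory (created if needed).
#' @param years Years for which records/temperatures are generated
#'   (default: the base year only).
#' @return Named list of file paths.
#' @export
write_scenario <- function(cfg, dir, years = cfg$base_year) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pyr <- simulate_pyramids(cfg)
  pyr_df <- do.call(rbind, lapply(pyr, function(p) {
    data.frame(year = attr(p, "year"), sex = ifelse(p$sex == "male", "M", "F"),
               age = ifelse(is.finite(p$age_upper),
                            paste0(p$age_lower, "-", p$age_upper),
                            paste0(p$age_lower, "+")),
               count = p$count)
  }))
  paths <- list(pyramids = file.path(dir, "pyramids.csv"))
  utils::write.csv(pyr_df, paths$pyramids, row.names = FALSE, quote = FALSE)
  for (y in years) {
    temps <- simulate_temperature(cfg, y)
    rec <- simulate_records(cfg, y, temps = temps)
    tp <- file.path(dir, sprintf("temperature_%d.csv", y))
    rp <- file.path(dir, sprintf("records_%d.csv", y))
    utils::write.csv(data.frame(date = temps$date,
                                temp = sprintf("%.3f", temps$temp)),
                     tp, row.names = FALSE, quote = FALSE)
    rec_out <- data.frame(
      date = format(rec$date),
      age = ifelse(is.na(rec$age), "", rec$age),
      sex = ifelse(is.na(rec$sex), "", ifelse(rec$sex == "male", "M", "F")),
      triage = rec$triage, trauma = as.integer(rec$trauma))
    utils::write.csv(rec_out, rp, row.names = FALSE, quote = FALSE)
    paths[[sprintf("temperature_%d", y)]] <- tp
    paths[[sprintf("records_%d", y)]] <- rp
  }
  mf <- file.path(dir, "manifest.txt")
  writeLines(c(
    sprintf("seed=%d", cfg$seed),
    sprintf("base_year=%d", cfg$base_year),
    sprintf("horizon_year=%d", cfg$horizon_year),
    sprintf("temp_mean=%g", cfg$temp_mean),
    sprintf("temp_amplitude=%g", cfg$temp_amplitude),
    sprintf("temp_phase=%g", cfg$temp_phase),
    sprintf("temp_sd=%g", cfg$temp_sd),
    sprintf("p_trauma=%g", cfg$p_trauma),
    sprintf("frac_incomplete=%g", cfg$frac_incomplete)
  ), mf)
  paths$manifest <- mf
  paths
}
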