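# Shared fixtures built in code.

# yearly ambulance totals used for outlier screening examples
yearly_totals <- c(141250, 140153, 136988, 143243, 144539)
yearly_labels <- 2011:2015

two_band_scheme <- function() age_scheme(c(0L, 65L))

# random single-year pyramid for property loops
random_pyramid <- function(year, max_age = 99, min_count = 1, max_count = 1000) {
  ages <- 0:max_age
  new_pyramid_df(year,
                 sex = rep(c("M", "F"), each = length(ages)),
                 age = rep(ages, 2L),
                 count = sample(min_count:max_count, 2L * length(ages),
                                replace = TRUE))
}

# scale every count of a pyramid by k
scale_pyramid <- function(p, k, year = attr(p, "year")) {
  q <- p
  q$count <- q$count * k
  attr(q, "year") <- year
  q
}

# in-memory records constructor
make_records <- function(date, age = NA_integer_, sex = NA_character_,
                         triage = NA_integer_, trauma = NA) {
  n <- length(date)
  structure(data.frame(date = as.Date(date),
                       age = rep_len(as.integer(age), n),
                       sex = rep_len(as.character(sex), n),
                       triage = rep_len(as.integer(triage), n),
                       trauma = rep_len(as.logical(trauma), n),
                       stringsAsFactors = FALSE),
            class = c("eas_records", "data.frame"))
}

write_lines_tmp <- function(lines, ext = ".csv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# a small, fast scenario (populations and rates scaled down ~20x)
small_scenario <- function(horizon_year = 2020L, seed = 42L) {
  st <- default_strata(2015L, 2051L)
  st$base_pop <- round(st$base_pop / 20)
  st$growth <- (c(0.76, 1.77, 2.77, 4.20, 0.66, 1.78, 2.91, 10.13)^(1 / 36)) - 1
  for (col in c("c0", "c1", "c2")) st[[col]] <- st[[col]] / 20
  eas_scenario(base_year = 2015L, horizon_year = horizon_year, strata = st,
               seed = seed)
}
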