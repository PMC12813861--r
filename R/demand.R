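#' Read patient-level ambulance records
#'
#' The file must have a header containing at least `date,age,sex`; columns
#' `triage` (1-5) and `trauma` (0/1) are optional. Dates are ISO-8601.
#' Malformed optional fields (age outside 0-130, triage outside 1-5,
#' trauma not 0/1) become missing with a warning giving the count; rows
#' whose date cannot be parsed are dropped, also with a warning.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default `","`).
#' @return A data frame of class `eas_records` with columns `date` (`Date`),
#'   `age` (integer or `NA`), `sex` (`"male"`/`"female"`/`NA`), `triage`
#'   (integer or `NA`), `trauma` (logical or `NA`).
#' @export
read_records <- function(path, sep = ",") {
  if (!file.exists(path)) stop(sprintf("records file not found: %s", path))
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         colClasses = "character", strip.white = TRUE)
  need <- c("date", "age", "sex")
  if (!all(need %in% names(raw)))
    stop("records file must have columns date, age, sex")
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    warning(sprintf("%d rows with unparseable dates dropped", sum(is.na(date))))
    raw <- raw[!is.na(date), , drop = FALSE]
    date <- date[!is.na(date)]
  }
  age <- suppressWarnings(as.integer(raw$age))
  bad_age <- !is.na(age) & (age < 0L | age > 130L)
  if (any(bad_age)) {
    warning(sprintf("%d ages outside 0-130 set to missing", sum(bad_age)))
    age[bad_age] <- NA_integer_
  }
  sex <- decode_sex(raw$sex)
  triage <- if ("triage" %in% names(raw)) {
    tr <- suppressWarnings(as.integer(raw$triage))
    bad <- !is.na(tr) & !(tr %in% 1:5)
    if (any(bad)) {
      warning(sprintf("%d triage values outside 1-5 set to missing", sum(bad)))
      tr[bad] <- NA_integer_
    }
    tr
  } else rep(NA_integer_, nrow(raw))
  trauma <- if ("trauma" %in% names(raw)) {
    tv <- trimws(raw$trauma)
    out <- rep(NA, nrow(raw))
    out[tv == "1"] <- TRUE
    out[tv == "0"] <- FALSE
    bad <- !(tv %in% c("0", "1", "", "NA"))
    if (any(bad))
      warning(sprintf("%d trauma values not 0/1 set to missing", sum(bad)))
    out
  } else rep(NA, nrow(raw))
  structure(
    data.frame(date = date, age = age, sex = sex, triage = triage,
               trauma = trauma, stringsAsFactors = FALSE),
    class = c("eas_records", "data.frame")
  )
}

#' Aggregate records into a stratum demand table
#'
#' Counts records per (period key, age band, sex) cell; records missing age
#' or sex are excluded from the table and counted in the `n_dropped`
#' attribute, so that `sum(cells for one sex) + n_dropped` reconstructs the
#' record count. Both-sex cells (male + female) are included.
#'
#' @param records An `eas_records` data frame (or any data frame with
#'   `date`, `age`, `sex`).
#' @param scheme An `eas_scheme`; defaults to [projection_scheme()].
#' @param period `"yearly"` or `"daily"`.
#' @return An `eas_demand` data frame with columns `period_key` (year or
#'   ISO date as character), `age_band`, `sex` and integer `count`;
#'   attributes `period`, `n_dropped`, `scheme`. Cells are complete over
#'   observed period keys x scheme bands x sexes (zeros filled in).
#' @export
aggregate_demand <- function(records, scheme = projection_scheme(),
                             period = c("yearly", "daily")) {
  period <- match.arg(period)
  keep <- !is.na(records$age) & !is.na(records$sex)
  n_dropped <- sum(!keep)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L) {
    out <- data.frame(period_key = character(), age_band = character(),
                      sex = character(), count = integer())
    return(structure(out, period = period, n_dropped = n_dropped,
                     scheme = scheme,
                     class = c("eas_demand", "data.frame")))
  }
  key <- if (period == "yearly") format(r$date, "%Y") else format(r$date)
  band <- assign_band(r$age, scheme)
  keys <- sort(unique(key))
  cells <- expand.grid(period_key = keys, age_band = scheme$label,
                       sex = c("male", "female"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(paste(key, band, r$sex, sep = "\r")))
  id <- paste(cells$period_key, cells$age_band, cells$sex, sep = "\r")
  cells$count <- as.integer(tab[id])
  cells$count[is.na(cells$count)] <- 0L
  both <- cells[cells$sex == "male", , drop = FALSE]
  both$sex <- "both"
  both$count <- both$count + cells$count[cells$sex == "female"]
  out <- rbind(cells, both)
  out <- out[order(out$period_key, match(out$sex, c("male", "female", "both")),
                   match(out$age_band, scheme$label)), ]
  rownames(out) <- NULL
  structure(out, period = period, n_dropped = n_dropped, scheme = scheme,
            class = c("eas_demand", "data.frame"))
}

#' @export
print.eas_demand <- function(x, ...) {
  cat(sprintf("%s demand table: %d cells, %s records (%d dropped for missing age/sex)\n",
              attr(x, "period"), nrow(x),
              format(sum(x$count[x$sex != "both"]), big.mark = ","),
              attr(x, "n_dropped")))
  invisible(x)
}

#' Descriptive profile of one year of demand
#'
#' Tabulates counts and percentage shares by age category (default
#' `0-14, 15-34, 35-64, 65+`), triage level, sex and trauma status.
#' Within each block the denominator is the number of records with a
#' non-missing value for that block's variable, so blocks may have
#' different denominators.
#'
#' @param records An `eas_records` data frame.
#' @param year Calendar year to profile.
#' @param scheme Age scheme for the age block; defaults to
#'   [profile_scheme()].
#' @return A data frame with columns `block`, `category`, `count`,
#'   `percent` (one decimal).
#' @export
demand_profile <- function(records, year, scheme = profile_scheme()) {
  r <- records[format(records$date, "%Y") == as.character(year), , drop = FALSE]
  block <- function(name, values, levels) {
    v <- factor(values, levels = levels)
    cnt <- as.integer(table(v))
    denom <- sum(cnt)
    data.frame(block = name, category = levels, count = cnt,
               percent = if (denom > 0) round(100 * cnt / denom, 1) else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    block("age", assign_band(r$age, scheme), scheme$label),
    block("triage", r$triage, as.character(1:5)),
    block("sex", r$sex, c("female", "male")),
    block("trauma", ifelse(r$trauma, "trauma", "nontrauma"),
          c("trauma", "nontrauma"))
  )
  rownames(out) <- NULL
  out
}

#' Grubbs' test for a single outlier
#'
#' Screens a small sample of yearly totals for one outlying value using the
#' maximum studentized deviation. Each value's Z statistic is
#' `|x - mean| / s` with `s` the sample (n-1) standard deviation; the
#' two-sided critical value at level `alpha` for sample size `n` is
#' `((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the upper
#' `alpha/(2n)` quantile of the t distribution on `n-2` degrees of freedom.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param alpha Significance level (default 0.05).
#' @param labels Optional labels for the values (e.g. years).
#' @return An object of class `eas_grubbs`: list with `table` (label,
#'   value, z), `max_item`, `max_z`, `critical_value`, `alpha`,
#'   `significant`.
#' @examples
#' grubbs_test(c(141250, 140153, 136988, 143243, 144539),
#'             labels = 2011:2015)
#' @export
grubbs_test <- function(values, alpha = 0.05, labels = NULL) {
  n <- length(values)
  if (n < 3L) stop("Grubbs' test requires at least 3 values")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  s <- stats::sd(values)
  z <- if (s > 0) abs(values - mean(values)) / s else rep(0, n)
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  imax <- which.max(z)
  structure(list(
    table = data.frame(label = as.character(labels), value = values, z = z,
                       stringsAsFactors = FALSE),
    max_item = as.character(labels)[imax],
    max_z = z[imax],
    critical_value = crit,
    alpha = alpha,
    significant = s > 0 && z[imax] > crit
  ), class = "eas_grubbs")
}

#' @export
print.eas_grubbs <- function(x, ...) {
  df <- x$table
  df$z <- round(df$z, 2)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("max Z = %.2f at %s; critical value %.3f (alpha = %g): %s\n",
              x$max_z, x$max_item, x$critical_value, x$alpha,
              if (x$significant) "significant outlier"
              else "no significant outlier"))
  invisible(x)
}
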