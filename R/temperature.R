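#' Read a daily mean temperature series
#'
#' Expects a header `date,temp` with ISO-8601 dates and temperatures in
#' degrees Celsius; values outside -20..50 are rejected as implausible
#' for a daily mean.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default `","`).
#' @return Data frame `date` (`Date`), `temp` (numeric), one row per day.
#' @export
read_temperature <- function(path, sep = ",") {
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         strip.white = TRUE)
  if (!all(c("date", "temp") %in% names(raw)))
    stop("temperature file must have columns date, temp")
  date <- as.Date(as.character(raw$date), format = "%Y-%m-%d")
  if (anyNA(date)) stop("unparseable date in temperature file")
  temp <- as.numeric(raw$temp)
  if (any(is.na(temp) | temp < -20 | temp > 50))
    stop("temperature outside plausible range -20..50 degC")
  if (anyDuplicated(date)) stop("duplicate dates in temperature series")
  data.frame(date = date, temp = temp)
}

#' Quadratic temperature-demand model
#'
#' Container for one stratum's daily-demand equation
#' `demand = constant + b1 * T + b2 * T^2` (counts/day, T in degC), with
#' 95% confidence intervals for the temperature coefficients and the
#' adjusted R-squared of the fit where available.
#'
#' @param constant,b1,b2 Coefficients.
#' @param ci_b1,ci_b2 Length-2 numeric CIs (or `NA`).
#' @param adj_r2 Adjusted R-squared (or `NA`).
#' @param n Number of days used in the fit (or `NA`).
#' @param sex,age_band Optional stratum labels.
#' @return An object of class `eas_quadmodel`.
#' @export
quad_model <- function(constant, b1, b2, ci_b1 = c(NA_real_, NA_real_),
                       ci_b2 = c(NA_real_, NA_real_), adj_r2 = NA_real_,
                       n = NA_integer_, sex = NA_character_,
                       age_band = NA_character_) {
  stopifnot(length(ci_b1) == 2L, length(ci_b2) == 2L)
  if (!anyNA(ci_b1) && ci_b1[1L] > ci_b1[2L]) stop("ci_b1 bounds out of order")
  if (!anyNA(ci_b2) && ci_b2[1L] > ci_b2[2L]) stop("ci_b2 bounds out of order")
  structure(list(constant = constant, b1 = b1, b2 = b2,
                 ci_b1 = as.numeric(ci_b1), ci_b2 = as.numeric(ci_b2),
                 adj_r2 = adj_r2, n = n, sex = sex, age_band = age_band),
            class = "eas_quadmodel")
}

#' @export
print.eas_quadmodel <- function(x, ...) {
  lab <- if (!is.na(x$sex)) sprintf(" [%s %s]", x$sex, x$age_band) else ""
  cat(sprintf("%s%s: %.2f %+.2fT %+.2fT^2", "quadratic temperature-demand model",
              lab, x$constant, x$b1, x$b2))
  if (!is.na(x$adj_r2)) cat(sprintf("  (adj R2 = %.2f, n = %d)", x$adj_r2, x$n))
  cat("\n")
  invisible(x)
}

#' Fit the quadratic temperature-demand regression for one stratum
#'
#' Ordinary least squares of daily counts on `(1, T, T^2)`, with t-based
#' 95% confidence intervals for the linear and quadratic coefficients and
#' adjusted R-squared `1 - (1 - R2)(n-1)/(n-3)`. Days with zero demand are
#' ordinary observations; the demand and temperature series are joined on
#' date and every common day is used.
#'
#' @param daily Daily counts for one stratum: a data frame with columns
#'   `date` and `count` (e.g. one stratum slice of a daily `eas_demand`
#'   with `period_key` as date).
#' @param temps Temperature series from [read_temperature()] (columns
#'   `date`, `temp`).
#' @param conf_level Confidence level for the coefficient CIs.
#' @return An `eas_quadmodel`.
#' @export
fit_quadratic <- function(daily, temps, conf_level = 0.95) {
  if ("period_key" %in% names(daily) && !("date" %in% names(daily)))
    daily$date <- as.Date(daily$period_key)
  stopifnot(all(c("date", "count") %in% names(daily)),
            all(c("date", "temp") %in% names(temps)))
  m <- merge(daily[, c("date", "count")], temps, by = "date")
  if (length(unique(m$temp)) < 3L)
    stop("need at least 3 distinct temperature values to fit a quadratic")
  fit <- stats::lm(count ~ temp + I(temp^2), data = m)
  co <- stats::coef(fit)
  ci <- stats::confint(fit, level = conf_level)
  s <- summary(fit)
  quad_model(constant = unname(co[1L]), b1 = unname(co[2L]),
             b2 = unname(co[3L]),
             ci_b1 = unname(ci[2L, ]), ci_b2 = unname(ci[3L, ]),
             adj_r2 = s$adj.r.squared, n = nrow(m))
}

#' Fit quadratic models for every sex-specific stratum of a daily table
#'
#' @param daily An `eas_demand` with `period = "daily"`.
#' @param temps Temperature series (columns `date`, `temp`).
#' @return Named list of `eas_quadmodel` objects, one per
#'   (sex, age band) with sex in male/female, named `"sex age_band"`.
#' @export
fit_strata <- function(daily, temps) {
  stopifnot(inherits(daily, "eas_demand"),
            identical(attr(daily, "period"), "daily"))
  scheme <- attr(daily, "scheme")
  out <- list()
  for (sx in c("male", "female")) for (band in scheme$label) {
    cells <- daily[daily$sex == sx & daily$age_band == band, , drop = FALSE]
    m <- fit_quadratic(data.frame(date = as.Date(cells$period_key),
                                  count = cells$count), temps)
    m$sex <- sx; m$age_band <- band
    out[[paste(sx, band)]] <- m
  }
  out
}

#' Project a temperature-demand equation to a target year
#'
#' Multiplies all three coefficients (and the coefficient CIs) by the
#' stratum's population-change weighting factor; the equation projection
#' is the same weighted linear combination as the yearly-demand
#' projection, applied to equations instead of scalars. The adjusted
#' R-squared describes the base-year fit and carries over unchanged.
#'
#' @param m An `eas_quadmodel`.
#' @param weight Positive weighting factor.
#' @return The scaled `eas_quadmodel`.
#' @examples
#' f85 <- quad_model(44.25, -1.69, 0.03, sex = "female", age_band = "85+")
#' project_equation(f85, 10.13)  # 2051 projection: 448.25 - 17.12T + 0.30T^2
#' @export
project_equation <- function(m, weight) {
  stopifnot(inherits(m, "eas_quadmodel"), weight > 0)
  quad_model(constant = m$constant * weight, b1 = m$b1 * weight,
             b2 = m$b2 * weight, ci_b1 = m$ci_b1 * weight,
             ci_b2 = m$ci_b2 * weight, adj_r2 = m$adj_r2, n = m$n,
             sex = m$sex, age_band = m$age_band)
}

#' Combine stratum equations into an overall equation
#'
#' Coefficient-wise sum of the stratum curves: the combined curve equals
#' the pointwise sum of the stratum curves at every temperature. CIs and
#' adjusted R-squared are not defined for the combined equation.
#'
#' @param models Non-empty list of `eas_quadmodel` objects.
#' @return An `eas_quadmodel` with `sex = "both"`, `age_band = "ALL"`.
#' @export
combine_equations <- function(models) {
  if (length(models) == 0L) stop("no equations to combine")
  stopifnot(all(vapply(models, inherits, logical(1), "eas_quadmodel")))
  quad_model(
    constant = sum(vapply(models, `[[`, numeric(1), "constant")),
    b1 = sum(vapply(models, `[[`, numeric(1), "b1")),
    b2 = sum(vapply(models, `[[`, numeric(1), "b2")),
    sex = "both", age_band = "ALL"
  )
}

#' Evaluate a quadratic model
#'
#' @param m An `eas_quadmodel`.
#' @param temp Numeric vector of temperatures (degC).
#' @return Predicted demand (counts/day).
#' @export
predict_demand <- function(m, temp) {
  m$constant + m$b1 * temp + m$b2 * temp^2
}

#' Temperature of minimum demand (vertex of the U-shaped curve)
#'
#' For a convex quadratic (`b2 > 0`) the demand is minimal at
#' `T* = -b1 / (2 b2)`.
#'
#' @param m An `eas_quadmodel` with `b2 > 0`.
#' @return Temperature in degC.
#' @examples
#' vertex(quad_model(438.87, -6.99, 0.13))  # about 26.9 degC
#' @export
vertex <- function(m) {
  stopifnot(inherits(m, "eas_quadmodel"))
  if (!(m$b2 > 0)) stop("no interior minimum: quadratic coefficient must be positive")
  -m$b1 / (2 * m$b2)
}

#' Tabulate a demand curve over a temperature grid
#'
#' Evaluates the quadratic on a regular grid. Extrapolated predictions can
#' be negative; they are reported raw and flagged in the `negative`
#' column, never clamped.
#'
#' @param m An `eas_quadmodel`.
#' @param t_min,t_max Grid range (degC), `t_min < t_max`.
#' @param step Grid step (degC), positive.
#' @return Data frame `temp`, `predicted`, `negative`.
#' @export
curve_table <- function(m, t_min = 0, t_max = 50, step = 1) {
  stopifnot(t_min < t_max, step > 0)
  grid <- seq(t_min, t_max, by = step)
  pred <- predict_demand(m, grid)
  data.frame(temp = grid, predicted = pred, negative = pred < 0)
}
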