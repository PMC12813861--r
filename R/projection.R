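#' Project base-year demand with age-gender weighting
#'
#' Applies the demographic weighting to a yearly base-year demand table:
#' each sex-specific stratum's projected demand is its weighting factor
#' times its base-year count (the weighted linear combination over age and
#' sex strata). Both-sex cells are obtained either as the sum of the two
#' projected sexes (`"sum_of_sex"`, the literal double sum) or as the
#' both-sex weighting factor times the base both-sex count
#' (`"aggregate_weight"`, matching published both-sex projection tables;
#' the two modes differ exactly when male and female weights differ within
#' a band).
#'
#' @param base Yearly demand: an `eas_demand` (yearly) or any data frame
#'   with columns `age_band`, `sex`, `count`.
#' @param w An `eas_weights` table on the same band scheme.
#' @param both_mode `"sum_of_sex"` (default) or `"aggregate_weight"`.
#' @return A data frame `age_band`, `sex`, `projected` covering male,
#'   female and both rows for every band, plus an `ALL` row per sex with
#'   the column totals.
#' @examples
#' base <- data.frame(age_band = "65-74", sex = "male", count = 7366)
#' w <- as_eas_weights(
#'   data.frame(age_band = "65-74", sex = c("male", "female", "both"),
#'              weight = c(1.66, 1.72, 1.69)),
#'   2015, 2036, overall_ratio = 1.04)
#' project_adjusted(base, w)
#' @export
project_adjusted <- function(base, w,
                             both_mode = c("sum_of_sex", "aggregate_weight")) {
  both_mode <- match.arg(both_mode)
  base <- as_yearly_cells(base)
  bands <- unique(base$age_band)
  out <- list()
  # a weight may be absent only for an unpopulated stratum
  wt <- function(band, sex, cnt) if (cnt == 0) 0 else weight_for(w, band, sex) * cnt
  for (band in bands) {
    m <- cell_count(base, band, "male")
    f <- cell_count(base, band, "female")
    pm <- wt(band, "male", m)
    pf <- wt(band, "female", f)
    pb <- if (both_mode == "sum_of_sex") pm + pf
          else wt(band, "both", cell_count(base, band, "both", default = m + f))
    out[[band]] <- data.frame(age_band = band,
                              sex = c("male", "female", "both"),
                              projected = c(pm, pf, pb),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  add_all_rows(res, "projected")
}

#' Project base-year demand by the overall population ratio only
#'
#' The uniform-scaling benchmark: every stratum cell is multiplied by the
#' single all-age both-sex population ratio, ignoring age-gender
#' composition. Comparing this against [project_adjusted()] quantifies the
#' misestimation incurred by ignoring demographic structure.
#'
#' @inheritParams project_adjusted
#' @return A data frame `age_band`, `sex`, `projected` (with `ALL` rows).
#' @export
project_unadjusted <- function(base, w) {
  base <- as_yearly_cells(base)
  ratio <- attr(w, "overall_ratio")
  if (is.null(ratio)) stop("weight table has no overall_ratio")
  res <- data.frame(age_band = base$age_band, sex = base$sex,
                    projected = ratio * base$count, stringsAsFactors = FALSE)
  add_all_rows(res, "projected")
}

#' Misestimation between unadjusted and adjusted projections
#'
#' Percentage difference `100 * (unadjusted - adjusted) / adjusted`;
#' negative values mean the unadjusted projection underestimates demand.
#'
#' @param adjusted,unadjusted Numeric vectors (adjusted must be positive).
#' @param digits Rounding for reporting; `0` (default) gives the integer
#'   percentages used in projection tables, `NA` returns full precision.
#' @return Numeric vector of percentages.
#' @examples
#' misestimation(190599, 132977)  # -30: a 30% underestimate
#' @export
misestimation <- function(adjusted, unadjusted, digits = 0) {
  if (any(adjusted <= 0)) stop("adjusted projection must be positive")
  pct <- 100 * (unadjusted - adjusted) / adjusted
  if (is.na(digits)) pct else round(pct, digits)
}

#' Year-by-year projection trajectory
#'
#' Computes adjusted and unadjusted total projected demand for every year
#' with an available pyramid, using the base year's pyramid as denominator
#' (year-specific overall ratios for the unadjusted series).
#'
#' @param base Yearly base demand (see [project_adjusted()]).
#' @param pyramids Named list of `eas_pyramid` objects, one per year,
#'   including the base year.
#' @param base_year Calendar base year.
#' @param scheme An `eas_scheme`; defaults to [projection_scheme()].
#' @param both_mode Passed to [project_adjusted()].
#' @return Data frame `year`, `adjusted_total`, `unadjusted_total`.
#' @export
project_trajectory <- function(base, pyramids, base_year,
                               scheme = projection_scheme(),
                               both_mode = c("sum_of_sex", "aggregate_weight")) {
  both_mode <- match.arg(both_mode)
  years <- vapply(pyramids, function(p) attr(p, "year"), numeric(1))
  if (!(base_year %in% years))
    stop(sprintf("no pyramid for base year %d", base_year))
  span <- seq(min(years), max(years))
  missing_years <- setdiff(span, years)
  if (length(missing_years))
    stop(sprintf("missing pyramids for years: %s",
                 paste(missing_years, collapse = ", ")))
  p0 <- pyramids[[which(years == base_year)]]
  rows <- lapply(sort(years), function(y) {
    w <- compute_weights(p0, pyramids[[which(years == y)]], scheme)
    adj <- project_adjusted(base, w, both_mode)
    una <- project_unadjusted(base, w)
    data.frame(year = y,
               adjusted_total = proj_total(adj, both_mode),
               unadjusted_total = proj_total(una, "sum_of_sex"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# total over the mode's cells: sum_of_sex -> male+female ALL; aggregate -> both ALL
proj_total <- function(proj, both_mode) {
  sexes <- if (both_mode == "aggregate_weight") "both" else c("male", "female")
  sum(proj$projected[proj$age_band == "ALL" & proj$sex %in% sexes])
}

#' Full projection table for one target year
#'
#' Combines actual base demand, unadjusted and adjusted projections and
#' the misestimation percentage in one table per stratum and sex.
#'
#' @inheritParams project_adjusted
#' @return Data frame `target_year`, `age_band`, `sex`, `actual_base`,
#'   `unadjusted`, `adjusted`, `difference_pct`.
#' @export
projection_table <- function(base, w,
                             both_mode = c("sum_of_sex", "aggregate_weight")) {
  both_mode <- match.arg(both_mode)
  cells <- as_yearly_cells(base)
  cells <- add_all_rows(cells, "count")
  adj <- project_adjusted(base, w, both_mode)
  una <- project_unadjusted(base, w)
  key <- paste(adj$age_band, adj$sex)
  out <- data.frame(
    target_year = attr(w, "target_year"),
    age_band = adj$age_band, sex = adj$sex,
    actual_base = cells$count[match(key, paste(cells$age_band, cells$sex))],
    unadjusted = una$projected[match(key, paste(una$age_band, una$sex))],
    adjusted = adj$projected,
    stringsAsFactors = FALSE
  )
  out$difference_pct <- misestimation(out$adjusted, out$unadjusted)
  out
}

# ---- helpers ----

# normalize a base demand input to (age_band, sex, count) cells, one year,
# with both-sex rows available on demand
as_yearly_cells <- function(base) {
  if (inherits(base, "eas_demand")) {
    if (!identical(attr(base, "period"), "yearly"))
      stop("projection needs a yearly demand table")
    yrs <- unique(base$period_key)
    if (length(yrs) > 1L)
      stop("base demand table spans several years; subset to the base year")
    df <- as.data.frame(base)[, c("age_band", "sex", "count")]
  } else {
    df <- as.data.frame(base)
    if (!all(c("age_band", "sex", "count") %in% names(df)))
      stop("base demand needs columns age_band, sex, count")
    df <- df[, c("age_band", "sex", "count")]
  }
  df <- df[df$age_band != "ALL", , drop = FALSE]
  rownames(df) <- NULL
  df
}

cell_count <- function(cells, band, sex, default = 0) {
  i <- which(cells$age_band == band & cells$sex == sex)
  if (length(i) == 0L) default else sum(cells$count[i])
}

# append ALL rows (column sums over bands) per sex present
add_all_rows <- function(df, value_col) {
  df <- df[df$age_band != "ALL", , drop = FALSE]
  sexes <- intersect(c("male", "female", "both"), unique(df$sex))
  alls <- do.call(rbind, lapply(sexes, function(sx) {
    r <- df[df$sex == sx, , drop = FALSE][1L, , drop = FALSE]
    r$age_band <- "ALL"
    r[[value_col]] <- sum(df[[value_col]][df$sex == sx])
    r
  }))
  out <- rbind(df, alls)
  rownames(out) <- NULL
  out
}
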