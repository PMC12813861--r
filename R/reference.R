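#' Bundled Taipei reference tables
#'
#' The package ships the published Taipei 2015 base-year reference values
#' as plain CSVs: the age-gender weighting factors for 2036 and 2051, the
#' 2015 yearly demand by stratum, the base-year temperature-demand
#' equations, the reference projection table, and the reference projected
#' equations. They serve as fixed inputs for reproducing the reported
#' projections (the record-level data behind them is restricted and not
#' distributable).
#'
#' @param name One of `"weights"`, `"demand_2015"`, `"equations_2015"`,
#'   `"projection"`, `"equations_projected"`.
#' @return The table as a data frame.
#' @export
taipei_reference <- function(name = c("weights", "demand_2015",
                                      "equations_2015", "projection",
                                      "equations_projected")) {
  name <- match.arg(name)
  file <- c(weights = "taipei_weights.csv",
            demand_2015 = "taipei_demand_2015.csv",
            equations_2015 = "taipei_equations_2015.csv",
            projection = "taipei_projection_2036_2051.csv",
            equations_projected = "taipei_equations_projected.csv")[[name]]
  path <- system.file("extdata", file, package = "easproj", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", strip.white = TRUE)
}

#' Reference weighting factors as an `eas_weights` table
#'
#' @param target_year 2036 or 2051.
#' @return An `eas_weights` object (base year 2015); the overall ratio is
#'   the all-age both-sex factor of the reference table.
#' @export
taipei_weight_table <- function(target_year) {
  w <- taipei_reference("weights")
  w <- w[w$target_year == target_year, , drop = FALSE]
  if (nrow(w) == 0L) stop("reference weights available for 2036 and 2051 only")
  overall <- w$weight[w$age_band == "ALL" & w$sex == "both"]
  as_eas_weights(w[w$age_band != "ALL", c("age_band", "sex", "weight")],
                 base_year = 2015L, target_year = as.integer(target_year),
                 overall_ratio = overall)
}

#' Reference base-year equations as quadratic models
#'
#' @param combined If `TRUE`, include the summed all-strata equation.
#' @return Named list of `eas_quadmodel` objects (`"sex age_band"`).
#' @export
taipei_base_equations <- function(combined = FALSE) {
  eq <- taipei_reference("equations_2015")
  if (!combined) eq <- eq[eq$age_band != "ALL", , drop = FALSE]
  out <- lapply(seq_len(nrow(eq)), function(i) {
    r <- eq[i, ]
    quad_model(r$constant, r$b1, r$b2,
               ci_b1 = c(r$ci_b1_low, r$ci_b1_high),
               ci_b2 = c(r$ci_b2_low, r$ci_b2_high),
               adj_r2 = r$adj_r2, sex = r$sex, age_band = r$age_band)
  })
  names(out) <- paste(eq$sex, eq$age_band)
  out
}
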