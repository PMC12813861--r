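#' Read every population pyramid in a file
#'
#' @param path Pyramid file (header `year,sex,age,count`) possibly
#'   covering many years.
#' @param sep Field separator.
#' @return Named list of `eas_pyramid` objects keyed by year.
#' @export
read_pyramids <- function(path, sep = ",") {
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         colClasses = "character", strip.white = TRUE)
  if (!("year" %in% names(raw))) stop("pyramid file must have a year column")
  years <- sort(unique(as.integer(raw$year)))
  out <- lapply(years, function(y) read_pyramid(path, y, sep = sep))
  names(out) <- years
  out
}

#' Export stratum equations in the standard layout
#'
#' @param models List of `eas_quadmodel` objects.
#' @param path Output file.
#' @param target_year,adjustment Optional columns for projected equations.
#' @param header_comment Optional leading comment line.
#' @return `path`, invisibly.
#' @export
write_equations <- function(models, path, target_year = NULL,
                            adjustment = NULL, header_comment = NULL) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  df <- do.call(rbind, lapply(models, function(m) data.frame(
    sex = m$sex, age_band = m$age_band,
    constant = fmt(m$constant), b1 = fmt(m$b1), b2 = fmt(m$b2),
    ci_b1_low = fmt(m$ci_b1[1L]), ci_b1_high = fmt(m$ci_b1[2L]),
    ci_b2_low = fmt(m$ci_b2[1L]), ci_b2_high = fmt(m$ci_b2[2L]),
    adj_r2 = fmt(m$adj_r2), stringsAsFactors = FALSE)))
  if (!is.null(adjustment)) df <- cbind(adjustment = adjustment, df)
  if (!is.null(target_year)) df <- cbind(target_year = target_year, df)
  rownames(df) <- NULL
  write_table_with_comment(df, path, header_comment)
}

#' Export a projection table in the standard layout
#'
#' Demand cells are rounded to integers, percentages to integers.
#'
#' @param tab Output of [projection_table()].
#' @param path Output file.
#' @param header_comment Optional leading comment line.
#' @return `path`, invisibly.
#' @export
write_projection <- function(tab, path, header_comment = NULL) {
  out <- tab
  for (col in c("actual_base", "unadjusted", "adjusted"))
    out[[col]] <- sprintf("%.0f", out[[col]])
  out$difference_pct <- sprintf("%.0f", out$difference_pct)
  write_table_with_comment(out, path, header_comment)
}

# small stable config fingerprint for output provenance headers
# (polynomial rolling hash mod 2^31-1; exact in double arithmetic)
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full projection pipeline
#'
#' Executes every stage end to end: read (or accept in-memory) records,
#' pyramids and temperatures; screen yearly totals with Grubbs' test when
#' several years of records are supplied; aggregate demand; compute
#' weighting factors; project yearly demand (adjusted and unadjusted) for
#' each target year; build the year-by-year trajectory; fit the
#' stratum-level quadratic temperature-demand equations on the base year;
#' project and combine them; and export every table.
#'
#' Artifacts written to `out_dir`: `weights_<target>.csv`,
#' `projection.csv`, `equations_base.csv`, `equations_projected.csv`,
#' `trajectory.csv`, `curves_base.csv`, `curves_<target>.csv`, and
#' `run_log.txt`. Every CSV carries a header comment with the config
#' fingerprint and seed, so a rerun on identical inputs is byte-identical.
#'
#' @param records `eas_records` data frame or path to a records file.
#' @param pyramids Named list of `eas_pyramid` (keyed by year) or path to
#'   a pyramid file.
#' @param temps Temperature data frame (`date`, `temp`) or path.
#' @param base_year Base calendar year.
#' @param target_years Target years (default `c(2036, 2051)`).
#' @param scheme Band scheme (default [projection_scheme()]).
#' @param both_mode Both-sex mode for [project_adjusted()].
#' @param alpha Grubbs significance level.
#' @param grid Curve grid `c(t_min, t_max, step)`.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in output headers (for provenance of
#'   synthetic inputs; the pipeline itself is deterministic).
#' @return Invisible list with the computed objects (`weights`,
#'   `projection`, `trajectory`, `base_models`, `projected_models`,
#'   `combined`, `grubbs`) and `files` (paths).
#' @export
run_pipeline <- function(records, pyramids, temps, base_year,
                         target_years = c(2036L, 2051L),
                         scheme = projection_scheme(),
                         both_mode = c("sum_of_sex", "aggregate_weight"),
                         alpha = 0.05, grid = c(0, 50, 1),
                         out_dir = ".", seed = NA_integer_) {
  both_mode <- match.arg(both_mode)
  stopifnot(all(target_years >= base_year), length(grid) == 3L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  recs <- stage("read_records",
                if (is.character(records)) read_records(records) else records)
  pyrs <- stage("read_pyramids",
                if (is.character(pyramids)) read_pyramids(pyramids) else pyramids)
  tmps <- stage("read_temperature",
                if (is.character(temps)) read_temperature(temps) else temps)
  cfg_fp <- config_hash(list(base_year, target_years, scheme$label, both_mode,
                             alpha, grid, nrow(recs), seed))
  hdr <- sprintf("easproj %s | config %s | seed %s",
                 as.character(utils::packageVersion("easproj")), cfg_fp,
                 ifelse(is.na(seed), "none", seed))
  say("easproj pipeline, version %s, config %s, seed %s",
      as.character(utils::packageVersion("easproj")), cfg_fp,
      ifelse(is.na(seed), "none", seed))
  say("records in: %d", nrow(recs))

  # base-year screening: only meaningful with >= 3 years of records
  rec_years <- table(format(recs$date, "%Y"))
  grb <- NULL
  if (length(rec_years) >= 3L) {
    grb <- stage("grubbs", grubbs_test(as.numeric(rec_years), alpha = alpha,
                                       labels = names(rec_years)))
    say("Grubbs screening over %d years: max Z %.2f at %s (critical %.3f), %s",
        length(rec_years), grb$max_z, grb$max_item, grb$critical_value,
        ifelse(grb$significant, "SIGNIFICANT OUTLIER", "no significant outlier"))
  }

  base_recs <- recs[format(recs$date, "%Y") == as.character(base_year), ,
                    drop = FALSE]
  yearly <- stage("aggregate_yearly",
                  aggregate_demand(base_recs, scheme, "yearly"))
  daily <- stage("aggregate_daily",
                 aggregate_demand(base_recs, scheme, "daily"))
  say("base year %d: %d records kept, %d dropped for missing age/sex",
      base_year, sum(yearly$count[yearly$sex != "both"]),
      attr(yearly, "n_dropped"))

  files <- list()
  p0 <- pyrs[[as.character(base_year)]]
  if (is.null(p0)) stop(sprintf("stage 'weights' failed: no pyramid for base year %d",
                                base_year))
  weights <- list(); projection <- list()
  base_models <- stage("fit_equations", fit_strata(daily, tmps))
  projected_models <- list()
  combined <- list(base = combine_equations(base_models))
  files$curves_base <- file.path(out_dir, "curves_base.csv")
  write_table_with_comment(curve_table(combined$base, grid[1], grid[2], grid[3]),
                           files$curves_base, hdr)
  for (ty in target_years) {
    key <- as.character(ty)
    pt <- pyrs[[key]]
    if (is.null(pt)) stop(sprintf("stage 'weights' failed: no pyramid for target year %s", key))
    w <- stage("weights", compute_weights(p0, pt, scheme))
    weights[[key]] <- w
    files[[paste0("weights_", key)]] <- file.path(out_dir,
                                                  sprintf("weights_%s.csv", key))
    write_weights(w, files[[paste0("weights_", key)]], hdr)
    projection[[key]] <- stage("project", projection_table(yearly, w, both_mode))
    adj_models <- lapply(base_models, function(m)
      project_equation(m, weight_for(w, m$age_band, m$sex)))
    una_models <- lapply(base_models, function(m)
      project_equation(m, attr(w, "overall_ratio")))
    projected_models[[key]] <- list(with = adj_models, without = una_models)
    combined[[paste0("with_", key)]] <- combine_equations(adj_models)
    combined[[paste0("without_", key)]] <- combine_equations(una_models)
    files[[paste0("curves_", key)]] <- file.path(out_dir,
                                                 sprintf("curves_%s.csv", key))
    curves <- rbind(
      cbind(adjustment = "with",
            curve_table(combined[[paste0("with_", key)]], grid[1], grid[2], grid[3])),
      cbind(adjustment = "without",
            curve_table(combined[[paste0("without_", key)]], grid[1], grid[2], grid[3])))
    write_table_with_comment(curves, files[[paste0("curves_", key)]], hdr)
    as_proj <- function(col) stats::setNames(
      projection[[key]][c("age_band", "sex", col)],
      c("age_band", "sex", "projected"))
    say("target %s: overall ratio %.4f, adjusted total %.0f, unadjusted total %.0f",
        key, attr(w, "overall_ratio"),
        proj_total(as_proj("adjusted"), both_mode),
        proj_total(as_proj("unadjusted"), "sum_of_sex"))
  }
  proj_all <- do.call(rbind, projection)
  rownames(proj_all) <- NULL
  files$projection <- file.path(out_dir, "projection.csv")
  write_projection(proj_all, files$projection, hdr)

  files$equations_base <- file.path(out_dir, "equations_base.csv")
  write_equations(c(base_models, list(combined$base)), files$equations_base,
                  header_comment = hdr)
  files$equations_projected <- file.path(out_dir, "equations_projected.csv")
  eq_rows <- list(); tys <- character(); adjs <- character()
  for (ty in as.character(target_years)) for (ad in c("with", "without")) {
    ms <- c(projected_models[[ty]][[ad]],
            list(combined[[paste0(ad, "_", ty)]]))
    eq_rows <- c(eq_rows, ms)
    tys <- c(tys, rep(ty, length(ms)))
    adjs <- c(adjs, rep(ad, length(ms)))
  }
  write_equations(eq_rows, files$equations_projected, target_year = tys,
                  adjustment = adjs, header_comment = hdr)

  traj <- stage("trajectory",
                project_trajectory(yearly, pyrs, base_year, scheme, both_mode))
  files$trajectory <- file.path(out_dir, "trajectory.csv")
  write_table_with_comment(
    data.frame(year = traj$year,
               adjusted_total = sprintf("%.1f", traj$adjusted_total),
               unadjusted_total = sprintf("%.1f", traj$unadjusted_total)),
    files$trajectory, hdr)

  files$run_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, files$run_log)
  invisible(list(weights = weights, projection = proj_all, trajectory = traj,
                 base_models = base_models, projected_models = projected_models,
                 combined = combined, grubbs = grb, files = files))
}
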