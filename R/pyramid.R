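#' Read a population pyramid from a delimited text file
#'
#' The file must have a header `year,sex,age,count`. `sex` is `M`/`F`
#' (case-insensitive; `male`/`female` also accepted). `age` is either a
#' single-year integer or a band label (`"a-b"`, `"a+"`); single-year ages
#' are retained so the pyramid can later be re-binned to any scheme.
#'
#' @param path Path to the delimited file.
#' @param year Calendar year to extract.
#' @param sep Field separator (default `","`).
#' @return An `eas_pyramid`: a data frame with columns `sex` (`"male"` /
#'   `"female"`), `age_lower`, `age_upper` (`Inf` for an open band) and
#'   `count`, with the year stored as an attribute.
#' @export
read_pyramid <- function(path, year, sep = ",") {
  raw <- utils::read.csv(path, sep = sep, comment.char = "#",
                         colClasses = "character", strip.white = TRUE)
  need <- c("year", "sex", "age", "count")
  if (!all(need %in% names(raw)))
    stop("pyramid file must have columns year, sex, age, count")
  raw <- raw[as.integer(raw$year) == as.integer(year), , drop = FALSE]
  if (nrow(raw) == 0L)
    stop(sprintf("no rows for requested year %d", as.integer(year)))
  sex <- decode_sex(raw$sex)
  if (anyNA(sex)) {
    bad <- which(is.na(sex))[1L]
    stop(sprintf("unknown sex code '%s' at row %d", raw$sex[bad], bad))
  }
  count <- suppressWarnings(as.numeric(raw$count))
  if (anyNA(count) || any(count < 0)) {
    bad <- which(is.na(count) | count < 0)[1L]
    stop(sprintf("invalid count '%s' at row %d", raw$count[bad], bad))
  }
  bounds <- lapply(raw$age, parse_band_label)
  out <- data.frame(
    sex       = sex,
    age_lower = vapply(bounds, `[[`, numeric(1), 1L),
    age_upper = vapply(bounds, `[[`, numeric(1), 2L),
    count     = count,
    stringsAsFactors = FALSE
  )
  new_pyramid(out, as.integer(year))
}

new_pyramid <- function(df, year) {
  structure(df, year = year, class = c("eas_pyramid", "data.frame"))
}

#' @export
print.eas_pyramid <- function(x, ...) {
  cat(sprintf("Population pyramid, year %d: %s persons in %d rows\n",
              attr(x, "year"), format(sum(x$count), big.mark = ","), nrow(x)))
  invisible(x)
}

decode_sex <- function(x) {
  key <- tolower(trimws(x))
  out <- rep(NA_character_, length(key))
  out[key %in% c("m", "male")] <- "male"
  out[key %in% c("f", "female")] <- "female"
  out
}

#' Bin a pyramid to an age-band scheme
#'
#' Sums single-year (or finer-band) counts into the bands of `scheme`. The
#' grand total is conserved exactly; source intervals that straddle a band
#' boundary are rejected.
#'
#' @param p An `eas_pyramid`.
#' @param scheme An `eas_scheme` (see [age_scheme()]).
#' @return An `eas_pyramid` with one row per (sex, band) present.
#' @export
bin_pyramid <- function(p, scheme) {
  stopifnot(inherits(p, "eas_pyramid"), inherits(scheme, "eas_scheme"))
  band <- assign_band_interval(p$age_lower, p$age_upper, scheme)
  agg <- stats::aggregate(count ~ band + sex,
                          data = cbind(as.data.frame(p), band = band),
                          FUN = sum)
  bi <- match(agg$band, scheme$label)
  si <- match(agg$sex, c("male", "female"))
  ord <- order(si, bi)
  out <- data.frame(sex = agg$sex,
                    age_lower = scheme$lower[bi],
                    age_upper = scheme$upper[bi],
                    count = agg$count, stringsAsFactors = FALSE)[ord, ]
  rownames(out) <- NULL
  new_pyramid(out, attr(p, "year"))
}

# counts per scheme band for one sex ("male"/"female") or "both"
band_counts <- function(p, scheme, sex) {
  b <- bin_pyramid(p, scheme)
  lab <- ifelse(is.finite(b$age_upper),
                paste0(b$age_lower, "-", b$age_upper),
                paste0(b$age_lower, "+"))
  keep <- if (identical(sex, "both")) rep(TRUE, nrow(b)) else b$sex == sex
  out <- vapply(scheme$label, function(L) sum(b$count[keep & lab == L]),
                numeric(1))
  names(out) <- scheme$label
  out
}

#' Age-gender-specific weighting factors between two pyramids
#'
#' For each (age band, sex) stratum the weighting factor is the ratio of the
#' target-year population to the base-year population in that stratum: the
#' population-change index that multiplies base-year demand (and base-year
#' temperature-demand equations) in the projection. Both-sex weights and the
#' overall (all-age, both-sex) ratio are also computed.
#'
#' @param base,target `eas_pyramid` objects for the base and target years.
#' @param scheme An `eas_scheme`; defaults to [projection_scheme()].
#' @return An `eas_weights` data frame with columns `age_band`, `sex`
#'   (`"male"`, `"female"`, `"both"`) and `weight`, plus attributes
#'   `base_year`, `target_year`, `overall_ratio` and `scheme`.
#' @examples
#' p0 <- new_pyramid_df(2015, sex = c("male", "female"),
#'                      age = c(90, 90), count = c(10, 25))
#' compute_weights(p0, p0, age_scheme(c(0, 65)))  # identity: all weights 1
#' @export
compute_weights <- function(base, target, scheme = projection_scheme()) {
  by <- attr(base, "year"); ty <- attr(target, "year")
  rows <- list()
  for (sx in c("male", "female", "both")) {
    b <- band_counts(base, scheme, sx)
    t <- band_counts(target, scheme, sx)
    zero <- b == 0 & t > 0
    if (any(zero))
      stop(sprintf("zero base population in stratum (%s, %s)",
                   names(b)[zero][1L], sx))
    w <- ifelse(b > 0, t / b, NA_real_)
    rows[[sx]] <- data.frame(age_band = scheme$label, sex = sx, weight = w,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  total_b <- sum(band_counts(base, scheme, "both"))
  total_t <- sum(band_counts(target, scheme, "both"))
  new_weights(out, base_year = by, target_year = ty,
              overall_ratio = total_t / total_b, scheme = scheme)
}

new_weights <- function(df, base_year, target_year, overall_ratio, scheme) {
  structure(df, base_year = base_year, target_year = target_year,
            overall_ratio = overall_ratio, scheme = scheme,
            class = c("eas_weights", "data.frame"))
}

#' Construct a weight table from known weighting factors
#'
#' Used when the weighting factors come from a published table rather than
#' from pyramid division (e.g. reproducing reported projections).
#'
#' @param df Data frame with columns `age_band`, `sex`, `weight`.
#' @param base_year,target_year Calendar years.
#' @param overall_ratio All-age both-sex population ratio target/base.
#' @return An `eas_weights` object.
#' @export
as_eas_weights <- function(df, base_year, target_year, overall_ratio) {
  stopifnot(all(c("age_band", "sex", "weight") %in% names(df)),
            all(df$weight > 0), overall_ratio > 0)
  scheme <- parse_scheme(unique(df$age_band))
  new_weights(df[, c("age_band", "sex", "weight")],
              base_year = base_year, target_year = target_year,
              overall_ratio = overall_ratio, scheme = scheme)
}

#' @export
print.eas_weights <- function(x, ...) {
  cat(sprintf("Weighting factors %d -> %d (overall ratio %.4f)\n",
              attr(x, "base_year"), attr(x, "target_year"),
              attr(x, "overall_ratio")))
  print.data.frame(cbind(x[c("age_band", "sex")],
                         weight = round(x$weight, 2)))
  invisible(x)
}

# weight lookup; errors if the stratum is absent
weight_for <- function(w, band, sex) {
  i <- which(w$age_band == band & w$sex == sex)
  if (length(i) != 1L)
    stop(sprintf("no weighting factor for stratum (%s, %s)", band, sex))
  w$weight[i]
}

#' Build a pyramid in code
#'
#' Convenience constructor mainly for examples and tests: single-year ages
#' or bands given as vectors.
#'
#' @param year Calendar year.
#' @param sex Character vector (`"male"`/`"female"` or `M`/`F`).
#' @param age Integer ages or band labels.
#' @param count Non-negative counts.
#' @return An `eas_pyramid`.
#' @export
new_pyramid_df <- function(year, sex, age, count) {
  sx <- decode_sex(sex)
  stopifnot(!anyNA(sx), all(count >= 0))
  bounds <- lapply(as.character(age), parse_band_label)
  new_pyramid(data.frame(
    sex = sx,
    age_lower = vapply(bounds, `[[`, numeric(1), 1L),
    age_upper = vapply(bounds, `[[`, numeric(1), 2L),
    count = as.numeric(count), stringsAsFactors = FALSE
  ), as.integer(year))
}

#' Export a weight table in the standard layout
#'
#' Writes `base_year,target_year,age_band,sex,weight` rows (weights at 2 dp)
#' plus a final `ALL,BOTH` row carrying the overall population ratio.
#'
#' @param w An `eas_weights` object.
#' @param path Output file path.
#' @param header_comment Optional comment line(s) written before the header.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path, header_comment = NULL) {
  df <- data.frame(base_year = attr(w, "base_year"),
                   target_year = attr(w, "target_year"),
                   age_band = w$age_band, sex = w$sex,
                   weight = sprintf("%.2f", w$weight))
  df <- rbind(df, data.frame(base_year = attr(w, "base_year"),
                             target_year = attr(w, "target_year"),
                             age_band = "ALL", sex = "BOTH",
                             weight = sprintf("%.2f", attr(w, "overall_ratio"))))
  write_table_with_comment(df, path, header_comment)
}

write_table_with_comment <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
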