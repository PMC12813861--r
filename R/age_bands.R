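#' Age-band schemes
#'
#' An age-band scheme partitions ages 0, 1, 2, ... into contiguous, disjoint
#' bands, the last of which is open-ended. Two schemes are used throughout:
#' the projection scheme `0-64, 65-74, 75-84, 85+` that drives the
#' age-gender weighting, and the profile scheme `0-14, 15-34, 35-64, 65+`
#' used for descriptive demand tables.
#'
#' @param lowers Integer vector of band lower bounds, starting at 0 and
#'   strictly increasing. The last band is open-ended.
#' @return A data frame of class `eas_scheme` with columns `lower`, `upper`
#'   (`Inf` for the open band) and `label` (e.g. `"65-74"`, `"85+"`).
#' @examples
#' age_scheme(c(0, 65, 75, 85))
#' @export
age_scheme <- function(lowers) {
  lowers <- as.integer(lowers)
  if (length(lowers) < 1L || lowers[1L] != 0L)
    stop("scheme must start at age 0")
  if (is.unsorted(lowers, strictly = TRUE))
    stop("band lower bounds must be strictly increasing")
  upper <- c(lowers[-1L] - 1L, Inf)
  label <- ifelse(is.finite(upper),
                  paste0(lowers, "-", upper),
                  paste0(lowers, "+"))
  out <- data.frame(lower = lowers, upper = upper, label = label,
                    stringsAsFactors = FALSE)
  class(out) <- c("eas_scheme", "data.frame")
  out
}

#' Parse an age-band scheme from band labels
#'
#' Accepts labels of the form `"a-b"`, `"a+"`, `"<b"` (shorthand for
#' `0-(b-1)`) or a single age `"a"`. The labels must describe disjoint bands
#' that cover every age from 0 upwards with no gap; a gapped or overlapping
#' set is rejected with the offending age.
#'
#' @param labels Character vector of band labels.
#' @return An `eas_scheme` (see [age_scheme()]).
#' @examples
#' parse_scheme(c("<15", "15-34", "35-64", "65+"))
#' @export
parse_scheme <- function(labels) {
  bounds <- lapply(labels, parse_band_label)
  lower <- vapply(bounds, `[[`, numeric(1), 1L)
  upper <- vapply(bounds, `[[`, numeric(1), 2L)
  o <- order(lower)
  lower <- lower[o]; upper <- upper[o]
  if (lower[1L] != 0)
    stop("gap at 0: scheme must cover age 0")
  n <- length(lower)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      if (lower[i + 1L] <= upper[i])
        stop(sprintf("overlapping bands at age %d", as.integer(lower[i + 1L])))
      if (lower[i + 1L] > upper[i] + 1)
        stop(sprintf("gap at %d", as.integer(upper[i] + 1)))
    }
  }
  if (is.finite(upper[n]))
    stop("last band must be open-ended (\"a+\")")
  age_scheme(lower)
}

# "a-b" / "a+" / "<b" / "a" -> c(lower, upper)
parse_band_label <- function(x) {
  x <- gsub("–|—", "-", trimws(x))  # en/em dashes
  if (grepl("^<\\s*[0-9]+$", x)) {
    b <- as.numeric(sub("^<\\s*", "", x))
    return(c(0, b - 1))
  }
  if (grepl("^[0-9]+\\s*\\+$", x))
    return(c(as.numeric(sub("\\+.*$", "", x)), Inf))
  if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", x)) {
    parts <- as.numeric(strsplit(x, "-")[[1L]])
    if (parts[2L] < parts[1L]) stop(sprintf("invalid band '%s'", x))
    return(parts)
  }
  if (grepl("^[0-9]+$", x))
    return(rep(as.numeric(x), 2L))
  stop(sprintf("cannot parse age band '%s'", x))
}

#' Default schemes
#'
#' `projection_scheme()` returns the four-band scheme `0-64, 65-74, 75-84,
#' 85+` used for the demographic weighting; `profile_scheme()` returns the
#' descriptive scheme `0-14, 15-34, 35-64, 65+`.
#'
#' @return An `eas_scheme`.
#' @export
projection_scheme <- function() age_scheme(c(0L, 65L, 75L, 85L))

#' @rdname projection_scheme
#' @export
profile_scheme <- function() age_scheme(c(0L, 15L, 35L, 65L))

# Map integer ages to band labels; NA ages propagate.
assign_band <- function(age, scheme) {
  idx <- findInterval(age, scheme$lower)
  lab <- scheme$label[idx]
  lab[is.na(age)] <- NA_character_
  lab
}

# Map (age_lower, age_upper) rows (single years or bands) to scheme bands;
# a source interval that straddles a scheme boundary is an error.
assign_band_interval <- function(lower, upper, scheme) {
  li <- findInterval(lower, scheme$lower)
  cap <- ifelse(is.finite(upper), upper, pmax(lower, scheme$lower[nrow(scheme)]))
  ui <- findInterval(cap, scheme$lower)
  bad <- which(li != ui)
  if (length(bad))
    stop(sprintf("age interval %s-%s straddles a band boundary of the scheme",
                 lower[bad[1L]], upper[bad[1L]]))
  scheme$label[li]
}
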