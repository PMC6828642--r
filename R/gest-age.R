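#' Gestational age as weeks + days
#'
#' Gestational ages are carried as an integer number of days since
#' conception and displayed in the obstetric `weeks + days` notation
#' (e.g. `"25 + 4"`). Storing whole days avoids any rounding drift in
#' week/day arithmetic; decimal weeks are always derived, never stored.
#'
#' @param weeks Integer vector of completed weeks (>= 0).
#' @param days Integer vector of remaining days, each in 0..6.
#' @return An object of class `gest_age` (an integer vector of days).
#' @examples
#' ga <- gest_age(25, 4)
#' ga_decimal_weeks(ga)
#' @export
gest_age <- function(weeks, days = 0L) {
  if (length(days) == 1L) days <- rep(days, length(weeks))
  if (length(weeks) != length(days)) {
    stopf("'weeks' and 'days' must have the same length")
  }
  if (any(!is.finite(weeks)) || any(!is.finite(days))) {
    stopf("gestational-age components must be finite")
  }
  if (any(weeks != floor(weeks)) || any(days != floor(days))) {
    stopf("gestational-age components must be whole numbers")
  }
  if (any(weeks < 0)) stopf("weeks must be >= 0")
  if (any(days < 0 | days > 6)) stopf("days must be in 0..6")
  structure(as.integer(weeks) * 7L + as.integer(days), class = "gest_age")
}

new_gest_age_days <- function(total_days) {
  if (any(total_days < 0)) stopf("gestational age cannot be negative")
  structure(as.integer(round(total_days)), class = "gest_age")
}

#' Parse gestational ages written as "weeks + days" or decimal weeks
#'
#' Accepts the notation used in clinical tables, e.g. `"25 + 4"` (25 weeks
#' and 4 days) with or without spaces, or a bare decimal-weeks number such
#' as `"25.571"`, which is converted to the nearest whole day.
#'
#' @param text Character vector.
#' @return A [gest_age] vector.
#' @examples
#' parse_gest_age("39 + 6")
#' parse_gest_age("40.0")
#' @export
parse_gest_age <- function(text) {
  text <- trimws(as.character(text))
  out <- integer(length(text))
  for (i in seq_along(text)) {
    s <- text[[i]]
    if (grepl("^\\d+\\s*\\+\\s*\\d+$", s)) {
      parts <- as.integer(strsplit(s, "\\+")[[1]])
      out[[i]] <- unclass(gest_age(parts[[1]], parts[[2]]))
    } else if (grepl("^\\d+(\\.\\d+)?$", s)) {
      w <- as.numeric(s)
      out[[i]] <- as.integer(round(w * 7))
    } else {
      stopf("cannot parse gestational age '%s'", s)
    }
  }
  structure(out, class = "gest_age")
}

#' @rdname gest_age
#' @param x A `gest_age` object.
#' @export
ga_weeks <- function(x) {
  stopifnot(inherits(x, "gest_age"))
  unclass(x) %/% 7L
}

#' @rdname gest_age
#' @export
ga_days <- function(x) {
  stopifnot(inherits(x, "gest_age"))
  unclass(x) %% 7L
}

#' @rdname gest_age
#' @export
ga_decimal_weeks <- function(x) {
  stopifnot(inherits(x, "gest_age"))
  unclass(x) / 7
}

#' @export
format.gest_age <- function(x, ...) {
  sprintf("%d + %d", ga_weeks(x), ga_days(x))
}

#' @export
print.gest_age <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
`[.gest_age` <- function(x, i) {
  structure(unclass(x)[i], class = "gest_age")
}

#' Gestational age at MRI from birth age and postnatal interval
#'
#' The gestational age at MRI (GAMRI) is the gestational age at birth plus
#' the postnatal period up to the scan date, computed in exact whole days
#' and renormalised to weeks + days.
#'
#' @param ga_birth [gest_age] at birth.
#' @param postnatal_days Integer vector of days between birth and the MRI
#'   examination (>= 0).
#' @return A [gest_age] vector.
#' @examples
#' compute_gamri(gest_age(39, 6), 17)  # 42 + 2
#' @export
compute_gamri <- function(ga_birth, postnatal_days) {
  stopifnot(inherits(ga_birth, "gest_age"))
  if (any(!is.finite(postnatal_days)) || any(postnatal_days < 0) ||
      any(postnatal_days != floor(postnatal_days))) {
    stopf("'postnatal_days' must be whole numbers >= 0")
  }
  new_gest_age_days(unclass(ga_birth) + as.integer(postnatal_days))
}

#' Allocate a subject to the preterm or term-born group
#'
#' Births before 37 completed weeks of gestation are preterm; births at or
#' after 37 + 0 weeks are term. The cutoff is a step function with its
#' single breakpoint at exactly 37.0 decimal weeks.
#'
#' @param ga_birth [gest_age] at birth.
#' @return Character vector, `"preterm"` or `"term"`.
#' @export
allocate_group <- function(ga_birth) {
  stopifnot(inherits(ga_birth, "gest_age"))
  ifelse(ga_decimal_weeks(ga_birth) < 37, "preterm", "term")
}
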