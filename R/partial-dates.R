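#' Parse FAERS partial dates
#'
#' FAERS date fields (`FDA_DT`, `EVENT_DT`, `START_DT`) are numeric strings of
#' 4, 6 or 8 digits, carrying year, month or day precision. The canonical
#' in-memory representation kept throughout the package is the validated digit
#' string itself (`"2023"`, `"202304"`, `"20230415"`), with `NA` as the
#' missing-value marker. Anything malformed — wrong length, non-digits, month
#' outside 1-12, or an impossible calendar day such as `"20230231"` — parses
#' to `NA`; the function is total and never throws on content.
#'
#' @param raw character vector of raw date strings (or anything coercible).
#' @return character vector of canonical partial dates, `NA` where missing or
#'   invalid.
#' @examples
#' parse_partial_date(c("20230415", "202304", "2023", "20230231", ""))
#' @export
parse_partial_date <- function(raw) {
  x <- trimws(as.character(raw))
  x[!is.na(x) & x == ""] <- NA_character_
  out <- rep(NA_character_, length(x))
  ok <- which(!is.na(x) & grepl("^([0-9]{4}|[0-9]{6}|[0-9]{8})$", x))
  if (length(ok) == 0) return(out)
  cand <- x[ok]
  nc <- nchar(cand)
  valid <- rep(TRUE, length(cand))
  has_m <- nc >= 6
  if (any(has_m)) {
    m <- as.integer(substr(cand[has_m], 5, 6))
    valid[has_m][m < 1 | m > 12] <- FALSE
  }
  is8 <- nc == 8 & valid
  if (any(is8)) {
    valid[is8] <- !is.na(as.Date(cand[is8], format = "%Y%m%d"))
  }
  out[ok[valid]] <- cand[valid]
  out
}

#' Partial-date accessors
#'
#' Field accessors and precision for canonical partial-date strings as
#' produced by [parse_partial_date()].
#'
#' @param pd character vector of canonical partial dates.
#' @return `pd_precision()` returns `"year"`, `"month"` or `"day"` (`NA` for
#'   missing); `pd_year()`, `pd_month()`, `pd_day()` return integers (`NA`
#'   where the component is absent); `pd_as_date()` returns a `Date`, `NA`
#'   unless day precision.
#' @export
pd_precision <- function(pd) {
  unname(c("4" = "year", "6" = "month", "8" = "day")[as.character(nchar(pd))])
}

#' @rdname pd_precision
#' @export
pd_year <- function(pd) as.integer(substr(pd, 1, 4))

#' @rdname pd_precision
#' @export
pd_month <- function(pd) {
  out <- rep(NA_integer_, length(pd))
  i <- !is.na(pd) & nchar(pd) >= 6
  out[i] <- as.integer(substr(pd[i], 5, 6))
  out
}

#' @rdname pd_precision
#' @export
pd_day <- function(pd) {
  out <- rep(NA_integer_, length(pd))
  i <- !is.na(pd) & nchar(pd) == 8
  out[i] <- as.integer(substr(pd[i], 7, 8))
  out
}

#' @rdname pd_precision
#' @export
pd_as_date <- function(pd) {
  out <- rep(as.Date(NA), length(pd))
  i <- !is.na(pd) & nchar(pd) == 8
  out[i] <- as.Date(pd[i], format = "%Y%m%d")
  out
}

#' Compare partial dates at the coarsest common precision
#'
#' Two partial dates are compared by truncating both to the coarser of the two
#' precisions, so `"2023"` vs `"20230315"` compares `2023` against `2023`
#' (equal). This is the ordering used by the deduplication rule and the
#' temporal exclusion; a strict inequality at the coarsest common precision is
#' the only way one date counts as "later" than the other.
#'
#' @param x,y character vectors of canonical partial dates (recycled).
#' @return integer vector: `-1` (`x` earlier), `0` (equal at common
#'   precision), `1` (`x` later); `NA` when either side is missing.
#' @export
pd_compare <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  out <- rep(NA_integer_, n)
  i <- !is.na(x) & !is.na(y)
  if (any(i)) {
    k <- pmin(nchar(x[i]), nchar(y[i]))
    xv <- as.numeric(substr(x[i], 1, k))
    yv <- as.numeric(substr(y[i], 1, k))
    out[i] <- as.integer(sign(xv - yv))
  }
  out
}
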