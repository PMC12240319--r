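#' Collapse report versions to one record per case
#'
#' FAERS distributes every revision of a case as a separate report
#' (`PRIMARYID`) under a shared `CASEID`. The FDA-recommended rule keeps, per
#' case, the record with the latest receipt date (`FDA_DT`); when receipt
#' dates tie, the higher `PRIMARYID` survives. Receipt dates of differing
#' precision are compared at the coarsest common precision (see
#' [pd_compare()]); a missing receipt date sorts lowest. `PRIMARYID`s are
#' compared numerically when both parse as numbers, otherwise
#' lexicographically after left-zero-padding to equal length.
#'
#' @param demo tibble of DEMO records (`primaryid`, `caseid`, `fda_dt` at
#'   minimum).
#' @return list with `demo` (one surviving row per `caseid`), and `report`
#'   containing `n_input`, `n_cases`, `removed_primaryids`,
#'   `n_primaryid_ties` (groups decided by the tie-break) and
#'   `n_coarse_comparisons` (groups where mixed date precisions forced a
#'   coarsened comparison).
#' @export
dedupe_cases <- function(demo) {
  stopifnot(all(c("primaryid", "caseid", "fda_dt") %in% names(demo)))
  if (any(is.na(demo$caseid) | demo$caseid == "") ||
      any(is.na(demo$primaryid) | demo$primaryid == "")) {
    stop("dedupe_cases: caseid and primaryid must be nonempty")
  }
  pid_case <- unique(demo[c("primaryid", "caseid")])
  if (anyDuplicated(pid_case$primaryid)) {
    bad <- pid_case$primaryid[duplicated(pid_case$primaryid)]
    stop("corrupt input: primaryid(s) appear under multiple caseids: ",
         paste(head(unique(bad), 5), collapse = ", "))
  }

  dup_case <- unique(demo$caseid[duplicated(demo$caseid)])
  single <- !(demo$caseid %in% dup_case)
  ties <- 0L
  coarse <- 0L
  keep_idx <- which(single)
  if (length(dup_case)) {
    grp <- split(which(!single), demo$caseid[!single])
    pick <- vapply(grp, function(idx) {
      fda <- demo$fda_dt[idx]
      prec <- nchar(fda)
      if (length(unique(prec[!is.na(fda)])) > 1) coarse <<- coarse + 1L
      best <- idx[1]
      for (j in idx[-1]) {
        cmp <- .later_fda(demo$fda_dt[j], demo$fda_dt[best])
        if (cmp == 1L) {
          best <- j
        } else if (cmp == 0L) {
          ties <<- ties + 1L
          if (.pid_greater(demo$primaryid[j], demo$primaryid[best])) best <- j
        }
      }
      best
    }, integer(1))
    keep_idx <- c(keep_idx, unname(pick))
  }
  keep_idx <- sort(keep_idx)
  survivors <- demo[keep_idx, ]
  removed <- demo$primaryid[-keep_idx]
  list(
    demo = survivors,
    report = list(
      n_input = nrow(demo),
      n_cases = nrow(survivors),
      removed_primaryids = removed,
      n_primaryid_ties = ties,
      n_coarse_comparisons = coarse
    )
  )
}

# -1/0/1 comparison of fda_dt with missing sorting lowest.
.later_fda <- function(x, y) {
  if (is.na(x) && is.na(y)) return(0L)
  if (is.na(x)) return(-1L)
  if (is.na(y)) return(1L)
  pd_compare(x, y)
}

# TRUE if primaryid x outranks y: numeric when both numeric, else
# lexicographic after zero-padding to equal width.
.pid_greater <- function(x, y) {
  num <- grepl("^[0-9]+$", c(x, y))
  if (all(num)) return(as.numeric(x) > as.numeric(y))
  w <- max(nchar(x), nchar(y))
  formatC(x, width = w, flag = "0") > formatC(y, width = w, flag = "0")
}

#' Drop child-table rows belonging to removed report versions
#'
#' Deduplication removes superseded `primaryid`s from DEMO; the same pass must
#' drop their DRUG/REAC/OUTC/THER rows so no stage sees orphan records.
#'
#' @param tbl child-table tibble with a `primaryid` column.
#' @param kept_primaryids character vector of surviving `primaryid`s.
#' @return filtered tibble.
#' @export
filter_to_primaryids <- function(tbl, kept_primaryids) {
  tbl[tbl$primaryid %in% kept_primaryids, ]
}
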