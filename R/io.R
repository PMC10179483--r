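COHORT_COLS <- c("mouse_id", "line", "sex", "diet", "measure", "week", "t_min", "value")
COHORT_MEASURES <- c("bw_g", "glucose_mg_dl", "liver_g", "spleen_g", "heart_g")

#' Write a cohort to the tidy interchange CSV
#'
#' One row per mouse x measurement; columns
#' `mouse_id,line,sex,diet,measure,week,t_min,value`. `t_min` is empty
#' except on glucose rows. The file round-trips exactly through
#' [read_cohort()].
#'
#' @param cohort a `cc_cohort` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort), all(COHORT_COLS %in% names(cohort)))
  write.csv(cohort[COHORT_COLS], path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a cohort from the tidy interchange CSV
#'
#' Validates the schema as it parses: missing columns, non-numeric values
#' and non-positive weights raise errors naming the offending row and
#' column, so malformed inputs fail at the boundary rather than deep in the
#' analysis.
#'
#' @param path CSV file as written by [write_cohort()].
#' @return a `cc_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  raw <- read.csv(path, colClasses = "character", na.strings = "")
  missing_cols <- setdiff(COHORT_COLS, names(raw))
  if (length(missing_cols))
    stop_input("cohort CSV %s is missing column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  raw <- raw[COHORT_COLS]
  num <- function(col) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(x))
    if (length(bad))
      stop_input("cohort CSV parse error: non-numeric '%s' at row %d (value '%s')",
                 col, bad[1L], raw[[col]][bad[1L]])
    x
  }
  out <- data.frame(mouse_id = raw$mouse_id, line = raw$line, sex = raw$sex,
                    diet = raw$diet, measure = raw$measure,
                    week = num("week"), t_min = num("t_min"),
                    value = num("value"), stringsAsFactors = FALSE)
  if (nrow(out)) {
    out$week <- as.integer(out$week)
    bad <- which(is.na(out$value))
    if (length(bad))
      stop_input("cohort CSV parse error: missing 'value' at row %d", bad[1L])
    bad <- which(!out$measure %in% COHORT_MEASURES)
    if (length(bad))
      stop_input("cohort CSV parse error: unknown measure '%s' at row %d",
                 out$measure[bad[1L]], bad[1L])
    bad <- which(out$value <= 0)
    if (length(bad))
      stop_input("cohort CSV parse error: non-positive 'value' at row %d (measure %s)",
                 bad[1L], out$measure[bad[1L]])
    bad <- which(!is.na(out$t_min) & out$measure != "glucose_mg_dl")
    if (length(bad))
      stop_input("cohort CSV parse error: 't_min' set on non-glucose row %d", bad[1L])
    bad <- which(is.na(out$t_min) & out$measure == "glucose_mg_dl")
    if (length(bad))
      stop_input("cohort CSV parse error: missing 't_min' on glucose row %d", bad[1L])
  }
  class(out) <- c("cc_cohort", "data.frame")
  out
}

#' @export
print.cc_cohort <- function(x, ...) {
  cat(sprintf("CC cohort: %d animals, %d lines, %d measurement rows\n",
              length(unique(x$mouse_id)), length(unique(x$line)), nrow(x)))
  NextMethod()
}
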