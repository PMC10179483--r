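#' Construct a study design for a CC diet-challenge cohort
#'
#' A study design fixes the panel of CC lines, the per-cell animal counts
#' (line x sex x diet), the bi-weekly body-weight measurement schedule, the
#' weeks at which an intraperitoneal glucose tolerance test (IPGTT) is run,
#' and the IPGTT sampling minutes.
#'
#' @param group_sizes data.frame with columns `line`, `sex` (`"F"`/`"M"`),
#'   `diet` (`"CHD"`/`"HFD"`) and `n` (non-negative integer counts). One row
#'   per design cell; omitted cells count 0.
#' @param weeks ordered integer vector of measurement weeks.
#' @param ipgtt_weeks subset of `weeks` with an IPGTT.
#' @param ipgtt_timepoints_min strictly increasing minutes, starting at 0.
#' @return an object of class `cc_design`.
#' @seealso [default_design()] for the 8-line reference design.
#' @export
study_design <- function(group_sizes,
                         weeks = seq(0L, 12L, by = 2L),
                         ipgtt_weeks = c(6L, 12L),
                         ipgtt_timepoints_min = c(0L, 15L, 30L, 60L, 120L, 180L)) {
  stopifnot(is.data.frame(group_sizes),
            all(c("line", "sex", "diet", "n") %in% names(group_sizes)))
  gs <- group_sizes
  gs$line <- as.character(gs$line)
  if (!all(gs$sex %in% c("F", "M"))) stop_input("sex must be 'F' or 'M'")
  if (!all(gs$diet %in% c("CHD", "HFD"))) stop_input("diet must be 'CHD' or 'HFD'")
  if (!all(vapply(gs$n, is_count, logical(1L))))
    stop_input("all group sizes must be non-negative integers")
  gs$n <- as.integer(gs$n)
  if (anyDuplicated(gs[c("line", "sex", "diet")]))
    stop_input("duplicate (line, sex, diet) cell in group_sizes")
  if (is.unsorted(weeks, strictly = TRUE)) stop_input("weeks must be strictly increasing")
  if (!all(ipgtt_weeks %in% weeks)) stop_input("ipgtt_weeks must be a subset of weeks")
  tp <- ipgtt_timepoints_min
  if (length(tp) < 2L || tp[1L] != 0 || is.unsorted(tp, strictly = TRUE))
    stop_input("ipgtt timepoints must be strictly increasing and start at 0")
  structure(list(lines = unique(gs$line),
                 group_sizes = gs[order(match(gs$line, unique(gs$line)), gs$sex, gs$diet), ,
                                  drop = FALSE],
                 weeks = as.integer(weeks),
                 ipgtt_weeks = as.integer(ipgtt_weeks),
                 ipgtt_timepoints_min = as.numeric(tp)),
            class = "cc_design")
}

#' The reference 8-line, 207-animal study design
#'
#' Returns the diet-challenge design of the reference cohort: 8 CC lines,
#' two sexes, two diet arms (standard chow, CHD, vs high-fat, HFD), with the
#' published per-cell animal counts totalling 207; body weight recorded
#' bi-weekly over the 12-week challenge and IPGTT at weeks 6 and 12 sampled
#' at 0, 15, 30, 60, 120 and 180 minutes.
#'
#' @return a `cc_design` object.
#' @export
#' @examples
#' d <- default_design()
#' sum(d$group_sizes$n)  # 207
default_design <- function() {
  # per-cell counts: (CHD F, CHD M, HFD F, HFD M) per line
  counts <- list(
    IL72   = c(4, 4, 4, 6),
    IL557  = c(6, 3, 8, 5),
    IL711  = c(7, 4, 7, 5),
    IL1912 = c(10, 9, 7, 8),
    IL2513 = c(4, 5, 3, 7),
    IL3912 = c(4, 10, 10, 7),
    IL4141 = c(4, 8, 7, 6),
    IL5000 = c(7, 5, 14, 9)
  )
  gs <- do.call(rbind, lapply(names(counts), function(l) {
    data.frame(line = l,
               sex = c("F", "M", "F", "M"),
               diet = c("CHD", "CHD", "HFD", "HFD"),
               n = counts[[l]],
               stringsAsFactors = FALSE)
  }))
  study_design(gs)
}

#' @export
print.cc_design <- function(x, ...) {
  cat(sprintf("CC study design: %d lines, %d animals\n",
              length(x$lines), sum(x$group_sizes$n)))
  cat(sprintf("  weeks: %s; IPGTT at weeks %s (t = %s min)\n",
              paste(x$weeks, collapse = ","),
              paste(x$ipgtt_weeks, collapse = ","),
              paste(x$ipgtt_timepoints_min, collapse = ",")))
  invisible(x)
}

design_total <- function(design) sum(design$group_sizes$n)
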