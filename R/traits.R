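#' Trapezoidal area under a glucose curve
#'
#' Integrates a glucose tolerance curve by the trapezoid rule over all
#' adjacent timepoint pairs, from the first to the last reading: each
#' segment contributes (time difference) x (sum of its two glucose levels)/2,
#' and the total is the sum of segments. For the standard 0-180 min IPGTT
#' this is the total (not baseline-subtracted) AUC in min.mg/dL.
#'
#' @param t_min timepoints in minutes, strictly increasing; or a data.frame
#'   with columns `t_min` and `glucose_mg_dl`.
#' @param glucose_mg_dl glucose readings, same length as `t_min`.
#' @return the AUC (min.mg/dL).
#' @export
#' @examples
#' compute_auc(c(0, 15, 30, 60, 120, 180), rep(100, 6))  # 18000
compute_auc <- function(t_min, glucose_mg_dl = NULL) {
  if (is.data.frame(t_min)) {
    glucose_mg_dl <- t_min$glucose_mg_dl
    t_min <- t_min$t_min
  }
  if (length(t_min) < 2L) stop_input("AUC needs at least 2 readings")
  if (length(t_min) != length(glucose_mg_dl))
    stop_input("times and readings differ in length")
  if (anyNA(t_min) || anyNA(glucose_mg_dl)) stop_input("AUC input contains NA")
  if (is.unsorted(t_min, strictly = TRUE))
    stop_input("timepoints must be strictly increasing")
  sum(diff(t_min) * (glucose_mg_dl[-length(glucose_mg_dl)] + glucose_mg_dl[-1L]) / 2)
}

#' Body-weight change over the challenge
#'
#' `BW(final week) - BW(week 0)`; may be negative for animals that lost
#' weight.
#'
#' @param bw named numeric vector of body weights, names = weeks.
#' @param final_week the challenge's last week (default 12).
#' @return weight change in grams.
#' @export
delta_bw <- function(bw, final_week = 12) {
  w <- as.numeric(names(bw))
  if (!0 %in% w) stop_input("week-0 body weight missing")
  if (!final_week %in% w) stop_input("week-%s body weight missing", final_week)
  unname(bw[match(final_week, w)] - bw[match(0, w)])
}

#' Percent (adjusted) organ weight
#'
#' Organ weight as a percentage of final body weight:
#' `organ_g / final_bw_g x 100`. Invariant under joint rescaling of both
#' weights.
#'
#' @param organ_g organ weight (g), > 0.
#' @param final_bw_g final body weight (g), > 0.
#' @return percent organ weight.
#' @export
percent_organ_weight <- function(organ_g, final_bw_g) {
  if (any(!is.finite(organ_g)) || any(!is.finite(final_bw_g)) ||
      any(organ_g <= 0) || any(final_bw_g <= 0))
    stop_input("organ and body weight must be positive")
  organ_g / final_bw_g * 100
}

#' Group-level diet contrast of organ-weight change per body-weight change
#'
#' For one (line, sex) cell, the difference of mean organ weight between the
#' HFD and CHD groups divided by the difference of mean body-weight change
#' (delta-BW) between the same groups. A zero denominator is flagged, never
#' returned as an infinity.
#'
#' @param traits a `cc_traits` table from [derive_traits()].
#' @param line,sex the cell.
#' @param organ `"liver"`, `"spleen"` or `"heart"`.
#' @return a list with the four group means, `ratio`, `n_hfd`, `n_chd` and a
#'   `flag` (`""`, or `"undefined_zero_dbw_difference"`).
#' @export
group_delta_ratio <- function(traits, line, sex, organ = c("liver", "spleen", "heart")) {
  organ <- match.arg(organ)
  cell <- traits[traits$line == line & traits$sex == sex, , drop = FALSE]
  hfd <- cell[cell$diet == "HFD", , drop = FALSE]
  chd <- cell[cell$diet == "CHD", , drop = FALSE]
  if (nrow(hfd) == 0L || nrow(chd) == 0L)
    stop_input("empty diet group for line %s sex %s", line, sex)
  ocol <- paste0(organ, "_g")
  num <- mean(hfd[[ocol]]) - mean(chd[[ocol]])
  den <- mean(hfd$dbw_g) - mean(chd$dbw_g)
  out <- list(line = line, sex = sex, organ = organ,
              mean_organ_hfd = mean(hfd[[ocol]]), mean_organ_chd = mean(chd[[ocol]]),
              mean_dbw_hfd = mean(hfd$dbw_g), mean_dbw_chd = mean(chd$dbw_g),
              n_hfd = nrow(hfd), n_chd = nrow(chd),
              ratio = if (den == 0) NA_real_ else num / den,
              flag = if (den == 0) "undefined_zero_dbw_difference" else "")
  out
}

#' Derive the per-mouse phenotype table from a raw cohort
#'
#' Computes, for every animal: initial and final body weight, delta-BW,
#' total glucose AUC at each IPGTT week, actual terminal organ weights and
#' percent (final-BW-adjusted) organ weights. Per-mouse problems (missing
#' endpoint weights, incomplete glucose curves, missing organs) raise errors
#' naming the mouse.
#'
#' @param cohort a `cc_cohort` (from [generate_cohort()] or [read_cohort()]).
#' @param final_week last challenge week (default: the cohort's maximum
#'   body-weight week).
#' @return a `cc_traits` data.frame, one row per mouse, with columns
#'   `mouse_id, line, sex, diet, bw0_g, bw_final_g, dbw_g, auc_wk<w>...,
#'   liver_g, spleen_g, heart_g, pct_liver, pct_spleen, pct_heart`.
#' @export
derive_traits <- function(cohort, final_week = NULL) {
  stopifnot(is.data.frame(cohort))
  if (nrow(cohort) == 0L) stop_input("empty cohort")
  bw <- cohort[cohort$measure == "bw_g", , drop = FALSE]
  glu <- cohort[cohort$measure == "glucose_mg_dl", , drop = FALSE]
  if (is.null(final_week)) final_week <- max(bw$week)
  ipgtt_weeks <- sort(unique(glu$week))
  t_window <- range(glu$t_min)
  ids <- unique(cohort$mouse_id)

  rows <- lapply(ids, function(id) {
    m <- cohort[cohort$mouse_id == id, , drop = FALSE]
    mbw <- m[m$measure == "bw_g", , drop = FALSE]
    bwv <- setNames(mbw$value, mbw$week)
    db <- tryCatch(delta_bw(bwv, final_week),
                   error = function(e) stop_input("mouse %s: %s", id, conditionMessage(e)))
    bw0 <- unname(bwv[match(0, as.numeric(names(bwv)))])
    bwf <- unname(bwv[match(final_week, as.numeric(names(bwv)))])
    aucs <- vapply(ipgtt_weeks, function(w) {
      g <- m[m$measure == "glucose_mg_dl" & m$week == w, , drop = FALSE]
      g <- g[order(g$t_min), , drop = FALSE]
      if (nrow(g) == 0L) stop_input("mouse %s: no IPGTT at week %d", id, w)
      if (min(g$t_min) != t_window[1L] || max(g$t_min) != t_window[2L])
        stop_input("mouse %s: week-%d glucose curve does not span %g-%g min",
                   id, w, t_window[1L], t_window[2L])
      compute_auc(g$t_min, g$value)
    }, numeric(1L))
    org <- vapply(c("liver_g", "spleen_g", "heart_g"), function(oc) {
      v <- m$value[m$measure == oc]
      if (length(v) != 1L) stop_input("mouse %s: missing terminal %s", id, oc)
      v
    }, numeric(1L))
    c(list(mouse_id = id, line = m$line[1L], sex = m$sex[1L], diet = m$diet[1L],
           bw0_g = bw0, bw_final_g = bwf, dbw_g = db),
      setNames(as.list(aucs), paste0("auc_wk", ipgtt_weeks)),
      as.list(org),
      list(pct_liver = percent_organ_weight(org[["liver_g"]], bwf),
           pct_spleen = percent_organ_weight(org[["spleen_g"]], bwf),
           pct_heart = percent_organ_weight(org[["heart_g"]], bwf)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  bad <- out$mouse_id[out$pct_liver >= 100 | out$pct_spleen >= 100 | out$pct_heart >= 100]
  if (length(bad))
    stop_input("mouse %s: organ weight not below body weight", bad[1L])
  rownames(out) <- NULL
  class(out) <- c("cc_traits", "data.frame")
  out
}

#' All (line, sex, organ) group delta ratios of a trait table
#'
#' Convenience wrapper applying [group_delta_ratio()] over every (line, sex)
#' cell with both diet groups present; cells with an empty diet arm are
#' flagged and kept.
#'
#' @param traits a `cc_traits` table.
#' @return data.frame, one row per line x sex x organ.
#' @export
group_delta_ratio_table <- function(traits) {
  cells <- unique(traits[c("line", "sex")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    do.call(rbind, lapply(c("liver", "spleen", "heart"), function(o) {
      cell <- traits[traits$line == cells$line[i] & traits$sex == cells$sex[i], ]
      if (!all(c("CHD", "HFD") %in% cell$diet)) {
        return(data.frame(line = cells$line[i], sex = cells$sex[i], organ = o,
                          mean_organ_hfd = NA_real_, mean_organ_chd = NA_real_,
                          mean_dbw_hfd = NA_real_, mean_dbw_chd = NA_real_,
                          n_hfd = sum(cell$diet == "HFD"), n_chd = sum(cell$diet == "CHD"),
                          ratio = NA_real_, flag = "empty_diet_group",
                          stringsAsFactors = FALSE))
      }
      as.data.frame(group_delta_ratio(traits, cells$line[i], cells$sex[i], o),
                    stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
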