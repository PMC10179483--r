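#' Simulation parameters for a synthetic CC diet-challenge cohort
#'
#' Defines the generative model behind [generate_cohort()]. Each trait family
#' follows an additive linear model with line, sex, diet and line-by-diet
#' effects plus residual noise:
#'
#' * **Body weight** (raw grams): a per-animal intercept
#'   `mu0 + sex_effect x male + line + animal` grows linearly at
#'   `growth + line_growth + animal_growth` g/week, with HFD animals adding
#'   `growth_hfd + line-by-diet growth` g/week from challenge week 0 onward
#'   (so diet arms coincide in expectation at week 0, when the high-fat diet
#'   starts). Weekly readings add measurement noise; non-positive draws are
#'   rejected and redrawn.
#' * **Glucose / IPGTT**: fasting glucose is linear-additive in mg/dL; each
#'   test curve follows the gamma-pulse
#'   `glucose(t) = fasting + A (t/tau) exp(1 - t/tau) + noise`, which rises
#'   to an exact peak `fasting + A` at `t = tau` and then clears
#'   monotonically. High-fat animals have both `A` and `tau` inflated by
#'   `hfd_clearance_mult`, slowing clearance and raising the curve.
#' * **Organ weights** (liver, spleen, heart): linear-additive on the log
#'   scale (effects are log-ratios), guaranteeing positive weights and the
#'   right-skew of weight data; `mu` is the median weight in grams of a
#'   chow-fed female.
#'
#' Line effects are drawn once per line per trait family and shared by all
#' of that line's animals; the implied broad-sense heritability of a family
#' is `sigma_line^2 / (sigma_line^2 + sigma_within^2)` (see [implied_h2()]).
#' Defaults are chosen so that trait heritabilities span roughly 0.1-0.8,
#' the range typical of line-replicate panels.
#'
#' @param bw,glucose,liver,spleen,heart named lists overriding individual
#'   defaults of that family (see Details for the field names).
#' @param seed integer seed; the generator is bit-reproducible given the
#'   seed and design.
#' @return an object of class `cc_params`.
#' @export
sim_params <- function(bw = list(), glucose = list(), liver = list(),
                       spleen = list(), heart = list(), seed = 42L) {
  def <- list(
    bw = list(mu0 = 21, sex_effect = 4, growth = 0.55, growth_hfd = 0.45,
              sigma_line = 1.8, sigma_line_growth = 0.12,
              sigma_int_growth = 0.10, sigma_animal = 1.3,
              sigma_animal_growth = 0.08, sigma_meas = 0.3),
    glucose = list(fasting_mu = 100, sex_effect = 8, diet_effect = 15,
                   sigma_line = 8, sigma_int = 6, sigma_animal = 10,
                   sigma_meas = 5, peak_amplitude = 180, time_to_peak = 30,
                   hfd_clearance_mult = 1.35, sigma_line_amp = 15),
    liver = list(mu = 1.30, sex_effect = 0.10, diet_effect = 0.18,
                 sigma_line = 0.15, sigma_int = 0.06, sigma_e = 0.10),
    spleen = list(mu = 0.09, sex_effect = -0.05, diet_effect = 0.10,
                  sigma_line = 0.12, sigma_int = 0.08, sigma_e = 0.15),
    heart = list(mu = 0.15, sex_effect = 0.08, diet_effect = -0.03,
                 sigma_line = 0.08, sigma_int = 0.04, sigma_e = 0.10)
  )
  user <- list(bw = bw, glucose = glucose, liver = liver,
               spleen = spleen, heart = heart)
  for (fam in names(user)) {
    bad <- setdiff(names(user[[fam]]), names(def[[fam]]))
    if (length(bad)) stop_input("unknown %s parameter(s): %s", fam, paste(bad, collapse = ", "))
    def[[fam]][names(user[[fam]])] <- user[[fam]]
  }
  sds <- unlist(lapply(def, function(f) f[grep("^sigma", names(f))]))
  if (any(sds < 0)) stop_input("all s.d. parameters must be >= 0")
  if (def$glucose$time_to_peak <= 0) stop_input("time_to_peak must be > 0")
  if (def$glucose$peak_amplitude < 0) stop_input("peak_amplitude must be >= 0")
  if (def$glucose$hfd_clearance_mult <= 0) stop_input("hfd_clearance_mult must be > 0")
  def$seed <- as.integer(seed)
  structure(def, class = "cc_params")
}

#' Heritability implied by simulation parameters
#'
#' The broad-sense heritability a trait family was generated with:
#' between-line variance over between-line plus within-line variance, on the
#' scale the family is simulated on (log scale for organs; the body-weight
#' value refers to the 12-week weight change `dbw`).
#'
#' @param params a `cc_params` object.
#' @param trait one of `"liver"`, `"spleen"`, `"heart"`, `"dbw"`, `"fasting"`.
#' @return implied H-squared in `[0, 1]`.
#' @export
implied_h2 <- function(params, trait = c("liver", "spleen", "heart", "dbw", "fasting")) {
  trait <- match.arg(trait)
  if (trait %in% c("liver", "spleen", "heart")) {
    f <- params[[trait]]
    vg <- f$sigma_line^2
    ve <- f$sigma_e^2
  } else if (trait == "dbw") {
    f <- params$bw
    vg <- (12 * f$sigma_line_growth)^2
    ve <- (12 * f$sigma_animal_growth)^2 + 2 * f$sigma_meas^2
  } else {
    f <- params$glucose
    vg <- f$sigma_line^2
    ve <- f$sigma_animal^2 + f$sigma_meas^2
  }
  if (vg + ve == 0) return(NA_real_)
  vg / (vg + ve)
}

# gamma-pulse IPGTT mean curve; peaks at exactly fasting + A when t = tau
ipgtt_mean_curve <- function(t, fasting, A, tau) {
  fasting + A * (t / tau) * exp(1 - t / tau)
}

#' Simulate one IPGTT glucose curve
#'
#' Draws a single intraperitoneal glucose tolerance test curve under the
#' gamma-pulse model of [sim_params()]. With zero measurement noise the
#' curve equals the model mean exactly: `fasting` at t = 0 and
#' `fasting + A` at the (diet-inflated) time-to-peak.
#'
#' @param week test week; must be one of the design's IPGTT weeks.
#' @param diet `"CHD"` or `"HFD"`; HFD inflates `A` and `tau` by the
#'   clearance-slowing multiplier.
#' @param params a `cc_params` object.
#' @param design a `cc_design`; supplies timepoints and valid weeks.
#' @param fasting fasting glucose (mg/dL); default is the family grand mean
#'   (plus diet effect for HFD).
#' @return data.frame with columns `t_min`, `glucose_mg_dl`.
#' @export
simulate_ipgtt <- function(week, diet = c("CHD", "HFD"), params = sim_params(),
                           design = default_design(), fasting = NULL) {
  diet <- match.arg(diet)
  if (!week %in% design$ipgtt_weeks)
    stop_input("week %s has no IPGTT in this design (IPGTT weeks: %s)",
               week, paste(design$ipgtt_weeks, collapse = ", "))
  g <- params$glucose
  hfd <- diet == "HFD"
  if (is.null(fasting)) fasting <- g$fasting_mu + if (hfd) g$diet_effect else 0
  A <- g$peak_amplitude * if (hfd) g$hfd_clearance_mult else 1
  tau <- g$time_to_peak * if (hfd) g$hfd_clearance_mult else 1
  t <- design$ipgtt_timepoints_min
  y <- ipgtt_mean_curve(t, fasting, A, tau) + rnorm(length(t), 0, g$sigma_meas)
  data.frame(t_min = t, glucose_mg_dl = y)
}

#' Generate a synthetic CC diet-challenge cohort
#'
#' Simulates one animal per design slot under the generative model of
#' [sim_params()]: bi-weekly body weights over the challenge, IPGTT glucose
#' curves at the design's IPGTT weeks, and terminal liver, spleen and heart
#' weights at the final week. Line (and line-by-diet) effects are drawn once
#' per line per trait family; the same seed yields a bit-identical cohort.
#'
#' @param design a `cc_design` (default: [default_design()]).
#' @param params a `cc_params` (default: [sim_params()]).
#' @return a `cc_cohort`: a tidy data.frame with one row per measurement and
#'   columns `mouse_id, line, sex, diet, measure, week, t_min, value`, where
#'   `measure` is one of `bw_g`, `glucose_mg_dl`, `liver_g`, `spleen_g`,
#'   `heart_g`. Values are rounded to 4 decimals (the precision of the CSV
#'   interchange format).
#' @export
#' @examples
#' co <- generate_cohort(default_design(), sim_params(seed = 1))
#' length(unique(co$mouse_id))  # 207
generate_cohort <- function(design = default_design(), params = sim_params()) {
  stopifnot(inherits(design, "cc_design"), inherits(params, "cc_params"))
  gs <- design$group_sizes[design$group_sizes$n > 0, , drop = FALSE]
  with_seed(child_seed(params$seed, "generate_cohort"), generate_cohort_impl(design, gs, params))
}

generate_cohort_impl <- function(design, gs, params) {

  lines <- design$lines
  nl <- length(lines)
  p <- params
  # line effects, one draw per line per trait family (fixed draw order)
  le <- list(
    bw_int    = setNames(rnorm(nl, 0, p$bw$sigma_line), lines),
    bw_growth = setNames(rnorm(nl, 0, p$bw$sigma_line_growth), lines),
    bw_intx   = setNames(rnorm(nl, 0, p$bw$sigma_int_growth), lines),
    glu_fast  = setNames(rnorm(nl, 0, p$glucose$sigma_line), lines),
    glu_intx  = setNames(rnorm(nl, 0, p$glucose$sigma_int), lines),
    glu_amp   = setNames(rnorm(nl, 0, p$glucose$sigma_line_amp), lines),
    liver     = setNames(rnorm(nl, 0, p$liver$sigma_line), lines),
    liver_x   = setNames(rnorm(nl, 0, p$liver$sigma_int), lines),
    spleen    = setNames(rnorm(nl, 0, p$spleen$sigma_line), lines),
    spleen_x  = setNames(rnorm(nl, 0, p$spleen$sigma_int), lines),
    heart     = setNames(rnorm(nl, 0, p$heart$sigma_line), lines),
    heart_x   = setNames(rnorm(nl, 0, p$heart$sigma_int), lines)
  )

  # animal table in design order
  an <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i) {
    r <- gs[i, ]
    data.frame(line = r$line, sex = r$sex, diet = r$diet,
               rep = seq_len(r$n), stringsAsFactors = FALSE)
  }))
  an$mouse_id <- sprintf("%s_%s_%s_%02d", an$line, an$sex, an$diet, an$rep)
  n <- nrow(an)
  male <- as.numeric(an$sex == "M")
  hfd <- as.numeric(an$diet == "HFD")
  weeks <- design$weeks
  final_week <- max(weeks)

  # body weight: per-animal intercept and growth rate, weekly readings
  bw_int <- p$bw$mu0 + p$bw$sex_effect * male + le$bw_int[an$line] +
    rnorm(n, 0, p$bw$sigma_animal)
  bw_slope <- p$bw$growth + le$bw_growth[an$line] +
    rnorm(n, 0, p$bw$sigma_animal_growth) +
    hfd * (p$bw$growth_hfd + le$bw_intx[an$line])
  mu_bw <- outer(bw_int, rep(1, length(weeks))) + outer(bw_slope, weeks)
  bw <- mu_bw + matrix(rnorm(n * length(weeks), 0, p$bw$sigma_meas), n)
  for (k in seq_len(100)) {           # reject non-positive readings
    bad <- which(bw <= 0)
    if (!length(bad)) break
    bw[bad] <- mu_bw[bad] + rnorm(length(bad), 0, p$bw$sigma_meas)
  }
  if (any(bw <= 0)) stop_input("body-weight rejection sampling failed; check parameters")

  # glucose: per-animal fasting level and curve amplitude
  fast <- p$glucose$fasting_mu + p$glucose$sex_effect * male +
    hfd * (p$glucose$diet_effect + le$glu_intx[an$line]) +
    le$glu_fast[an$line] + rnorm(n, 0, p$glucose$sigma_animal)
  amp <- pmax(0, p$glucose$peak_amplitude + le$glu_amp[an$line]) *
    ifelse(hfd == 1, p$glucose$hfd_clearance_mult, 1)
  tau <- p$glucose$time_to_peak * ifelse(hfd == 1, p$glucose$hfd_clearance_mult, 1)
  tp <- design$ipgtt_timepoints_min
  glu <- lapply(design$ipgtt_weeks, function(w) {
    y <- t(vapply(seq_len(n),
                  function(i) ipgtt_mean_curve(tp, fast[i], amp[i], tau[i]),
                  numeric(length(tp))))
    y + matrix(rnorm(n * length(tp), 0, p$glucose$sigma_meas), n)
  })
  names(glu) <- design$ipgtt_weeks

  # terminal organ weights, log-additive
  organ <- sapply(c("liver", "spleen", "heart"), function(o) {
    f <- p[[o]]
    lx <- le[[o]][an$line]
    ix <- le[[paste0(o, "_x")]][an$line]
    exp(log(f$mu) + f$sex_effect * male + hfd * (f$diet_effect + ix) + lx +
          rnorm(n, 0, f$sigma_e))
  })

  blocks <- vector("list", 3L)
  blocks[[1L]] <- data.frame(
    mouse_id = rep(an$mouse_id, each = length(weeks)),
    line = rep(an$line, each = length(weeks)),
    sex = rep(an$sex, each = length(weeks)),
    diet = rep(an$diet, each = length(weeks)),
    measure = "bw_g",
    week = rep(weeks, times = n),
    t_min = NA_real_,
    value = as.vector(t(bw)),
    stringsAsFactors = FALSE)
  blocks[[2L]] <- do.call(rbind, lapply(names(glu), function(w) data.frame(
    mouse_id = rep(an$mouse_id, each = length(tp)),
    line = rep(an$line, each = length(tp)),
    sex = rep(an$sex, each = length(tp)),
    diet = rep(an$diet, each = length(tp)),
    measure = "glucose_mg_dl",
    week = as.integer(w),
    t_min = rep(tp, times = n),
    value = as.vector(t(glu[[w]])),
    stringsAsFactors = FALSE)))
  blocks[[3L]] <- data.frame(
    mouse_id = rep(an$mouse_id, times = 3L),
    line = rep(an$line, times = 3L),
    sex = rep(an$sex, times = 3L),
    diet = rep(an$diet, times = 3L),
    measure = rep(c("liver_g", "spleen_g", "heart_g"), each = n),
    week = final_week,
    t_min = NA_real_,
    value = as.vector(organ),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, blocks)
  out <- out[order(match(out$mouse_id, an$mouse_id),
                   match(out$measure, c("bw_g", "glucose_mg_dl",
                                        "liver_g", "spleen_g", "heart_g")),
                   out$week, out$t_min, na.last = FALSE), , drop = FALSE]
  rownames(out) <- NULL
  out$value <- round(out$value, 4L)
  class(out) <- c("cc_cohort", "data.frame")
  out
}

#' Simulate a single line-replicate trait at a target heritability
#'
#' A direct generator for estimator calibration: draws `n_lines` line means
#' from `N(mu, h2 * sigma_p^2)` and adds residuals from
#' `N(0, (1 - h2) * sigma_p^2)`, so the implied broad-sense heritability is
#' exactly `h2`. Used by the parameter-recovery tests of the heritability
#' machinery at design sizes where simulating full cohorts would be wasteful.
#'
#' @param n_lines number of lines (>= 2).
#' @param n_per_line replicates per line.
#' @param h2 target heritability in `[0, 1]`.
#' @param mu grand mean. @param sigma_p total phenotypic s.d.
#' @param seed optional integer seed.
#' @return data.frame with columns `line`, `value`.
#' @export
simulate_line_trait <- function(n_lines, n_per_line, h2, mu = 0, sigma_p = 1,
                                seed = NULL) {
  stopifnot(n_lines >= 2L, n_per_line >= 1L, h2 >= 0, h2 <= 1, sigma_p >= 0)
  gen <- function() {
    lev <- sprintf("L%03d", seq_len(n_lines))
    lm_ <- rnorm(n_lines, 0, sigma_p * sqrt(h2))
    data.frame(line = rep(lev, each = n_per_line),
               value = mu + rep(lm_, each = n_per_line) +
                 rnorm(n_lines * n_per_line, 0, sigma_p * sqrt(1 - h2)),
               stringsAsFactors = FALSE)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
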