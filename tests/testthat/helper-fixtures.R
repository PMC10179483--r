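# Shared fixture builders. Everything is generated in code; no stored data.

# a small balanced design: 3 lines x 2 sexes x 2 diets x n each
tiny_design <- function(n = 3L, lines = c("L1", "L2", "L3")) {
  gs <- expand.grid(line = lines, sex = c("F", "M"), diet = c("CHD", "HFD"),
                    stringsAsFactors = FALSE)
  gs$n <- n
  study_design(gs)
}

# single-stratum design used for estimator recovery (one sex, one diet)
stratum_design <- function(n_lines, n_per_line) {
  study_design(data.frame(line = sprintf("L%02d", seq_len(n_lines)),
                          sex = "F", diet = "CHD", n = n_per_line))
}

# parameters with every noise source and effect switched off
silent_params <- function(seed = 1L) {
  z <- function(x) setNames(as.list(rep(0, length(x))), x)
  sim_params(
    bw = z(c("sex_effect", "growth_hfd", "sigma_line", "sigma_line_growth",
             "sigma_int_growth", "sigma_animal", "sigma_animal_growth",
             "sigma_meas")),
    glucose = c(z(c("sex_effect", "diet_effect", "sigma_line", "sigma_int",
                    "sigma_animal", "sigma_meas", "sigma_line_amp")),
                list(hfd_clearance_mult = 1)),
    liver = z(c("sex_effect", "diet_effect", "sigma_line", "sigma_int", "sigma_e")),
    spleen = z(c("sex_effect", "diet_effect", "sigma_line", "sigma_int", "sigma_e")),
    heart = z(c("sex_effect", "diet_effect", "sigma_line", "sigma_int", "sigma_e")),
    seed = seed)
}

# liver-only heritability target: total log-scale s.d. 0.15 split so the
# implied H2 equals h2 exactly, all other families at defaults
liver_h2_params <- function(h2, seed) {
  sim_params(liver = list(sigma_line = 0.15 * sqrt(h2),
                          sigma_e = 0.15 * sqrt(1 - h2),
                          sigma_int = 0),
             seed = seed)
}

# estimate H2 for one trait vector by the package's full estimator chain
estimate_h2 <- function(values, line) {
  an <- one_way_anova(values, line)
  vc <- variance_components(an$MSB, an$MSW, an$n0)
  heritability(vc$Vg, vc$Ve)
}

# direct-loop ANOVA oracle: sums of squares via explicit loops, no vectorised
# shortcuts shared with the implementation
anova_oracle <- function(values, line) {
  lev <- unique(line)
  a <- length(lev)
  N <- length(values)
  mu <- sum(values) / N
  ssb <- 0; ssw <- 0; sumsq_n <- 0
  for (l in lev) {
    v <- values[line == l]
    m <- sum(v) / length(v)
    ssb <- ssb + length(v) * (m - mu)^2
    for (x in v) ssw <- ssw + (x - m)^2
    sumsq_n <- sumsq_n + length(v)^2
  }
  list(MSB = ssb / (a - 1), MSW = ssw / (N - a),
       n0 = (N - sumsq_n / N) / (a - 1))
}

# held-out R^2 oracle by explicit loops
r2_oracle <- function(y, yhat) {
  m <- 0
  for (v in y) m <- m + v / length(y)
  sse <- 0; sst <- 0
  for (i in seq_along(y)) {
    sse <- sse + (y[i] - yhat[i])^2
    sst <- sst + (y[i] - m)^2
  }
  1 - sse / sst
}
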