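#' One-way ANOVA for a line-replicate trait
#'
#' Sums of squares between and within lines for the one-way random-effects
#' layout used in genetic reference populations: `MSB = SSB/(a-1)`,
#' `MSW = SSW/(N-a)`, with the unbalanced effective per-line sample size
#' `n0 = (N - sum(n_i^2)/N) / (a-1)` that makes `E[MSB] = Ve + n0 Vg`.
#'
#' @param values numeric trait values.
#' @param line line label per value.
#' @return list with `a` (lines), `N`, `n0`, `SSB`, `SSW`, `MSB`, `MSW`.
#' @export
#' @examples
#' one_way_anova(c(10, 12, 20, 22, 30, 32), rep(c("A", "B", "C"), each = 2))
one_way_anova <- function(values, line) {
  keep <- is.finite(values) & !is.na(line)
  values <- values[keep]
  line <- as.character(line[keep])
  ni <- table(line)
  a <- length(ni)
  N <- length(values)
  if (a < 2L) stop_input("one-way ANOVA needs at least 2 lines")
  if (all(ni < 2L)) stop_input("all lines are singletons; within-line variance inestimable")
  gm <- tapply(values, line, mean)
  mu <- mean(values)
  ssb <- sum(as.numeric(ni) * (gm[names(ni)] - mu)^2)
  ssw <- sum((values - gm[line])^2)
  n0 <- (N - sum(as.numeric(ni)^2) / N) / (a - 1)
  list(a = a, N = N, n0 = n0, SSB = ssb, SSW = ssw,
       MSB = ssb / (a - 1), MSW = ssw / (N - a))
}

#' Variance components from mean squares
#'
#' Method-of-moments extraction on the one-way random-effects model:
#' `Ve = MSW` and `Vg = max(0, (MSB - MSW)/n0)` (negative genetic-variance
#' estimates are clamped to zero).
#'
#' @param MSB,MSW between/within-line mean squares.
#' @param n0 effective per-line sample size (> 0).
#' @return list with `Vg` and `Ve`.
#' @export
variance_components <- function(MSB, MSW, n0) {
  if (!is.finite(n0) || n0 <= 0) stop_input("n0 must be > 0")
  list(Vg = max(0, (MSB - MSW) / n0), Ve = MSW)
}

#' Broad-sense heritability
#'
#' `H2 = Vg / (Vg + Ve)`: the fraction of phenotypic variance attributable
#' to genetic differences among lines. Returns `NA` (flagged-undefined) when
#' both components are zero.
#'
#' @param Vg genetic (between-line) variance, >= 0.
#' @param Ve environmental (within-line) variance, >= 0.
#' @return H2 in `[0, 1]`, or `NA` if `Vg + Ve == 0`.
#' @export
heritability <- function(Vg, Ve) {
  if (Vg < 0 || Ve < 0) stop_input("variance components must be >= 0")
  if (Vg + Ve == 0) return(NA_real_)
  Vg / (Vg + Ve)
}

#' Genetic coefficient of variation
#'
#' `CVg = SD(line means) / overall mean`: the sample standard deviation
#' (n-1 denominator) among per-line trait means, divided by the trait mean
#' over all animals. A scale-relative measure of absolute genetic variation;
#' undefined (NA) at zero overall mean.
#'
#' @param line_means per-line trait means (>= 2).
#' @param overall_mean animal-level trait mean.
#' @return CVg, or `NA` if `overall_mean == 0`.
#' @export
genetic_cv <- function(line_means, overall_mean) {
  if (length(line_means) < 2L) stop_input("CVg needs at least 2 line means")
  if (overall_mean == 0) return(NA_real_)
  sd(line_means) / overall_mean
}

h2_one_stratum <- function(values, line, trait, sex, diet) {
  flags <- character(0)
  base <- data.frame(trait = trait, sex = sex, diet = diet,
                     a = NA_real_, N = NA_real_, n0 = NA_real_,
                     MSB = NA_real_, MSW = NA_real_, Vg = NA_real_, Ve = NA_real_,
                     H2 = NA_real_, SD_lines = NA_real_, overall_mean = NA_real_,
                     CVg = NA_real_, flags = "", stringsAsFactors = FALSE)
  an <- tryCatch(one_way_anova(values, line), error = function(e) conditionMessage(e))
  if (is.character(an)) {
    base$flags <- paste0("anova_failed: ", an)
    return(base)
  }
  vc <- variance_components(an$MSB, an$MSW, an$n0)
  h2 <- heritability(vc$Vg, vc$Ve)
  if (is.na(h2)) flags <- c(flags, "zero_variance")
  lm_ <- tapply(values, as.character(line), mean)
  mu <- mean(values, na.rm = TRUE)
  cv <- genetic_cv(as.numeric(lm_), mu)
  if (is.na(cv)) flags <- c(flags, "zero_mean")
  base[c("a", "N", "n0", "MSB", "MSW", "Vg", "Ve", "H2",
         "SD_lines", "overall_mean", "CVg")] <-
    list(an$a, an$N, an$n0, an$MSB, an$MSW, vc$Vg, vc$Ve, h2,
         sd(as.numeric(lm_)), mu, cv)
  base$flags <- paste(flags, collapse = ";")
  base
}

#' Heritability and CVg table over all trait strata
#'
#' Estimates broad-sense heritability and the genetic coefficient of
#' variation for each trait within every sex x diet stratum (delta-BW,
#' glucose AUC, actual and percent organ weights), plus the per-sex,
#' diet-pooled ratio traits delta-liver/delta-BW and delta-spleen/delta-BW.
#' The ratio traits are computed on per-animal `organ_g / dbw_g` (an ANOVA
#' needs an animal-level quantity; the group-level contrast of
#' [group_delta_ratio()] has no replication), with animals of non-positive
#' delta-BW excluded and counted in `flags`. Strata whose ANOVA
#' preconditions fail are reported with flags, never dropped.
#'
#' @param traits a `cc_traits` table.
#' @param trait_cols columns of `traits` to analyse per sex x diet stratum;
#'   default: `dbw_g`, the last `auc_wk*` column, actual and percent organ
#'   weights.
#' @param ratio_traits include the diet-pooled per-sex ratio rows (default
#'   TRUE).
#' @return data.frame with columns `trait, sex, diet, a, N, n0, MSB, MSW,
#'   Vg, Ve, H2, SD_lines, overall_mean, CVg, flags`.
#' @export
heritability_table <- function(traits, trait_cols = NULL, ratio_traits = TRUE) {
  stopifnot(is.data.frame(traits), nrow(traits) > 0L)
  if (is.null(trait_cols)) {
    auc_cols <- grep("^auc_wk", names(traits), value = TRUE)
    auc_col <- if (length(auc_cols)) auc_cols[length(auc_cols)] else character(0)
    trait_cols <- c("dbw_g", auc_col, "liver_g", "spleen_g", "heart_g",
                    "pct_liver", "pct_spleen", "pct_heart")
    trait_cols <- intersect(trait_cols, names(traits))
  }
  out <- list()
  for (sx in sort(unique(traits$sex))) {
    for (dt in sort(unique(traits$diet))) {
      sub <- traits[traits$sex == sx & traits$diet == dt, , drop = FALSE]
      for (tc in trait_cols)
        out[[length(out) + 1L]] <- h2_one_stratum(sub[[tc]], sub$line, tc, sx, dt)
    }
  }
  if (ratio_traits) {
    for (sx in sort(unique(traits$sex))) {
      sub <- traits[traits$sex == sx, , drop = FALSE]
      ok <- sub$dbw_g > 0
      ratio_map <- c(dlw_dbw = "liver_g", dsw_dbw = "spleen_g")
      for (rt in names(ratio_map)) {
        oc <- ratio_map[[rt]]
        row <- h2_one_stratum(sub[[oc]][ok] / sub$dbw_g[ok], sub$line[ok],
                              rt, sx, "pooled")
        nexcl <- sum(!ok)
        if (nexcl > 0L)
          row$flags <- paste(c(row$flags[row$flags != ""],
                               sprintf("excluded_%d_nonpositive_dbw", nexcl)),
                             collapse = ";")
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
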