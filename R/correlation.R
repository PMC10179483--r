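#' Pearson correlation matrix of traits within a stratum
#'
#' Pairwise-complete Pearson correlations among the requested trait columns
#' for the animals matching the stratum filter (sex, diet, optionally a
#' single line), so a missing measurement drops a mouse only from the cells
#' that need it. Cells with fewer than 3 complete pairs or zero variance are
#' flagged-undefined (`NA` in `r`, reason in `flags`).
#'
#' @param traits a `cc_traits` table.
#' @param sex,diet,line optional stratum filters; `NULL` means no filter.
#' @param trait_cols trait columns to correlate; defaults to all numeric
#'   phenotype columns.
#' @return a `cc_cormat`: list with matrices `r`, `n`, `flags`, plus the
#'   `stratum` and `traits` used.
#' @export
pearson_matrix <- function(traits, sex = NULL, diet = NULL, line = NULL,
                           trait_cols = NULL) {
  sub <- traits
  if (!is.null(sex)) sub <- sub[sub$sex == sex, , drop = FALSE]
  if (!is.null(diet)) sub <- sub[sub$diet == diet, , drop = FALSE]
  if (!is.null(line)) sub <- sub[sub$line == line, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop_input("stratum (sex=%s, diet=%s, line=%s) has %d animals; need >= 3",
               sex %||% "*", diet %||% "*", line %||% "*", nrow(sub))
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(sub)[vapply(sub, is.numeric, logical(1L))],
                          character(0))
  }
  k <- length(trait_cols)
  r <- n <- matrix(NA_real_, k, k, dimnames = list(trait_cols, trait_cols))
  flags <- matrix("", k, k, dimnames = list(trait_cols, trait_cols))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- sub[[trait_cols[i]]]
      y <- sub[[trait_cols[j]]]
      ok <- is.finite(x) & is.finite(y)
      n[i, j] <- sum(ok)
      if (sum(ok) < 3L) {
        flags[i, j] <- "n_lt_3"
      } else if (var(x[ok]) == 0 || var(y[ok]) == 0) {
        flags[i, j] <- "zero_variance"
      } else {
        r[i, j] <- cor(x[ok], y[ok])
      }
    }
  }
  structure(list(r = r, n = n, flags = flags,
                 stratum = list(sex = sex, diet = diet, line = line),
                 traits = trait_cols),
            class = "cc_cormat")
}

#' @export
print.cc_cormat <- function(x, ...) {
  s <- x$stratum
  cat(sprintf("Pearson correlation matrix (%d traits; sex=%s diet=%s line=%s)\n",
              length(x$traits), s$sex %||% "*", s$diet %||% "*", s$line %||% "*"))
  print(round(x$r, 3))
  invisible(x)
}

#' Welch diet contrast for one trait
#'
#' Welch two-sample t-test of HFD vs CHD for a trait, within a (line, sex)
#' cell or (with `line = NULL`) for an overall sex population, with the
#' conventional star annotation (`*`, `**`, `***` at p < 0.05, 0.01, 0.001).
#' Welch's unequal-variance form is used because diet-arm sizes are
#' unbalanced in these designs. Degenerate cells (a group with n < 2, or
#' both groups constant) are flagged and left untested.
#'
#' @param traits a `cc_traits` table.
#' @param trait trait column name.
#' @param sex `"F"` or `"M"`.
#' @param line optional line label; `NULL` pools all lines of that sex.
#' @return a list: `trait, line, sex, n_chd, n_hfd, estimate` (HFD - CHD
#'   mean difference), `statistic, p_value, stars, flag`.
#' @export
diet_contrast <- function(traits, trait, sex, line = NULL) {
  sub <- traits[traits$sex == sex, , drop = FALSE]
  if (!is.null(line)) sub <- sub[sub$line == line, , drop = FALSE]
  x <- sub[[trait]][sub$diet == "HFD"]
  y <- sub[[trait]][sub$diet == "CHD"]
  out <- list(trait = trait, line = line %||% "overall", sex = sex,
              n_chd = length(y), n_hfd = length(x),
              estimate = NA_real_, statistic = NA_real_, p_value = NA_real_,
              stars = "", flag = "")
  if (length(x) < 2L || length(y) < 2L) {
    out$flag <- "group_too_small"
    return(out)
  }
  out$estimate <- mean(x) - mean(y)
  tt <- tryCatch(t.test(x, y, var.equal = FALSE),
                 error = function(e) NULL)
  if (is.null(tt)) {         # constant data in both groups
    out$flag <- "zero_variance"
    return(out)
  }
  out$statistic <- unname(tt$statistic)
  out$p_value <- tt$p.value
  out$stars <- p_stars(tt$p.value)
  out
}

#' All diet contrasts of a trait table
#'
#' Runs [diet_contrast()] for every trait x sex, both per line and for the
#' overall sex populations. By default no multiple-testing correction is
#' applied (each panel is tested on its own, the convention the star
#' annotations come from); `adjust = "BH"` adds a Benjamini-Hochberg
#' adjusted p-value column and derives the stars from it instead.
#'
#' @param traits a `cc_traits` table.
#' @param trait_cols trait columns; defaults to all numeric phenotypes.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame of contrast rows.
#' @export
contrast_table <- function(traits, trait_cols = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.null(trait_cols))
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1L))]
  grid <- expand.grid(trait = trait_cols,
                      sex = sort(unique(traits$sex)),
                      line = c(NA, sort(unique(traits$line))),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    ln <- if (is.na(grid$line[i])) NULL else grid$line[i]
    as.data.frame(diet_contrast(traits, grid$trait[i], grid$sex[i], ln),
                  stringsAsFactors = FALSE)
  }))
  if (adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- p_stars(out$p_adjusted)
  }
  rownames(out) <- NULL
  out
}

#' Render a correlation heatmap
#'
#' Writes a colour-keyed heatmap of a [pearson_matrix()] result spanning the
#' full correlation range `[-1, 1]` (blue-white-red), with flagged-undefined
#' cells in a distinct grey. Rows and columns keep the trait order (no
#' clustering), so output is deterministic for a given matrix.
#'
#' @param cormat a `cc_cormat`.
#' @param path output image path (`.png`).
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(cormat, path) {
  stopifnot(inherits(cormat, "cc_cormat"))
  s <- cormat$stratum
  ttl <- sprintf("Pearson r (sex=%s diet=%s line=%s)",
                 s$sex %||% "*", s$diet %||% "*", s$line %||% "*")
  pheatmap::pheatmap(cormat$r,
                     cluster_rows = FALSE, cluster_cols = FALSE,
                     breaks = seq(-1, 1, length.out = 101),
                     color = grDevices::colorRampPalette(
                       c("#2166AC", "#FFFFFF", "#B2182B"))(100),
                     na_col = "#BDBDBD",
                     display_numbers = TRUE, number_format = "%.2f",
                     main = ttl, filename = path, silent = TRUE)
  if (!file.exists(path)) stop_input("failed to write heatmap to %s", path)
  invisible(path)
}
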