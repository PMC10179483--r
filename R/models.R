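#' Binary labels at a percentile threshold
#'
#' Labels each value 1 iff it lies strictly above the linear-interpolation
#' quantile (R type 7) of the labelling population at `q` percent; ties with
#' the threshold label 0. At the default q = 70 this marks the top ~30% of
#' the data.
#'
#' @param values numeric vector (>= 4 values).
#' @param q percentile in `[0, 100)` (default 70).
#' @return integer 0/1 vector with attribute `threshold`.
#' @export
#' @examples
#' label_top_percentile(1:10)  # threshold 7.3; 8, 9, 10 are positive
label_top_percentile <- function(values, q = 70) {
  if (length(values) < 4L) stop_input("need at least 4 values to label")
  if (anyNA(values)) stop_input("labelling values contain NA")
  if (length(unique(values)) == 1L)
    stop_input("all values identical; labels degenerate")
  thr <- unname(quantile(values, q / 100, type = 7L))
  structure(as.integer(values > thr), threshold = thr)
}

#' Cross-validation protocol
#'
#' @param k number of folds (default 4).
#' @param stratified stratify folds by class label (default TRUE; with
#'   per-line samples of 18-35 animals, unstratified folds are frequently
#'   single-class and unscorable).
#' @param seed integer seed controlling fold assignment and model
#'   randomness.
#' @return a `cc_cv_protocol` list.
#' @export
cv_protocol <- function(k = 4L, stratified = TRUE, seed = 1L) {
  stopifnot(is_count(k), k >= 2L)
  structure(list(k = as.integer(k), stratified = stratified,
                 seed = as.integer(seed), scorer = "roc_auc"),
            class = "cc_cv_protocol")
}

#' Repeated train/test-split regression protocol
#'
#' @param iterations number of random splits (default 100).
#' @param train_frac training fraction in (0, 1) (default 0.70).
#' @param seed integer seed.
#' @return a `cc_reg_protocol` list.
#' @export
regression_protocol <- function(iterations = 100L, train_frac = 0.70, seed = 1L) {
  stopifnot(is_count(iterations), iterations >= 1L,
            train_frac > 0, train_frac < 1)
  structure(list(iterations = as.integer(iterations), train_frac = train_frac,
                 seed = as.integer(seed), scorer = "r_squared"),
            class = "cc_reg_protocol")
}

#' K-fold partition of sample indices
#'
#' Returns a fold id per sample: disjoint folds covering all samples, of
#' near-equal size, optionally stratified so each fold receives a
#' near-proportional share of each class.
#'
#' @param y 0/1 labels (used only when `stratified`).
#' @param k folds. @param stratified stratify by `y`. @param seed seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k, stratified = TRUE, seed = 1L) {
  n <- length(y)
  with_seed(child_seed(seed, "folds"), {
    fold <- integer(n)
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
      }
    } else {
      fold <- rep_len(seq_len(k), n)[sample.int(n)]
    }
    fold
  })
}

#' Cross-validated classification score for one model family
#'
#' Mean over folds of held-out ROC-AUC for one classifier family under a
#' [cv_protocol()]. Folds whose held-out part is single-class cannot be
#' scored and are skipped and recorded; data-level preconditions (both
#' classes present, n >= 2k, enough minority samples for stratified folds)
#' are reported as a flagged skip rather than an error.
#'
#' @param X numeric feature matrix (rows = animals).
#' @param y 0/1 labels.
#' @param family one of `"decision_tree"`, `"naive_bayes"`, `"knn"`,
#'   `"random_forest"`.
#' @param protocol a `cc_cv_protocol`.
#' @return list with `mean_auc`, `fold_aucs`, `skipped_folds`, `n`, `flag`.
#' @export
run_classification_cv <- function(X, y, family = CLASSIFIER_FAMILIES,
                                  protocol = cv_protocol()) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  out <- list(mean_auc = NA_real_, fold_aucs = numeric(0),
              skipped_folds = integer(0), n = n, flag = "")
  if (length(unique(y)) < 2L) {
    out$flag <- "single_class"
    return(out)
  }
  if (n < 2L * protocol$k) {
    out$flag <- sprintf("too_few_animals_n%d_lt_2k", n)
    return(out)
  }
  if (protocol$stratified && min(table(y)) < protocol$k) {
    out$flag <- "minority_class_smaller_than_k"
    return(out)
  }
  fold <- make_folds(y, protocol$k, protocol$stratified, protocol$seed)
  aucs <- rep(NA_real_, protocol$k)
  for (f in seq_len(protocol$k)) {
    te <- fold == f
    if (length(unique(y[te])) < 2L || length(unique(y[!te])) < 2L) {
      out$skipped_folds <- c(out$skipped_folds, f)
      next
    }
    sc <- classifier_score(family, X[!te, , drop = FALSE], y[!te],
                           X[te, , drop = FALSE],
                           seed = child_seed(protocol$seed, paste0(family, f)))
    aucs[f] <- roc_auc(sc, y[te])
  }
  out$fold_aucs <- aucs[!is.na(aucs)]
  if (!length(out$fold_aucs)) {
    out$flag <- "no_scorable_fold"
    return(out)
  }
  out$mean_auc <- mean(out$fold_aucs)
  out
}

#' Repeated-split regression score for one model family
#'
#' Mean held-out R-squared over repeated random 70/30 train-test splits.
#' Both the raw mean (which can be negative when the model predicts worse
#' than the test mean) and the zero-floored score `max(0, raw mean)` are
#' returned; the floored value is the table-comparable score.
#'
#' @param X numeric feature matrix.
#' @param y numeric regression target.
#' @param family `"linear"` or `"knn"`.
#' @param protocol a `cc_reg_protocol`.
#' @return list with `mean_r2` (raw), `score` (floored), `iter_r2`, `n`,
#'   `flag`.
#' @export
run_regression_iters <- function(X, y, family = REGRESSOR_FAMILIES,
                                 protocol = regression_protocol()) {
  family <- match.arg(family)
  X <- as.matrix(X)
  n <- nrow(X)
  out <- list(mean_r2 = NA_real_, score = NA_real_, iter_r2 = numeric(0),
              n = n, flag = "")
  if (n < 10L) {
    out$flag <- sprintf("too_few_animals_n%d", n)
    return(out)
  }
  ntr <- max(2L, min(n - 2L, round(protocol$train_frac * n)))
  r2 <- with_seed(child_seed(protocol$seed, paste0("reg_", family)),
    vapply(seq_len(protocol$iterations), function(i) {
      tr <- sample.int(n, ntr)
      yhat <- regressor_predict(family, X[tr, , drop = FALSE], y[tr],
                                X[-tr, , drop = FALSE])
      r_squared(y[-tr], yhat)
    }, numeric(1L)))
  out$iter_r2 <- r2
  out$mean_r2 <- mean(r2, na.rm = TRUE)
  out$score <- max(0, out$mean_r2)
  out
}

#' Assemble the model feature matrix from a trait table
#'
#' The default (`"paper-text"`) feature set is sex, diet (0/1-encoded:
#' M = 1, HFD = 1), initial and final body weight, and total glucose AUC at
#' both IPGTT weeks. The `"table-caption"` variant drops final body weight,
#' mapping the caption's "initial organ weight" (which cannot exist, since
#' organs are weighed only at sacrifice) to initial body weight. Rows with
#' missing features are dropped with a logged count.
#'
#' @param traits a `cc_traits` table.
#' @param feature_set `"paper-text"` (default) or `"table-caption"`.
#' @return numeric matrix with attributes `rows_kept` (row indices into
#'   `traits`) and `n_dropped`.
#' @export
build_features <- function(traits, feature_set = c("paper-text", "table-caption")) {
  feature_set <- match.arg(feature_set)
  auc_cols <- grep("^auc_wk", names(traits), value = TRUE)
  cols <- if (feature_set == "paper-text") {
    c("bw0_g", "bw_final_g", auc_cols)
  } else {
    c("bw0_g", auc_cols)
  }
  X <- cbind(sex_m = as.numeric(traits$sex == "M"),
             diet_hfd = as.numeric(traits$diet == "HFD"),
             as.matrix(traits[cols]))
  keep <- which(stats::complete.cases(X))
  structure(X[keep, , drop = FALSE],
            rows_kept = keep, n_dropped = nrow(X) - length(keep))
}

#' Per-line model score grid for one organ
#'
#' The per-line modelling table: for each CC line (columns) and model family
#' (rows), the cross-validated classification ROC-AUC of "percent organ
#' weight above its 70th percentile", or the repeated-split regression score
#' of percent organ weight. Labels are computed within the modelled subset
#' (per line in per-line mode). Cells whose preconditions fail - a line with
#' a single sex x diet group, degenerate labels, too few animals - are
#' flagged, never silently dropped, and the grid is deterministic for fixed
#' protocol seeds.
#'
#' @param traits a `cc_traits` table.
#' @param organ `"liver"`, `"spleen"` or `"heart"`.
#' @param task `"classify"` or `"regress"`.
#' @param cv a `cc_cv_protocol` (classification).
#' @param reg a `cc_reg_protocol` (regression).
#' @param feature_set see [build_features()].
#' @param per_line model each line separately (default, the published
#'   layout); `FALSE` fits one global model on all animals.
#' @param label_q labelling percentile (default 70).
#' @return a `cc_modelgrid`: long data.frame (`model`, `line`, `score`,
#'   `raw_score`, `n`, `flag`) with the protocols and settings in
#'   attributes; `as.matrix()` yields the model x line score matrix.
#' @export
model_grid <- function(traits, organ = c("liver", "spleen", "heart"),
                       task = c("classify", "regress"),
                       cv = cv_protocol(), reg = regression_protocol(),
                       feature_set = "paper-text", per_line = TRUE,
                       label_q = 70) {
  organ <- match.arg(organ)
  task <- match.arg(task)
  target_col <- paste0("pct_", organ)
  groups <- if (per_line) sort(unique(traits$line)) else "all"
  families <- if (task == "classify") CLASSIFIER_FAMILIES else REGRESSOR_FAMILIES

  cells <- list()
  for (ln in groups) {
    sub <- if (per_line) traits[traits$line == ln, , drop = FALSE] else traits
    X <- build_features(sub, feature_set)
    sub <- sub[attr(X, "rows_kept"), , drop = FALSE]
    tgt <- sub[[target_col]]
    cell_flag <- ""
    if (nrow(sub) < 4L) {
      cell_flag <- "too_few_animals"
    } else if (nrow(unique(sub[c("sex", "diet")])) < 2L) {
      cell_flag <- "single_sex_diet_group"
    }
    y <- NULL
    if (task == "classify" && cell_flag == "") {
      y <- tryCatch(label_top_percentile(tgt, label_q),
                    error = function(e) NULL)
      if (is.null(y)) cell_flag <- "degenerate_labels"
    }
    for (fam in families) {
      if (cell_flag != "") {
        cells[[length(cells) + 1L]] <- data.frame(
          model = fam, line = ln, score = NA_real_, raw_score = NA_real_,
          n = nrow(sub), flag = cell_flag, stringsAsFactors = FALSE)
        next
      }
      if (task == "classify") {
        cvp <- cv
        cvp$seed <- child_seed(cv$seed, paste(organ, ln, "classify"))
        r <- run_classification_cv(X, y, fam, cvp)
        cells[[length(cells) + 1L]] <- data.frame(
          model = fam, line = ln, score = r$mean_auc, raw_score = r$mean_auc,
          n = r$n, flag = r$flag, stringsAsFactors = FALSE)
      } else {
        rp <- reg
        rp$seed <- child_seed(reg$seed, paste(organ, ln, "regress"))
        r <- run_regression_iters(X, tgt, fam, rp)
        cells[[length(cells) + 1L]] <- data.frame(
          model = fam, line = ln, score = r$score, raw_score = r$mean_r2,
          n = r$n, flag = r$flag, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  structure(out, class = c("cc_modelgrid", "data.frame"),
            organ = organ, task = task, feature_set = feature_set,
            label_q = label_q, cv = cv, reg = reg)
}

#' @export
as.matrix.cc_modelgrid <- function(x, ...) {
  models <- unique(x$model)
  lines <- unique(x$line)
  m <- matrix(NA_real_, length(models), length(lines),
              dimnames = list(models, lines))
  for (i in seq_len(nrow(x))) m[x$model[i], x$line[i]] <- x$score[i]
  m
}

#' @export
print.cc_modelgrid <- function(x, ...) {
  cat(sprintf("%s grid for %s (features: %s)\n", attr(x, "task"),
              attr(x, "organ"), attr(x, "feature_set")))
  print(round(as.matrix(x), 3))
  flagged <- x[x$flag != "", c("model", "line", "flag")]
  if (nrow(flagged)) {
    cat("flagged cells:\n")
    print(flagged, row.names = FALSE)
  }
  invisible(x)
}
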