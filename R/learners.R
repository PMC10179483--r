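# Model families for the per-line phenotype classification/regression.
# Each classifier exposes one contract: fit on (Xtrain, ytrain), return a
# class-1 score per test row suitable for ROC ranking. All features are
# numeric (categoricals arrive 0/1-encoded), which keeps every family free
# of formula/factor plumbing.

CLASSIFIER_FAMILIES <- c("decision_tree", "naive_bayes", "knn", "random_forest")
REGRESSOR_FAMILIES <- c("linear", "knn")

#' Area under the ROC curve of a score vector
#'
#' Rank-based (Mann-Whitney) ROC-AUC with midrank tie handling: the
#' probability that a random positive is scored above a random negative,
#' counting ties as one half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_input("ROC-AUC needs both classes")
  r <- rank(scores)   # midranks handle ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Gaussian naive Bayes score: log-posterior difference converted to P(y=1).
# Per-class, per-feature variances are floored to avoid zero-variance spikes
# (same role as scikit-learn's var_smoothing).
nb_score <- function(Xtr, ytr, Xte) {
  eps <- 1e-9 * max(apply(Xtr, 2L, var), 1e-12, na.rm = TRUE)
  ll_class <- function(cls) {
    Xc <- Xtr[ytr == cls, , drop = FALSE]
    mu <- colMeans(Xc)
    v <- apply(Xc, 2L, function(x) if (length(x) > 1L) var(x) else 0) + eps
    lp <- log(nrow(Xc) / nrow(Xtr))
    rowSums(vapply(seq_along(mu), function(j)
      dnorm(Xte[, j], mu[j], sqrt(v[j]), log = TRUE), numeric(nrow(Xte)))) + lp
  }
  l1 <- ll_class(1L)
  l0 <- ll_class(0L)
  1 / (1 + exp(pmin(700, pmax(-700, l0 - l1))))
}

# kNN class-1 score: the fraction of the k nearest training neighbours
# (Euclidean) labelled 1. Distance ties resolve by training-row order.
knn_score <- function(Xtr, ytr, Xte, k = 5L) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1L, function(row) mean(ytr[order(row)[seq_len(k)]]))
}

knn_reg_predict <- function(Xtr, ytr, Xte, k = 5L) {
  k <- min(k, nrow(Xtr))
  d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") - 2 * Xte %*% t(Xtr)
  apply(d2, 1L, function(row) mean(ytr[order(row)[seq_len(k)]]))
}

# single CART tree: all features considered at each split, no bootstrap
tree_score <- function(Xtr, ytr, Xte, seed) {
  .cart_fit_predict(Xtr, as.integer(ytr), Xte, ntree = 1L, mtry = ncol(Xtr),
                    minsplit = 2L, bootstrap = FALSE, seed = seed)
}

# random forest: 100 fully grown trees, bootstrap + sqrt(p) feature draw
forest_score <- function(Xtr, ytr, Xte, seed, ntree = 100L) {
  .cart_fit_predict(Xtr, as.integer(ytr), Xte, ntree = ntree,
                    mtry = max(1L, floor(sqrt(ncol(Xtr)))),
                    minsplit = 2L, bootstrap = TRUE, seed = seed)
}

classifier_score <- function(family, Xtr, ytr, Xte, seed) {
  switch(family,
         decision_tree = tree_score(Xtr, ytr, Xte, seed),
         naive_bayes = nb_score(Xtr, ytr, Xte),
         knn = knn_score(Xtr, ytr, Xte),
         random_forest = forest_score(Xtr, ytr, Xte, seed),
         stop_input("unknown classifier family '%s'", family))
}

regressor_predict <- function(family, Xtr, ytr, Xte) {
  switch(family,
         linear = {
           fit <- stats::lm.fit(cbind(1, Xtr), ytr)
           b <- fit$coefficients
           b[is.na(b)] <- 0      # collinear columns drop out of the fit
           as.numeric(cbind(1, Xte) %*% b)
         },
         knn = knn_reg_predict(Xtr, ytr, Xte),
         stop_input("unknown regressor family '%s'", family))
}

# held-out coefficient of determination, 1 - SSE/SST about the test mean
# (the scikit-learn r2_score convention; negative when worse than the mean)
r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((y - yhat)^2) / sst
}
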