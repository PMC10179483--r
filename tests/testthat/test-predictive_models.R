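test_that("percentile labelling follows the strict-inequality convention", {
  y <- label_top_percentile(1:10)
  expect_equal(attr(y, "threshold"), 7.3)
  expect_identical(which(y == 1L), 8:10)
  y0 <- label_top_percentile(1:10, q = 0)
  expect_identical(sum(y0), 9L)   # only the minimum is non-positive
  expect_identical(y0[1L], 0L)
  expect_error(label_top_percentile(rep(2, 10)), "identical")
  expect_error(label_top_percentile(1:3), "at least 4")
})

test_that("folds are disjoint, covering, and stratified", {
  set.seed(1)
  y <- rep(c(0L, 1L), times = c(28, 12))
  for (seed in 1:5) {
    f <- make_folds(y, 4L, stratified = TRUE, seed = seed)
    expect_identical(sort(unique(f)), 1:4)
    expect_identical(length(f), length(y))            # every sample in a fold
    expect_true(all(table(f, y)[, "1"] == 3))          # equal positive share
    expect_true(all(abs(table(f) - 10) <= 1))
  }
  f <- make_folds(y, 4L, stratified = FALSE, seed = 2)
  expect_identical(sort(unique(f)), 1:4)
  expect_true(all(abs(table(f) - 10) <= 1))
})

test_that("roc_auc matches a direct pair-counting oracle", {
  set.seed(66)
  for (i in 1:20) {
    n <- 30L
    y <- as.integer(runif(n) < 0.4)
    if (length(unique(y)) < 2L) next
    s <- round(rnorm(n), 1)  # force some ties
    pos <- s[y == 1L]; neg <- s[y == 0L]
    wins <- 0
    for (a in pos) for (b in neg) wins <- wins + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(s, y), wins / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("a perfect label leak yields ROC-AUC 1 for every family", {
  set.seed(5)
  n <- 60L
  y <- rep(c(0L, 1L), each = n / 2)[sample.int(n)]
  X <- cbind(leak = 10 * as.numeric(y), noise = rnorm(n))
  for (fam in c("decision_tree", "naive_bayes", "knn", "random_forest")) {
    r <- run_classification_cv(X, y, fam, cv_protocol(seed = 3))
    expect_equal(r$mean_auc, 1.0, tolerance = 1e-9)
  }
})

test_that("classification preconditions produce flagged skips", {
  X <- matrix(rnorm(40), 20)
  expect_identical(run_classification_cv(X, rep(1L, 20), "knn")$flag, "single_class")
  expect_match(run_classification_cv(X[1:6, ], c(1L, 0L, 1L, 0L, 1L, 0L), "knn",
                                     cv_protocol(k = 4))$flag, "too_few")
  y <- c(rep(0L, 17), rep(1L, 3))
  expect_identical(run_classification_cv(X, y, "knn", cv_protocol(k = 4))$flag,
                   "minority_class_smaller_than_k")
})

test_that("classification CV is deterministic for a fixed seed", {
  set.seed(10)
  X <- matrix(rnorm(200), 50)
  y <- as.integer(runif(50) < 0.3)
  a <- run_classification_cv(X, y, "random_forest", cv_protocol(seed = 9))
  b <- run_classification_cv(X, y, "random_forest", cv_protocol(seed = 9))
  expect_identical(a, b)
  c_ <- run_classification_cv(X, y, "random_forest", cv_protocol(seed = 10))
  expect_false(identical(a$mean_auc, c_$mean_auc))
})

test_that("small permutation null is centred near 0.5 (full run in acceptance)", {
  set.seed(77)
  X <- matrix(rnorm(120 * 4), 120)
  y <- as.integer(rank(rnorm(120)) > 84)
  for (fam in c("decision_tree", "knn")) {
    a <- vapply(1:60, function(i) {
      run_classification_cv(X, y[sample.int(120)], fam, cv_protocol(seed = i))$mean_auc
    }, numeric(1L))
    expect_lt(abs(mean(a) - 0.5), 0.05)
  }
})

test_that("injected signal produces non-decreasing decision-tree AUC", {
  set.seed(42)
  n <- 80L
  means <- vapply(c(0, 1, 3), function(eff) {
    a <- vapply(1:40, function(i) {
      x1 <- rnorm(n)
      y <- as.integer(rank(x1 * eff + rnorm(n)) > 0.7 * n)
      X <- cbind(x1, rnorm(n))
      run_classification_cv(X, y, "decision_tree", cv_protocol(seed = i))$mean_auc
    }, numeric(1L))
    mean(a)
  }, numeric(1L))
  expect_true(all(diff(means) > 0))
})

test_that("regression: identity target, nulls, and the R^2 oracle", {
  set.seed(30)
  n <- 100L
  X <- cbind(a = rnorm(n), b = rnorm(n))
  # target equals a feature: perfect score
  r <- run_regression_iters(X, X[, "a"], "linear", regression_protocol(seed = 2))
  expect_equal(r$mean_r2, 1.0, tolerance = 1e-9)
  expect_equal(r$score, 1.0, tolerance = 1e-9)
  # independent noise: raw mean <= 0, floored score 0
  rn <- run_regression_iters(X, rnorm(n), "linear", regression_protocol(seed = 2))
  expect_lte(rn$mean_r2, 0)
  expect_identical(rn$score, 0)
  rk <- run_regression_iters(X, rnorm(n), "knn", regression_protocol(seed = 3))
  expect_lte(rk$mean_r2, 0.02)
  # strong linear signal
  y <- 2 * X[, "a"] - X[, "b"] + rnorm(n, 0, 0.1)
  rs <- run_regression_iters(X, y, "linear", regression_protocol(seed = 4))
  expect_gt(rs$mean_r2, 0.9)
  # held-out R^2 equals the direct-loop oracle
  yh <- y + rnorm(n, 0, 0.5)
  expect_equal(r_squared(y, yh), r2_oracle(y, yh), tolerance = 1e-10)
  expect_match(run_regression_iters(X[1:8, ], y[1:8], "linear")$flag, "too_few")
})

test_that("feature assembly matches the documented encodings", {
  tr <- derive_traits(generate_cohort(tiny_design(n = 2L), sim_params(seed = 6)))
  X <- build_features(tr)
  expect_identical(colnames(X),
                   c("sex_m", "diet_hfd", "bw0_g", "bw_final_g", "auc_wk6", "auc_wk12"))
  expect_identical(as.numeric(X[, "sex_m"]), as.numeric(tr$sex == "M"))
  Xc <- build_features(tr, "table-caption")
  expect_false("bw_final_g" %in% colnames(Xc))
  tr$auc_wk6[3L] <- NA
  X2 <- build_features(tr)
  expect_identical(attr(X2, "n_dropped"), 1L)
  expect_identical(nrow(X2), nrow(tr) - 1L)
})

test_that("model_grid has the published shape, flags degenerate cells, and is deterministic", {
  tr <- derive_traits(generate_cohort(tiny_design(n = 5L), sim_params(seed = 13)))
  g <- model_grid(tr, "liver", "classify", cv = cv_protocol(seed = 2))
  m <- as.matrix(g)
  expect_identical(dim(m), c(4L, 3L))  # 4 model families x 3 lines
  expect_true(all(m >= 0 & m <= 1, na.rm = TRUE))
  g2 <- model_grid(tr, "liver", "classify", cv = cv_protocol(seed = 2))
  expect_identical(as.data.frame(g), as.data.frame(g2))

  # a line reduced to one sex x diet group is flagged, not scored
  tr1 <- tr[!(tr$line == "L1" & !(tr$sex == "F" & tr$diet == "CHD")), ]
  gf <- model_grid(tr1, "liver", "classify", cv = cv_protocol(seed = 2))
  expect_true(all(gf$flag[gf$line == "L1"] == "single_sex_diet_group"))
  expect_true(all(is.na(gf$score[gf$line == "L1"])))

  gr <- model_grid(tr, "liver", "regress", reg = regression_protocol(seed = 2))
  expect_identical(dim(as.matrix(gr)), c(2L, 3L))
  expect_true(all(gr$score >= 0, na.rm = TRUE))
})
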