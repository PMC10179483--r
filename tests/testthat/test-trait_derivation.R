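test_that("trapezoid AUC reproduces hand-computed examples", {
  t6 <- c(0, 15, 30, 60, 120, 180)
  expect_equal(compute_auc(t6, rep(100, 6)), 18000)
  expect_equal(compute_auc(c(0, 15), c(100, 120)), 1650)
  expect_equal(compute_auc(t6, c(80, 150, 200, 160, 120, 90)), 24450)
  expect_equal(compute_auc(data.frame(t_min = c(0, 15), glucose_mg_dl = c(100, 120))),
               1650)
})

test_that("AUC input validation", {
  expect_error(compute_auc(0, 100), "at least 2")
  expect_error(compute_auc(c(0, 30, 15), c(1, 2, 3)), "increasing")
  expect_error(compute_auc(c(0, 15, 15), c(1, 2, 3)), "increasing")
  expect_error(compute_auc(c(0, 15), c(1, NA)), "NA")
})

test_that("trapezoid AUC equals the closed-form integral of piecewise-linear curves", {
  set.seed(101)
  for (i in seq_len(200)) {
    k <- sample(3:8, 1L)
    t <- sort(sample(0:500, k))
    y <- runif(k, 10, 400)
    # independent oracle: integrate each linear piece a + b*t in closed form
    ora <- 0
    for (s in seq_len(k - 1L)) {
      b <- (y[s + 1L] - y[s]) / (t[s + 1L] - t[s])
      a <- y[s] - b * t[s]
      ora <- ora + a * (t[s + 1L] - t[s]) + b * (t[s + 1L]^2 - t[s]^2) / 2
    }
    expect_equal(compute_auc(t, y), ora, tolerance = 1e-12)
  }
})

test_that("AUC is additive over a partition of the time axis", {
  set.seed(7)
  t <- c(0, 15, 30, 60, 120, 180)
  y <- runif(6, 50, 350)
  cut <- 3L
  expect_equal(compute_auc(t, y),
               compute_auc(t[1:cut], y[1:cut]) + compute_auc(t[cut:6], y[cut:6]))
})

test_that("delta BW follows the endpoint convention and sign", {
  expect_equal(delta_bw(c(`0` = 25, `12` = 35)), 10)
  expect_equal(delta_bw(c(`0` = 30, `6` = 31, `12` = 30)), 0)
  expect_equal(delta_bw(c(`0` = 30, `12` = 28)), -2)
  expect_error(delta_bw(c(`2` = 30, `12` = 28)), "week-0")
  expect_error(delta_bw(c(`0` = 30, `10` = 28)), "week-12")
})

test_that("percent organ weight is a scale-invariant percentage", {
  expect_equal(percent_organ_weight(1.5, 30), 5)
  expect_equal(percent_organ_weight(42, 42), 100)
  expect_equal(percent_organ_weight(2.1, 42), 5)
  set.seed(3)
  o <- runif(20, 0.1, 2); b <- runif(20, 20, 45); k <- runif(20, 0.5, 3)
  expect_equal(percent_organ_weight(o * k, b * k), percent_organ_weight(o, b))
  expect_error(percent_organ_weight(0, 30), "positive")
  expect_error(percent_organ_weight(1, -2), "positive")
})

test_that("group delta ratio matches hand arithmetic and handles degeneracies", {
  mk <- function(liver_hfd, liver_chd, dbw_hfd, dbw_chd) {
    data.frame(line = "L1", sex = "F",
               diet = rep(c("HFD", "CHD"), times = c(length(liver_hfd), length(liver_chd))),
               liver_g = c(liver_hfd, liver_chd),
               dbw_g = c(dbw_hfd, dbw_chd))
  }
  tr <- mk(c(1.9, 2.1), c(1.4, 1.6), c(34, 36), c(27, 29))
  r <- group_delta_ratio(tr, "L1", "F", "liver")
  expect_equal(r$ratio, 0.5 / 7)
  expect_identical(r$flag, "")

  same <- mk(c(1.5, 1.7), c(1.5, 1.7), c(30, 32), c(30, 32))
  r0 <- group_delta_ratio(same, "L1", "F", "liver")
  expect_true(is.na(r0$ratio))
  expect_identical(r0$flag, "undefined_zero_dbw_difference")

  eq_org <- mk(c(1.5, 1.7), c(1.5, 1.7), c(34, 36), c(27, 29))
  expect_equal(group_delta_ratio(eq_org, "L1", "F", "liver")$ratio, 0)

  expect_error(group_delta_ratio(tr[tr$diet == "HFD", ], "L1", "F", "liver"),
               "empty diet group")
})

test_that("adding a constant to all organ weights leaves the ratio unchanged", {
  set.seed(9)
  tr <- data.frame(line = "L1", sex = "M",
                   diet = rep(c("HFD", "CHD"), each = 5),
                   liver_g = runif(10, 1, 2), dbw_g = c(runif(5, 5, 9), runif(5, 1, 4)))
  r1 <- group_delta_ratio(tr, "L1", "M", "liver")$ratio
  tr$liver_g <- tr$liver_g + 3.7
  expect_equal(group_delta_ratio(tr, "L1", "M", "liver")$ratio, r1)
})

test_that("derive_traits produces one valid row per mouse", {
  d <- tiny_design(n = 2L)
  co <- generate_cohort(d, sim_params(seed = 4))
  tr <- derive_traits(co)
  expect_identical(nrow(tr), sum(d$group_sizes$n))
  expect_equal(tr$dbw_g, tr$bw_final_g - tr$bw0_g)
  expect_true(all(tr$auc_wk6 > 0 & tr$auc_wk12 > 0))
  expect_true(all(tr$pct_liver > 0 & tr$pct_liver < 100))
  expect_true(all(tr$pct_spleen > 0 & tr$pct_heart < 100))
  # spot-check one mouse against direct computation from the raw rows
  id <- tr$mouse_id[5L]
  g <- co[co$mouse_id == id & co$measure == "glucose_mg_dl" & co$week == 12, ]
  expect_equal(tr$auc_wk12[5L], compute_auc(g$t_min[order(g$t_min)], g$value[order(g$t_min)]))
})

test_that("derive_traits errors name the offending mouse", {
  co <- generate_cohort(tiny_design(), sim_params(seed = 4))
  id <- unique(co$mouse_id)[3L]
  broken <- co[!(co$mouse_id == id & co$measure == "bw_g" & co$week == 12), ]
  expect_error(derive_traits(broken), id)
  broken2 <- co[!(co$mouse_id == id & co$measure == "glucose_mg_dl" &
                    co$week == 12 & co$t_min == 180), ]
  expect_error(derive_traits(broken2), "does not span")
  broken3 <- co[!(co$mouse_id == id & co$measure == "spleen_g"), ]
  expect_error(derive_traits(broken3), "spleen")
})

test_that("zero-noise cohorts give identical rows within (line, sex, diet)", {
  co <- generate_cohort(tiny_design(n = 3L), silent_params())
  tr <- derive_traits(co)
  num <- vapply(tr, is.numeric, logical(1L))
  sp <- split(tr[num], interaction(tr$line, tr$sex, tr$diet))
  for (cell in sp) expect_true(all(vapply(cell, function(v) diff(range(v)) == 0, logical(1L))))
})
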