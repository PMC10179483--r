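test_that("default design reproduces the published cell counts", {
  d <- default_design()
  gs <- d$group_sizes
  expect_length(d$lines, 8L)
  expect_identical(sum(gs$n), 207L)
  cell <- function(l, s, dt) gs$n[gs$line == l & gs$sex == s & gs$diet == dt]
  expect_identical(cell("IL5000", "F", "HFD"), 14L)
  expect_identical(cell("IL1912", "F", "CHD"), 10L)
  expect_identical(sum(gs$n[gs$sex == "F" & gs$diet == "CHD"]), 46L)
  expect_identical(sum(gs$n[gs$line == "IL5000"]), 35L)
})

test_that("study_design validates its invariants", {
  gs <- data.frame(line = "A", sex = "F", diet = "CHD", n = 2)
  expect_s3_class(study_design(gs), "cc_design")
  expect_error(study_design(transform(gs, n = -1)), "non-negative")
  expect_error(study_design(transform(gs, sex = "X")), "sex")
  expect_error(study_design(gs, ipgtt_weeks = 5), "subset")
  expect_error(study_design(gs, ipgtt_timepoints_min = c(15, 30)), "start at 0")
  expect_error(study_design(gs, ipgtt_timepoints_min = c(0, 30, 30)), "increasing")
  expect_error(study_design(rbind(gs, gs)), "duplicate")
})

test_that("generated cohort matches the design cell-for-cell", {
  d <- tiny_design(n = 4L)
  co <- generate_cohort(d, sim_params(seed = 3))
  animals <- unique(co[c("mouse_id", "line", "sex", "diet")])
  expect_identical(nrow(animals), sum(d$group_sizes$n))
  got <- aggregate(mouse_id ~ line + sex + diet, animals, length)
  merged <- merge(d$group_sizes, got, by = c("line", "sex", "diet"))
  expect_equal(merged$n, merged$mouse_id)
  # per-animal completeness: every design week, every IPGTT timepoint, organs
  one <- co[co$mouse_id == animals$mouse_id[1L], ]
  expect_setequal(one$week[one$measure == "bw_g"], d$weeks)
  expect_setequal(one$t_min[one$measure == "glucose_mg_dl" & one$week == 6],
                  d$ipgtt_timepoints_min)
  expect_setequal(one$measure[is.na(one$t_min) & one$week == max(d$weeks)],
                  c("bw_g", "liver_g", "spleen_g", "heart_g"))
  expect_true(all(co$value > 0))
})

test_that("same seed gives a bit-identical cohort; different seed differs", {
  d <- tiny_design()
  a <- generate_cohort(d, sim_params(seed = 11))
  b <- generate_cohort(d, sim_params(seed = 11))
  c_ <- generate_cohort(d, sim_params(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a$value, c_$value))
})

test_that("zero-variance parameters collapse animals of one sex/diet/week", {
  co <- generate_cohort(tiny_design(n = 3L), silent_params())
  bw <- co[co$measure == "bw_g", ]
  spread <- tapply(bw$value, interaction(bw$sex, bw$diet, bw$week), function(v) diff(range(v)))
  expect_true(all(spread == 0))
  liver <- co[co$measure == "liver_g", ]
  expect_equal(diff(range(liver$value)), 0)
})

test_that("diet effects recover from group means", {
  # exact at zero noise: HFD - CHD final-BW gap equals growth_hfd * 12 and
  # the organ log-gap equals the configured log diet effect
  p <- silent_params()
  p$bw$growth_hfd <- 0.45
  p$liver$diet_effect <- 0.18
  co <- generate_cohort(tiny_design(n = 2L), p)
  fin <- co[co$measure == "bw_g" & co$week == 12, ]
  gap <- mean(fin$value[fin$diet == "HFD"]) - mean(fin$value[fin$diet == "CHD"])
  expect_equal(gap, 0.45 * 12, tolerance = 1e-3)  # values stored at 4 decimals
  liv <- co[co$measure == "liver_g", ]
  expect_equal(mean(log(liv$value[liv$diet == "HFD"])) -
                 mean(log(liv$value[liv$diet == "CHD"])), 0.18, tolerance = 1e-3)
  # noisy case: recovered within 3 SEM over >= 200 animals
  pn <- sim_params(seed = 5)
  d <- tiny_design(n = 20L, lines = sprintf("L%d", 1:4))  # 320 animals
  co <- generate_cohort(d, pn)
  fin <- co[co$measure == "bw_g" & co$week == 12, ]
  hfd <- fin$value[fin$diet == "HFD"]; chd <- fin$value[fin$diet == "CHD"]
  sem <- sqrt(var(hfd) / length(hfd) + var(chd) / length(chd))
  expect_lt(abs((mean(hfd) - mean(chd)) - pn$bw$growth_hfd * 12), 3 * sem)
})

test_that("IPGTT curve peaks at fasting + A and starts at fasting", {
  p <- silent_params()
  p$glucose$peak_amplitude <- 150
  p$glucose$time_to_peak <- 30
  d <- study_design(data.frame(line = "A", sex = "F", diet = "CHD", n = 1),
                    ipgtt_timepoints_min = c(0, 15, 30, 60, 120, 180))
  cur <- simulate_ipgtt(6, "CHD", p, d, fasting = 90)
  expect_equal(cur$glucose_mg_dl[cur$t_min == 0], 90)
  expect_equal(cur$glucose_mg_dl[cur$t_min == 30], 90 + 150)
  expect_true(all(diff(cur$glucose_mg_dl[cur$t_min >= 30]) < 0))
  expect_error(simulate_ipgtt(4, "CHD", p, d), "no IPGTT")
})

test_that("HFD slows clearance: mean AUC(HFD) > mean AUC(CHD)", {
  p <- sim_params(seed = 1)
  d <- default_design()
  set.seed(child_seed(1, "ipgtt_mc"))
  aucs <- vapply(c("CHD", "HFD"), function(dt) {
    mean(vapply(seq_len(1000), function(i)
      compute_auc(simulate_ipgtt(12, dt, p, d)), numeric(1L)))
  }, numeric(1L))
  expect_gt(aucs[["HFD"]], aucs[["CHD"]])
})

test_that("cohort CSV round-trips exactly", {
  co <- generate_cohort(tiny_design(), sim_params(seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f)
  expect_equal(read_cohort(f), co)
})

test_that("cohort CSV parse errors name the offending row and column", {
  co <- generate_cohort(tiny_design(), sim_params(seed = 2))
  f <- withr::local_tempfile(fileext = ".csv")

  write_cohort(co, f)
  txt <- readLines(f)
  writeLines(txt[-2], f)  # still valid, fewer rows
  expect_s3_class(read_cohort(f), "cc_cohort")

  bad <- co; bad$value[5L] <- -1
  write_cohort(bad, f)
  expect_error(read_cohort(f), "non-positive 'value' at row 5")

  writeLines(c(txt[1L],
               sub("^([^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,).*$", "\\1oops",
                   txt[2:3])), f)
  expect_error(read_cohort(f), "non-numeric 'value' at row")

  writeLines(gsub("value", "weight", txt[1L]), f)
  expect_error(read_cohort(f), "missing column")

  writeLines(txt[1L], f)  # header only
  expect_identical(nrow(read_cohort(f)), 0L)
})
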