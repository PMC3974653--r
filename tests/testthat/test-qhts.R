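test_that("plate normalization maps the control medians to 0 and 100", {
  plate <- data.frame(
    read = c(2000, 2010, 1990, 200, 210, 190, 1100, 2000, 200),
    role = c(rep("dmso", 3), rep("pos_ctrl", 3), rep("sample", 3))
  )
  out <- normalize_plate(plate)
  expect_equal(out$normalized[7], 50)     # planted window (2000, 200)
  expect_equal(out$normalized[8], 0)      # read at median(dmso)
  expect_equal(out$normalized[9], 100)    # read at median(pos)

  # affine and idempotent with ideal, already-normalized controls
  norm2 <- data.frame(read = out$normalized, role = plate$role)
  norm2$read[1:3] <- 0; norm2$read[4:6] <- 100
  out2 <- normalize_plate(norm2)
  expect_equal(out2$normalized, norm2$read)

  expect_error(normalize_plate(data.frame(read = c(1, 1, 2), role =
    c("dmso", "pos_ctrl", "sample"))), "2 wells")
  flat <- data.frame(read = rep(5, 4), role = c("dmso", "dmso", "pos_ctrl",
                                                "pos_ctrl"))
  expect_error(normalize_plate(flat), "degenerate")
})

test_that("4PL fitting recovers known parameters and flags failures", {
  # complete curve in the activation-negative notation
  s <- make_series(bottom = 0, top = -90, ic50 = 0.47, hill = 1.5)
  f <- fit_4pl(s)
  expect_true(f$converged)
  expect_equal(f$ic50, 0.47, tolerance = 1e-4)
  expect_equal(f$hill, 1.5, tolerance = 1e-4)
  expect_equal(f$top, -90, tolerance = 1e-3)
  # efficacy is the fitted window capped at the observed response range
  expect_equal(f$efficacy,
               min(abs(f$top - f$bottom), diff(range(s$response))),
               tolerance = 1e-6)

  # flat series: no signal, class 4 downstream
  flat <- data.frame(concentration = qhts_concentrations(),
                     response = rep(2, 8))
  ff <- fit_4pl(flat)
  expect_true(!ff$converged || ff$efficacy < 1e-6)
  expect_equal(classify_curve(ff, flat), "4")

  expect_error(fit_4pl(data.frame(concentration = c(-1, 1, 2, 3),
                                  response = c(0, 1, 2, 3))), "positive")
  expect_error(fit_4pl(data.frame(concentration = c(1, 2, 3),
                                  response = c(0, 1, 2))), "4 titration")
})

test_that("monotone fraction-affected data converted to % fits cleanly", {
  t2 <- pheo_combination_rows()
  s <- data.frame(concentration = t2$dose_epi + t2$dose_saha,
                  response = 100 * t2$fa)
  f <- fit_4pl(s)
  pred <- fpl_curve(sort(s$concentration), f$bottom, f$top, f$ic50, f$hill)
  expect_true(all(diff(pred) > 0) || all(diff(pred) < 0))
  expect_gt(f$r2, 0.99)
})

test_that("4PL least squares matches a brute-force grid search", {
  set.seed(401)
  for (k in 1:20) {
    bottom <- runif(1, -5, 5)
    top <- runif(1, 40, 120)
    ic50 <- exp(runif(1, log(0.01), log(20)))
    hill <- runif(1, 0.8, 4)
    s <- make_series(bottom, top, ic50, hill, noise_sd = 4)
    f <- fit_4pl(s)
    sse_fit <- sse_4pl(f, s$concentration, s$response)
    sse_grid <- grid_4pl_sse(s$concentration, s$response)
    expect_lte(sse_fit, sse_grid + 1e-6 + 0.01 * sse_grid)
  }
})

test_that("curve classification follows the class definitions", {
  # complete sigmoid, high efficacy -> 1.1
  s11 <- make_series(0, 96, 0.5, 2)
  expect_equal(classify_curve(fit_4pl(s11), s11), "1.1")
  # complete sigmoid, efficacy < 80 -> 1.2
  s12 <- make_series(0, 70, 0.5, 2)
  expect_equal(classify_curve(fit_4pl(s12), s12), "1.2")
  # one asymptote (upper plateau unreached), efficacy ~75 observed -> 2.2
  s22 <- make_series(0, 75 / (1 / (1 + (15 / 46)^2)), 15, 2)
  expect_equal(classify_curve(fit_4pl(s22), s22), "2.2")
  # same shape, high observed efficacy -> 2.1
  s21 <- make_series(0, 95 / (1 / (1 + (15 / 46)^2)), 15, 2)
  expect_equal(classify_curve(fit_4pl(s21), s21), "2.1")
  # single-point activity at the top concentration -> 3
  s3 <- make_series(0, 300, 70, 4)
  expect_equal(classify_curve(fit_4pl(s3), s3), "3")
  # flat -> 4
  s4 <- data.frame(concentration = qhts_concentrations(), response = rep(0, 8))
  expect_equal(classify_curve(fit_4pl(s4), s4), "4")
})

test_that("classification is total and exhaustive over noisy inputs", {
  set.seed(402)
  labels <- c("1.1", "1.2", "2.1", "2.2", "3", "4")
  for (k in 1:40) {
    s <- data.frame(concentration = qhts_concentrations(),
                    response = rnorm(8, runif(1, -20, 120), runif(1, 0, 40)))
    f <- fit_4pl(s)
    cls <- classify_curve(f, s)
    expect_length(cls, 1)
    expect_true(cls %in% labels)
  }
})

test_that("activity triage implements the stated rule", {
  expect_equal(triage_activity("1.2", 74), "active")
  expect_equal(triage_activity("4", 99), "inactive")
  expect_equal(triage_activity("2.2", 52), "inconclusive")  # 52 <= 60
  expect_equal(triage_activity("3", 85), "inconclusive")
  expect_equal(triage_activity("1.1", 60), "inconclusive")  # strict >
  expect_error(triage_activity("5", 50), "unknown curve class")
  # vectorized and partitioning
  cls <- c("1.1", "1.2", "2.1", "2.2", "3", "4")
  eff <- c(90, 61, 59, 70, 90, 0)
  act <- triage_activity(cls, eff)
  expect_equal(as.vector(table(act)[c("active", "inactive", "inconclusive")]),
               c(3L, 1L, 2L))
})

test_that("triage counts partition the screen", {
  mix <- paper_class_mix()
  lib <- gen_screen_library(800, mix, seed = 21)
  act <- triage_activity(lib$true_class, lib$true_efficacy)
  expect_equal(sum(act == "active") + sum(act == "inactive") +
                 sum(act == "inconclusive"), 800)
})

test_that("hit ranking reproduces the published ordering", {
  t1 <- pheo_top50_hits()
  calls <- data.frame(compound_id = t1$name, curve_class = t1$curve_class,
                      ic50 = t1$ic50, efficacy = t1$efficacy,
                      activity = "active", stringsAsFactors = FALSE)
  ranked <- rank_hits(calls, 50)
  # class blocks in confidence order
  expect_equal(rle(ranked$curve_class)$values, c("1.1", "1.2", "2.1", "2.2"))
  # the complete high-efficacy block is sorted by potency, colchicine first
  blk <- ranked[ranked$curve_class == "1.1", ]
  expect_match(blk$compound_id[1], "Colchicine")
  expect_true(all(diff(blk$ic50) >= 0))

  expect_equal(nrow(rank_hits(calls[0, ], 10)), 0)
  expect_warning(r <- rank_hits(calls[1:3, ], 10), "only 3")
  expect_equal(nrow(r), 3)

  # every returned record is active
  calls$activity[1:10] <- "inconclusive"
  expect_true(all(suppressWarnings(rank_hits(calls, 50))$activity == "active"))
})

test_that("category enrichment ratios and flags are correct", {
  calls <- data.frame(
    compound_id = sprintf("c%02d", 1:20),
    category = rep(c("antiseptic", "background"), c(4, 16)),
    activity = c(rep("active", 2), rep("inactive", 2),
                 rep(c("active", "inactive"), c(1, 15))),
    stringsAsFactors = FALSE
  )
  enr <- category_enrichment(calls)
  expect_equal(enr$enrichment_ratio[enr$category == "antiseptic"], 50)
  expect_true(enr$flagged[enr$category == "antiseptic"])
  expect_false(enr$flagged[enr$category == "background"])
  expect_equal(enr$category[1], "antiseptic")  # sorted descending
  expect_equal(sum(enr$n_total), 20)
  # top-5 report has exactly 5 rows on a 5-category library
  calls5 <- data.frame(compound_id = sprintf("d%02d", 1:10),
                       category = rep(letters[1:5], 2),
                       activity = "active", stringsAsFactors = FALSE)
  expect_equal(nrow(utils::head(category_enrichment(calls5), 5)), 5)
})

test_that("observed-efficacy triage switch changes borderline calls", {
  # fitted window 55 (< 60) but an observed overshoot above 60
  conc <- qhts_concentrations()
  y <- fpl_curve(conc, 0, 55, 0.5, 2)
  y[8] <- 62  # overshooting top point
  cfg_obs <- qhts_config(triage_efficacy = "observed")
  f <- fit_4pl(data.frame(concentration = conc, response = y))
  cls <- classify_curve(f, data.frame(concentration = conc, response = y))
  expect_true(cls %in% c("1.1", "1.2", "2.1", "2.2"))
  expect_equal(triage_activity(cls, f$efficacy), "inconclusive")
  expect_equal(triage_activity(cls, f$obs_max, cfg_obs), "active")
})
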