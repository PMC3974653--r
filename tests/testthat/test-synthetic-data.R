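test_that("concentration series spans 0.5 nM - 46 uM at a 1:2.236^2 step", {
  conc <- qhts_concentrations()
  expect_length(conc, 8)
  expect_equal(max(conc), 46)
  expect_equal(min(conc) * 1000, 0.589, tolerance = 1e-3)  # nM
  steps <- conc[-1] / conc[-8]
  expect_equal(steps, rep(2.236^2, 7), tolerance = 1e-12)
  expect_true(all(diff(conc) > 0))
})

test_that("library generation honors the class mix and is deterministic", {
  lib <- gen_screen_library(100, list("4" = 1.0), seed = 1)
  expect_equal(nrow(lib), 100)
  expect_true(all(lib$true_class == "4"))

  mix <- paper_class_mix()
  lib2 <- gen_screen_library(3826, mix, seed = 2)
  counts <- table(lib2$true_class)
  expect_equal(sum(counts[c("1.1", "1.2", "2.1", "2.2")]), 76)
  expect_equal(unname(counts["3"]), 269)
  expect_equal(unname(counts["4"]), 3481)
  # counts match proportions to rounding
  expect_true(all(abs(counts - mix[names(counts)] * 3826) <= 1))

  expect_identical(gen_screen_library(200, mix, seed = 9),
                   gen_screen_library(200, mix, seed = 9))
  expect_false(identical(gen_screen_library(200, mix, seed = 9),
                         gen_screen_library(200, mix, seed = 10)))
})

test_that("library generation validates its inputs and invariants", {
  expect_error(gen_screen_library(10, list("4" = 0.5), seed = 1),
               "sum to 1")
  expect_error(gen_screen_library(10, list(banana = 1), seed = 1),
               "class_mix")
  lib <- gen_screen_library(500, paper_class_mix(), seed = 3)
  expect_false(any(duplicated(lib$compound_id)))
  active <- !is.na(lib$true_ic50)
  expect_true(all(lib$true_ic50[active] > 0))
  expect_true(all(lib$true_top >= lib$true_bottom))
  # efficacies planted >= 2 points away from the 60/80 boundaries
  eff <- lib$true_efficacy[lib$true_class %in% c("1.1", "1.2", "2.1", "2.2")]
  expect_true(all(abs(eff - 60) >= 2 & abs(eff - 80) >= 2))
  # active-class IC50s inside the tested range
  conc <- qhts_concentrations()
  in_range <- lib$true_class %in% c("1.1", "1.2", "2.1", "2.2")
  expect_true(all(lib$true_ic50[in_range] > min(conc) &
                    lib$true_ic50[in_range] < max(conc)))
})

test_that("plate simulation is anchored by controls and seeded", {
  lib <- gen_screen_library(30, list("1.1" = 0.5, "4" = 0.5), seed = 4)
  reads <- gen_plate_reads(lib, noise_sd = 0, seed = 5)
  expect_setequal(unique(reads$plates$role), c("dmso", "pos_ctrl", "sample"))
  # columns 1-4 are all controls, nothing else is
  ctrl <- reads$plates$role != "sample"
  expect_true(all(reads$plates$col[ctrl] %in% 1:4))
  expect_true(all(!reads$plates$col[!ctrl] %in% 1:4))
  expect_equal(sum(reads$map$compound_id == lib$compound_id[1]), 8)

  # noiseless class-4 compound: all normalized responses are 0
  norm <- normalize_plate(reads$plates)
  ser <- build_titrations(norm, reads$map)
  flat_ids <- lib$compound_id[lib$true_class == "4"]
  expect_true(all(abs(ser$response[ser$compound_id %in% flat_ids]) < 1e-9))

  r1 <- gen_plate_reads(lib, noise_sd = 3, seed = 11)
  r2 <- gen_plate_reads(lib, noise_sd = 3, seed = 11)
  expect_identical(r1, r2)

  expect_error(gen_plate_reads(lib, layout = plate_layout(control_cols = 1)),
               "control group")
})

test_that("noiseless plates round-trip through fit and classification", {
  mix <- c("1.1" = .3, "1.2" = .2, "2.1" = .2, "2.2" = .2, "4" = .1)
  lib <- gen_screen_library(60, as.list(mix), seed = 6)
  reads <- gen_plate_reads(lib, noise_sd = 0, seed = 7)
  res <- suppressMessages(analyze_screen(reads$plates, reads$map))
  m <- merge(lib, res, by = "compound_id")
  expect_gte(mean(m$true_class == m$curve_class), 0.99)
  act <- m$true_class %in% c("1.1", "1.2", "2.1", "2.2")
  expect_lt(max(abs(m$ic50[act] / m$true_ic50[act] - 1)), 1e-3)
})

test_that("expression pair hits the target cross-data-set correlation", {
  # perfect correlation, no noise
  p1 <- gen_expression_pair(200, rho = 1, seed = 1, sample_sd = 0,
                            frac_private = 0)
  r1 <- cor(rowMeans(p1$a), rowMeans(p1$b))
  expect_equal(r1, 1.0, tolerance = 1e-12)

  # null: |r| within 2/sqrt(n)
  p0 <- gen_expression_pair(4000, rho = 0, seed = 2, frac_private = 0)
  r0 <- cor(rowMeans(p0$a), rowMeans(p0$b))
  expect_lt(abs(r0), 2 / sqrt(4000))

  # intermediate rho recovered up to sampling error
  rs <- vapply(1:5, function(s) {
    p <- gen_expression_pair(1440, rho = 0.86, seed = s, frac_private = 0)
    cor(rowMeans(p$a)[seq_len(1440)], rowMeans(p$b)[seq_len(1440)])
  }, numeric(1))
  expect_equal(mean(rs), 0.86, tolerance = 0.02)

  expect_error(gen_expression_pair(2, rho = 0.5, seed = 1), "n_genes")
  expect_error(gen_expression_pair(10, rho = 1.5, seed = 1), "rho")

  # species namespaces: murine title-case, human uppercase, shared after
  # uppercasing
  expect_true(all(grepl("^[A-Z][a-z0-9]+$", rownames(p1$a))))
  expect_true(all(grepl("^[A-Z0-9]+$", rownames(p1$b))))
  expect_true(all(toupper(rownames(p1$a)) %in%
                    c(p1$shared_genes, toupper(rownames(p1$a)))))
})

test_that("drug-target map generator meets its size contract", {
  dmap <- gen_drug_target_map(seed = 1)
  expect_equal(length(unique(dmap$drug)), 22)
  expect_equal(length(unique(dmap$gene)), 2129)
  expect_equal(nrow(dmap), 3091)
  expect_false(any(duplicated(paste(dmap$drug, dmap$gene))))
  expect_identical(dmap, gen_drug_target_map(seed = 1))
})

test_that("combination generator plants the requested combination index", {
  tr <- combination_truth(dm1 = 5, dm2 = 1000, m1 = 0.6, m2 = 1.1,
                          ratio = 200, ci_true = 1, noise_sd = 0)
  assay <- gen_combination_assay(tr, seed = 1)
  an <- analyze_combination(assay$single1, assay$single2, assay$combo)
  expect_equal(an$rows$ci, rep(1, 5), tolerance = 1e-6)
  expect_true(all(an$rows$call == "additive"))

  # fa monotone increasing in dose level, all in (0, 1)
  ord <- order(assay$combo$dose1)
  expect_true(all(diff(assay$combo$fa[ord]) > 0))
  expect_true(all(assay$combo$fa > 0 & assay$combo$fa < 1))

  # Loewe fixed point: with unit slopes, half of each drug's median-effect
  # dose combines additively to exactly half effect
  tr2 <- combination_truth(dm1 = 0.005, dm2 = 1, m1 = 1, m2 = 1,
                           ratio = 200, ci_true = 1, noise_sd = 0)
  a2 <- gen_combination_assay(tr2, dose_levels = 0.5, seed = 1)
  expect_equal(a2$combo$fa, 0.5, tolerance = 1e-9)

  # recovery at mild noise
  tr3 <- combination_truth(5, 1000, 0.6, 1.1, 200, ci_true = 0.55,
                           noise_sd = 0.01)
  cis <- vapply(1:20, function(s) {
    a <- gen_combination_assay(tr3, seed = s)
    median(analyze_combination(a$single1, a$single2, a$combo)$rows$ci)
  }, numeric(1))
  expect_equal(mean(cis), 0.55, tolerance = 0.05)

  # mismatched dose ratio rejected; clipping flagged
  bad <- data.frame(dose1 = c(1, 2), dose2 = c(100, 500))
  expect_error(gen_combination_assay(tr, dose_levels = bad), "ratio")
  tr_noisy <- combination_truth(5, 1000, 0.6, 1.1, 200, ci_true = 0.2,
                                noise_sd = 0.3)
  a_noisy <- gen_combination_assay(tr_noisy, dose_levels = c(16, 32), seed = 2)
  expect_true(all(a_noisy$combo$fa > 0 & a_noisy$combo$fa < 1))
  expect_type(a_noisy$combo$clipped, "logical")
})

test_that("generators reject invalid combination truths", {
  expect_error(combination_truth(-1, 1, 1, 1, 1, 1), "doses")
  expect_error(combination_truth(1, 1, 0, 1, 1, 1), "exponents")
  expect_error(combination_truth(1, 1, 1, 1, -2, 1), "ratio")
})
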