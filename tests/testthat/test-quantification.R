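test_that("Grubbs filter removes a gross outlier and stops at n = 3", {
  # G = 1.4987 vs critical 1.4812 at alpha = 0.05, N = 4 (hand-computed)
  kept <- grubbs_filter(c(1.0, 1.1, 0.9, 5.0), alpha = 0.05)
  expect_equal(sort(as.numeric(kept)), c(0.9, 1.0, 1.1))
  expect_equal(attr(kept, "removed"), 5.0)
  # zero variance: untouched
  expect_equal(as.numeric(grubbs_filter(c(1, 1, 1, 1))), c(1, 1, 1, 1))
  # fewer than 3 values: untouched with warning
  expect_warning(out <- grubbs_filter(c(1.0, 1.1)), "at least 3")
  expect_equal(as.numeric(out), c(1.0, 1.1))
})

test_that("Grubbs false-removal rate is controlled on clean replicates", {
  set.seed(123)
  removed_any <- vapply(1:400, function(i) {
    length(attr(grubbs_filter(rnorm(4, 1, 0.05)), "removed")) > 0
  }, logical(1))
  expect_lt(mean(removed_any), 0.10)
})

test_that("planted gross calibration outliers are eliminated reliably", {
  set.seed(7)
  hits <- vapply(1:200, function(i) {
    cal <- generate_calibration("PC(16:0)", concentrations = c(0.1, 1, 5),
                                reps = 4, noise_cv = 0.05, outlier_rate = 1,
                                outlier_factor = 5, seed = i)
    planted <- cal$truth$outliers
    all(vapply(seq_len(nrow(planted)), function(j) {
      cc <- planted$concentration[j]
      reps <- cal$levels$ratio[cal$levels$concentration == cc]
      bad <- reps[planted$replicate[j]]
      !(bad %in% as.numeric(grubbs_filter(reps)))
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("calibration models average outlier-screened replicates per level", {
  cal <- generate_calibration("PE(16:0)", noise_cv = 0.05, seed = 42)
  model <- build_calibration(cal)
  expect_s3_class(model, "calibration_model")
  expect_setequal(model$applies_to, c("PE", "PME", "PDME"))
  expect_true(model$monotone)
  # level means within 2 sd / sqrt(4) of the true response
  truth <- cal$truth$slope * model$levels$concentration
  rel_err <- abs(model$levels$mean_ratio - truth) / truth
  expect_true(all(rel_err < 2 * 0.05 / sqrt(4) + 0.03))
  # planted outliers do not bias the level means
  cal_out <- generate_calibration("PE(16:0)", noise_cv = 0.05,
                                  outlier_rate = 1, outlier_factor = 5,
                                  seed = 43)
  model_out <- build_calibration(cal_out)
  truth2 <- cal_out$truth$slope * model_out$levels$concentration
  expect_true(all(abs(model_out$levels$mean_ratio - truth2) / truth2 < 0.12))
  # insufficient levels
  short <- generate_calibration("PC(16:0)",
                                concentrations = c(0.01, 0.1, 1, 10),
                                seed = 1)
  expect_error(build_calibration(short), "insufficient levels")
})

test_that("five calibration levels are selected around the sample ratio", {
  model <- structure(list(
    standard_id = "PC(16:0)", applies_to = "PC",
    levels = data.frame(concentration = 1:9, mean_ratio = (1:9) / 10,
                        n_retained = 4),
    monotone = TRUE), class = "calibration_model")
  mid <- select_levels(0.52, model)
  expect_equal(mid$concentration, 3:7)
  expect_false(attr(mid, "extrapolated"))
  expect_warning(lo <- select_levels(0.01, model), "extrapolating")
  expect_equal(lo$concentration, 1:5)
  expect_warning(hi <- select_levels(5, model), "extrapolating")
  expect_equal(hi$concentration, 5:9)
  # a ratio exactly at a level mean keeps that level in the window
  at <- select_levels(0.40, model)
  expect_true(4 %in% at$concentration)
})

test_that("quantification inverts the local calibration line", {
  cal <- generate_calibration("PC(16:0)", noise_cv = 0, seed = 1)
  model <- build_calibration(cal)
  slope <- cal$truth$slope
  # noiseless: exact inversion
  conc <- quantify_species(area = slope * 1.0 * 1e6, is_area = 1e6, model)
  expect_equal(as.numeric(conc), 1.0, tolerance = 1e-6)
  expect_false(attr(conc, "floored"))
  # zero area floors at zero
  z <- quantify_species(0, 1e6, model)
  expect_equal(as.numeric(z), 0)
  expect_error(quantify_species(100, 0, model), "internal standard")
  # 5% multiplicative noise: mean relative error below 5%
  set.seed(55)
  errs <- vapply(1:100, function(i) {
    true <- 1.0
    area <- slope * true * 1e6 * rlnorm(1, -0.5 * log(1.0025),
                                        sqrt(log(1.0025)))
    abs(as.numeric(quantify_species(area, 1e6, model)) - true) / true
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("quantification is unbiased against a noiseless linear response", {
  cal <- generate_calibration("PS(16:0)", noise_cv = 0, seed = 2)
  model <- build_calibration(cal)
  slope <- cal$truth$slope
  set.seed(9)
  truths <- runif(1000, 0.01, 9)
  rel <- vapply(truths, function(tt) {
    est <- as.numeric(quantify_species(slope * tt * 1e6, 1e6, model))
    abs(est - tt) / tt
  }, numeric(1))
  expect_lt(mean(rel), 0.01)
})

test_that("blank subtraction floors at zero and drops blanked species", {
  smp <- data.frame(species = c("PC(32:0)", "PC(34:1)", "PE(34:1)"),
                    concentration = c(2.0, 0.3, 1.0),
                    stringsAsFactors = FALSE)
  blank <- data.frame(species = c("PC(32:0)", "PC(34:1)"),
                      concentration = c(0.5, 0.5), stringsAsFactors = FALSE)
  out <- blank_subtract(smp, list(blank))
  expect_equal(out$concentration[out$species == "PC(32:0)"], 1.5)
  expect_false("PC(34:1)" %in% out$species)   # fully blanked out
  expect_equal(out$concentration[out$species == "PE(34:1)"], 1.0)
  expect_warning(same <- blank_subtract(smp, list()), "no process blanks")
  expect_equal(same$concentration, smp$concentration)
})

test_that("percentage distributions sum to 100 and are scale invariant", {
  tab <- data.frame(species = c("PC(32:0)", "PC(38:6)"),
                    concentration = c(1, 3), stringsAsFactors = FALSE)
  pd <- percentage_distribution(tab, "s1", "stomach", "Jan")
  expect_equal(pd$pct, c(25, 75))
  expect_equal(sum(pd$pct), 100, tolerance = 1e-9)
  # single species
  one <- percentage_distribution(tab[1, , drop = FALSE])
  expect_equal(one$pct, 100)
  # scaling every concentration leaves the composition unchanged
  tab10 <- tab; tab10$concentration <- tab10$concentration * 17.3
  expect_equal(percentage_distribution(tab10)$pct, pd$pct)
  expect_error(percentage_distribution(
    data.frame(species = "PC(32:0)", concentration = 0)), "empty")
})

test_that("free-fatty-acid tables reduce to SFA/MUFA/PUFA percentages", {
  gc <- data.frame(fa = c("16:0", "18:1", "20:5"), area = c(100, 100, 100),
                   is_area = 50)
  out <- ingest_ffa_table(gc)
  expect_equal(unname(unlist(out)), rep(100 / 3, 3), tolerance = 1e-9)
  # doubling all areas changes nothing
  gc2 <- gc; gc2$area <- gc2$area * 2
  expect_equal(ingest_ffa_table(gc2), out)
  # planted composition with known response factors recovered exactly
  rf <- c(SFA = 2, MUFA = 1, PUFA = 0.5)
  conc_true <- c(`16:0` = 1, `18:1` = 2, `20:5` = 5)
  gc3 <- data.frame(fa = names(conc_true),
                    area = conc_true * rf[c("SFA", "MUFA", "PUFA")] * 50,
                    is_area = 50)
  out3 <- ingest_ffa_table(gc3, rf)
  expect_equal(unname(unlist(out3)), 100 * conc_true / sum(conc_true),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(ingest_ffa_table(data.frame(fa = "C16", area = 1,
                                           is_area = 1)), "unknown fatty")
})
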