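test_that("class identification follows the head-group diagnostic rules", {
  rules <- build_rule_table()
  # PC: phosphocholine fragment ion present
  mzp <- precursor_mz("PC(38:6)", "positive")$mz
  f_pc <- feature("f", "positive", 5, mzp, 1,
                  ms2_spectrum(mzp, c(184.0733, 500.1), c(1000, 10)))
  expect_equal(identify_class(f_pc, rules)$cls[1], "PC")
  # PE: neutral loss of the head group from the precursor
  mze <- precursor_mz("PE(32:0)", "positive")$mz
  f_pe <- feature("f", "positive", 6, mze, 1,
                  ms2_spectrum(mze, mze - 141.0191, 900))
  expect_equal(identify_class(f_pe, rules)$cls[1], "PE")
  # neither diagnostic: no candidate
  f_none <- feature("f", "positive", 6, mze, 1,
                    ms2_spectrum(mze, c(100.1, 200.2), c(5, 5)))
  expect_equal(nrow(identify_class(f_none, rules)), 0)
  # no MS2 at all: unidentifiable
  expect_equal(nrow(identify_class(feature("f", "positive", 6, mze, 1),
                                   rules)), 0)
})

test_that("sum composition inference is exhaustive and unique at sane tolerance", {
  hits <- infer_sum_composition(806.5694, "PC", "positive", 5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$c_total, 38)
  expect_equal(hits$dbe_total, 6)
  # independent brute force over the same grid
  brute <- list()
  for (cc in 20:70) for (dd in 0:16) {
    mz <- tryCatch(precursor_mz(sum_comp("PC", cc, dd), "positive")$mz,
                   error = function(e) NA_real_)
    if (!is.na(mz) && abs(ppm_error(806.5694, mz)) <= 5) {
      brute[[length(brute) + 1L]] <- c(cc, dd)
    }
  }
  expect_equal(length(brute), 1)
  expect_equal(brute[[1]], c(38, 6))
  # absurd tolerance yields many hits and a warning
  expect_warning(wide <- infer_sum_composition(806.5694, "PC", "positive",
                                               5000), "tolerance")
  expect_gt(nrow(wide), 1)
  # below the grid: no hit
  expect_equal(nrow(infer_sum_composition(184.0733, "PC", "positive", 5)), 0)
})

test_that("acyl pair enumeration resolves chain compositions and sn-2", {
  # one acyl pair uniquely explains the overall composition
  s58 <- ms2_spectrum(NA, c(acyl_anion_mz(22, 6), acyl_anion_mz(36, 8)),
                      c(400, 900))
  p58 <- enumerate_acyl_pairs("PC(58:14)", s58)
  expect_equal(nrow(p58), 1)
  expect_equal(pair_keys(p58), "22:6+36:8")
  # the more intense fragment is assigned sn-2
  s38 <- ms2_spectrum(NA, c(acyl_anion_mz(16, 0), acyl_anion_mz(22, 6)),
                      c(255, 1000))
  p38 <- enumerate_acyl_pairs("PC(38:6)", s38)
  expect_equal(nrow(p38), 1)
  sn2 <- if (p38$sn2 == "a") c(p38$c_a, p38$dbe_a) else c(p38$c_b, p38$dbe_b)
  expect_equal(sn2, c(22, 6))
  expect_equal(p38$label, "22:6/16:0")
  # several combinations may fit one saturated sum
  s36 <- ms2_spectrum(NA, c(acyl_anion_mz(16, 0), acyl_anion_mz(18, 0),
                            acyl_anion_mz(20, 0)), c(10, 20, 30))
  p36 <- enumerate_acyl_pairs("PC(36:0)", s36)
  expect_setequal(pair_keys(p36), c("16:0+20:0", "18:0+18:0"))
})

test_that("pair enumeration equals the brute-force double-loop oracle", {
  set.seed(99)
  for (rep in 1:200) {
    cls <- sample(PL_CLASSES, 1)
    ct <- sample(24:60, 1); dt <- sample(0:14, 1)
    sc <- sum_comp(cls, ct, dt)
    n_peaks <- sample(2:6, 1)
    peaks <- vapply(seq_len(n_peaks), function(i) {
      acyl_anion_mz(sample(12:36, 1), sample(0:8, 1))
    }, numeric(1))
    peaks <- unique(peaks)
    spec <- ms2_spectrum(NA, peaks, seq_along(peaks) * 10)
    got <- pair_keys(enumerate_acyl_pairs(sc, spec, 10))
    want <- brute_force_pairs(sc, peaks, 10)
    expect_equal(got, want)
  }
})

test_that("permuting acyl intensities swaps sn-2 but never the pair set", {
  spec_ab <- ms2_spectrum(NA, c(acyl_anion_mz(16, 0), acyl_anion_mz(22, 6)),
                          c(100, 900))
  spec_ba <- ms2_spectrum(NA, c(acyl_anion_mz(16, 0), acyl_anion_mz(22, 6)),
                          c(900, 100))
  pa <- enumerate_acyl_pairs("PC(38:6)", spec_ab)
  pb <- enumerate_acyl_pairs("PC(38:6)", spec_ba)
  expect_equal(pair_keys(pa), pair_keys(pb))
  expect_false(pa$label == pb$label)
  expect_equal(pb$label, "16:0/22:6")
})

test_that("the confirmation gate requires every line of evidence", {
  pr <- make_species_pair("PC(38:6)", list(c(16, 0, 22, 6)))
  res <- confirm_species(pr)
  expect_true(res$ok)
  expect_equal(res$annotation$species, "PC(38:6)")
  expect_equal(res$pairs$label, "22:6/16:0")

  # acyl signals absent in ESI- MS2
  pr2 <- make_species_pair("PC(38:6)", list(c(16, 0, 22, 6)))
  keep <- pr2$neg$ms2$mz > 400   # strips both acyl anions, keeps the NL peak
  pr2$neg$ms2 <- ms2_spectrum(pr2$neg$mz, pr2$neg$ms2$mz[keep],
                              pr2$neg$ms2$intensity[keep])
  res2 <- confirm_species(pr2)
  expect_false(res2$ok)
  expect_match(res2$reason, "fatty acid")

  # negative precursor off-mass: not present in both polarities
  pr3 <- make_species_pair("PC(38:6)", list(c(16, 0, 22, 6)))
  pr3$neg$mz <- pr3$neg$mz + 0.5
  res3 <- confirm_species(pr3)
  expect_false(res3$ok)
  expect_match(res3$reason, "both polarities|sum composition")

  # PC without the methyl-formate loss in ESI- MS2 fails the class rule
  pr4 <- make_species_pair("PC(38:6)", list(c(16, 0, 22, 6)))
  keep <- pr4$neg$ms2$mz < 400   # acyl anions only
  pr4$neg$ms2 <- ms2_spectrum(pr4$neg$mz, pr4$neg$ms2$mz[keep],
                              pr4$neg$ms2$intensity[keep])
  res4 <- confirm_species(pr4)
  expect_false(res4$ok)
  expect_match(res4$reason, "class rule")
})

test_that("classes without a negative-mode rule confirm on precursor and acyls", {
  pr <- make_species_pair("PE(34:1)", list(c(16, 0, 18, 1)))
  res <- confirm_species(pr)
  expect_true(res$ok)
  expect_equal(res$annotation$species, "PE(34:1)")
})

test_that("annotate_run recovers a rendered lipidome with no false species", {
  cfg <- sim_config(n_species = 10, ppm_sd = 0, area_cv = 0)
  lip <- generate_lipidome(cfg, seed = 5)
  smp <- render_run(lip, "s1", "stomach", "Jan", seed = 5)
  ann <- annotate_run(smp)
  expect_setequal(ann$species, unique(lip$species))
  # every reported pair belongs to the truth for that species
  pairs <- attr(ann, "pairs")
  truth_keys <- unique(paste(lip$species,
                             paste0(lip$c_a, ":", lip$dbe_a),
                             paste0(lip$c_b, ":", lip$dbe_b)))
  got_keys <- paste(pairs$species,
                    pmin(paste0(pairs$c_a, ":", pairs$dbe_a),
                         paste0(pairs$c_b, ":", pairs$dbe_b)),
                    pmax(paste0(pairs$c_a, ":", pairs$dbe_a),
                         paste0(pairs$c_b, ":", pairs$dbe_b)))
  # allow truth keys in either chain order
  norm_truth <- vapply(strsplit(truth_keys, " "), function(x)
    paste(x[1], min(x[2], x[3]), max(x[2], x[3])), character(1))
  expect_true(all(got_keys %in% norm_truth))
})

test_that("decoy features and blanks yield no annotations", {
  cfg <- sim_config(n_species = 8, ppm_sd = 0, area_cv = 0, decoy_n = 10)
  lip <- generate_lipidome(cfg, seed = 21)
  smp <- render_run(lip, "s1", "stomach", "Jan", seed = 21)
  ann <- annotate_run(smp)
  expect_setequal(ann$species, unique(lip$species))

  blank <- render_run(lip, "b1", "stomach", "Jan", seed = 22,
                      is_blank = TRUE)
  expect_equal(nrow(annotate_run(blank)), 0)

  # near-miss decoys planted 20 ppm off a real species fail a 5 ppm gate
  pr <- make_species_pair("PC(38:6)", list(c(16, 0, 22, 6)),
                          ppm_shift = 20)
  paired <- pair_features(list(pr$pos), list(pr$neg), 0.1, 5)
  confirmed <- if (length(paired$pairs) == 0) list() else
    Filter(function(p) confirm_species(p)$ok, paired$pairs)
  expect_length(confirmed, 0)
})

test_that("shrinking any tolerance never adds an annotation", {
  cfg <- sim_config(n_species = 12, ppm_sd = 2, area_cv = 0.05)
  lip <- generate_lipidome(cfg, seed = 31)
  smp <- render_run(lip, "s1", "digestive_gland", "Jan", seed = 31)
  base <- annotate_run(smp, ipl_config())
  for (shrunk in list(ipl_config(ms1_tol_ppm = 2),
                      ipl_config(ms2_tol_ppm = 3),
                      ipl_config(rt_tol_min = 0.02))) {
    tight <- annotate_run(smp, shrunk)
    expect_true(all(tight$species %in% base$species))
    expect_lte(nrow(tight), nrow(base))
  }
})
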