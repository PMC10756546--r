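# small synthetic composition table builder
comp_row <- function(sid, organ, month, species, pct) {
  data.frame(sample_id = sid, organ = organ, month = month,
             species = species,
             cls = vapply(species, function(s) parse_species(s)$cls,
                          character(1)),
             pct = pct, stringsAsFactors = FALSE, row.names = NULL)
}

test_that("grouping bins species into class-wise mass and DBE tertiles", {
  species <- sprintf("PC(%d:%d)", seq(30, 46, 2), c(0:8))
  df <- comp_row("s1", "stomach", "Jan", species, rep(100 / 9, 9))
  scheme <- derive_grouping(df)
  groups <- species_group(species, scheme)
  mw <- sub("^PC\\.([A-Z]+)\\..*$", "\\1", groups)
  du <- sub("^.*\\.", "", groups)
  expect_equal(unname(table(mw)[c("LMW", "MMW", "HMW")]),
               array(c(3L, 3L, 3L)), ignore_attr = TRUE)
  expect_equal(unname(table(du)[c("LDU", "MDU", "HDU")]),
               array(c(3L, 3L, 3L)), ignore_attr = TRUE)
  # explicit breakpoints override the tertiles
  ov <- list(PC = list(du_breaks = c(0.5, 7.5)))
  scheme2 <- derive_grouping(df, overrides = ov)
  du2 <- sub("^.*\\.", "", species_group(species, scheme2))
  expect_equal(sum(du2 == "LDU"), 1)
  expect_equal(sum(du2 == "HDU"), 1)
  # grouping does not depend on sample order
  df_perm <- df[sample(nrow(df)), ]
  expect_equal(derive_grouping(df_perm), scheme, ignore_attr = TRUE)
  # degenerate class collapses to a single bin with warning
  one <- comp_row("s1", "stomach", "Jan", c("PS(34:1)", "PS(34:1)"),
                  c(50, 50))
  expect_warning(s1 <- derive_grouping(one), "fewer than 3")
  expect_equal(species_group("PS(34:1)", s1), c(`PS(34:1)` = "PS.MMW.MDU"))
})

test_that("group matrix conserves row sums and respects the scheme", {
  species <- c("PC(30:0)", "PC(38:6)", "PC(44:10)")
  df <- rbind(comp_row("s1", "stomach", "Jan", species, c(20, 30, 50)),
              comp_row("s2", "stomach", "May", species, c(60, 30, 10)))
  scheme <- derive_grouping(df)
  gm <- group_matrix(df, scheme)
  expect_equal(unname(rowSums(gm)), c(100, 100), tolerance = 1e-9)
  # distinct group per species: matrix is a permutation of the species table
  expect_equal(ncol(gm), 3)
  expect_setequal(as.numeric(gm["s1", ]), c(20, 30, 50))
  # unmapped species error
  df_bad <- rbind(df, comp_row("s1", "stomach", "Jan", "PE(34:1)", 0))
  expect_error(group_matrix(df_bad, scheme), "not covered")
})

test_that("PCA separates planted clusters and rejects degenerate input", {
  set.seed(8)
  base <- c(40, 30, 20, 10)
  mat <- rbind(
    t(replicate(5, base + rnorm(4, 0, 1))),
    t(replicate(5, rev(base) + rnorm(4, 0, 1))))
  rownames(mat) <- paste0("s", 1:10)
  p <- pca_scores(mat)
  pc1 <- p$scores[, 1]
  expect_true(all(sign(pc1[1:5]) == sign(pc1[1])))
  expect_true(all(sign(pc1[6:10]) == -sign(pc1[1])))
  # scores of distinct components are orthogonal
  expect_lt(abs(sum(p$scores[, 1] * p$scores[, 2])), 1e-8)
  expect_error(pca_scores(mat[1, , drop = FALSE]), "at least 3")
  expect_error(pca_scores(matrix(5, 4, 3)), "constant")
})

test_that("seasonal ratios report mean-over-mean with correct orientation", {
  sp <- c("PC(32:0)", "PC(44:10)")
  df <- rbind(
    comp_row("a1", "digestive_gland", "May", sp, c(60, 40)),
    comp_row("a2", "digestive_gland", "May", sp, c(70, 30)),
    comp_row("b1", "digestive_gland", "Jan", sp, c(30, 70)),
    comp_row("b2", "digestive_gland", "Mar", sp, c(35, 65)))
  r <- seasonal_ratios(df, months_a = "May", months_b = c("Jan", "Mar"),
                       cls = "PC")
  expect_equal(r$ratio[r$species == "PC(32:0)"], 65 / 32.5)
  expect_equal(r$ratio[r$species == "PC(44:10)"], 35 / 67.5)
  expect_equal(r$mean_pct_b[r$species == "PC(44:10)"], 67.5)
  # reciprocity when the groups are swapped
  r_swap <- seasonal_ratios(df, c("Jan", "Mar"), "May", cls = "PC")
  expect_equal(r_swap$ratio, 1 / r$ratio)
  # identical groups: all ratios 1
  df_same <- rbind(comp_row("x1", "stomach", "Jan", sp, c(50, 50)),
                   comp_row("x2", "stomach", "May", sp, c(50, 50)))
  expect_equal(seasonal_ratios(df_same, "May", "Jan")$ratio, c(1, 1))
  # species present on one side only is flagged, not imputed
  df_one <- rbind(comp_row("y1", "stomach", "Jan", sp, c(40, 60)),
                  comp_row("y2", "stomach", "May", "PC(32:0)", 100))
  r_one <- seasonal_ratios(df_one, "May", "Jan")
  expect_true(r_one$one_sided[r_one$species == "PC(44:10)"])
  expect_true(is.na(r_one$ratio[r_one$species == "PC(44:10)"]))
})

test_that("ternary compositions follow the equal-split and apportionment rules", {
  pairs_386 <- data.frame(species = "PC(38:6)", c_a = 16, dbe_a = 0,
                          c_b = 22, dbe_b = 6, intensity_a = 100,
                          intensity_b = 900, sn2 = "b", label = "22:6/16:0",
                          stringsAsFactors = FALSE)
  df <- comp_row("s1", "stomach", "Jan", "PC(38:6)", 100)
  t1 <- fa_saturation_ternary(df, list(s1 = pairs_386), classes = "PC")
  expect_equal(c(t1$SFA, t1$MUFA, t1$PUFA), c(50, 0, 50))
  # 18:1/18:1 only: all monounsaturated
  pairs_362 <- data.frame(species = "PC(36:2)", c_a = 18, dbe_a = 1,
                          c_b = 18, dbe_b = 1, intensity_a = 500,
                          intensity_b = 500, sn2 = "b", label = "18:1/18:1",
                          stringsAsFactors = FALSE)
  df2 <- comp_row("s1", "stomach", "Jan", "PC(36:2)", 100)
  t2 <- fa_saturation_ternary(df2, list(s1 = pairs_362), classes = "PC")
  expect_equal(c(t2$SFA, t2$MUFA, t2$PUFA), c(0, 100, 0))
  expect_equal(t2$SFA + t2$MUFA + t2$PUFA, 100, tolerance = 1e-9)
  # multi-pair species: apportioned by the more abundant acyl signal
  pairs_iso <- rbind(pairs_386,
                     data.frame(species = "PC(38:6)", c_a = 18, dbe_a = 3,
                                c_b = 20, dbe_b = 3, intensity_a = 300,
                                intensity_b = 100, sn2 = "a",
                                label = "18:3/20:3",
                                stringsAsFactors = FALSE))
  t3 <- fa_saturation_ternary(df, list(s1 = pairs_iso), classes = "PC")
  # weights 900/(900+300) and 300/1200: SFA = 75*0.5... = 37.5, PUFA = 62.5
  expect_equal(c(t3$SFA, t3$MUFA, t3$PUFA), c(37.5, 0, 62.5))
  # sum-composition-only species are excluded and counted
  df_mix <- rbind(df, comp_row("s1", "stomach", "Jan", "PC(40:8)", 0))
  t4 <- fa_saturation_ternary(df_mix, list(s1 = pairs_386), classes = "PC")
  expect_equal(t4$n_excluded, 1)
})

test_that("unsaturation and EPA/DHA indices follow their definitions", {
  pairs_386 <- data.frame(species = "PC(38:6)", c_a = 16, dbe_a = 0,
                          c_b = 22, dbe_b = 6, intensity_a = 100,
                          intensity_b = 900, sn2 = "b", label = "22:6/16:0",
                          stringsAsFactors = FALSE)
  df <- comp_row("s1", "stomach", "Jan", "PC(38:6)", 100)
  ix <- pufa_indices(df, list(s1 = pairs_386), "PC")
  expect_equal(ix$mean_unsaturation, 3.0)
  expect_equal(ix$epa_pct, 0)
  expect_equal(ix$dha_pct, 100)
  # adding a DHA-free species at equal abundance halves the DHA index
  pairs2 <- rbind(pairs_386,
                  data.frame(species = "PC(32:0)", c_a = 16, dbe_a = 0,
                             c_b = 16, dbe_b = 0, intensity_a = 500,
                             intensity_b = 500, sn2 = "b",
                             label = "16:0/16:0", stringsAsFactors = FALSE))
  df2 <- rbind(comp_row("s1", "stomach", "Jan", "PC(38:6)", 50),
               comp_row("s1", "stomach", "Jan", "PC(32:0)", 50))
  ix2 <- pufa_indices(df2, list(s1 = pairs2), "PC")
  expect_equal(ix2$dha_pct, 50)
  expect_equal(ix2$mean_unsaturation, 1.5)
  expect_error(pufa_indices(df, list(s1 = pairs_386), "PE"), "no species")
})

test_that("reference overlap counts formulas and abundance coverage per class", {
  df <- rbind(comp_row("s1", "stomach", "Jan",
                       c("PC(32:0)", "PC(38:6)", "PE(34:1)"),
                       c(30, 50, 20)))
  # identity: full overlap on both sides
  ref_same <- data.frame(species = c("PC(32:0)", "PC(38:6)", "PE(34:1)"),
                         pct = c(10, 20, 70), stringsAsFactors = FALSE)
  ov <- reference_overlap(df, ref_same)
  expect_equal(ov$n_overlap, ov$n_own)
  expect_equal(ov$pct_own_overlap, c(100, 100))
  expect_equal(ov$pct_ref_overlap, c(100, 100))
  # disjoint: zero overlap
  ref_dis <- data.frame(species = c("PC(40:10)", "PE(38:5)"), pct = c(1, 1),
                        stringsAsFactors = FALSE)
  ov0 <- reference_overlap(df, ref_dis)
  expect_equal(ov0$n_overlap, c(0, 0))
  expect_equal(ov0$pct_own_overlap, c(0, 0))
  # half overlap, hand-enumerated
  ref_half <- data.frame(species = c("PC(32:0)", "PC(44:10)"),
                         pct = c(30, 70), stringsAsFactors = FALSE)
  ovh <- reference_overlap(df, ref_half, classes = "PC")
  expect_equal(ovh$n_own, 2)
  expect_equal(ovh$n_ref, 2)
  expect_equal(ovh$n_overlap, 1)
  expect_equal(ovh$pct_own_overlap, 100 * 30 / 80)
  expect_equal(ovh$pct_ref_overlap, 30)
  expect_error(reference_overlap(df, data.frame()), "empty reference")
})
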