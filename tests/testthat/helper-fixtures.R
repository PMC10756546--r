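# Shared fixtures and independent oracles used across the test files.

# Independent additive-assembly oracle for neutral species formulas:
# glycerol + phosphoric acid + head alcohol + two free fatty acids, with
# one water condensed per ester/phosphoester bond (4 bonds in a diacyl
# phospholipid). Deliberately does not touch species_formula().
HEAD_ALCOHOL <- list(
  PC = "C5H13NO", PE = "C2H7NO", PME = "C3H9NO", PDME = "C4H11NO",
  PS = "C3H7NO3", PG = "C3H8O3", PI = "C6H12O6"
)

assemble_species <- function(cls, ca, da, cb, db) {
  parts <- list(
    comp("C3H8O3"),                      # glycerol
    comp("H3O4P"),                       # phosphoric acid
    comp(HEAD_ALCOHOL[[cls]]),
    comp(c(C = ca, H = 2 * ca - 2 * da, O = 2)),
    comp(c(C = cb, H = 2 * cb - 2 * db, O = 2))
  )
  total <- Reduce(comp_add, parts)
  water4 <- comp(c(H = 8, O = 4))
  comp_sub(total, water4)
}

# Brute-force oracle for acyl-pair enumeration: the full cross of the
# acyl search space against itself, with vectorized peak matching.
# Independent of the constrained enumeration in the package.
make_fa_space <- function(crng = c(12L, 40L), drng = c(0L, 10L)) {
  fa <- expand.grid(c = crng[1]:crng[2], d = drng[1]:drng[2])
  fa <- fa[fa$d <= fa$c - 2, , drop = FALSE]
  fa$mz <- vapply(seq_len(nrow(fa)),
                  function(i) acyl_anion_mz(fa$c[i], fa$d[i]), numeric(1))
  fa
}
.FA_SPACE <- make_fa_space()

brute_force_pairs <- function(sc, peak_mz, tol_ppm = 10, fa = .FA_SPACE) {
  matched <- vapply(fa$mz, function(m)
    any(abs(peak_mz - m) <= m * tol_ppm * 1e-6), logical(1))
  ok <- outer(fa$c, fa$c, "+") == sc$c_total &
    outer(fa$d, fa$d, "+") == sc$dbe_total &
    outer(matched, matched, "&")
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) return(character(0))
  keys <- vapply(seq_len(nrow(idx)), function(k) {
    a <- idx[k, 1]; b <- idx[k, 2]
    paste(sort(c(paste0(fa$c[a], ":", fa$d[a]),
                 paste0(fa$c[b], ":", fa$d[b]))), collapse = "+")
  }, character(1))
  sort(unique(keys))
}

# Unordered pair key per row (row order preserved)
pair_key_rows <- function(pairs_df) {
  if (nrow(pairs_df) == 0) return(character(0))
  vapply(seq_len(nrow(pairs_df)), function(i) {
    paste(sort(c(paste0(pairs_df$c_a[i], ":", pairs_df$dbe_a[i]),
                 paste0(pairs_df$c_b[i], ":", pairs_df$dbe_b[i]))),
          collapse = "+")
  }, character(1))
}

# Sorted key set for whole-table comparisons
pair_keys <- function(pairs_df) sort(pair_key_rows(pairs_df))

# Hand-built fully confirmable feature pair for one species with one or
# more acyl pairs (list of c(ca, da, cb, db)); intensities give the second
# chain of each pair double weight (sn-2).
make_species_pair <- function(species, acyls, rt = 5.0, area = 1e5,
                              ppm_shift = 0) {
  sc <- parse_species(species)
  rules <- build_rule_table()
  shift <- function(mz) mz * (1 + ppm_shift * 1e-6)
  mzp <- precursor_mz(sc, "positive")$mz
  mzn <- precursor_mz(sc, "negative")$mz
  rp <- rules[rules$mode == "positive" & rules$cls == sc$cls, ]
  frag_pos <- if (rp$rule_kind == "fragment_ion") rp$mass else mzp - rp$mass
  pos <- feature("fp", "positive", rt, shift(mzp), area,
                 ms2_spectrum(shift(mzp), shift(frag_pos), 1000))
  frag_mz <- numeric(0); frag_int <- numeric(0)
  rn <- rules[rules$mode == "negative" & rules$cls == sc$cls, ]
  if (nrow(rn) > 0) {
    f <- if (rn$rule_kind == "fragment_ion") rn$mass else mzn - rn$mass
    frag_mz <- c(frag_mz, shift(f)); frag_int <- c(frag_int, 800)
  }
  for (p in acyls) {
    frag_mz <- c(frag_mz, shift(acyl_anion_mz(p[1], p[2])),
                 shift(acyl_anion_mz(p[3], p[4])))
    frag_int <- c(frag_int, 500, 1000)
  }
  neg <- feature("fn", "negative", rt, shift(mzn), area,
                 ms2_spectrum(shift(mzn), frag_mz, frag_int))
  list(pos = pos, neg = neg)
}

# Fraction of distinct rendered sum compositions recovered with the
# correct species label by annotate_run.
recovery_rate <- function(study_sample, lipidome, config = ipl_config()) {
  ann <- annotate_run(study_sample, config)
  truth <- unique(lipidome$species)
  mean(truth %in% ann$species)
}
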