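#' @keywords internal
"_PACKAGE"

## Monoisotopic atomic masses (IUPAC/CODATA). D (2H) is carried as its own
## symbol for the deuterated internal standard.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  D = 2.01410177785,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

.ELECTRON_MASS <- 5.48579909070e-4

#' Head-group classes of diacyl glycerophospholipids handled by the package
#'
#' PC phosphatidylcholine, PE phosphatidylethanolamine, PME/PDME the mono-
#' and dimethylated ethanolamines, PI phosphoinositide, PG
#' phosphatidylglycerol, PS phosphatidylserine. Lyso- and ether lipids are
#' outside the model: every species is assumed to carry two ester-bound
#' acyl chains.
#' @export
PL_CLASSES <- c("PC", "PE", "PME", "PDME", "PI", "PG", "PS")

#' Build an elemental composition
#'
#' An elemental composition is a named integer vector of atom counts over
#' the supported elements (C, H, D, N, O, P). Arithmetic on compositions is
#' element-wise; subtraction below zero is an error because a fragment
#' cannot remove atoms its precursor does not have.
#'
#' @param x a molecular formula string such as `"C5H15NO4P"`, or a named
#'   numeric vector of counts.
#' @return named integer vector of class `elemental_composition`.
#' @examples
#' comp("C5H15NO4P")
#' comp(c(C = 2, H = 4, O = 2))
#' @export
comp <- function(x) {
  if (is.character(x)) {
    counts <- parse_formula(x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else {
    stop("composition must be a formula string or a named count vector")
  }
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown) > 0) {
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative atom count in composition")
  if (any(counts != round(counts))) stop("atom counts must be integers")
  out <- counts[counts > 0]
  storage.mode(out) <- "integer"
  class(out) <- "elemental_composition"
  out
}

parse_formula <- function(s) {
  s <- gsub("\\s", "", s)
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  toks <- toks[nzchar(toks)]
  if (sum(nchar(toks)) != nchar(s)) stop("cannot parse formula: ", s)
  counts <- numeric(0)
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  counts
}

#' @export
format.elemental_composition <- function(x, ...) {
  ord <- intersect(c("C", "H", "D", "N", "O", "P"), names(x))
  paste0(vapply(ord, function(el) {
    n <- x[[el]]
    if (n == 1) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<composition>", format(x), "\n")
  invisible(x)
}

#' Element-wise composition arithmetic
#'
#' @param a,b elemental compositions (or inputs accepted by [comp()]).
#' @return an `elemental_composition`.
#' @export
comp_add <- function(a, b) {
  a <- comp(a); b <- comp(b)
  els <- union(names(a), names(b))
  out <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) +
      (if (el %in% names(b)) b[[el]] else 0L)
  }, numeric(1))
  comp(out)
}

#' @rdname comp_add
#' @export
comp_sub <- function(a, b) {
  a <- comp(a); b <- comp(b)
  els <- union(names(a), names(b))
  out <- vapply(els, function(el) {
    (if (el %in% names(a)) a[[el]] else 0L) -
      (if (el %in% names(b)) b[[el]] else 0L)
  }, numeric(1))
  if (any(out < 0)) {
    stop("composition subtraction yields negative count for ",
         paste(els[out < 0], collapse = ", "))
  }
  comp(out)
}

#' Monoisotopic mass of an elemental composition
#'
#' For charged species the electron mass is subtracted per positive charge
#' and added per negative charge, so the result is an ion m/z, not a
#' neutral mass. This correction matters at the fourth decimal: the
#' phosphocholine fragment is 184.0733 with it and 184.0739 without.
#'
#' @param x an elemental composition (or formula string).
#' @param charge integer in -1, 0, +1.
#' @return mass (Da) or m/z for charged species.
#' @examples
#' composition_mass("C5H15NO4P", charge = 1) # 184.0733
#' composition_mass("C2H4O2")                # 60.0211
#' @export
composition_mass <- function(x, charge = 0L) {
  x <- comp(x)
  if (length(x) == 0 || sum(x) == 0) stop("empty composition")
  if (abs(charge) > 1) stop("|charge| must be <= 1")
  sum(.ATOMIC_MASS[names(x)] * as.numeric(x)) - charge * .ELECTRON_MASS
}

#' Fatty acyl chain descriptor
#'
#' Chains are labelled carbons:DBE (double-bond equivalents), e.g. `20:5`
#' for EPA. The structural feasibility guard `n_dbe <= n_carbon - 2` can be
#' relaxed for chains that may carry rings.
#'
#' @param n_carbon carbons including the carboxyl carbon (>= 2).
#' @param n_dbe double-bond equivalents in the chain (>= 0).
#' @param check_feasible enforce `n_dbe <= n_carbon - 2`.
#' @return list of class `fatty_acyl`.
#' @export
fatty_acyl <- function(n_carbon, n_dbe, check_feasible = TRUE) {
  n_carbon <- as.integer(n_carbon); n_dbe <- as.integer(n_dbe)
  if (n_carbon < 2) stop("fatty acyl needs at least 2 carbons")
  if (n_dbe < 0) stop("negative DBE")
  if (check_feasible && n_dbe > n_carbon - 2) {
    stop("infeasible acyl ", n_carbon, ":", n_dbe,
         " (DBE exceeds n_carbon - 2)")
  }
  structure(list(n_carbon = n_carbon, n_dbe = n_dbe), class = "fatty_acyl")
}

#' @export
format.fatty_acyl <- function(x, ...) paste0(x$n_carbon, ":", x$n_dbe)

#' @export
print.fatty_acyl <- function(x, ...) {
  cat("<acyl>", format(x), "\n")
  invisible(x)
}

#' Sum composition of an intact phospholipid
#'
#' Head-group class plus total acyl carbons and total DBE, written
#' `PC(38:6)`. The two chains are not resolved at this level.
#'
#' @param cls head-group class, one of [PL_CLASSES].
#' @param c_total summed acyl carbons (>= 4).
#' @param dbe_total summed acyl DBE (>= 0).
#' @return list of class `sum_composition`.
#' @export
sum_comp <- function(cls, c_total, dbe_total) {
  cls <- match.arg(cls, PL_CLASSES)
  c_total <- as.integer(c_total); dbe_total <- as.integer(dbe_total)
  if (c_total < 4) stop("c_total must be >= 4 (two chains of >= 2 carbons)")
  if (dbe_total < 0) stop("dbe_total must be >= 0")
  structure(list(cls = cls, c_total = c_total, dbe_total = dbe_total),
            class = "sum_composition")
}

#' @export
format.sum_composition <- function(x, ...) {
  paste0(x$cls, "(", x$c_total, ":", x$dbe_total, ")")
}

#' @export
print.sum_composition <- function(x, ...) {
  cat("<species>", format(x), "\n")
  invisible(x)
}

#' Parse a species label like "PC(38:6)"
#' @param s species string.
#' @return a `sum_composition`.
#' @export
parse_species <- function(s) {
  m <- regmatches(s, regexec("^([A-Z]+)\\((\\d+):(\\d+)\\)$", s))[[1]]
  if (length(m) != 4) stop("cannot parse species label: ", s)
  sum_comp(m[2], as.integer(m[3]), as.integer(m[4]))
}

## Head-group substituents attached to the phosphate, as composition deltas
## relative to phosphatidic acid. Closed forms below were derived from
## additive assembly (glycerol + phosphate + head alcohol + 2 acyls, one
## H2O condensed per ester/phosphoester bond) and are cross-checked against
## that assembly in the tests.
.SPECIES_FORMULA <- list(
  PC   = function(C, D) c(C = C + 8, H = 2 * C - 2 * D + 16, N = 1, O = 8,  P = 1),
  PE   = function(C, D) c(C = C + 5, H = 2 * C - 2 * D + 10, N = 1, O = 8,  P = 1),
  PME  = function(C, D) c(C = C + 6, H = 2 * C - 2 * D + 12, N = 1, O = 8,  P = 1),
  PDME = function(C, D) c(C = C + 7, H = 2 * C - 2 * D + 14, N = 1, O = 8,  P = 1),
  PS   = function(C, D) c(C = C + 6, H = 2 * C - 2 * D + 10, N = 1, O = 10, P = 1),
  PG   = function(C, D) c(C = C + 6, H = 2 * C - 2 * D + 11, N = 0, O = 10, P = 1),
  PI   = function(C, D) c(C = C + 9, H = 2 * C - 2 * D + 15, N = 0, O = 13, P = 1)
)

#' Neutral elemental formula of a diacyl phospholipid species
#'
#' @param sc a `sum_composition` (or species string).
#' @return the neutral `elemental_composition`.
#' @examples
#' species_formula("PC(38:6)") # C46H80NO8P
#' @export
species_formula <- function(sc) {
  if (is.character(sc)) sc <- parse_species(sc)
  counts <- .SPECIES_FORMULA[[sc$cls]](sc$c_total, sc$dbe_total)
  if (counts[["H"]] <= 0) {
    stop("infeasible composition: ", format(sc), " has no hydrogens")
  }
  comp(counts[counts > 0])
}

#' Neutral monoisotopic mass of a species
#' @inheritParams species_formula
#' @return mass in Da.
#' @export
species_neutral_mass <- function(sc) composition_mass(species_formula(sc), 0L)

#' Adduct definitions
#'
#' Composition deltas applied to the neutral formula, with the ion charge.
#' PC forms the formate adduct in negative mode; PI and PG ionize as
#' ammonium adducts in positive mode (ammonium-acetate buffer), all other
#' classes as protonated/deprotonated species.
#' @export
ADDUCTS <- list(
  "[M+H]+"    = list(delta = c(H = 1), sign = +1, charge = +1L),
  "[M+NH4]+"  = list(delta = c(N = 1, H = 4), sign = +1, charge = +1L),
  "[M-H]-"    = list(delta = c(H = 1), sign = -1, charge = -1L),
  "[M+HCOO]-" = list(delta = c(C = 1, H = 1, O = 2), sign = +1, charge = -1L)
)

#' Default adduct for a class and polarity
#' @param cls head-group class.
#' @param mode `"positive"` or `"negative"`.
#' @return adduct name (a key of [ADDUCTS]).
#' @export
default_adduct <- function(cls, mode = c("positive", "negative")) {
  mode <- match.arg(mode)
  cls <- match.arg(cls, PL_CLASSES)
  if (mode == "positive") {
    if (cls %in% c("PI", "PG")) "[M+NH4]+" else "[M+H]+"
  } else {
    if (cls == "PC") "[M+HCOO]-" else "[M-H]-"
  }
}

#' Apply an adduct to a neutral composition
#' @param neutral an elemental composition.
#' @param adduct adduct name.
#' @return list with `composition` (of the ion) and `charge`.
#' @export
apply_adduct <- function(neutral, adduct) {
  a <- ADDUCTS[[adduct]]
  if (is.null(a)) stop("unknown adduct: ", adduct)
  ion <- if (a$sign > 0) comp_add(neutral, comp(a$delta)) else
    comp_sub(neutral, comp(a$delta))
  list(composition = ion, charge = a$charge)
}

#' Theoretical precursor m/z of a species in one polarity
#'
#' @param sc a `sum_composition` or species string.
#' @param mode `"positive"` or `"negative"`.
#' @param adduct optional adduct override; default per [default_adduct()].
#' @return list with `mz` and `adduct`.
#' @examples
#' precursor_mz("PC(38:6)", "positive") # [M+H]+ 806.5694
#' precursor_mz("PC(38:6)", "negative") # [M+HCOO]- 850.5604
#' @export
precursor_mz <- function(sc, mode = c("positive", "negative"),
                         adduct = NULL) {
  mode <- match.arg(mode)
  if (is.character(sc)) sc <- parse_species(sc)
  if (is.null(adduct)) adduct <- default_adduct(sc$cls, mode)
  ion <- apply_adduct(species_formula(sc), adduct)
  list(mz = composition_mass(ion$composition, ion$charge), adduct = adduct)
}

## The head-group diagnostic rules. Fragment ions are charged; neutral
## losses are uncharged mass differences from the class's default adduct.
## Every mass is computed from its composition at call time.
.RULE_DEFS <- list(
  list(cls = "PC",   mode = "positive", kind = "fragment_ion",
       formula = "C5H15NO4P"),  # phosphocholine cation
  list(cls = "PC",   mode = "negative", kind = "neutral_loss",
       formula = "C2H4O2"),     # methyl formate off [M+HCOO]- -> [M-CH3]-
  list(cls = "PE",   mode = "positive", kind = "neutral_loss",
       formula = "C2H8NO4P"),
  list(cls = "PME",  mode = "positive", kind = "neutral_loss",
       formula = "C3H10NO4P"),
  list(cls = "PDME", mode = "positive", kind = "neutral_loss",
       formula = "C4H12NO4P"),
  list(cls = "PI",   mode = "positive", kind = "neutral_loss",
       formula = "C6H16NO9P"),  # inositol phosphate + NH3 off [M+NH4]+
  list(cls = "PI",   mode = "negative", kind = "fragment_ion",
       formula = "C6H12O9P"),
  list(cls = "PG",   mode = "positive", kind = "neutral_loss",
       formula = "C3H12NO6P"),  # glycerophosphate + NH3 off [M+NH4]+
  list(cls = "PS",   mode = "positive", kind = "neutral_loss",
       formula = "C3H8NO6P"),
  list(cls = "PS",   mode = "negative", kind = "neutral_loss",
       formula = "C3H5NO2")     # dehydroalanine (serine - H2O)
)

#' Characteristic head-group fragment-ion and neutral-loss rule table
#'
#' The diagnostic MS2 signals for each class and polarity: PC gives the
#' phosphocholine fragment ion at m/z 184.0733 in ESI+ and loses methyl
#' formate (60.0211 Da) from its formate adduct in ESI-; the other classes
#' lose their head group as a neutral in ESI+ (for PI and PG including the
#' NH3 of the ammonium adduct); PI additionally yields the inositol
#' cyclic-phosphate anion and PS loses dehydroalanine in ESI-. Masses are
#' computed from elemental compositions, never stored as decimals.
#'
#' @return data.frame with columns `cls`, `mode`, `rule_kind`, `formula`,
#'   `mass` (m/z for fragment ions, neutral Da for losses).
#' @export
build_rule_table <- function() {
  rows <- lapply(.RULE_DEFS, function(r) {
    charge <- if (r$kind == "fragment_ion") {
      if (r$mode == "positive") 1L else -1L
    } else 0L
    data.frame(cls = r$cls, mode = r$mode, rule_kind = r$kind,
               formula = format(comp(r$formula)),
               mass = composition_mass(r$formula, charge),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Carboxylate anion m/z of a fatty acyl chain
#'
#' The acyl fragment observed in negative-mode MS2 (`CnH(2n-2d-1)O2-`),
#' used to resolve the chain composition of a species.
#'
#' @param fa a `fatty_acyl`, or carbons when `n_dbe` given.
#' @param n_dbe DBE when `fa` is a plain carbon count.
#' @return m/z of the anion.
#' @examples
#' acyl_anion_mz(fatty_acyl(16, 0)) # 255.2330
#' acyl_anion_mz(22, 6)             # 327.2330 (DHA)
#' @export
acyl_anion_mz <- function(fa, n_dbe = NULL) {
  if (!inherits(fa, "fatty_acyl")) fa <- fatty_acyl(fa, n_dbe)
  h <- 2 * fa$n_carbon - 2 * fa$n_dbe - 1
  if (h <= 0) stop("infeasible acyl anion for ", format(fa))
  composition_mass(comp(c(C = fa$n_carbon, H = h, O = 2)), -1L)
}

#' Neutral free-fatty-acid composition of an acyl chain
#' @param fa a `fatty_acyl`.
#' @return `elemental_composition` of CnH(2n-2d)O2.
#' @export
acyl_ffa_formula <- function(fa) {
  comp(c(C = fa$n_carbon, H = 2 * fa$n_carbon - 2 * fa$n_dbe, O = 2))
}

#' The deuterated internal standard d70-PC(36:0)
#'
#' 1,2-distearoyl-d70-glycerophosphocholine: PC(36:0) with all 70 chain
#' hydrogens replaced by deuterium. Spiked before extraction; all
#' quantification is by area ratio to its ESI+ peak.
#'
#' @return list with `formula`, neutral `mass` and positive-mode `mz`.
#' @export
internal_standard <- function() {
  base <- species_formula(sum_comp("PC", 36L, 0L))
  counts <- as.numeric(base); names(counts) <- names(base)
  counts[["H"]] <- counts[["H"]] - 70
  counts <- c(counts, D = 70)
  f <- comp(counts)
  ion <- apply_adduct(f, "[M+H]+")
  list(formula = f,
       mass = composition_mass(f, 0L),
       mz = composition_mass(ion$composition, ion$charge))
}

#' Relative mass error in parts per million
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return signed ppm error.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}

#' Absolute m/z window for a ppm tolerance
#' @param mz reference m/z.
#' @param tol_ppm tolerance in ppm.
#' @return half-width in Da.
#' @keywords internal
ppm_window <- function(mz, tol_ppm) mz * tol_ppm * 1e-6
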