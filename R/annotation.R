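## Best matching peak in a spectrum for a target m/z within a ppm window.
## Returns list(mz, intensity) of the most intense in-window peak, or NULL.
match_peak <- function(spec, target_mz, tol_ppm) {
  if (is.null(spec) || length(spec$mz) == 0) return(NULL)
  win <- ppm_window(target_mz, tol_ppm)
  hit <- which(abs(spec$mz - target_mz) <= win)
  if (length(hit) == 0) return(NULL)
  best <- hit[which.max(spec$intensity[hit])]
  list(mz = spec$mz[best], intensity = spec$intensity[best])
}

#' Candidate head-group classes from a positive-mode MS2 spectrum
#'
#' PC is diagnosed by its phosphocholine fragment ion; every other class by
#' the neutral loss of its head group, i.e. a fragment at precursor m/z
#' minus the class's neutral-loss mass. Candidates are ranked by the
#' intensity of the matched diagnostic fragment.
#'
#' @param f a positive-mode [feature()] with MS2 attached.
#' @param rules rule table from [build_rule_table()].
#' @param tol_ppm MS2 matching tolerance.
#' @return data.frame with `cls`, `matched_mz`, `intensity`, ranked by
#'   intensity (0 rows when nothing matches or MS2 is absent).
#' @export
identify_class <- function(f, rules = build_rule_table(), tol_ppm = 10) {
  empty <- data.frame(cls = character(0), matched_mz = numeric(0),
                      intensity = numeric(0), stringsAsFactors = FALSE)
  if (is.null(f$ms2)) return(empty)
  pos_rules <- rules[rules$mode == "positive", , drop = FALSE]
  rows <- lapply(seq_len(nrow(pos_rules)), function(i) {
    r <- pos_rules[i, ]
    target <- if (r$rule_kind == "fragment_ion") r$mass else f$mz - r$mass
    if (target <= 0) return(NULL)
    hit <- match_peak(f$ms2, target, tol_ppm)
    if (is.null(hit)) return(NULL)
    data.frame(cls = r$cls, matched_mz = hit$mz, intensity = hit$intensity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  out[order(-out$intensity), , drop = FALSE]
}

## Precursor m/z over the full (c_total, dbe_total) grid for one class and
## mode, computed once and cached. Each cell still goes through
## species_formula/precursor_mz, so the cache holds honest values.
.grid_cache <- new.env(parent = emptyenv())

precursor_grid <- function(cls, mode, c_range, dbe_range) {
  key <- paste(cls, mode, paste(c_range, collapse = "-"),
               paste(dbe_range, collapse = "-"), sep = "|")
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  cs <- seq.int(c_range[1], c_range[2])
  ds <- seq.int(dbe_range[1], dbe_range[2])
  grid <- expand.grid(c_total = cs, dbe_total = ds)
  grid$mz <- vapply(seq_len(nrow(grid)), function(i) {
    sc <- sum_comp(cls, grid$c_total[i], grid$dbe_total[i])
    tryCatch(precursor_mz(sc, mode)$mz, error = function(e) NA_real_)
  }, numeric(1))
  grid <- grid[!is.na(grid$mz), , drop = FALSE]
  .grid_cache[[key]] <- grid
  grid
}

#' Infer sum compositions consistent with an accurate precursor mass
#'
#' Exhaustive scan of the (total carbons, total DBE) grid for the class;
#' every composition whose theoretical adduct m/z falls within the ppm
#' tolerance is returned, nearest mass first. At sane tolerances (a few
#' ppm) the hit is unique over the grid; a multi-hit result signals an
#' over-wide tolerance and triggers a warning.
#'
#' @param mz observed precursor m/z.
#' @param cls head-group class.
#' @param mode polarity the m/z was observed in.
#' @param tol_ppm MS1 tolerance.
#' @param config an [ipl_config()] supplying the grid bounds.
#' @return data.frame `c_total`, `dbe_total`, `mz_theoretical`, `ppm`.
#' @export
infer_sum_composition <- function(mz, cls, mode = "positive", tol_ppm = 5,
                                  config = ipl_config()) {
  grid <- precursor_grid(cls, mode, config$c_total_range,
                         config$dbe_total_range)
  ppm <- ppm_error(mz, grid$mz)
  hit <- which(abs(ppm) <= tol_ppm)
  out <- data.frame(c_total = grid$c_total[hit],
                    dbe_total = grid$dbe_total[hit],
                    mz_theoretical = grid$mz[hit], ppm = ppm[hit])
  out <- out[order(abs(out$ppm)), , drop = FALSE]
  if (nrow(out) > 1) {
    warning("multiple sum compositions within ", tol_ppm,
            " ppm of m/z ", format(mz), " for class ", cls,
            "; tolerance may be too wide")
  }
  out
}

#' Enumerate acyl pairs explaining a sum composition
#'
#' All unordered chain pairs {a, b} from the search space whose carbon and
#' DBE totals match the sum composition and whose carboxylate anions are
#' both present in the negative-mode MS2 spectrum. The more intense acyl
#' fragment is assigned the sn-2 position. Candidates are ordered by the
#' sn-2 fragment intensity (descending), then lexicographically, so the
#' result is deterministic.
#'
#' @param sc a `sum_composition` or species string.
#' @param neg_ms2 an [ms2_spectrum()] from ESI-.
#' @param tol_ppm MS2 tolerance.
#' @param config an [ipl_config()] supplying the acyl search space.
#' @return data.frame with one row per pair: `c_a`, `dbe_a`, `c_b`,
#'   `dbe_b`, `intensity_a`, `intensity_b`, `sn2` ("a" or "b"), `label`
#'   (sn-2 acyl listed first).
#' @export
enumerate_acyl_pairs <- function(sc, neg_ms2, tol_ppm = 10,
                                 config = ipl_config()) {
  if (is.character(sc)) sc <- parse_species(sc)
  crng <- config$fa_carbon_range; drng <- config$fa_dbe_range
  rows <- list()
  for (ca in seq.int(crng[1], crng[2])) {
    cb <- sc$c_total - ca
    if (cb < ca || cb > crng[2]) next   # unordered: a is the lighter chain
    for (da in seq.int(drng[1], min(drng[2], sc$dbe_total))) {
      db <- sc$dbe_total - da
      if (db < drng[1] || db > drng[2]) next
      if (ca == cb && db < da) next     # avoid double-counting swapped DBEs
      fa_a <- tryCatch(fatty_acyl(ca, da, config$fa_check_feasible),
                       error = function(e) NULL)
      fa_b <- tryCatch(fatty_acyl(cb, db, config$fa_check_feasible),
                       error = function(e) NULL)
      if (is.null(fa_a) || is.null(fa_b)) next
      hit_a <- match_peak(neg_ms2, acyl_anion_mz(fa_a), tol_ppm)
      hit_b <- match_peak(neg_ms2, acyl_anion_mz(fa_b), tol_ppm)
      if (is.null(hit_a) || is.null(hit_b)) next
      sn2 <- if (hit_a$intensity > hit_b$intensity) "a" else "b"
      first <- if (sn2 == "a") fa_a else fa_b
      second <- if (sn2 == "a") fa_b else fa_a
      rows[[length(rows) + 1L]] <- data.frame(
        c_a = ca, dbe_a = da, c_b = cb, dbe_b = db,
        intensity_a = hit_a$intensity, intensity_b = hit_b$intensity,
        sn2 = sn2, label = paste0(format(first), "/", format(second)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    c_a = integer(0), dbe_a = integer(0), c_b = integer(0),
    dbe_b = integer(0), intensity_a = numeric(0), intensity_b = numeric(0),
    sn2 = character(0), label = character(0), stringsAsFactors = FALSE))))
  sn2_int <- ifelse(out$sn2 == "a", out$intensity_a, out$intensity_b)
  out[order(-sn2_int, out$label), , drop = FALSE]
}

.NEG_RULES <- function(rules) rules[rules$mode == "negative", , drop = FALSE]

#' Confirm a cross-polarity feature pair as an annotated species
#'
#' The full identification gate: a positive-mode class-diagnostic MS2
#' signal, a sum composition inferred from the accurate positive-mode
#' precursor mass, the corresponding negative-mode adduct observed within
#' tolerance, the class's negative-mode diagnostic (methyl-formate loss
#' for PC, the inositol-phosphate anion for PI, the dehydroalanine loss
#' for PS; the other classes have none) and at least one acyl pair whose
#' carboxylate anions are both present in ESI- MS2. Any failed stage
#' rejects the pair with a machine-readable reason.
#'
#' @param pr one pair from [pair_features()] (`list(pos, neg, ...)`).
#' @param rules rule table.
#' @param config an [ipl_config()].
#' @param require_pairs reject species with no matching acyl pair (the
#'   default); when `FALSE` such species pass flagged `sum_comp_only` and
#'   are excluded from fatty-acid-level statistics downstream.
#' @return list with `ok`; on success `annotation` (one-row data.frame)
#'   and `pairs` (pair table); on rejection `reason`.
#' @export
confirm_species <- function(pr, rules = build_rule_table(),
                            config = ipl_config(), require_pairs = TRUE) {
  pos <- pr$pos; neg <- pr$neg
  cand <- identify_class(pos, rules, config$ms2_tol_ppm)
  if (nrow(cand) == 0) {
    return(list(ok = FALSE, reason = "no class-diagnostic MS2 fragment in ESI+"))
  }
  neg_rules <- .NEG_RULES(rules)
  ## candidates are tried in rank order; on overall failure the rejection
  ## reason reflects the deepest stage any candidate reached
  stage_reached <- 0L
  stage_reason <- "no sum composition within tolerance"
  fail <- function(stage, reason) {
    if (stage > stage_reached) {
      stage_reached <<- stage; stage_reason <<- reason
    }
  }
  for (k in seq_len(nrow(cand))) {
    cls <- cand$cls[k]
    scs <- infer_sum_composition(pos$mz, cls, "positive",
                                 config$ms1_tol_ppm, config)
    if (nrow(scs) == 0) next
    for (s in seq_len(nrow(scs))) {
      sc <- sum_comp(cls, scs$c_total[s], scs$dbe_total[s])
      theo_neg <- precursor_mz(sc, "negative")
      ppm_neg <- ppm_error(neg$mz, theo_neg$mz)
      if (abs(ppm_neg) > config$ms1_tol_ppm) {
        fail(1L, "not present in both polarities"); next
      }
      nr <- neg_rules[neg_rules$cls == cls, , drop = FALSE]
      if (nrow(nr) > 0) {
        if (is.null(neg$ms2)) {
          fail(2L, "no ESI- MS2 for class confirmation"); next
        }
        ok_rule <- all(vapply(seq_len(nrow(nr)), function(i) {
          target <- if (nr$rule_kind[i] == "fragment_ion") nr$mass[i]
                    else neg$mz - nr$mass[i]
          !is.null(match_peak(neg$ms2, target, config$ms2_tol_ppm))
        }, logical(1)))
        if (!ok_rule) {
          fail(2L, "negative-mode class rule not confirmed"); next
        }
      }
      pairs <- enumerate_acyl_pairs(sc, neg$ms2, config$ms2_tol_ppm, config)
      if (nrow(pairs) == 0 && require_pairs) {
        fail(3L, "no matching fatty acid signals"); next
      }
      ann <- data.frame(
        species = format(sc), cls = cls, c_total = sc$c_total,
        dbe_total = sc$dbe_total, rt = pos$rt, area_pos = pos$area,
        n_pairs = nrow(pairs), sum_comp_only = nrow(pairs) == 0,
        pair_labels = paste(pairs$label, collapse = ";"),
        ppm_ms1_pos = scs$ppm[s], ppm_ms1_neg = ppm_neg,
        pos_id = pos$feature_id, neg_id = neg$feature_id,
        stringsAsFactors = FALSE)
      if (nrow(pairs) > 0) pairs$species <- format(sc)
      return(list(ok = TRUE, annotation = ann, pairs = pairs))
    }
  }
  list(ok = FALSE, reason = stage_reason)
}

#' Annotate every confirmed species in one dual-polarity sample
#'
#' Pairs the two polarities by retention time and implied neutral mass,
#' runs the confirmation gate on every pair, and combines isomeric entries
#' (same species label at the same retention time, which co-elute and were
#' integrated as one peak) into single rows carrying all acyl pairs.
#'
#' @param sample an [ipl_sample()].
#' @param config an [ipl_config()].
#' @param rules rule table.
#' @param require_pairs see [confirm_species()].
#' @return data.frame of annotations (one row per species), with
#'   attributes `pairs` (long pair table with a `species` column),
#'   `rejections` (pair-level reasons) and `unpaired` (feature ids that
#'   found no cross-polarity partner).
#' @export
annotate_run <- function(sample, config = ipl_config(),
                         rules = build_rule_table(), require_pairs = TRUE) {
  paired <- pair_features(sample$features_pos, sample$features_neg,
                          config$rt_tol_min, config$ms1_tol_ppm)
  anns <- list(); pair_tabs <- list(); rej <- list()
  for (pr in paired$pairs) {
    res <- confirm_species(pr, rules, config, require_pairs)
    if (res$ok) {
      anns[[length(anns) + 1L]] <- res$annotation
      if (nrow(res$pairs) > 0) pair_tabs[[length(pair_tabs) + 1L]] <- res$pairs
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        pos_id = pr$pos$feature_id, neg_id = pr$neg$feature_id,
        reason = res$reason, stringsAsFactors = FALSE)
    }
  }
  empty_ann <- data.frame(
    species = character(0), cls = character(0), c_total = integer(0),
    dbe_total = integer(0), rt = numeric(0), area_pos = numeric(0),
    n_pairs = integer(0), sum_comp_only = logical(0),
    pair_labels = character(0), ppm_ms1_pos = numeric(0),
    ppm_ms1_neg = numeric(0), pos_id = character(0), neg_id = character(0),
    stringsAsFactors = FALSE)
  out <- do.call(rbind, c(anns, list(empty_ann)))
  ## combine isomeric duplicates: same species within the RT pairing window
  if (nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      dup <- which(keep & out$species == out$species[i] &
                     abs(out$rt - out$rt[i]) <= config$rt_tol_min)
      dup <- setdiff(dup, i)
      if (length(dup) > 0) {
        out$area_pos[i] <- out$area_pos[i] + sum(out$area_pos[dup])
        labels <- unique(unlist(strsplit(
          paste(c(out$pair_labels[i], out$pair_labels[dup]), collapse = ";"),
          ";", fixed = TRUE)))
        labels <- labels[nzchar(labels)]
        out$pair_labels[i] <- paste(labels, collapse = ";")
        out$n_pairs[i] <- length(labels)
        keep[dup] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$cls, out$c_total, out$dbe_total), , drop = FALSE]
  rownames(out) <- NULL
  pairs_all <- do.call(rbind, pair_tabs)
  if (!is.null(pairs_all)) {
    pairs_all <- unique(pairs_all)
    rownames(pairs_all) <- NULL
  }
  attr(out, "pairs") <- pairs_all
  attr(out, "rejections") <- do.call(rbind, c(rej, list(data.frame(
    pos_id = character(0), neg_id = character(0), reason = character(0),
    stringsAsFactors = FALSE))))
  attr(out, "unpaired") <- list(pos = paired$unpaired_pos,
                                neg = paired$unpaired_neg)
  out
}
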