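## Class-level retention-time means (min) within the 3.5-9 min window the
## HILIC separation of these classes occupies.
.CLASS_RT <- c(PC = 5.0, PE = 6.0, PME = 6.3, PDME = 6.6,
               PI = 7.3, PG = 7.9, PS = 8.5)

#' Default krill-like fatty-acyl pool
#'
#' Chains and sampling weights emulating the acyl repertoire of a krill
#' digestive-organ lipidome: 16:0, 18:1, 20:5 (EPA) and 22:6 (DHA)
#' dominate, with a tail of very long chain polyunsaturated acyls (26:6,
#' 28:8, 36:8).
#' @return data.frame `c`, `dbe`, `weight`.
#' @export
default_fa_pool <- function() {
  data.frame(
    c   = c(12, 14, 16, 16, 17, 18, 18, 18, 18, 18, 20, 20, 20, 22, 22, 22,
            24, 26, 28, 36),
    dbe = c( 0,  0,  0,  1,  0,  0,  1,  2,  3,  4,  1,  4,  5,  1,  5,  6,
             1,  6,  8,  8),
    weight = c(0.5, 1, 3, 1.5, 0.3, 1, 3, 1, 1, 1, 0.5, 1, 4, 0.5, 1, 3,
               0.3, 0.4, 0.4, 0.3)
  )
}

#' Default simulated study design and noise model
#'
#' The emulated design follows the field study: three sampling months
#' (Jan, Mar = Antarctic summer; May = autumn), the three digestive organs
#' plus organ-free tissue, eight replicates per month and organ (three for
#' tissue), and a doubling of high-molecular-weight/high-unsaturation
#' species in summer digestive-gland samples. Noise defaults: 2 ppm mass
#' error, 0.02 min RT jitter, 10% area CV, no decoys.
#'
#' @param ... overrides.
#' @return named list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_species = 60L,
    class_weights = c(PC = 59, PE = 27, PDME = 13, PI = 11, PME = 7,
                      PG = 6, PS = 4),            # observed class diversity
    fa_pool = default_fa_pool(),
    conc_meanlog = log(0.05), conc_sdlog = 1,     # baseline conc, ug/mL
    effect_factor = 2,                            # summer DG HMW/HDU boost
    months = c("Jan", "Mar", "May"),
    organs = c("stomach", "digestive_gland", "hind_gut"),
    replicates = 8L,
    tissue_replicates = 3L,
    n_blanks = 3L,
    is_area = 1e6,                                # internal-standard area
    response_slope = 0.25,                        # area ratio per ug/mL
    ppm_sd = 2, rt_sd = 0.02, area_cv = 0.1,
    decoy_n = 0L,
    sn2_boost = 2                                 # sn-2 acyl anion intensity x
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0) stop("unknown sim config key: ",
                            paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Generate a random krill-like lipidome
#'
#' Species are drawn as a head-group class (PC-dominated, in proportion to
#' the class diversity observed in krill digestive organs) plus an acyl
#' pair from the pool; duplicates collapse, so slightly fewer species than
#' requested can result. Baseline concentrations are log-normal. Species
#' in the top tertile of both total carbons and total DBE are flagged
#' `hmw_hdu`; their concentration is multiplied by `effect_factor` in
#' summer digestive-gland renders.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (full determinism).
#' @return data.frame, one row per species, with attribute `config`.
#' @export
generate_lipidome <- function(config = sim_config(), seed = 1L) {
  set.seed(seed)
  pool <- config$fa_pool
  if (nrow(pool) == 0 || any(pool$dbe > pool$c - 2)) {
    stop("infeasible FA pool")
  }
  cw <- config$class_weights / sum(config$class_weights)
  rows <- list(); seen <- character(0)
  max_draws <- config$n_species * 30L
  for (draw in seq_len(max_draws)) {
    if (length(rows) >= config$n_species) break
    cls <- sample(names(cw), 1L, prob = cw)
    idx <- sample.int(nrow(pool), 2L, replace = TRUE, prob = pool$weight)
    a <- pool[idx[1], ]; b <- pool[idx[2], ]
    ## order the pair (lighter chain first) for a canonical key
    if (a$c > b$c || (a$c == b$c && a$dbe > b$dbe)) { tmp <- a; a <- b; b <- tmp }
    key <- paste(cls, a$c, a$dbe, b$c, b$dbe)
    if (key %in% seen) next
    seen <- c(seen, key)
    sc <- sum_comp(cls, a$c + b$c, a$dbe + b$dbe)
    ## the more unsaturated chain sits at sn-2 (ties: the heavier chain)
    sn2 <- if (a$dbe > b$dbe) "a" else "b"
    rows[[length(rows) + 1L]] <- data.frame(
      species = format(sc), cls = cls, c_total = sc$c_total,
      dbe_total = sc$dbe_total, c_a = a$c, dbe_a = a$dbe,
      c_b = b$c, dbe_b = b$dbe, sn2 = sn2,
      conc_base = stats::rlnorm(1, config$conc_meanlog, config$conc_sdlog),
      stringsAsFactors = FALSE)
  }
  lip <- do.call(rbind, rows)
  hi_c <- stats::quantile(lip$c_total, 2 / 3, type = 7)
  hi_d <- stats::quantile(lip$dbe_total, 2 / 3, type = 7)
  lip$hmw_hdu <- lip$c_total >= hi_c & lip$dbe_total >= hi_d
  rownames(lip) <- NULL
  attr(lip, "config") <- config
  lip
}

#' True concentration of each lipidome species under a condition
#' @param lipidome from [generate_lipidome()].
#' @param organ,month condition.
#' @return numeric vector (ug/mL) aligned with the lipidome rows.
#' @export
condition_concentration <- function(lipidome, organ, month) {
  cfg <- attr(lipidome, "config")
  boost <- ifelse(lipidome$hmw_hdu & organ == "digestive_gland" &
                    month %in% c("Jan", "Mar"),
                  cfg$effect_factor, 1)
  lipidome$conc_base * boost
}

## Theoretical precursor m/z of every lipidome species in one polarity,
## used to keep decoys away from real signals.
.theoretical_mzs <- function(lipidome) {
  sp <- unique(lipidome$species)
  c(vapply(sp, function(s) precursor_mz(s, "positive")$mz, numeric(1)),
    vapply(sp, function(s) precursor_mz(s, "negative")$mz, numeric(1)),
    internal_standard()$mz)
}

#' Render one sample of a simulated study to dual-polarity peak lists
#'
#' Isomeric species (same class and sum composition) co-elute and are
#' rendered as one combined feature per polarity, mirroring combined peak
#' integration. ESI+ carries the class-diagnostic MS2 signal (the
#' phosphocholine fragment for PC, the head-group neutral loss otherwise)
#' and the internal-standard feature; ESI- carries the precursor adduct,
#' the class's negative-mode diagnostic where one exists, and the acyl
#' carboxylate anions with the sn-2 chain rendered more intense. Mass
#' errors are Gaussian in ppm; areas have log-normal noise; optional decoy
#' features are drawn at least 3 tolerance widths away from any real
#' signal and carry no MS2.
#'
#' @param lipidome from [generate_lipidome()].
#' @param sample_id identifier.
#' @param organ,month condition (drives the planted effect).
#' @param seed integer seed.
#' @param is_blank render a process blank (internal standard and decoys
#'   only, no lipid species).
#' @return an [ipl_sample()].
#' @export
render_run <- function(lipidome, sample_id, organ, month, seed = 1L,
                       is_blank = FALSE) {
  cfg <- attr(lipidome, "config")
  set.seed(seed)
  ## Mass error = one per-run calibration bias shared by every ion in the
  ## run (both polarities acquire under the same calibration), plus small
  ## per-scan scatter. The bias is truncated normal at 2.5 sigma, reading
  ## ppm_sd as an instrument mass-accuracy specification.
  run_bias <- if (cfg$ppm_sd > 0) {
    repeat {
      b <- stats::rnorm(1, 0, cfg$ppm_sd)
      if (abs(b) <= 2.5 * cfg$ppm_sd) break
    }
    b
  } else 0
  scatter_sd <- cfg$ppm_sd / 8
  ppm_noise <- function(mz) {
    mz * (1 + (run_bias + stats::rnorm(length(mz), 0, scatter_sd)) * 1e-6)
  }
  area_noise <- function(n) stats::rlnorm(n, -0.5 * log(1 + cfg$area_cv^2),
                                          sqrt(log(1 + cfg$area_cv^2)))
  pos <- list(); neg <- list()
  if (!is_blank) {
    conc <- condition_concentration(lipidome, organ, month)
    key <- paste(lipidome$cls, lipidome$c_total, lipidome$dbe_total)
    for (k in unique(key)) {
      idx <- which(key == k)
      cls <- lipidome$cls[idx[1]]
      sc <- sum_comp(cls, lipidome$c_total[idx[1]], lipidome$dbe_total[idx[1]])
      total_conc <- sum(conc[idx])
      rt <- .CLASS_RT[[cls]] + stats::rnorm(1, 0, cfg$rt_sd)
      area <- cfg$is_area * cfg$response_slope * total_conc * area_noise(1)
      mz_pos_theo <- precursor_mz(sc, "positive")$mz
      mz_neg_theo <- precursor_mz(sc, "negative")$mz
      mz_pos <- ppm_noise(mz_pos_theo)
      mz_neg <- ppm_noise(mz_neg_theo)
      ## ESI+ MS2: class diagnostic
      rules <- build_rule_table()
      rp <- rules[rules$mode == "positive" & rules$cls == cls, ]
      frag_pos <- if (rp$rule_kind == "fragment_ion") rp$mass else
        mz_pos_theo - rp$mass
      pos_spec <- ms2_spectrum(mz_pos, ppm_noise(frag_pos), 1000)
      ## ESI- MS2: class diagnostic (when one exists) + acyl anions
      frag_mz <- numeric(0); frag_int <- numeric(0)
      rn <- rules[rules$mode == "negative" & rules$cls == cls, ]
      if (nrow(rn) > 0) {
        f <- if (rn$rule_kind == "fragment_ion") rn$mass else
          mz_neg_theo - rn$mass
        frag_mz <- c(frag_mz, ppm_noise(f))
        frag_int <- c(frag_int, 800)
      }
      iso_w <- conc[idx] / total_conc
      for (m in seq_along(idx)) {
        i <- idx[m]
        int_a <- 500 * iso_w[m] *
          (if (lipidome$sn2[i] == "a") cfg$sn2_boost else 1)
        int_b <- 500 * iso_w[m] *
          (if (lipidome$sn2[i] == "b") cfg$sn2_boost else 1)
        frag_mz <- c(frag_mz,
                     ppm_noise(acyl_anion_mz(lipidome$c_a[i], lipidome$dbe_a[i])),
                     ppm_noise(acyl_anion_mz(lipidome$c_b[i], lipidome$dbe_b[i])))
        frag_int <- c(frag_int, int_a, int_b)
      }
      neg_spec <- ms2_spectrum(mz_neg, frag_mz, frag_int)
      fid <- gsub(" ", "_", k)
      pos[[length(pos) + 1L]] <- feature(paste0(fid, "_p"), "positive",
                                         rt, mz_pos, area, pos_spec)
      neg[[length(neg) + 1L]] <- feature(paste0(fid, "_n"), "negative",
                                         rt, mz_neg, area * 0.8, neg_spec)
    }
  }
  ## internal standard, ESI+ only, fixed nominal area
  is_mz <- internal_standard()$mz
  pos[[length(pos) + 1L]] <- feature("IS_d70PC", "positive",
                                     .CLASS_RT[["PC"]] +
                                       stats::rnorm(1, 0, cfg$rt_sd),
                                     ppm_noise(is_mz), cfg$is_area)
  ## decoys: uniform m/z kept >= 3 tolerance widths from any real signal
  if (cfg$decoy_n > 0) {
    avoid <- .theoretical_mzs(lipidome)
    guard <- 3 * 5e-6   # 3x a 5 ppm tolerance, relative
    draw_decoys <- function(polarity, tag) {
      out <- list()
      while (length(out) < cfg$decoy_n) {
        m <- stats::runif(1, 400, 1000)
        if (all(abs(m - avoid) / avoid > guard)) {
          out[[length(out) + 1L]] <- feature(
            paste0(tag, length(out) + 1L), polarity,
            stats::runif(1, 3.5, 9), m, stats::runif(1, 1e3, 1e5))
        }
      }
      out
    }
    pos <- c(pos, draw_decoys("positive", "decoy_p"))
    neg <- c(neg, draw_decoys("negative", "decoy_n"))
  }
  ipl_sample(sample_id, organ, month, features_pos = pos,
             features_neg = neg, is_blank = is_blank)
}

#' Generate a calibration replicate series for one standard
#'
#' Linear true response (area ratio = slope x concentration) with
#' multiplicative log-normal noise. Outliers are planted at the given rate
#' as gross multiplicative errors (a replicate times `outlier_factor`,
#' emulating a dilution or transcription mistake) — the kind of error
#' outlier screening of quadruplicate calibrations can actually flag,
#' since the two-sided Grubbs statistic at n = 4 has an algebraic ceiling
#' of 1.5 against a 0.05-level critical value of 1.481 and therefore
#' essentially no power against mere noise-scale deviations.
#'
#' @param standard_id one of the names of [CALIBRATION_MAP].
#' @param concentrations level concentrations in ug/mL (within
#'   1e-7 .. 10).
#' @param reps replicates per level (quadruplicates by default).
#' @param slope true response slope (ratio per ug/mL).
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param outlier_rate probability a level carries one planted outlier.
#' @param outlier_factor multiplicative magnitude of a planted outlier.
#' @param seed integer seed.
#' @return list with `standard_id`, `levels` (long data.frame
#'   `concentration`, `ratio`), `truth` (slope, outlier positions).
#' @export
generate_calibration <- function(standard_id = "PC(16:0)",
                                 concentrations = 10^seq(-4, 1,
                                                         length.out = 9),
                                 reps = 4L, slope = 0.25, noise_cv = 0.05,
                                 outlier_rate = 0, outlier_factor = 5,
                                 seed = 1L) {
  stopifnot(standard_id %in% names(CALIBRATION_MAP),
            all(concentrations >= 1e-7), all(concentrations <= 10),
            length(concentrations) >= 1)
  set.seed(seed)
  rows <- list(); outliers <- list()
  for (cc in sort(concentrations)) {
    true <- slope * cc
    ratio <- if (noise_cv > 0) {
      true * stats::rlnorm(reps, -0.5 * log(1 + noise_cv^2),
                           sqrt(log(1 + noise_cv^2)))
    } else rep(true, reps)
    if (outlier_rate > 0 && stats::runif(1) < outlier_rate) {
      j <- sample.int(reps, 1L)
      ratio[j] <- ratio[j] * outlier_factor
      outliers[[length(outliers) + 1L]] <- data.frame(concentration = cc,
                                                      replicate = j)
    }
    rows[[length(rows) + 1L]] <- data.frame(concentration = cc, ratio = ratio)
  }
  list(standard_id = standard_id,
       levels = do.call(rbind, rows),
       truth = list(slope = slope,
                    outliers = do.call(rbind, outliers)))
}

#' Simulate a complete study: lipidome, samples, blanks, calibrations
#'
#' @param config a [sim_config()].
#' @param seed master integer seed; all per-sample seeds derive from it.
#' @return list of class `simulated_study` with `lipidome`, `samples`,
#'   `blanks`, `calibrations`, `config`, `seed`.
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  lipidome <- generate_lipidome(config, seed)
  design <- expand.grid(month = config$months, organ = config$organs,
                        rep = seq_len(config$replicates),
                        stringsAsFactors = FALSE)
  if (config$tissue_replicates > 0) {
    design <- rbind(design,
                    expand.grid(month = config$months, organ = "tissue",
                                rep = seq_len(config$tissue_replicates),
                                stringsAsFactors = FALSE))
  }
  set.seed(seed)
  sample_seeds <- sample.int(1e8, nrow(design) + config$n_blanks + 4L)
  samples <- lapply(seq_len(nrow(design)), function(i) {
    sid <- sprintf("S%03d_%s_%s_r%d", i, design$month[i], design$organ[i],
                   design$rep[i])
    render_run(lipidome, sid, design$organ[i], design$month[i],
               seed = sample_seeds[i])
  })
  names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  blanks <- lapply(seq_len(config$n_blanks), function(b) {
    render_run(lipidome, sprintf("BLANK%02d", b), "stomach", "Jan",
               seed = sample_seeds[nrow(design) + b], is_blank = TRUE)
  })
  names(blanks) <- vapply(blanks, `[[`, character(1), "sample_id")
  calibrations <- lapply(seq_along(names(CALIBRATION_MAP)), function(k) {
    generate_calibration(names(CALIBRATION_MAP)[k],
                         slope = sim_config()$response_slope,
                         noise_cv = 0.05,
                         seed = sample_seeds[nrow(design) +
                                               config$n_blanks + k])
  })
  names(calibrations) <- names(CALIBRATION_MAP)
  structure(list(lipidome = lipidome, samples = samples, blanks = blanks,
                 calibrations = calibrations, config = config, seed = seed),
            class = "simulated_study")
}

#' Write a simulated study to a directory of plain-text tables
#'
#' Layout: `samples.tsv` (metadata), `features/<sample>_<pol>.tsv` (+
#' `_ms2.tsv`) per polarity, `calibration/<standard>.tsv`, and truth
#' tables `truth_lipidome.tsv` / `truth_concentrations.tsv` for scoring.
#'
#' @param study a `simulated_study`.
#' @param dir output directory (created).
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "features"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "calibration"), showWarnings = FALSE)
  all_samples <- c(study$samples, study$blanks)
  meta <- do.call(rbind, lapply(all_samples, function(s) {
    data.frame(sample_id = s$sample_id, organ = s$organ, month = s$month,
               is_blank = s$is_blank, stringsAsFactors = FALSE)
  }))
  utils::write.table(meta, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in all_samples) {
    write_feature_table(s$features_pos,
                        file.path(dir, "features",
                                  paste0(s$sample_id, "_pos")))
    write_feature_table(s$features_neg,
                        file.path(dir, "features",
                                  paste0(s$sample_id, "_neg")))
  }
  for (std in names(study$calibrations)) {
    utils::write.table(study$calibrations[[std]]$levels,
                       file.path(dir, "calibration",
                                 paste0(gsub("[()：:]", "", std), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$lipidome, file.path(dir, "truth_lipidome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_conc <- do.call(rbind, lapply(study$samples, function(s) {
    data.frame(sample_id = s$sample_id, species = study$lipidome$species,
               concentration = condition_concentration(study$lipidome,
                                                       s$organ, s$month),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(truth_conc,
                     file.path(dir, "truth_concentrations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a study directory back into sample objects
#' @param dir directory written by [write_study()] (or hand-assembled in
#'   the same layout).
#' @return list with `samples`, `blanks`, `calibrations`.
#' @export
read_study <- function(dir) {
  meta_path <- file.path(dir, "samples.tsv")
  if (!file.exists(meta_path)) stop("not a study directory: ", dir)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  load_one <- function(i) {
    sid <- meta$sample_id[i]
    ipl_sample(sid, meta$organ[i], meta$month[i],
               features_pos = read_feature_table(
                 file.path(dir, "features", paste0(sid, "_pos")), "positive"),
               features_neg = read_feature_table(
                 file.path(dir, "features", paste0(sid, "_neg")), "negative"),
               is_blank = meta$is_blank[i])
  }
  all_samples <- lapply(seq_len(nrow(meta)), load_one)
  names(all_samples) <- meta$sample_id
  cal_files <- list.files(file.path(dir, "calibration"), full.names = TRUE)
  calibrations <- list()
  for (std in names(CALIBRATION_MAP)) {
    f <- cal_files[basename(cal_files) == paste0(gsub("[()：:]", "", std),
                                                 ".tsv")]
    if (length(f) == 1) {
      calibrations[[std]] <- list(
        standard_id = std,
        levels = utils::read.delim(f, stringsAsFactors = FALSE))
    }
  }
  list(samples = all_samples[!meta$is_blank],
       blanks = all_samples[meta$is_blank],
       calibrations = calibrations)
}
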