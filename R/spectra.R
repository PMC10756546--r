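#' Default pipeline configuration
#'
#' Tolerances and search bounds used throughout annotation. The instrument
#' study this emulates integrated peaks in vendor software without stating
#' matching tolerances, so these are engineering defaults typical for an
#' Orbitrap: 5 ppm MS1, 10 ppm MS2, 0.1 min retention-time pairing window.
#'
#' @param ... overrides for any config key.
#' @return named list of class `ipl_config`.
#' @export
ipl_config <- function(...) {
  cfg <- list(
    ms1_tol_ppm = 5,
    ms2_tol_ppm = 10,
    rt_tol_min = 0.1,
    # sum-composition grid
    c_total_range = c(20L, 70L),
    dbe_total_range = c(0L, 16L),
    # acyl search space, covers the observed 12:0 .. 36:8 range
    fa_carbon_range = c(12L, 40L),
    fa_dbe_range = c(0L, 10L),
    fa_check_feasible = TRUE,
    # quantification
    grubbs_alpha = 0.05,
    n_cal_levels = 5L,
    rt_window_min = c(3.5, 9)   # sanity warning only
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad) > 0) stop("unknown config key: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  for (k in c("ms1_tol_ppm", "ms2_tol_ppm", "rt_tol_min")) {
    if (cfg[[k]] <= 0) stop(k, " must be > 0")
  }
  structure(cfg, class = "ipl_config")
}

#' Construct an MS2 spectrum
#' @param precursor_mz precursor m/z.
#' @param mz,intensity fragment peak vectors (sorted by m/z on creation).
#' @return list of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(precursor_mz, mz, intensity) {
  stopifnot(length(mz) == length(intensity), all(mz > 0),
            all(intensity >= 0))
  ord <- order(mz)
  structure(list(precursor_mz = precursor_mz,
                 mz = as.numeric(mz[ord]),
                 intensity = as.numeric(intensity[ord])),
            class = "ms2_spectrum")
}

#' Construct an MS1 feature
#'
#' @param feature_id identifier, unique within a polarity.
#' @param polarity `"positive"` or `"negative"`.
#' @param rt retention time in minutes (> 0).
#' @param mz feature m/z.
#' @param area integrated peak area (>= 0).
#' @param ms2 optional [ms2_spectrum()].
#' @return list of class `feature`.
#' @export
feature <- function(feature_id, polarity, rt, mz, area, ms2 = NULL) {
  polarity <- match.arg(polarity, c("positive", "negative"))
  stopifnot(rt > 0, mz > 0, area >= 0)
  structure(list(feature_id = as.character(feature_id), polarity = polarity,
                 rt = rt, mz = mz, area = area, ms2 = ms2),
            class = "feature")
}

.ORGANS <- c("stomach", "digestive_gland", "hind_gut", "tissue")
.MONTHS <- c("Jan", "Mar", "May")

#' Season of a sampling month
#'
#' January and March are Antarctic summer; May is autumn.
#' @param month one of `"Jan"`, `"Mar"`, `"May"`.
#' @return `"summer"` or `"autumn"`.
#' @export
month_season <- function(month) {
  month <- match.arg(month, .MONTHS, several.ok = TRUE)
  ifelse(month == "May", "autumn", "summer")
}

#' Construct a sample: metadata plus dual-polarity feature lists
#'
#' @param sample_id identifier.
#' @param organ one of stomach, digestive_gland, hind_gut, tissue.
#' @param month one of Jan, Mar, May.
#' @param sex recorded but unused downstream.
#' @param features_pos,features_neg lists of [feature()].
#' @param is_blank process-blank flag.
#' @return list of class `ipl_sample`.
#' @export
ipl_sample <- function(sample_id, organ, month, sex = NA_character_,
                       features_pos = list(), features_neg = list(),
                       is_blank = FALSE) {
  organ <- match.arg(organ, .ORGANS)
  month <- match.arg(month, .MONTHS)
  structure(list(sample_id = as.character(sample_id), organ = organ,
                 month = month, season = month_season(month), sex = sex,
                 features_pos = features_pos, features_neg = features_neg,
                 is_blank = isTRUE(is_blank)),
            class = "ipl_sample")
}

#' @export
print.ipl_sample <- function(x, ...) {
  cat(sprintf("<sample %s> %s, %s (%s)%s: %d +features, %d -features\n",
              x$sample_id, x$organ, x$month, x$season,
              if (x$is_blank) " [blank]" else "",
              length(x$features_pos), length(x$features_neg)))
  invisible(x)
}

.MANDATORY_MS1_COLS <- c("feature_id", "rt_min", "mz", "area")
.MANDATORY_MS2_COLS <- c("feature_id", "fragment_mz", "intensity")

#' Write a feature list to the TSV interchange pair
#'
#' Two files: `<stem>.tsv` with one row per MS1 feature (feature_id,
#' rt_min, mz, area) and `<stem>_ms2.tsv` with long-format fragment rows
#' (feature_id, fragment_mz, intensity).
#'
#' @param features list of [feature()].
#' @param stem path stem without extension.
#' @return invisibly, the two file paths.
#' @export
write_feature_table <- function(features, stem) {
  ms1 <- data.frame(
    feature_id = vapply(features, `[[`, character(1), "feature_id"),
    rt_min = vapply(features, `[[`, numeric(1), "rt"),
    mz = vapply(features, `[[`, numeric(1), "mz"),
    area = vapply(features, `[[`, numeric(1), "area"),
    stringsAsFactors = FALSE
  )
  ms2_rows <- lapply(features, function(f) {
    if (is.null(f$ms2) || length(f$ms2$mz) == 0) return(NULL)
    data.frame(feature_id = f$feature_id, fragment_mz = f$ms2$mz,
               intensity = f$ms2$intensity, stringsAsFactors = FALSE)
  })
  ms2 <- do.call(rbind, c(ms2_rows, list(
    data.frame(feature_id = character(0), fragment_mz = numeric(0),
               intensity = numeric(0)))))
  p1 <- paste0(stem, ".tsv"); p2 <- paste0(stem, "_ms2.tsv")
  utils::write.table(format(ms1, digits = 15, trim = TRUE, scientific = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(ms2, digits = 15, trim = TRUE, scientific = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read a feature list from the TSV interchange pair
#'
#' @param stem path stem (as written by [write_feature_table()]), or a path
#'   to the MS1 `.tsv` itself.
#' @param polarity polarity to stamp on the features.
#' @return list of [feature()].
#' @examples
#' demo <- system.file("extdata", "example_pos.tsv", package = "krillipids")
#' feats <- read_feature_table(demo, "positive")
#' feats[[1]]$mz   # a PC(38:6) [M+H]+ precursor
#' @export
read_feature_table <- function(stem, polarity) {
  path <- if (file.exists(stem)) stem else paste0(stem, ".tsv")
  if (!file.exists(path)) stop("no such feature table: ", path)
  ms1 <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(feature_id = "character"))
  missing_cols <- setdiff(.MANDATORY_MS1_COLS, names(ms1))
  if (length(missing_cols) > 0) {
    stop("feature table ", path, " missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(ms1) == 0) {
    warning("empty feature table: ", path)
    return(list())
  }
  for (col in c("rt_min", "mz", "area")) {
    v <- suppressWarnings(as.numeric(ms1[[col]]))
    drop <- is.na(v)
    if (any(drop)) {
      warning("dropping ", sum(drop), " row(s) with non-numeric ", col)
      ms1 <- ms1[!drop, , drop = FALSE]
      v <- v[!drop]
    }
    ms1[[col]] <- v
  }
  ms2_path <- sub("\\.tsv$", "_ms2.tsv", path)
  ms2 <- if (file.exists(ms2_path)) {
    utils::read.delim(ms2_path, stringsAsFactors = FALSE,
                      colClasses = c(feature_id = "character"))
  } else {
    data.frame(feature_id = character(0), fragment_mz = numeric(0),
               intensity = numeric(0))
  }
  missing_cols <- setdiff(.MANDATORY_MS2_COLS, names(ms2))
  if (length(missing_cols) > 0) {
    stop("MS2 table ", ms2_path, " missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lapply(seq_len(nrow(ms1)), function(i) {
    row <- ms1[i, ]
    frag <- ms2[ms2$feature_id == row$feature_id, , drop = FALSE]
    spec <- if (nrow(frag) > 0) {
      ms2_spectrum(row$mz, as.numeric(frag$fragment_mz),
                   as.numeric(frag$intensity))
    } else NULL
    feature(row$feature_id, polarity, row$rt_min, row$mz, row$area,
            ms2 = spec)
  })
}

.IMPLIED_POS_ADDUCTS <- c("[M+H]+", "[M+NH4]+")
.IMPLIED_NEG_ADDUCTS <- c("[M-H]-", "[M+HCOO]-")

implied_neutral_mass <- function(mz, adduct) {
  a <- ADDUCTS[[adduct]]
  mz + a$charge * .ELECTRON_MASS -
    a$sign * composition_mass(comp(a$delta), 0L)
}

#' Pair positive- and negative-mode features by retention time and mass
#'
#' A confirmed species must appear in both polarities at the same retention
#' time; the two observed m/z must imply the same neutral mass under some
#' admissible adduct pair ([M+H]+ or [M+NH4]+ against [M-H]- or [M+HCOO]-).
#' Matching is greedy over candidate pairs sorted by RT difference, ties
#' broken by the smaller implied-mass ppm error; each feature is used at
#' most once.
#'
#' @param pos,neg lists of [feature()] in the respective polarity.
#' @param rt_tol RT window in minutes.
#' @param ms1_tol_ppm tolerance on the implied neutral-mass agreement.
#' @return list with `pairs` (list of `list(pos, neg, adducts, ppm)`),
#'   `unpaired_pos`, `unpaired_neg` (feature-id vectors).
#' @export
pair_features <- function(pos, neg, rt_tol = 0.1, ms1_tol_ppm = 5) {
  stopifnot(rt_tol > 0, ms1_tol_ppm > 0)
  cand <- list()
  for (i in seq_along(pos)) {
    for (j in seq_along(neg)) {
      drt <- abs(pos[[i]]$rt - neg[[j]]$rt)
      if (drt > rt_tol) next
      best <- NULL
      for (ap in .IMPLIED_POS_ADDUCTS) {
        mp <- implied_neutral_mass(pos[[i]]$mz, ap)
        for (an in .IMPLIED_NEG_ADDUCTS) {
          mn <- implied_neutral_mass(neg[[j]]$mz, an)
          ppm <- abs(ppm_error(mp, mn))
          if (ppm <= ms1_tol_ppm && (is.null(best) || ppm < best$ppm)) {
            best <- list(adducts = c(pos = ap, neg = an), ppm = ppm)
          }
        }
      }
      if (!is.null(best)) {
        cand[[length(cand) + 1L]] <- list(i = i, j = j, drt = drt,
                                          adducts = best$adducts,
                                          ppm = best$ppm)
      }
    }
  }
  if (length(cand) > 0) {
    ord <- order(vapply(cand, `[[`, numeric(1), "drt"),
                 vapply(cand, `[[`, numeric(1), "ppm"))
    cand <- cand[ord]
  }
  used_pos <- logical(length(pos)); used_neg <- logical(length(neg))
  pairs <- list()
  for (cc in cand) {
    if (used_pos[cc$i] || used_neg[cc$j]) next
    used_pos[cc$i] <- TRUE; used_neg[cc$j] <- TRUE
    pairs[[length(pairs) + 1L]] <- list(pos = pos[[cc$i]], neg = neg[[cc$j]],
                                        adducts = cc$adducts, ppm = cc$ppm)
  }
  list(pairs = pairs,
       unpaired_pos = vapply(pos[!used_pos], `[[`, character(1), "feature_id"),
       unpaired_neg = vapply(neg[!used_neg], `[[`, character(1), "feature_id"))
}
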