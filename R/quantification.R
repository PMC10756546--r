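#' Iterative two-sided Grubbs outlier elimination
#'
#' Removes at most one extreme value per pass: the test statistic is
#' G = max|x - mean| / sd, compared against the critical value
#' ((N-1)/sqrt(N)) * sqrt(t^2 / (N - 2 + t^2)) with t the upper
#' alpha/(2N) quantile of Student's t on N-2 degrees of freedom.
#' Iteration stops when G falls below the critical value or only three
#' values remain. Sets smaller than three, or with zero variance, are
#' returned untouched.
#'
#' @param values numeric replicate set.
#' @param alpha significance threshold (default 0.05).
#' @return the retained values, with attribute `removed` giving any
#'   eliminated values in removal order.
#' @export
grubbs_filter <- function(values, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  x <- as.numeric(values)
  removed <- numeric(0)
  if (length(x) < 3) {
    warning("Grubbs test needs at least 3 values; returning unchanged")
    attr(x, "removed") <- removed
    return(x)
  }
  repeat {
    n <- length(x)
    s <- stats::sd(x)
    if (n <= 3 || s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    t_crit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    g_crit <- ((n - 1) / sqrt(n)) * sqrt(t_crit^2 / (n - 2 + t_crit^2))
    if (g <= g_crit) break
    drop <- which.max(dev)
    removed <- c(removed, x[drop])
    x <- x[-drop]
  }
  attr(x, "removed") <- removed
  x
}

#' Class-to-standard calibration mapping
#'
#' Each authentic standard calibrates its own class plus, for PE(16:0),
#' the methylated ethanolamines, and for PG(16:0), the inositides.
#' @export
CALIBRATION_MAP <- list(
  "PC(16:0)" = "PC",
  "PE(16:0)" = c("PE", "PME", "PDME"),
  "PG(16:0)" = c("PG", "PI"),
  "PS(16:0)" = "PS"
)

#' Standard used to quantify a head-group class
#' @param cls head-group class.
#' @return standard id (a name of [CALIBRATION_MAP]).
#' @export
standard_for_class <- function(cls) {
  for (std in names(CALIBRATION_MAP)) {
    if (cls %in% CALIBRATION_MAP[[std]]) return(std)
  }
  stop("no calibration standard maps to class ", cls)
}

#' Build a calibration model from a replicate series
#'
#' Replicate area ratios at each level pass the Grubbs filter, then are
#' averaged; the model is the per-level (concentration, mean ratio)
#' lookup. Mean ratios are expected to increase with concentration; a
#' violation is flagged but the model is still built.
#'
#' @param series list with `standard_id` and `levels`, a data.frame with
#'   columns `concentration` (ug/mL) and `ratio` (replicate area ratios to
#'   the internal standard, several rows per concentration), as produced
#'   by [generate_calibration()] or read from a calibration TSV.
#' @param alpha Grubbs significance threshold.
#' @return list of class `calibration_model` with `standard_id`,
#'   `applies_to`, `levels` (concentration, mean_ratio, n_retained) and
#'   `monotone`.
#' @export
build_calibration <- function(series, alpha = 0.05) {
  lv <- series$levels
  stopifnot(all(c("concentration", "ratio") %in% names(lv)))
  concs <- sort(unique(lv$concentration))
  if (length(concs) < 5) stop("insufficient levels: calibration needs >= 5")
  if (any(concs < 1e-7 - 1e-12) || any(concs > 10 + 1e-9)) {
    warning("calibration level(s) outside the 0.1 pg/mL .. 10 ug/mL range")
  }
  rows <- lapply(concs, function(cc) {
    reps <- lv$ratio[lv$concentration == cc]
    kept <- if (length(reps) >= 3) grubbs_filter(reps, alpha) else reps
    data.frame(concentration = cc, mean_ratio = mean(kept),
               n_retained = length(kept))
  })
  levels_df <- do.call(rbind, rows)
  monotone <- all(diff(levels_df$mean_ratio) > 0)
  if (!monotone) {
    warning("calibration mean ratios are not strictly increasing with ",
            "concentration for ", series$standard_id)
  }
  structure(list(standard_id = series$standard_id,
                 applies_to = CALIBRATION_MAP[[series$standard_id]],
                 levels = levels_df, monotone = monotone),
            class = "calibration_model")
}

#' Select the five calibration levels used to quantify one area ratio
#'
#' Contiguous five-level windows (levels ordered by concentration) are
#' scored by total distance of their mean ratios to the sample ratio; a
#' window that brackets the ratio (at least one level on each side) is
#' preferred when one exists, and ties go to the window with lower
#' concentrations. Ratios outside the calibrated range take the extreme
#' window with an extrapolation warning.
#'
#' @param ratio sample area ratio to the internal standard.
#' @param model a `calibration_model`.
#' @param n_levels window size (default 5).
#' @return the selected rows of `model$levels`, with attribute
#'   `extrapolated`.
#' @export
select_levels <- function(ratio, model, n_levels = 5L) {
  lv <- model$levels[order(model$levels$concentration), , drop = FALSE]
  n <- nrow(lv)
  if (n < n_levels) stop("insufficient levels: model has ", n)
  starts <- seq_len(n - n_levels + 1L)
  brackets <- vapply(starts, function(s) {
    w <- lv$mean_ratio[s:(s + n_levels - 1L)]
    min(w) <= ratio && ratio <= max(w)
  }, logical(1))
  score <- vapply(starts, function(s) {
    sum(abs(lv$mean_ratio[s:(s + n_levels - 1L)] - ratio))
  }, numeric(1))
  pool <- if (any(brackets)) starts[brackets] else starts
  ## ties toward lower concentration: which.min takes the first (lowest) start
  best <- pool[which.min(score[pool])]
  out <- lv[best:(best + n_levels - 1L), , drop = FALSE]
  extrapolated <- !any(brackets)
  if (extrapolated) {
    warning("area ratio ", format(ratio), " outside calibrated range; ",
            "extrapolating from the ",
            if (ratio > max(lv$mean_ratio)) "top" else "bottom",
            " ", n_levels, " levels")
  }
  attr(out, "extrapolated") <- extrapolated
  out
}

#' Concentration of one species from its area ratio
#'
#' An ordinary least-squares line through the five selected
#' (concentration, mean ratio) points, inverted at the sample ratio.
#' Negative predictions are floored at zero and flagged.
#'
#' @param area integrated species area (positive mode).
#' @param is_area internal-standard area in the same run (> 0).
#' @param model a `calibration_model`.
#' @param n_levels calibration window size.
#' @return concentration in ug/mL with attributes `extrapolated` and
#'   `floored`.
#' @export
quantify_species <- function(area, is_area, model, n_levels = 5L) {
  if (!is.finite(is_area) || is_area <= 0) stop("internal standard missing")
  stopifnot(area >= 0)
  ratio <- area / is_area
  sel <- select_levels(ratio, model, n_levels)
  fit <- stats::lm(mean_ratio ~ concentration, data = sel)
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] == 0) stop("degenerate calibration window")
  conc <- unname((ratio - b[1]) / b[2])
  floored <- conc < 0
  if (floored) conc <- 0
  structure(conc, extrapolated = attr(sel, "extrapolated"),
            floored = floored)
}

#' Quantify an annotation table against calibration models
#'
#' @param annotations output of [annotate_run()].
#' @param is_area internal-standard area for the run.
#' @param models named list of `calibration_model`s (names are standard
#'   ids covering all classes present).
#' @param n_levels calibration window size.
#' @return data.frame `species`, `cls`, `concentration`, `extrapolated`,
#'   `floored`.
#' @export
quantify_run <- function(annotations, is_area, models, n_levels = 5L) {
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    cls <- annotations$cls[i]
    std <- standard_for_class(cls)
    if (!std %in% names(models)) {
      stop("no calibration model supplied for standard ", std)
    }
    q <- quantify_species(annotations$area_pos[i], is_area, models[[std]],
                          n_levels)
    data.frame(species = annotations$species[i], cls = cls,
               concentration = as.numeric(q),
               extrapolated = attr(q, "extrapolated"),
               floored = attr(q, "floored"), stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(data.frame(
    species = character(0), cls = character(0), concentration = numeric(0),
    extrapolated = logical(0), floored = logical(0),
    stringsAsFactors = FALSE))))
}

#' Subtract mean process-blank concentrations
#'
#' Per-species concentration minus the mean concentration of that species
#' across the blanks, floored at zero; species fully absorbed by the blank
#' are dropped.
#'
#' @param sample_table quantification table (`species`, `concentration`).
#' @param blank_tables list of quantification tables from process blanks
#'   (may be empty: the sample passes through with a warning).
#' @return corrected table with a `blank_subtracted` column.
#' @export
blank_subtract <- function(sample_table, blank_tables = list()) {
  if (length(blank_tables) == 0) {
    warning("no process blanks provided; concentrations uncorrected")
    sample_table$blank_subtracted <- 0
    return(sample_table)
  }
  all_blank <- do.call(rbind, blank_tables)
  blank_mean <- tapply(all_blank$concentration, all_blank$species, mean)
  sub <- blank_mean[sample_table$species]
  sub[is.na(sub)] <- 0
  out <- sample_table
  out$blank_subtracted <- as.numeric(sub)
  out$concentration <- pmax(out$concentration - out$blank_subtracted, 0)
  out[out$concentration > 0, , drop = FALSE]
}

#' Percentage distribution of species concentrations in one sample
#'
#' Sample weighing was not part of the workflow this emulates, so all
#' downstream statistics run on within-sample percentage distributions.
#'
#' @param corrected quantification table with positive total concentration.
#' @param sample_id,organ,month optional metadata carried along.
#' @return data.frame of class `sample_composition` with `species`, `cls`,
#'   `pct` summing to 100.
#' @export
percentage_distribution <- function(corrected, sample_id = NA_character_,
                                    organ = NA_character_,
                                    month = NA_character_) {
  tot <- sum(corrected$concentration)
  if (nrow(corrected) == 0 || tot <= 0) stop("empty composition")
  out <- data.frame(sample_id = sample_id, organ = organ, month = month,
                    species = corrected$species,
                    cls = if ("cls" %in% names(corrected)) corrected$cls
                          else vapply(corrected$species,
                                      function(s) parse_species(s)$cls,
                                      character(1)),
                    pct = 100 * corrected$concentration / tot,
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_composition", class(out))
  rownames(out) <- NULL
  out
}

#' Free-fatty-acid composition from a GC-MS table
#'
#' Concentrations are computed by area ratio to the deuterated 18:0
#' internal standard with one response factor per saturation class (the
#' calibration used 22:0 for saturated, 22:1 for monounsaturated and 20:5
#' for polyunsaturated fatty acids), then reduced to SFA/MUFA/PUFA
#' percentages of the total lipid extract.
#'
#' @param gc_table data.frame with columns `fa` ("C:D" tokens), `area`,
#'   and `is_area` (d18:0 internal-standard area, one value per row or a
#'   single recycled value).
#' @param response_factors named numeric: `SFA`, `MUFA`, `PUFA`.
#' @return one-row data.frame `SFA`, `MUFA`, `PUFA` (percent, sums to 100).
#' @export
ingest_ffa_table <- function(gc_table,
                             response_factors = c(SFA = 1, MUFA = 1,
                                                  PUFA = 1)) {
  stopifnot(all(c("fa", "area", "is_area") %in% names(gc_table)))
  stopifnot(all(c("SFA", "MUFA", "PUFA") %in% names(response_factors)))
  parsed <- regmatches(gc_table$fa,
                       regexec("^(\\d+):(\\d+)$", gc_table$fa))
  bad <- vapply(parsed, length, integer(1)) != 3
  if (any(bad)) {
    stop("unknown fatty acid token: ",
         paste(gc_table$fa[bad], collapse = ", "))
  }
  dbe <- vapply(parsed, function(p) as.integer(p[3]), integer(1))
  sat <- saturation_class(dbe)
  conc <- (gc_table$area / gc_table$is_area) / response_factors[sat]
  totals <- tapply(conc, factor(sat, levels = c("SFA", "MUFA", "PUFA")),
                   sum, default = 0)
  if (sum(totals) <= 0) stop("empty composition")
  pct <- 100 * totals / sum(totals)
  data.frame(SFA = pct[["SFA"]], MUFA = pct[["MUFA"]], PUFA = pct[["PUFA"]])
}

#' Saturation class of a DBE count
#' @param dbe double-bond equivalents (vectorized).
#' @return `"SFA"` (0), `"MUFA"` (1) or `"PUFA"` (>= 2).
#' @export
saturation_class <- function(dbe) {
  ifelse(dbe == 0, "SFA", ifelse(dbe == 1, "MUFA", "PUFA"))
}
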