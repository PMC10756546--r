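#' Locate the internal-standard feature in a positive-mode feature list
#'
#' The d70-PC(36:0) spike is found by accurate mass; when several features
#' fall in the window the most intense is taken.
#'
#' @param features list of positive-mode features.
#' @param tol_ppm mass tolerance.
#' @return the feature, or `NULL` when absent.
#' @export
find_internal_standard <- function(features, tol_ppm = 5) {
  target <- internal_standard()$mz
  hits <- Filter(function(f) abs(ppm_error(f$mz, target)) <= tol_ppm,
                 features)
  if (length(hits) == 0) return(NULL)
  hits[[which.max(vapply(hits, `[[`, numeric(1), "area"))]]
}

#' Run the full analysis pipeline over a study
#'
#' Stages: annotate every sample (and blank) from its dual-polarity
#' feature lists; build calibration models; quantify each annotated
#' species by area ratio to the internal standard; subtract process
#' blanks; reduce to percentage compositions; derive the
#' molecular-weight/unsaturation grouping and group matrix; PCA; seasonal
#' ratio tables (autumn/summer for all classes' dominant class PC, and
#' Jan/Mar); ternary SFA/MUFA/PUFA compositions and EPA/DHA indices for
#' PC and PE. Deterministic for fixed inputs; rerunning on the same study
#' writes identical tables.
#'
#' @param study a `simulated_study`, the list returned by [read_study()],
#'   or a study directory path.
#' @param config an [ipl_config()].
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV.
#' @return list with `annotations`, `pairs_by_sample`, `rejections`,
#'   `quantifications`, `compositions`, `comp_df`, `scheme`,
#'   `group_matrix`, `pca`, `ratios_autumn_summer`, `ratios_jan_mar`,
#'   `ternary`, `indices_pc`, `indices_pe`, `n_species`.
#' @export
run_pipeline <- function(study, config = ipl_config(), out_dir = NULL) {
  if (is.character(study)) study <- read_study(study)
  samples <- study$samples
  blanks <- if (!is.null(study$blanks)) study$blanks else list()
  if (length(samples) == 0) stop("study contains no samples")
  rules <- build_rule_table()

  annotations <- lapply(samples, annotate_run, config = config,
                        rules = rules)
  blank_ann <- lapply(blanks, annotate_run, config = config, rules = rules)
  pairs_by_sample <- lapply(annotations, attr, "pairs")
  rejections <- do.call(rbind, lapply(names(annotations), function(sid) {
    r <- attr(annotations[[sid]], "rejections")
    if (nrow(r) > 0) cbind(sample_id = sid, r) else NULL
  }))

  models <- lapply(study$calibrations, build_calibration,
                   alpha = config$grubbs_alpha)
  quantify_one <- function(sample, ann) {
    isf <- find_internal_standard(sample$features_pos, config$ms1_tol_ppm)
    if (is.null(isf)) stop("internal standard missing in ",
                           sample$sample_id)
    quantify_run(ann, isf$area, models, config$n_cal_levels)
  }
  blank_tables <- mapply(function(s, a) quantify_one(s, a),
                         blanks, blank_ann, SIMPLIFY = FALSE)
  quantifications <- list(); compositions <- list()
  for (sid in names(samples)) {
    q <- quantify_one(samples[[sid]], annotations[[sid]])
    q <- if (length(blank_tables) > 0) blank_subtract(q, blank_tables)
         else q
    quantifications[[sid]] <- q
    if (nrow(q) > 0 && sum(q$concentration) > 0) {
      compositions[[sid]] <- percentage_distribution(
        q, sid, samples[[sid]]$organ, samples[[sid]]$month)
    }
  }
  comp_df <- bind_compositions(compositions)

  scheme <- derive_grouping(comp_df)
  gm <- group_matrix(comp_df, scheme)
  pca <- if (nrow(gm) >= 3) pca_scores(gm) else NULL
  has_both_seasons <- length(unique(month_season(unique(comp_df$month)))) == 2
  ratios_as <- if (has_both_seasons) {
    seasonal_ratios(comp_df, "May", c("Jan", "Mar"), cls = "PC")
  } else NULL
  months_present <- unique(comp_df$month)
  ratios_jm <- if (all(c("Jan", "Mar") %in% months_present)) {
    seasonal_ratios(comp_df, "Jan", "Mar", cls = "PC")
  } else NULL
  ternary <- fa_saturation_ternary(comp_df, pairs_by_sample,
                                   classes = c("PC", "PE"))
  indices_pc <- pufa_indices(comp_df, pairs_by_sample, "PC")
  indices_pe <- tryCatch(pufa_indices(comp_df, pairs_by_sample, "PE"),
                         error = function(e) NULL)

  res <- list(annotations = annotations, pairs_by_sample = pairs_by_sample,
              rejections = rejections, quantifications = quantifications,
              compositions = compositions, comp_df = comp_df,
              scheme = scheme, group_matrix = gm, pca = pca,
              ratios_autumn_summer = ratios_as, ratios_jan_mar = ratios_jm,
              ternary = ternary, indices_pc = indices_pc,
              indices_pe = indices_pe,
              n_species = length(unique(comp_df$species)))
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write pipeline result tables as TSV
#' @param res result list from [run_pipeline()].
#' @param out_dir output directory (created).
#' @return invisibly, `out_dir`.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df) || nrow(as.data.frame(df)) == 0) return(invisible())
    utils::write.table(format(as.data.frame(df), digits = 12, trim = TRUE),
                       file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ann_all <- do.call(rbind, lapply(names(res$annotations), function(sid) {
    a <- res$annotations[[sid]]
    if (nrow(a) > 0) cbind(sample_id = sid, a) else NULL
  }))
  wt(ann_all, "annotations.tsv")
  pairs_all <- do.call(rbind, lapply(names(res$pairs_by_sample),
                                     function(sid) {
    p <- res$pairs_by_sample[[sid]]
    if (!is.null(p) && nrow(p) > 0) cbind(sample_id = sid, p) else NULL
  }))
  wt(pairs_all, "pairs.tsv")
  wt(res$rejections, "rejections.tsv")
  quant_all <- do.call(rbind, lapply(names(res$quantifications),
                                     function(sid) {
    q <- res$quantifications[[sid]]
    if (nrow(q) > 0) cbind(sample_id = sid, q) else NULL
  }))
  wt(quant_all, "quantifications.tsv")
  wt(res$comp_df, "compositions.tsv")
  gm <- as.data.frame(res$group_matrix)
  gm <- cbind(sample_id = rownames(res$group_matrix), gm)
  wt(gm, "group_matrix.tsv")
  if (!is.null(res$pca)) {
    sc <- as.data.frame(res$pca$scores)
    wt(cbind(sample_id = rownames(sc), sc), "pca_scores.tsv")
    ld <- as.data.frame(res$pca$loadings)
    wt(cbind(group = rownames(ld), ld), "pca_loadings.tsv")
  }
  wt(res$ratios_autumn_summer, "ratios_autumn_summer.tsv")
  wt(res$ratios_jan_mar, "ratios_jan_mar.tsv")
  wt(res$ternary, "ternary.tsv")
  wt(res$indices_pc, "indices_pc.tsv")
  wt(res$indices_pe, "indices_pe.tsv")
  invisible(out_dir)
}
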