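#' Bind per-sample compositions into one long study table
#' @param compositions list of [percentage_distribution()] outputs.
#' @return data.frame `sample_id`, `organ`, `month`, `species`, `cls`, `pct`.
#' @export
bind_compositions <- function(compositions) {
  out <- do.call(rbind, lapply(compositions, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Derive a molecular-weight / unsaturation grouping scheme
#'
#' Species are binned, separately within each head-group class, into
#' low/medium/high molecular weight (LMW/MMW/HMW, by neutral monoisotopic
#' mass) and low/medium/high degree of unsaturation (LDU/MDU/HDU, by total
#' DBE). Default breakpoints are the tertiles of the distinct species
#' values within the class; explicit breakpoints can be injected per
#' class. Classes with fewer than three distinct values collapse to a
#' single bin with a warning.
#'
#' @param comp_df long composition table from [bind_compositions()].
#' @param probs quantile probabilities for the breakpoints.
#' @param overrides named list (by class) of lists with `mw_breaks` and/or
#'   `du_breaks` (each two increasing numbers) replacing the tertiles.
#' @return named list (by class) of `mw_breaks` / `du_breaks`, class
#'   `grouping_scheme`.
#' @export
derive_grouping <- function(comp_df, probs = c(1, 2) / 3, overrides = NULL) {
  species <- unique(comp_df$species)
  cls <- vapply(species, function(s) parse_species(s)$cls, character(1))
  scheme <- list()
  for (cl in unique(cls)) {
    sp <- species[cls == cl]
    mass <- vapply(sp, species_neutral_mass, numeric(1))
    dbe <- vapply(sp, function(s) parse_species(s)$dbe_total, numeric(1))
    brk <- function(v, what) {
      u <- unique(v)
      if (length(u) < 3) {
        warning("class ", cl, " has fewer than 3 distinct ", what,
                " values; single group")
        return(numeric(0))
      }
      q <- unname(stats::quantile(v, probs = probs, type = 7))
      # skewed distributions can collapse the tertiles; fall back to the
      # quantiles of the distinct values, then to a single bin
      if (any(diff(q) <= 0)) {
        q <- unname(stats::quantile(sort(u), probs = probs, type = 7))
      }
      if (any(diff(q) <= 0)) {
        warning("class ", cl, " ", what,
                " values too concentrated for tertiles; single group")
        return(numeric(0))
      }
      q
    }
    entry <- list(mw_breaks = brk(mass, "mass"), du_breaks = brk(dbe, "DBE"))
    ov <- overrides[[cl]]
    if (!is.null(ov)) {
      for (k in intersect(names(ov), c("mw_breaks", "du_breaks"))) {
        if (is.unsorted(ov[[k]], strictly = TRUE)) {
          stop("override ", k, " for ", cl, " must be strictly increasing")
        }
        entry[[k]] <- ov[[k]]
      }
    }
    scheme[[cl]] <- entry
  }
  structure(scheme, class = "grouping_scheme")
}

.bin3 <- function(v, breaks, labels) {
  if (length(breaks) == 0) return(rep(labels[2], length(v)))
  as.character(cut(v, breaks = c(-Inf, breaks, Inf), labels = labels,
                   right = TRUE))
}

#' Group label of a species under a scheme
#' @param species species strings.
#' @param scheme a `grouping_scheme`.
#' @return character like `"PC.HMW.HDU"`.
#' @export
species_group <- function(species, scheme) {
  vapply(species, function(s) {
    sc <- parse_species(s)
    entry <- scheme[[sc$cls]]
    if (is.null(entry)) stop("species ", s, " not covered by grouping scheme")
    mw <- .bin3(species_neutral_mass(sc), entry$mw_breaks,
                c("LMW", "MMW", "HMW"))
    du <- .bin3(sc$dbe_total, entry$du_breaks, c("LDU", "MDU", "HDU"))
    paste(sc$cls, mw, du, sep = ".")
  }, character(1))
}

#' Samples-by-groups percentage matrix
#'
#' Group percentage is the sum of member-species percentages, so every row
#' still sums to 100.
#'
#' @param comp_df long composition table.
#' @param scheme a `grouping_scheme` covering every species present.
#' @return numeric matrix (rownames sample ids, colnames group labels)
#'   with attribute `meta` (sample_id, organ, month in row order).
#' @export
group_matrix <- function(comp_df, scheme) {
  grp <- species_group(comp_df$species, scheme)
  tab <- tapply(comp_df$pct, list(comp_df$sample_id, grp), sum, default = 0)
  mat <- as.matrix(tab)
  meta <- unique(comp_df[, c("sample_id", "organ", "month")])
  meta <- meta[match(rownames(mat), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  attr(mat, "meta") <- meta
  mat
}

#' Principal component analysis of a composition matrix
#'
#' Column-centred singular value decomposition via [stats::prcomp()];
#' scaling to unit variance is optional and off by default because the
#' inputs are percentages on a common scale.
#'
#' @param mat samples-by-groups (or -species) matrix.
#' @param scale. scale columns to unit variance.
#' @return list with `scores`, `loadings`, `sdev`, `var_explained`.
#' @export
pca_scores <- function(mat, scale. = FALSE) {
  if (nrow(mat) < 3) stop("PCA needs at least 3 samples")
  keep <- apply(mat, 2, stats::sd) > 0
  if (!any(keep)) stop("constant matrix: no variance to decompose")
  p <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE,
                     scale. = scale.)
  list(scores = p$x, loadings = p$rotation, sdev = p$sdev,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Seasonal abundance ratios per species
#'
#' For each species of the class: mean percentage across samples of month
#' group A divided by mean percentage across group B (a species absent
#' from a sample counts as zero there). Ratios above one mean more
#' abundant in A. `mean_pct_b` carries the B-side mean for the
#' log-intensity colour scale of the ratio barplots.
#'
#' @param comp_df long composition table.
#' @param months_a,months_b month sets defining the two groups (e.g.
#'   `"May"` vs `c("Jan", "Mar")` for autumn over summer).
#' @param cls restrict to one head-group class (default PC).
#' @return data.frame `species`, `mean_pct_a`, `mean_pct_b`, `ratio`,
#'   `log10_ratio`, `one_sided`.
#' @export
seasonal_ratios <- function(comp_df, months_a, months_b, cls = "PC") {
  sub <- comp_df[comp_df$cls == cls, , drop = FALSE]
  ids_a <- unique(comp_df$sample_id[comp_df$month %in% months_a])
  ids_b <- unique(comp_df$sample_id[comp_df$month %in% months_b])
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    stop("both month groups must contain samples")
  }
  species <- sort(unique(sub$species))
  mean_in <- function(sp, ids) {
    v <- sub$pct[sub$species == sp & sub$sample_id %in% ids]
    sum(v) / length(ids)   # absent-in-sample counts as zero
  }
  ma <- vapply(species, mean_in, numeric(1), ids = ids_a)
  mb <- vapply(species, mean_in, numeric(1), ids = ids_b)
  data.frame(species = species, mean_pct_a = ma, mean_pct_b = mb,
             ratio = ifelse(ma > 0 & mb > 0, ma / mb, NA_real_),
             log10_ratio = ifelse(ma > 0 & mb > 0, log10(ma / mb), NA_real_),
             one_sided = (ma == 0) != (mb == 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

## Apportionment weights across the acyl pairs of one species: the share
## of each pair is proportional to the intensity of its more abundant
## acyl fragment in ESI- MS2.
pair_weights <- function(pairs) {
  w <- pmax(pairs$intensity_a, pairs$intensity_b)
  if (sum(w) <= 0) rep(1 / nrow(pairs), nrow(pairs)) else w / sum(w)
}

#' SFA/MUFA/PUFA ternary composition extrapolated from annotated species
#'
#' Every species splits its percentage equally over its two acyl
#' positions; species with several consistent acyl pairs split across
#' pairs in proportion to the intensity of each pair's more abundant acyl
#' fragment. Acyls are binned saturated (0 DBE), monounsaturated (1) and
#' polyunsaturated (>= 2); the triple is renormalized to sum to 100 over
#' the species that carry resolved pairs. Sum-composition-only species
#' are excluded and counted.
#'
#' @param comp_df long composition table.
#' @param pairs_by_sample named list (by sample id) of pair tables, i.e.
#'   `attr(annotate_run(...), "pairs")`.
#' @param classes head-group classes in scope (e.g. `"PC"`, `"PE"`, or
#'   several).
#' @return data.frame per sample: `sample_id`, `organ`, `month`, `SFA`,
#'   `MUFA`, `PUFA`, `n_excluded`.
#' @export
fa_saturation_ternary <- function(comp_df, pairs_by_sample,
                                  classes = c("PC", "PE")) {
  meta <- unique(comp_df[, c("sample_id", "organ", "month")])
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$sample_id[i]
    sub <- comp_df[comp_df$sample_id == sid & comp_df$cls %in% classes, ,
                   drop = FALSE]
    pairs <- pairs_by_sample[[sid]]
    acc <- c(SFA = 0, MUFA = 0, PUFA = 0)
    n_excluded <- 0L
    for (j in seq_len(nrow(sub))) {
      sp_pairs <- if (is.null(pairs)) NULL else
        pairs[pairs$species == sub$species[j], , drop = FALSE]
      if (is.null(sp_pairs) || nrow(sp_pairs) == 0) {
        n_excluded <- n_excluded + 1L
        next
      }
      w <- pair_weights(sp_pairs)
      for (p in seq_len(nrow(sp_pairs))) {
        half <- sub$pct[j] * w[p] / 2
        sa <- saturation_class(sp_pairs$dbe_a[p])
        sb <- saturation_class(sp_pairs$dbe_b[p])
        acc[sa] <- acc[sa] + half
        acc[sb] <- acc[sb] + half
      }
    }
    tot <- sum(acc)
    if (tot > 0) acc <- 100 * acc / tot
    data.frame(sample_id = sid, organ = meta$organ[i], month = meta$month[i],
               SFA = acc[["SFA"]], MUFA = acc[["MUFA"]], PUFA = acc[["PUFA"]],
               n_excluded = n_excluded, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unsaturation and EPA/DHA indices per sample for one class
#'
#' The weighted mean unsaturation per fatty acid is the abundance-weighted
#' mean of total DBE divided by the two chains; the EPA (20:5) and DHA
#' (22:6) indices are the within-class percentage of species carrying at
#' least one such acyl, with multi-pair species counted by the apportioned
#' fraction of their pairs that contain the acyl.
#'
#' @param comp_df long composition table.
#' @param pairs_by_sample named list (by sample id) of pair tables.
#' @param cls `"PC"` or `"PE"`.
#' @return data.frame per sample: `mean_unsaturation`, `epa_pct`,
#'   `dha_pct`.
#' @export
pufa_indices <- function(comp_df, pairs_by_sample, cls = c("PC", "PE")) {
  cls <- match.arg(cls)
  sub_all <- comp_df[comp_df$cls == cls, , drop = FALSE]
  if (nrow(sub_all) == 0) stop("no species of class ", cls, " present")
  meta <- unique(comp_df[, c("sample_id", "organ", "month")])
  contains_frac <- function(sp_pairs, cn, dn) {
    if (is.null(sp_pairs) || nrow(sp_pairs) == 0) return(NA_real_)
    w <- pair_weights(sp_pairs)
    has <- (sp_pairs$c_a == cn & sp_pairs$dbe_a == dn) |
      (sp_pairs$c_b == cn & sp_pairs$dbe_b == dn)
    sum(w[has])
  }
  rows <- lapply(seq_len(nrow(meta)), function(i) {
    sid <- meta$sample_id[i]
    sub <- sub_all[sub_all$sample_id == sid, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(sample_id = sid, organ = meta$organ[i],
                        month = meta$month[i],
                        mean_unsaturation = NA_real_, epa_pct = NA_real_,
                        dha_pct = NA_real_, stringsAsFactors = FALSE))
    }
    dbe <- vapply(sub$species, function(s) parse_species(s)$dbe_total,
                  numeric(1))
    mean_unsat <- sum(sub$pct * dbe / 2) / sum(sub$pct)
    pairs <- pairs_by_sample[[sid]]
    fr_epa <- fr_dha <- numeric(nrow(sub))
    has_pairs <- logical(nrow(sub))
    for (j in seq_len(nrow(sub))) {
      sp_pairs <- if (is.null(pairs)) NULL else
        pairs[pairs$species == sub$species[j], , drop = FALSE]
      fe <- contains_frac(sp_pairs, 20L, 5L)
      fd <- contains_frac(sp_pairs, 22L, 6L)
      has_pairs[j] <- !is.na(fe)
      fr_epa[j] <- if (is.na(fe)) 0 else fe
      fr_dha[j] <- if (is.na(fd)) 0 else fd
    }
    denom <- sum(sub$pct[has_pairs])
    data.frame(sample_id = sid, organ = meta$organ[i], month = meta$month[i],
               mean_unsaturation = mean_unsat,
               epa_pct = if (denom > 0)
                 100 * sum(sub$pct * fr_epa) / denom else NA_real_,
               dha_pct = if (denom > 0)
                 100 * sum(sub$pct * fr_dha) / denom else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overlap of annotated sum compositions with a reference lipidome
#'
#' Per head-group class: counts of sum formulas on each side, the
#' intersection count, and the summed within-class percentage abundance of
#' the intersecting formulas on each side. The reference (e.g. an
#' environmental lipidome survey) is user-supplied as a table of species
#' labels and abundances.
#'
#' @param comp_df long composition table (this study's side; species
#'   abundances are averaged over samples and renormalized within class).
#' @param reference data.frame with `species` and `pct` columns.
#' @param classes classes to compare (default PC and PE).
#' @return data.frame per class: `n_own`, `n_ref`, `n_overlap`,
#'   `pct_own_overlap`, `pct_ref_overlap`.
#' @export
reference_overlap <- function(comp_df, reference, classes = c("PC", "PE")) {
  if (is.null(reference) || nrow(reference) == 0) stop("empty reference")
  n_samples <- length(unique(comp_df$sample_id))
  own_mean <- tapply(comp_df$pct, comp_df$species, sum) / n_samples
  own <- data.frame(species = names(own_mean), pct = as.numeric(own_mean),
                    stringsAsFactors = FALSE)
  own$cls <- vapply(own$species, function(s) parse_species(s)$cls,
                    character(1))
  ref <- reference
  ref$cls <- vapply(ref$species, function(s) parse_species(s)$cls,
                    character(1))
  rows <- lapply(classes, function(cl) {
    o <- own[own$cls == cl, , drop = FALSE]
    r <- ref[ref$cls == cl, , drop = FALSE]
    inter <- intersect(o$species, r$species)
    share <- function(df) {
      if (nrow(df) == 0 || sum(df$pct) <= 0) return(NA_real_)
      100 * sum(df$pct[df$species %in% inter]) / sum(df$pct)
    }
    data.frame(cls = cl, n_own = nrow(o), n_ref = nrow(r),
               n_overlap = length(inter),
               pct_own_overlap = share(o), pct_ref_overlap = share(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
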