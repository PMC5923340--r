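#' Metabolite retention filters
#'
#' Applies the two panel quality-control rules. A metabolite is retained
#' iff (1) its fraction of missing values (non-detectable peaks) is below
#' `max_missing_frac` within every outcome group, with both time points
#' pooled, and (2) at least `min_above_lod_frac` of all its sample
#' concentrations are above the limit of detection. Rule 2 counts a cell
#' as above LOD when it is observed and not flagged by the below-LOD
#' mask. The rules are order-independent: each is evaluated on the raw
#' tables and every excluded feature carries all rules it violates.
#'
#' @param table_d1,table_d7 Metabolite [omics_table()] objects at D1 and
#'   D7, with below-LOD masks.
#' @param metadata A [cohort_metadata()] data frame.
#' @param max_missing_frac Missingness bound per group (default 0.20,
#'   exclusive).
#' @param min_above_lod_frac Minimum fraction of concentrations above
#'   LOD (default 0.50, inclusive). Set to 0 to disable rule 2, in which
#'   case no mask is required.
#' @return List with `retained` (character vector of feature ids) and
#'   `report` (a QC data frame; see [qc_report()]).
#' @export
filter_metabolites <- function(table_d1, table_d7, metadata,
                               max_missing_frac = 0.20,
                               min_above_lod_frac = 0.50) {
  stopifnot(inherits(table_d1, "omics_table"), inherits(table_d7, "omics_table"))
  if (!identical(feature_ids(table_d1), feature_ids(table_d7))) {
    stop("D1 and D7 tables must share the same features")
  }
  metadata <- cohort_metadata(metadata)
  if (min_above_lod_frac > 0 &&
      (is.null(table_d1$below_lod_mask) || is.null(table_d7$below_lod_mask))) {
    stop("below-LOD mask required: supply masks on both tables or disable ",
         "rule 2 with min_above_lod_frac = 0")
  }
  feats <- feature_ids(table_d1)
  grp1 <- metadata$group[match(sample_ids(table_d1), metadata$sample_id)]
  grp7 <- metadata$group[match(sample_ids(table_d7), metadata$sample_id)]
  reasons <- stats::setNames(vector("list", length(feats)), feats)
  for (g in c("S", "NS")) {
    cells <- rbind(table_d1$values[grp1 == g, , drop = FALSE],
                   table_d7$values[grp7 == g, , drop = FALSE])
    miss_frac <- colMeans(is.na(cells))
    bad <- feats[miss_frac >= max_missing_frac]
    for (f in bad) reasons[[f]] <- union(reasons[[f]], "missingness_rule")
  }
  if (min_above_lod_frac > 0) {
    vals <- rbind(table_d1$values, table_d7$values)
    mask <- rbind(table_d1$below_lod_mask, table_d7$below_lod_mask)
    above <- colSums(!is.na(vals) & !mask) / nrow(vals)
    bad <- feats[above < min_above_lod_frac]
    for (f in bad) reasons[[f]] <- union(reasons[[f]], "lod_rule")
  }
  report <- qc_report(feats, layer = "metabolite", reasons = reasons)
  list(retained = feats[vapply(reasons, length, 1L) == 0L], report = report)
}

#' Build a QC report table
#'
#' One row per feature with a retention flag and the semicolon-joined
#' rule codes it violated. Retained + excluded always reconciles with
#' the number of input features.
#'
#' @param feature_ids Character vector of features considered.
#' @param layer Layer tag.
#' @param reasons Named list mapping feature id to a character vector of
#'   violated rules (empty means retained).
#' @return Data frame with columns `feature_id`, `layer`, `retained`,
#'   `reasons` and attributes `n_retained`, `n_excluded`.
#' @export
qc_report <- function(feature_ids, layer, reasons) {
  excl <- vapply(feature_ids, function(f) {
    paste(reasons[[f]] %||% character(0), collapse = ";")
  }, character(1))
  out <- data.frame(
    feature_id = feature_ids, layer = layer,
    retained = excl == "", reasons = excl, row.names = NULL
  )
  attr(out, "n_retained") <- sum(out$retained)
  attr(out, "n_excluded") <- sum(!out$retained)
  out
}

#' Select and LOESS-normalize iTRAQ protein intensities
#'
#' Protein selection applies three rules: the protein must be detected in
#' all iTRAQ runs, must not be a depletion-target contaminant, and must
#' be quantified with at least two unique peptides. Retained raw
#' intensities are log2 transformed and LOESS normalized against the
#' mean global intensity across all runs: per sample, a degree-1 LOESS
#' curve of the sample's deviation from the per-protein global mean
#' (M = sample - reference) versus the reference (A) is fitted and
#' subtracted, flattening any smooth intensity-dependent bias. With
#' `reference = "global_scalar"` the reference collapses to one overall
#' mean and the correction reduces to per-sample mean centering on that
#' scalar.
#'
#' @param raw Samples x proteins matrix of positive raw peak intensities.
#' @param evidence A [protein_evidence()] object.
#' @param timepoint Time point tag for the returned table.
#' @param span,degree LOESS smoothing parameters (defaults 0.75, 1).
#' @param reference `"per_protein_mean"` (default) or `"global_scalar"`.
#' @return List with `table` (an [omics_table()] of log2 intensities),
#'   `report` (QC data frame over all proteins in `evidence`).
#' @export
normalize_proteins <- function(raw, evidence, timepoint = "D1",
                               span = 0.75, degree = 1,
                               reference = c("per_protein_mean",
                                             "global_scalar")) {
  reference <- match.arg(reference)
  stopifnot(inherits(evidence, "protein_evidence"))
  bad <- which(!is.na(raw) & raw <= 0)
  if (length(bad)) {
    stop("nonpositive raw intensity at cell [",
         rownames(raw)[row(raw)[bad[1L]]], ", ",
         colnames(raw)[col(raw)[bad[1L]]], "]")
  }
  if (ncol(evidence$detected) < 2L) stop("need at least 2 batches")
  reasons <- stats::setNames(vector("list", length(evidence$protein_id)),
                             evidence$protein_id)
  all_det <- rowSums(evidence$detected) == ncol(evidence$detected)
  for (f in evidence$protein_id[!all_det]) {
    reasons[[f]] <- union(reasons[[f]], "evidence_rule")
  }
  for (f in evidence$protein_id[evidence$unique_peptides < 2L]) {
    reasons[[f]] <- union(reasons[[f]], "evidence_rule")
  }
  for (f in evidence$protein_id[evidence$is_contaminant]) {
    reasons[[f]] <- union(reasons[[f]], "contaminant_rule")
  }
  report <- qc_report(evidence$protein_id, "protein", reasons)
  keep <- intersect(colnames(raw),
                    evidence$protein_id[vapply(reasons, length, 1L) == 0L])
  x <- log2(raw[, keep, drop = FALSE])
  ref <- if (reference == "per_protein_mean") {
    colMeans(x, na.rm = TRUE)
  } else {
    rep(mean(x, na.rm = TRUE), ncol(x))
  }
  for (i in seq_len(nrow(x))) {
    m <- x[i, ] - ref
    ok <- !is.na(m)
    if (reference == "global_scalar" || length(unique(ref[ok])) < 10L) {
      x[i, ok] <- x[i, ok] - mean(m[ok])
    } else {
      fit <- stats::loess(m[ok] ~ ref[ok], span = span, degree = degree,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      x[i, ok] <- x[i, ok] - stats::predict(fit, ref[ok])
    }
  }
  list(table = omics_table(x, "protein", timepoint,
                           value_semantics = "log2_intensity"),
       report = report)
}

#' Per-patient D7/D1 ratio features
#'
#' Forms the modeling substrate: one row per patient, one column per
#' feature, each cell the ratio of the D7 value over the D1 value. For
#' metabolite layers, censored (below-LOD) cells are first imputed at
#' half the per-feature limit of detection — the standard targeted
#' metabolomics convention for a measurement known to be small — while
#' cells missing completely at random are imputed at the per-feature,
#' per-time-point median of the observed values, the appropriate
#' central imputation when missingness carries no value information.
#' `lod_impute = "drop"` disables both imputations. Any feature left
#' with a missing or zero denominator (or a non-finite ratio) is
#' dropped with reason `zero_denominator`.
#'
#' @param table_d1,table_d7 [omics_table()] objects of one layer at the
#'   two time points, same patients and features.
#' @param metadata A [cohort_metadata()] data frame.
#' @param features Optional feature subset (e.g. the QC-retained set).
#' @param lod_impute `"half_lod"` (default) or `"drop"`.
#' @return A `ratio_table`: list with `values` (patients x features),
#'   `layer` (named character vector per feature), `group` (named per
#'   patient) and `report` (drop bookkeeping).
#' @export
compute_ratios <- function(table_d1, table_d7, metadata,
                           features = NULL,
                           lod_impute = c("half_lod", "drop")) {
  lod_impute <- match.arg(lod_impute)
  stopifnot(inherits(table_d1, "omics_table"), inherits(table_d7, "omics_table"))
  metadata <- cohort_metadata(metadata)
  only_one <- c(setdiff(sample_ids(table_d1), sample_ids(table_d7)),
                setdiff(sample_ids(table_d7), sample_ids(table_d1)))
  if (length(only_one)) {
    stop("patient '", only_one[1L], "' is present at only one time point")
  }
  pats <- sample_ids(table_d1)
  feats <- features %||% feature_ids(table_d1)
  feats <- intersect(feats, feature_ids(table_d1))
  grab <- function(tab) {
    v <- tab$values[pats, feats, drop = FALSE]
    if (tab$layer == "metabolite" && lod_impute == "drop" &&
        !is.null(tab$below_lod_mask)) {
      v[tab$below_lod_mask[pats, feats, drop = FALSE]] <- NA_real_
    }
    if (tab$layer == "metabolite" && lod_impute == "half_lod") {
      mask <- tab$below_lod_mask
      lod <- tab$lod
      if (is.null(lod)) {
        # estimate LOD as the smallest observed above-LOD value per feature
        lod <- vapply(feats, function(f) {
          obs <- tab$values[, f]
          ab <- if (is.null(mask)) obs else obs[!mask[, f]]
          suppressWarnings(min(ab, na.rm = TRUE))
        }, numeric(1))
      } else {
        lod <- lod[feats]
      }
      for (f in feats) {
        cens <- if (is.null(mask)) rep(FALSE, nrow(v)) else mask[pats, f]
        cens <- cens & !is.na(v[, f])
        if (any(cens) && is.finite(lod[f])) v[cens, f] <- lod[f] / 2
        miss <- is.na(v[, f])
        if (any(miss)) v[miss, f] <- stats::median(v[!miss, f])
      }
    }
    v
  }
  d1 <- grab(table_d1)
  d7 <- grab(table_d7)
  ratios <- d7 / d1
  bad_den <- colSums(is.na(d1) | d1 == 0) > 0L
  bad_fin <- colSums(!is.finite(ratios)) > 0L
  drop <- bad_den | bad_fin
  reasons <- stats::setNames(vector("list", length(feats)), feats)
  for (f in feats[drop]) reasons[[f]] <- "zero_denominator"
  report <- qc_report(feats, table_d1$layer, reasons)
  keep <- feats[!drop]
  grp <- metadata$group[match(pats, metadata$sample_id)]
  structure(
    list(values = ratios[, keep, drop = FALSE],
         layer = stats::setNames(rep(table_d1$layer, length(keep)), keep),
         group = stats::setNames(grp, pats),
         report = report),
    class = "ratio_table"
  )
}

#' Merge ratio tables across layers
#'
#' Column-binds ratio tables on the shared patients, preserving the
#' per-feature layer tags.
#'
#' @param ... `ratio_table` objects with identical patients.
#' @return A merged `ratio_table`.
#' @export
bind_ratios <- function(...) {
  tabs <- list(...)
  pats <- rownames(tabs[[1L]]$values)
  for (tab in tabs[-1L]) {
    if (!identical(rownames(tab$values), pats)) {
      stop("ratio tables must be aligned on the same patients")
    }
  }
  structure(
    list(values = do.call(cbind, lapply(tabs, `[[`, "values")),
         layer = do.call(c, lapply(tabs, `[[`, "layer")),
         group = tabs[[1L]]$group,
         report = NULL),
    class = "ratio_table"
  )
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf("<ratio_table> %d patients x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(table(x$layer)),
                            as.integer(table(x$layer))), collapse = ", ")))
  invisible(x)
}

#' Z-score standardization fitted on training rows
#'
#' Centers and scales each feature to mean 0 and unit standard deviation
#' (denominator n - 1) using statistics of the training rows only; the
#' same location and scale are then applied to any further matrices, so
#' no information leaks from test to training data. Zero-variance
#' features on the training rows are dropped with a warning. A
#' compatibility mode (`scope = "all"`) reproduces the
#' normalize-everything-first behaviour by fitting on all supplied rows.
#'
#' @param train Numeric matrix of training rows.
#' @param ... Further matrices to transform with the training statistics.
#' @param scope `"train"` (default) or `"all"`.
#' @return List with `train`, the transformed `...` matrices (named as
#'   supplied), `center`, `scale` and `dropped`.
#' @export
zscore <- function(train, ..., scope = c("train", "all")) {
  scope <- match.arg(scope)
  rest <- list(...)
  fit_on <- if (scope == "all") do.call(rbind, c(list(train), rest)) else train
  center <- colMeans(fit_on, na.rm = TRUE)
  scale_ <- apply(fit_on, 2L, stats::sd, na.rm = TRUE)
  dropped <- colnames(train)[is.na(scale_) | scale_ == 0]
  if (length(dropped)) {
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
  }
  keep <- setdiff(colnames(train), dropped)
  tf <- function(m) {
    m <- m[, keep, drop = FALSE]
    sweep(sweep(m, 2L, center[keep], "-"), 2L, scale_[keep], "/")
  }
  out <- c(list(train = tf(train)), lapply(rest, tf))
  out$center <- center[keep]
  out$scale <- scale_[keep]
  out$dropped <- dropped
  out
}
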