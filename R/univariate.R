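#' Two-group Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test between outcome groups.
#' The p-value is exact (by enumeration of the rank-sum distribution)
#' when the combined sample size is at most 25 and there are no ties;
#' otherwise the normal approximation with midranks, tie correction and
#' continuity correction is used.
#'
#' @param a,b Numeric vectors (missing values removed).
#' @return List with `statistic` (the Mann-Whitney U for the first
#'   group), `p` (two-sided) and `exact`.
#' @export
rank_sum_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("a group is empty after removing missing values")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && (length(a) + length(b)) <= 25L
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Paired Wilcoxon signed-rank test with trend call
#'
#' Tests the within-group change from D1 to D7. Zero differences are
#' dropped before ranking (standard signed-rank convention — stated
#' explicitly because the cohorts are tiny and the choice is visible).
#' The p-value is exact for at most 25 nonzero untied differences. The
#' trend is called from the median of all differences (including zeros):
#' `"down"` if median(D7 - D1) < 0, `"up"` if > 0, `"flat"` otherwise.
#'
#' @param d1,d7 Paired numeric vectors (pairs with missing values are
#'   removed).
#' @return List with `statistic` (V, sum of positive ranks), `p`
#'   (two-sided), `trend` and `exact`.
#' @export
signed_rank_test <- function(d1, d7) {
  ok <- !is.na(d1) & !is.na(d7)
  d <- d7[ok] - d1[ok]
  if (!length(d)) stop("no complete pairs")
  med <- stats::median(d)
  trend <- if (med < 0) "down" else if (med > 0) "up" else "flat"
  dn <- d[d != 0]
  if (!length(dn)) {
    warning("all differences are zero; p set to 1")
    return(list(statistic = NA_real_, p = 1, trend = "flat", exact = TRUE))
  }
  ties <- anyDuplicated(abs(dn)) > 0L
  exact <- !ties && length(dn) <= 25L
  ht <- suppressWarnings(
    stats::wilcox.test(dn, mu = 0, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, trend = trend,
       exact = exact)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, clipped at 1. Output order
#' matches input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

screen_one_family <- function(vals_by_feature, testfun, comparison, layer,
                              alpha, fdr) {
  res <- lapply(vals_by_feature, testfun)
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- bh_fdr(p)
  data.frame(
    feature_id = names(vals_by_feature),
    layer = layer, comparison = comparison,
    statistic = vapply(res, function(r) r$statistic %||% NA_real_, numeric(1)),
    p = p, q = q,
    significant = p < alpha & q < fdr,
    trend = vapply(res, function(r) r$trend %||% NA_character_, character(1)),
    row.names = NULL
  )
}

#' Univariate screen of a cohort
#'
#' Runs five comparison families per applicable layer: rank-sum tests
#' between survivors and non-survivors at D1, at D7 and on the D7/D1
#' ratio, and signed-rank tests of the D1-to-D7 change within each
#' group. Significance requires both `p < alpha` and `q < fdr` (the
#' dual threshold). False discovery rate is controlled per comparison
#' family per layer by default (`fdr_scope = "family"`); set
#' `fdr_scope = "global"` to adjust across everything at once.
#'
#' @param tables Named list of [omics_table()] objects
#'   (`<layer>_D1` / `<layer>_D7`).
#' @param metadata A [cohort_metadata()] data frame.
#' @param ratios Optional named list of `ratio_table` objects for the
#'   between-group ratio comparison.
#' @param alpha,fdr Dual significance thresholds (defaults 0.05, 0.15).
#' @param fdr_scope `"family"` or `"global"`.
#' @return Data frame of test results sorted by q then p.
#' @export
screen_cohort <- function(tables, metadata, ratios = NULL,
                          alpha = 0.05, fdr = 0.15,
                          fdr_scope = c("family", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  metadata <- cohort_metadata(metadata)
  validate_cohort(tables, metadata)
  out <- list()
  layers <- unique(vapply(tables, `[[`, character(1), "layer"))
  for (lay in layers) {
    d1 <- tables[[paste0(lay, "_D1")]]
    d7 <- tables[[paste0(lay, "_D7")]]
    if (is.null(d1) || is.null(d7)) next
    grp1 <- metadata$group[match(sample_ids(d1), metadata$sample_id)]
    for (tp in c("D1", "D7")) {
      tab <- if (tp == "D1") d1 else d7
      grp <- metadata$group[match(sample_ids(tab), metadata$sample_id)]
      cols <- stats::setNames(
        lapply(feature_ids(tab), function(f) tab$values[, f]),
        feature_ids(tab)
      )
      out[[length(out) + 1L]] <- screen_one_family(
        cols, function(v) rank_sum_test(v[grp == "S"], v[grp == "NS"]),
        paste0("S_vs_NS_at_", tp), lay, alpha, fdr
      )
    }
    pats <- intersect(sample_ids(d1), sample_ids(d7))
    grp_p <- metadata$group[match(pats, metadata$sample_id)]
    for (g in c("S", "NS")) {
      pg <- pats[grp_p == g]
      cols <- stats::setNames(
        lapply(feature_ids(d1), function(f) f), feature_ids(d1)
      )
      out[[length(out) + 1L]] <- screen_one_family(
        cols,
        function(f) signed_rank_test(d1$values[pg, f], d7$values[pg, f]),
        paste0("D1_vs_D7_within_", g), lay, alpha, fdr
      )
    }
  }
  for (rt in ratios %||% list()) {
    for (lay in unique(rt$layer)) {
      feats <- names(rt$layer)[rt$layer == lay]
      cols <- stats::setNames(
        lapply(feats, function(f) rt$values[, f]), feats
      )
      grp <- rt$group[rownames(rt$values)]
      out[[length(out) + 1L]] <- screen_one_family(
        cols, function(v) rank_sum_test(v[grp == "S"], v[grp == "NS"]),
        "S_vs_NS_ratio", lay, alpha, fdr
      )
    }
  }
  res <- do.call(rbind, out)
  if (fdr_scope == "global") {
    res$q <- bh_fdr(res$p)
    res$significant <- res$p < alpha & res$q < fdr
  }
  res[order(res$q, res$p), ]
}
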