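#' Ternary discretization at mean plus/minus a sigma multiple
#'
#' Codes a continuous column into three states: `-1` below
#' `mean - alpha * sd`, `+1` above `mean + alpha * sd`, `0` in between.
#' This is the conventional preprocessing of mutual-information mRMR
#' tools; it makes the subsequent ranking invariant to affine rescaling
#' of any feature. Constant columns code to all zeros with a warning.
#'
#' The default is `alpha = 0.5`. For a feature separating two balanced
#' classes by a shift `D` with within-class spread `s`, the class means
#' sit at `(D/2) / sqrt(s^2 + D^2/4)` pooled standard deviations from
#' the overall mean — a quantity below 1 for every `D` — so coding at
#' one full sigma leaves both class modes inside the middle band and is
#' nearly blind to group structure. Half a sigma resolves shifts larger
#' than about 1.2 within-class standard deviations.
#'
#' @param x Numeric vector.
#' @param alpha Positive multiplier of the standard deviation
#'   (default 0.5).
#' @return Integer vector of codes in `{-1, 0, 1}`.
#' @export
discretize_ternary <- function(x, alpha = 0.5) {
  stopifnot(alpha > 0)
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    warning("constant column: all codes set to 0")
    return(rep(0L, length(x)))
  }
  out <- integer(length(x))
  out[x < m - alpha * s] <- -1L
  out[x > m + alpha * s] <- 1L
  out[is.na(x)] <- NA_integer_
  out
}

#' Plug-in mutual information between two discrete codes
#'
#' `I(X; Y) = sum p(x, y) log2( p(x, y) / (p(x) p(y)) )` over observed
#' cells of the joint contingency table, in bits. Non-negative up to
#' floating point; exactly 0 for independent code patterns.
#'
#' @param x,y Equal-length vectors of discrete codes; pairs with missing
#'   entries are dropped.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (!n) stop("no complete pairs")
  xi <- match(x, unique(x)); yi <- match(y, unique(y))
  nx <- max(xi); ny <- max(yi)
  pj <- tabulate((yi - 1L) * nx + xi, nx * ny) / n
  px <- tabulate(xi, nx) / n
  py <- tabulate(yi, ny) / n
  pxy <- as.vector(outer(px, py))
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / pxy[nz]))
}

#' Greedy minimum-redundancy maximum-relevance feature ranking
#'
#' Ranks features by mutual information with the class label while
#' penalizing mutual information with already-selected features. The
#' first pick maximizes relevance `I(f; c)` alone; each subsequent pick
#' maximizes `I(f; c) - mean_s I(f; s)` over the selected set `s` for
#' the MID (difference) criterion, or the ratio
#' `I(f; c) / mean_s I(f; s)` for MIQ. Continuous features are ternary
#' discretized first (see [discretize_ternary()]). Ties are broken by
#' higher relevance, then by input column order, so rankings are
#' deterministic.
#'
#' @param x Samples x features numeric matrix with column names.
#' @param y Binary class labels (two levels).
#' @param k Number of features to rank (default all).
#' @param criterion `"MID"` (default) or `"MIQ"`.
#' @param alpha Sigma multiplier of the discretization rule.
#' @return Data frame with columns `rank`, `feature_id`, `relevance`,
#'   `redundancy` (mean mutual information to previously selected
#'   features; 0 for the first), `score`; attribute `criterion`.
#' @export
mrmr_rank <- function(x, y, k = ncol(x), criterion = c("MID", "MIQ"),
                      alpha = 0.5) {
  criterion <- match.arg(criterion)
  if (k <= 0L) stop("k must be >= 1")
  k <- min(k, ncol(x))
  if (length(unique(y[!is.na(y)])) != 2L) stop("class labels must be binary")
  if (is.null(colnames(x))) stop("x must have column names")
  ycode <- as.integer(factor(y))
  codes <- suppressWarnings(
    apply(x, 2L, discretize_ternary, alpha = alpha)
  )
  p <- ncol(x)
  relevance <- vapply(seq_len(p), function(j) {
    mutual_information(codes[, j], ycode)
  }, numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)
  rows <- vector("list", k)
  eps <- 1e-12
  # scores within a relative 1e-9 band are treated as tied so that the
  # ranking does not depend on floating-point summation order
  near <- function(a, b) abs(a - b) <= 1e-9 * max(1, abs(a), abs(b))
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    mean_red <- if (length(selected)) red_sum[cand] / length(selected) else
      numeric(length(cand))
    score <- if (criterion == "MID") {
      relevance[cand] - mean_red
    } else {
      relevance[cand] / pmax(mean_red, eps)
    }
    # max score; ties by higher relevance, then input column order
    top <- which(vapply(score, near, logical(1), b = max(score)))
    rel_top <- relevance[cand][top]
    top <- top[vapply(rel_top, near, logical(1), b = max(rel_top))]
    pick <- cand[top[1L]]
    ord_idx <- match(pick, cand)
    rows[[step]] <- data.frame(
      rank = step, feature_id = colnames(x)[pick],
      relevance = relevance[pick],
      redundancy = if (length(selected)) red_sum[pick] / length(selected) else 0,
      score = score[ord_idx], row.names = NULL
    )
    selected <- c(selected, pick)
    if (step < k) {
      rest <- setdiff(seq_len(p), selected)
      red_sum[rest] <- red_sum[rest] + vapply(rest, function(j) {
        mutual_information(codes[, j], codes[, pick])
      }, numeric(1))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "criterion") <- criterion
  out
}

ratio_matrix <- function(x) {
  if (inherits(x, "ratio_table")) x$values else x
}

top_features <- function(ranking, k, what = "features") {
  if (k > nrow(ranking)) {
    warning("requested top ", k, " ", what, " but only ", nrow(ranking),
            " are available; using all")
    k <- nrow(ranking)
  }
  ranking$feature_id[seq_len(k)]
}

#' Cascaded mRMR integration of omics layers
#'
#' Three-tier ranking scheme. Tier 1 ranks the metabolite ratios alone.
#' Tier 2 combines the top `sizes[1]` metabolites with the top
#' `sizes[2]` proteins (each from its own within-layer mRMR run) and
#' re-ranks the pooled set. Tier 3 adds all clinical variables to the
#' top `sizes[3]` features of tier 2 and re-ranks once more. Tier 1's
#' top metabolites are reused from the tier-1 ranking rather than
#' recomputed.
#'
#' @param metabolites,proteins,clinical `ratio_table` objects or
#'   patients x features matrices, aligned on the same patients.
#' @param y Binary class labels, one per patient.
#' @param sizes Cascade cut sizes `(metabolites, proteins,
#'   tier-2 carryover, clinical)`; defaults `c(50, 50, 20, 17)`.
#' @param rank_depth How deep to rank each tier (default: far enough for
#'   the cascade cuts and the top-30 models; the greedy ranking is
#'   truncated there since later positions are never consumed).
#' @param criterion,alpha Passed to [mrmr_rank()].
#' @return List with rankings `tier1`, `tier2`, `tier3` and the
#'   within-layer `protein_ranking`.
#' @export
cascade_rank <- function(metabolites, proteins, clinical, y,
                         sizes = c(50L, 50L, 20L, 17L),
                         rank_depth = max(sizes[1:3], 30L),
                         criterion = "MID", alpha = 0.5) {
  met <- ratio_matrix(metabolites)
  prot <- ratio_matrix(proteins)
  clin <- ratio_matrix(clinical)
  tier1 <- mrmr_rank(met, y, k = min(rank_depth, ncol(met)),
                     criterion = criterion, alpha = alpha)
  prot_rank <- mrmr_rank(prot, y, k = min(rank_depth, ncol(prot)),
                         criterion = criterion, alpha = alpha)
  top_met <- top_features(tier1, sizes[1L], "metabolites")
  top_prot <- top_features(prot_rank, sizes[2L], "proteins")
  pool2 <- cbind(met[, top_met, drop = FALSE], prot[, top_prot, drop = FALSE])
  tier2 <- mrmr_rank(pool2, y, k = min(rank_depth, ncol(pool2)),
                     criterion = criterion, alpha = alpha)
  carry <- top_features(tier2, sizes[3L], "tier-2 features")
  if (ncol(clin) > sizes[4L]) {
    warning("clinical layer has ", ncol(clin), " variables; cascade expects ",
            sizes[4L], " — using all")
  }
  pool3 <- cbind(pool2[, carry, drop = FALSE], clin)
  tier3 <- mrmr_rank(pool3, y, criterion = criterion, alpha = alpha)
  list(tier1 = tier1, tier2 = tier2, tier3 = tier3,
       protein_ranking = prot_rank)
}
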