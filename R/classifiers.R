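#' Stratified 2/3 - 1/3 train/test split
#'
#' Resolves a split plan: per outcome class, `round(train_fraction * n)`
#' patients (half-up rounding) go to the training set, the rest to the
#' test set. With 9 survivors and 8 non-survivors this gives an 11/6
#' split (6 + 5 train, 3 + 3 test). Deterministic under the seed.
#'
#' @param metadata A [cohort_metadata()] data frame.
#' @param train_fraction Training proportion (default 2/3).
#' @param stratified Stratify by outcome class (default `TRUE`).
#' @param seed Integer seed.
#' @return A `split_plan` list with `train` and `test` sample ids.
#' @export
make_split <- function(metadata, train_fraction = 2 / 3,
                       stratified = TRUE, seed = 1L) {
  metadata <- cohort_metadata(metadata)
  set.seed(seed)
  train <- character(0)
  if (stratified) {
    for (g in c("S", "NS")) {
      ids <- metadata$sample_id[metadata$group == g]
      if (length(ids) < 2L) stop("class ", g, " has fewer than 2 patients")
      n_tr <- round_half_up(train_fraction * length(ids))
      n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
      train <- c(train, sample(ids, n_tr))
    }
  } else {
    ids <- metadata$sample_id
    n_tr <- round_half_up(train_fraction * length(ids))
    train <- sample(ids, min(max(n_tr, 1L), length(ids) - 1L))
  }
  structure(
    list(train = sort(train), test = sort(setdiff(metadata$sample_id, train)),
         train_fraction = train_fraction, stratified = stratified,
         seed = seed),
    class = "split_plan"
  )
}

as_binary_outcome <- function(y) {
  # S = 0, NS = 1
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(y)
  }
  stats::setNames(as.numeric(as.character(y) == "NS"), names(y))
}

model_result <- function(family, features, coefficients = NULL,
                         vip = NULL, predicted = NULL, scores = NULL,
                         correct = NULL, total = NULL, ...) {
  structure(
    c(list(family = family, features = features,
           coefficients = coefficients, vip = vip,
           predicted = predicted, scores = scores,
           correct = correct, total = total), list(...)),
    class = "model_result"
  )
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s on %d features; test correct %s of %d\n",
              x$family, length(x$features),
              paste(unlist(x$correct), collapse = " and "), x$total))
  invisible(x)
}

stratified_foldid <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

lambda_grid <- function(x, y, alpha_mix, n_lambda = 100L,
                        lambda_min_ratio = 1e-4) {
  # smallest lambda zeroing all slopes for penalized logistic regression
  lmax <- max(abs(crossprod(x, y - mean(y)))) / (nrow(x) * alpha_mix)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

binomial_deviance <- function(y, prob) {
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Elastic-net logistic regression with two minimal-deviance strategies
#'
#' Fits penalized logistic regression (`S = 0`, `NS = 1`) on the
#' training patients with L1/L2 mixing weight `alpha_mix` (default 0.5,
#' an even compromise between lasso selection and ridge grouping of
#' correlated features). The cross-validated binomial deviance over the
#' lambda grid is computed `n_repetitions` times, each repetition with a
#' fresh random stratified fold assignment on the fixed training set.
#' Strategy A returns the coefficients of the model attaining minimal
#' cross-validated deviance across all (repetition, lambda) pairs;
#' strategy B takes the minimizing lambda and refits the elastic net
#' once on the full training set at that lambda. Classes are called by
#' thresholding the logistic output at 0.5.
#'
#' Features are expected already standardized (see [zscore()]); internal
#' re-standardization is disabled.
#'
#' @param x Patients x features matrix with patient rownames.
#' @param y Outcome labels (`"S"`/`"NS"` or 0/1), named by patient or
#'   aligned with `x`.
#' @param split A [make_split()] plan.
#' @param alpha_mix Elastic-net mixing weight in (0, 1].
#' @param n_repetitions Cross-validation repetitions (default 50).
#' @param n_folds Folds per repetition (default 5, capped at the
#'   smallest training class size).
#' @param lambda Optional lambda grid; defaults to 100 geometric values
#'   from the smallest all-zeroing lambda down to 1e-4 of it.
#' @param seed Integer seed for the fold assignments.
#' @return A `model_result` with per-strategy coefficient vectors
#'   (`coefficients$A`, `coefficients$B`), the chosen `lambda`, the
#'   minimal cross-validated deviance, per-strategy test predictions and
#'   correct-classification counts.
#' @export
fit_elastic_net <- function(x, y, split, alpha_mix = 0.5,
                            n_repetitions = 50L, n_folds = 5L,
                            lambda = NULL, seed = 1L) {
  stopifnot(alpha_mix > 0, alpha_mix <= 1, n_repetitions >= 1L)
  y <- as_binary_outcome(y)
  if (is.null(names(y))) names(y) <- rownames(x)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]
  yte <- y[split$test]
  if (length(unique(ytr)) < 2L) stop("training set has a single class")
  if (is.null(lambda)) lambda <- lambda_grid(xtr, ytr, alpha_mix)
  n_folds <- min(n_folds, min(table(ytr)))
  set.seed(seed)
  best <- list(cvm = Inf, lambda = NA_real_, fit = NULL)
  for (rep in seq_len(n_repetitions)) {
    foldid <- stratified_foldid(ytr, n_folds)
    cvfit <- suppressWarnings(glmnet::cv.glmnet(
      xtr, ytr, family = "binomial", alpha = alpha_mix, lambda = lambda,
      foldid = foldid, type.measure = "deviance", standardize = FALSE
    ))
    i <- which.min(cvfit$cvm)
    if (cvfit$cvm[i] < best$cvm) {
      best <- list(cvm = cvfit$cvm[i], lambda = cvfit$lambda[i],
                   fit = cvfit$glmnet.fit)
    }
  }
  coef_a <- as.numeric(stats::coef(best$fit, s = best$lambda))
  refit <- suppressWarnings(glmnet::glmnet(
    xtr, ytr, family = "binomial", alpha = alpha_mix, lambda = lambda,
    standardize = FALSE
  ))
  coef_b <- as.numeric(stats::coef(refit, s = best$lambda))
  nm <- c("(Intercept)", colnames(x))
  coefs <- list(A = stats::setNames(coef_a, nm),
                B = stats::setNames(coef_b, nm))
  predict_with <- function(beta) {
    eta <- drop(cbind(1, xte) %*% beta)
    prob <- 1 / (1 + exp(-eta))
    cls <- as.numeric(prob > 0.5)
    list(prob = stats::setNames(prob, rownames(xte)),
         class = stats::setNames(cls, rownames(xte)),
         correct = sum(cls == yte))
  }
  pred <- lapply(coefs, predict_with)
  model_result(
    family = "elastic_net", features = colnames(x), coefficients = coefs,
    predicted = lapply(pred, `[[`, "class"),
    scores = lapply(pred, `[[`, "prob"),
    correct = lapply(pred, `[[`, "correct"),
    total = length(yte),
    lambda = best$lambda, cv_deviance = best$cvm,
    alpha_mix = alpha_mix, refit = refit
  )
}

#' Linear discriminant analysis with shrinkage
#'
#' Two-class LDA on the training patients. The pooled within-class
#' covariance is shrunk towards a scaled identity,
#' `(1 - gamma) * S + gamma * mean(diag(S)) * I`, because the number of
#' features (10) approaches the number of training patients (11). By
#' default (`shrinkage = "auto"`) the shrinkage intensity is the
#' Ledoit-Wolf estimate, the standard choice for discriminant analysis
#' in the p-close-to-n regime; a numeric value fixes gamma, and
#' `shrinkage = 0` recovers plain LDA and errors on a singular
#' covariance. The linear boundary uses equal priors, so the 1-D
#' decision threshold between classes with equal variances sits at the
#' midpoint of the class means.
#'
#' @param x Patients x features matrix (standardized).
#' @param y Outcome labels.
#' @param split A [make_split()] plan.
#' @param shrinkage `"auto"` (Ledoit-Wolf, default) or a fixed gamma in
#'   `[0, 1]`.
#' @param priors `"equal"` (default) or `"proportional"` to training
#'   class sizes.
#' @return A `model_result` with boundary `coefficients` (intercept
#'   first; positive discriminant predicts NS), test predictions and the
#'   correct-classification count.
#' @export
fit_lda <- function(x, y, split, shrinkage = "auto",
                    priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  y <- as_binary_outcome(y)
  if (is.null(names(y))) names(y) <- rownames(x)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]
  yte <- y[split$test]
  x0 <- xtr[ytr == 0, , drop = FALSE]
  x1 <- xtr[ytr == 1, , drop = FALSE]
  m0 <- colMeans(x0); m1 <- colMeans(x1)
  n0 <- nrow(x0); n1 <- nrow(x1)
  z <- rbind(sweep(x0, 2L, m0), sweep(x1, 2L, m1))
  sw <- crossprod(z) / nrow(z)
  gamma <- if (identical(shrinkage, "auto")) ledoit_wolf_gamma(z, sw) else
    shrinkage
  stopifnot(is.numeric(gamma), gamma >= 0, gamma <= 1)
  if (gamma > 0) {
    sw <- (1 - gamma) * sw + gamma * mean(diag(sw)) * diag(ncol(xtr))
  }
  w <- tryCatch(
    solve(sw, m1 - m0),
    error = function(e) {
      stop("pooled within-class covariance is singular; ",
           "enable shrinkage (shrinkage > 0)")
    }
  )
  b <- -sum(w * (m0 + m1) / 2)
  if (priors == "proportional") b <- b + log(n1 / n0)
  disc <- drop(xte %*% w) + b
  cls <- as.numeric(disc > 0)
  model_result(
    family = "lda", features = colnames(x),
    coefficients = stats::setNames(c(b, w), c("(Intercept)", colnames(x))),
    predicted = stats::setNames(cls, rownames(xte)),
    scores = stats::setNames(disc, rownames(xte)),
    correct = sum(cls == yte), total = length(yte),
    shrinkage = gamma
  )
}

# Ledoit-Wolf shrinkage intensity towards the scaled identity, computed
# from class-mean-centered rows z with S = crossprod(z) / nrow(z)
ledoit_wolf_gamma <- function(z, S) {
  n <- nrow(z)
  p <- ncol(z)
  mu <- mean(diag(S))
  d2 <- sum((S - mu * diag(p))^2)
  if (d2 < 1e-30) return(0)
  b2 <- 0
  for (i in seq_len(n)) {
    b2 <- b2 + sum((tcrossprod(z[i, ]) - S)^2)
  }
  min(1, max(0, (b2 / n^2) / d2))
}

# NIPALS PLS1 with pre-centered x and y
pls1_nipals <- function(x, y, ncomp) {
  n <- nrow(x); p <- ncol(x)
  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp)
  q_vec <- numeric(ncomp)
  ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(x, y))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) {
      ncomp <- a - 1L
      break
    }
    w <- w / wn
    t <- drop(x %*% w)
    tt <- sum(t^2)
    pvec <- drop(crossprod(x, t)) / tt
    q <- sum(y * t) / tt
    x <- x - tcrossprod(t, pvec)
    y <- y - t * q
    w_mat[, a] <- w; p_mat[, a] <- pvec; t_mat[, a] <- t
    q_vec[a] <- q; ssy[a] <- q^2 * tt
  }
  list(w = w_mat[, seq_len(ncomp), drop = FALSE],
       p = p_mat[, seq_len(ncomp), drop = FALSE],
       t = t_mat[, seq_len(ncomp), drop = FALSE],
       q = q_vec[seq_len(ncomp)], ssy = ssy[seq_len(ncomp)],
       ncomp = ncomp)
}

#' PLS-DA with weighted centering and VIP scores
#'
#' Partial least squares discriminant analysis with the class coded
#' `S = -1`, `NS = +1`. Because the groups are unbalanced, each feature
#' is centered at the unweighted mean of its two class means (weighted
#' centering), so both classes contribute equally to the origin and the
#' decision boundary is not shifted towards the majority class; with
#' balanced classes this coincides with ordinary mean centering. Latent
#' components are extracted by the NIPALS algorithm. The variable
#' importance in projection is
#' `VIP_j = sqrt( p * sum_a w_ja^2 SSY_a / sum_a SSY_a )` with `SSY_a`
#' the response variance explained by component `a`; by construction the
#' mean squared VIP over features equals 1. Test patients are classified
#' by the sign of the predicted (centered) response.
#'
#' @param x Patients x features matrix (standardized).
#' @param y Outcome labels.
#' @param split A [make_split()] plan.
#' @param n_components Number of latent components (default 3); must not
#'   exceed `min(n_train - 1, n_features)`.
#' @return A `model_result` with `vip` scores, training and test latent
#'   `scores` (for 3-D score plots), regression `coefficients` on the
#'   centered scale, predictions and the correct-classification count.
#' @export
fit_plsda <- function(x, y, split, n_components = 3L) {
  y <- as_binary_outcome(y)
  if (is.null(names(y))) names(y) <- rownames(x)
  xtr <- x[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- x[split$test, , drop = FALSE]
  yte <- y[split$test]
  bound <- min(nrow(xtr) - 1L, ncol(xtr))
  if (n_components > bound) {
    stop("n_components must be <= min(n_train - 1, n_features) = ", bound)
  }
  ycode <- ifelse(ytr == 1, 1, -1)
  # weighted centering: mean of the two class means, per feature
  center <- (colMeans(xtr[ytr == 1, , drop = FALSE]) +
             colMeans(xtr[ytr == 0, , drop = FALSE])) / 2
  xc <- sweep(xtr, 2L, center)
  # the +/-1 class codes are already symmetric about 0
  fit <- pls1_nipals(xc, ycode, n_components)
  pfeat <- ncol(x)
  vip <- sqrt(pfeat * drop(fit$w^2 %*% fit$ssy) / sum(fit$ssy))
  names(vip) <- colnames(x)
  rot <- fit$w %*% solve(crossprod(fit$p, fit$w))
  beta <- drop(rot %*% fit$q)
  xte_c <- sweep(xte, 2L, center)
  pred <- drop(xte_c %*% beta)
  cls <- as.numeric(pred > 0)
  tr_scores <- fit$t
  rownames(tr_scores) <- rownames(xtr)
  te_scores <- xte_c %*% rot
  rownames(te_scores) <- rownames(xte)
  model_result(
    family = "plsda", features = colnames(x),
    coefficients = stats::setNames(beta, colnames(x)),
    vip = vip,
    predicted = stats::setNames(cls, rownames(xte)),
    scores = list(train = tr_scores, test = te_scores,
                  predicted_response = stats::setNames(pred, rownames(xte))),
    correct = sum(cls == yte), total = length(yte),
    n_components = fit$ncomp, ssy = fit$ssy, center = center
  )
}

selected_features <- function(m, vip_threshold = 1) {
  if (m$family == "plsda") {
    names(m$vip)[m$vip > vip_threshold]
  } else if (m$family == "elastic_net") {
    co <- m$coefficients$A
    setdiff(names(co)[co != 0], "(Intercept)")
  } else {
    co <- m$coefficients
    setdiff(names(co)[co != 0], "(Intercept)")
  }
}

feature_signs <- function(m) {
  if (m$family == "plsda") return(sign(m$coefficients))
  co <- if (m$family == "elastic_net") m$coefficients$A else m$coefficients
  sign(co[setdiff(names(co), "(Intercept)")])
}

#' Consensus table across fitted models
#'
#' Summarizes, per feature, membership in each model's selected set
#' (nonzero coefficient, or VIP above `vip_threshold` for PLS-DA), the
#' rank position by coefficient magnitude or VIP, and whether the
#' coefficient signs agree across the models that selected it. A feature
#' absent from a model's input tier is marked `NA` (not applicable), not
#' `FALSE`. Features selected by every supplied model are flagged.
#'
#' @param models Named list of `model_result` objects (at least 2).
#' @param vip_threshold VIP selection cut (default 1).
#' @return Data frame, one row per feature, with one selection column
#'   and one rank column per model plus `n_selected`, `n_applicable`,
#'   `selected_by_all` and `sign_consistent`.
#' @export
compare_models <- function(models, vip_threshold = 1) {
  stopifnot(length(models) >= 2L)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- paste0("model", seq_along(models))
  }
  universe <- unique(unlist(lapply(models, `[[`, "features")))
  sel <- matrix(NA, length(universe), length(models),
                dimnames = list(universe, names(models)))
  rnk <- sel
  sgn <- sel
  for (j in seq_along(models)) {
    m <- models[[j]]
    s <- selected_features(m, vip_threshold)
    sel[m$features, j] <- m$features %in% s
    mag <- if (m$family == "plsda") m$vip else {
      co <- if (m$family == "elastic_net") m$coefficients$A else m$coefficients
      abs(co[setdiff(names(co), "(Intercept)")])
    }
    rnk[names(mag), j] <- rank(-mag, ties.method = "min")
    sg <- feature_signs(m)
    sgn[names(sg), j] <- sg
  }
  n_sel <- rowSums(sel, na.rm = TRUE)
  n_app <- rowSums(!is.na(sel))
  sign_consistent <- vapply(seq_along(universe), function(i) {
    keep <- !is.na(sel[i, ]) & sel[i, ] & !is.na(sgn[i, ]) & sgn[i, ] != 0
    v <- sgn[i, keep]
    length(v) == 0L || all(v == v[1L])
  }, logical(1))
  out <- data.frame(
    feature_id = universe,
    sel, check.names = FALSE,
    n_selected = n_sel, n_applicable = n_app,
    selected_by_all = n_app == length(models) & n_sel == length(models),
    sign_consistent = sign_consistent,
    row.names = NULL
  )
  colnames(out)[2:(1 + length(models))] <- paste0("selected_", names(models))
  rank_df <- as.data.frame(rnk)
  colnames(rank_df) <- paste0("rank_", names(models))
  out <- cbind(out, rank_df)
  out[order(-out$n_selected, out$feature_id), ]
}
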