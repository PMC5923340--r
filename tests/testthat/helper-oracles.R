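# Independent brute-force oracles. These re-derive expected values from
# first principles (full enumeration, naive formulas) and deliberately
# share no code with the implementation they check.

# Exact two-sided rank-sum p-value by enumerating all C(m+n, m) group
# assignments of the pooled observations (untied values only).
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  m <- length(a)
  idx <- utils::combn(length(pooled), m)
  r <- rank(pooled)
  u_of <- function(take) sum(r[take]) - m * (m + 1) / 2
  u_all <- apply(idx, 2L, u_of)
  u_obs <- u_of(seq_len(m))
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign
# patterns over the ranks of |d| (nonzero untied differences only).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  v_all <- apply(signs, 1L, function(s) sum(r[s]))
  p_lo <- mean(v_all <= v_obs)
  p_hi <- mean(v_all >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Naive plug-in mutual information from a contingency table.
oracle_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  out <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        out <- out + unname(p[i, j] * log2(p[i, j] / (px[i] * py[j])))
      }
    }
  }
  out
}

# Naive ternary coding at mean +/- alpha * sd.
oracle_codes <- function(x, alpha) {
  m <- mean(x)
  s <- sd(x)
  if (s == 0) return(rep(0L, length(x)))
  ifelse(x < m - alpha * s, -1L, ifelse(x > m + alpha * s, 1L, 0L))
}

# Exhaustive greedy mRMR with explicit loops: at each step scores every
# remaining feature from scratch with oracle_mi, using the same
# criterion and tie rule (score, then relevance, then column order).
oracle_mrmr <- function(x, y, k = ncol(x), criterion = "MID", alpha = 0.5) {
  codes <- lapply(seq_len(ncol(x)), function(j) oracle_codes(x[, j], alpha))
  ycode <- as.integer(factor(y))
  rel <- vapply(codes, function(cj) oracle_mi(cj, ycode), numeric(1))
  near <- function(a, b) abs(a - b) <= 1e-9 * max(1, abs(a), abs(b))
  selected <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(x)), selected)
    best <- NULL
    for (j in cand) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) oracle_mi(codes[[j]], codes[[s]]),
                    numeric(1)))
      }
      score <- if (criterion == "MID") rel[j] - red else
        rel[j] / max(red, 1e-12)
      if (is.null(best) ||
          (score > best[["score"]] && !near(score, best[["score"]])) ||
          (near(score, best[["score"]]) &&
           rel[j] > best[["rel"]] && !near(rel[j], best[["rel"]]))) {
        best <- c(score = score, rel = rel[j], j = j)
      }
    }
    selected <- c(selected, best[["j"]])
  }
  colnames(x)[selected]
}

# Training-set binomial deviance of a logistic coefficient vector.
oracle_deviance <- function(x, y, beta) {
  eta <- drop(cbind(1, x) %*% beta)
  p <- 1 / (1 + exp(-eta))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(p) + (1 - y) * log(1 - p))
}
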