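test_that("ternary discretization codes against hand-computed thresholds", {
  # mean 2.5, sd 5 -> thresholds at -2.5 and 7.5 with alpha = 1
  expect_equal(discretize_ternary(c(0, 0, 0, 10), alpha = 1),
               c(0L, 0L, 0L, 1L))
  # symmetric column: equal counts of -1 and +1
  x <- c(-3, -2, -1, 1, 2, 3)
  codes <- discretize_ternary(x)
  expect_equal(sum(codes == -1L), sum(codes == 1L))
  expect_warning(z <- discretize_ternary(rep(4, 5)), "constant")
  expect_equal(z, rep(0L, 5))
  # location-scale equivariance (negative scale flips the sign)
  y <- -2 * x + 100
  expect_equal(discretize_ternary(y), -codes)
})

test_that("mutual information matches hand computations and the naive oracle", {
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1.0)
  expect_equal(mutual_information(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0.0)
  set.seed(77)
  for (i in 1:25) {
    x <- sample(-1:1, 20, replace = TRUE)
    y <- sample(0:1, 20, replace = TRUE)
    expect_equal(mutual_information(x, y), oracle_mi(x, y),
                 tolerance = 1e-12)
    expect_equal(mutual_information(x, y), mutual_information(y, x),
                 tolerance = 1e-12)
    expect_gte(mutual_information(x, y), -1e-12)
  }
  expect_error(mutual_information(1:3, 1:4), "equal length")
})

test_that("a fully redundant copy is deferred behind an independent feature", {
  # f1 is highly (not perfectly) class-relevant; f2 is an exact copy of
  # f1, hence fully redundant once f1 is in: its penalty is the full
  # entropy of f1 and its score goes negative. f3 is unrelated noise
  # with a near-zero score, so the greedy order is f1, f3, f2.
  y <- rep(c(0, 1), each = 6)
  f1 <- c(2, rep(-2, 5), rep(2, 6))   # one disagreement with the class
  f2 <- f1
  set.seed(5)
  f3 <- c(-2, 2, -2, 2, -2, 2, 2, -2, 2, -2, 2, -2) + rnorm(12, 0, 0.01)
  x <- cbind(f1 = f1, f2 = f2, f3 = f3)
  got <- mrmr_rank(x, y)
  expect_equal(got$feature_id, c("f1", "f3", "f2"))
  expect_equal(got$feature_id, oracle_mrmr(x, y))
  # f2's redundancy to already-selected features is dominated by f1
  expect_gt(got$redundancy[got$feature_id == "f2"], 0.4)
  # k = 1 returns the single most relevant feature
  expect_equal(mrmr_rank(x, y, k = 1)$feature_id, "f1")
  expect_error(mrmr_rank(x, y, k = 0), "k must be")
})

test_that("greedy ranking equals the exhaustive oracle on random instances", {
  set.seed(2024)
  for (i in 1:40) {
    n <- sample(8:30, 1)
    p <- sample(2:8, 1)
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", 1:p)))
    y <- sample(0:1, n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    crit <- sample(c("MID", "MIQ"), 1)
    expect_equal(mrmr_rank(x, y, criterion = crit)$feature_id,
                 oracle_mrmr(x, y, criterion = crit),
                 info = sprintf("instance %d (%s)", i, crit))
  }
})

test_that("a duplicated column never displaces its original", {
  set.seed(9)
  for (i in 1:10) {
    x <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("f", 1:4)))
    y <- sample(0:1, 20, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    x2 <- cbind(x, dup = x[, 2])
    r <- mrmr_rank(x2, y)
    expect_lt(which(r$feature_id == "f2"), which(r$feature_id == "dup"))
  }
})

test_that("ranking is invariant to affine rescaling of features", {
  set.seed(13)
  x <- matrix(rnorm(25 * 6), 25, dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(0, 1), length.out = 25)
  base <- mrmr_rank(x, y)$feature_id
  x_scaled <- x
  x_scaled[, 3] <- 100 * x[, 3] - 7
  x_scaled[, 5] <- 0.001 * x[, 5] + 2
  expect_equal(mrmr_rank(x_scaled, y)$feature_id, base)
})

test_that("cascade pool sizes follow the integration arithmetic", {
  set.seed(3)
  n <- 17
  met <- matrix(rnorm(n * 137), n, dimnames = list(NULL, paste0("m", 1:137)))
  prot <- matrix(rnorm(n * 132), n, dimnames = list(NULL, paste0("p", 1:132)))
  clin <- matrix(rnorm(n * 17), n, dimnames = list(NULL, paste0("c", 1:17)))
  y <- rep(c("S", "NS"), length.out = n)
  rk <- cascade_rank(met, prot, clin, y, rank_depth = 150)
  # tier 2 ranks the pooled 50 + 50 = 100 features
  expect_equal(nrow(rk$tier2), 100)
  expect_true(all(rk$tier2$feature_id %in%
                    c(head(rk$tier1$feature_id, 50),
                      head(rk$protein_ranking$feature_id, 50))))
  # tier 3 ranks 20 carryovers + 17 clinical = 37 features
  expect_equal(nrow(rk$tier3), 37)
  expect_true(all(paste0("c", 1:17) %in% rk$tier3$feature_id))
  # requesting more features than available warns and uses all
  small <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("s", 1:10)))
  expect_warning(cascade_rank(small, prot, clin, y), "using all")
})

test_that("planted protein effects dominate tier-2 ranks", {
  planted <- sprintf("PROT_%03d", c(1, 21, 41, 61))
  spec <- clean_spec(
    n_survivors = 15, n_nonsurvivors = 15,
    n_metabolites = 60, n_proteins = 80, n_clinical = 5,
    planted_features = lapply(planted, planted_effect, layer = "protein",
                              log2_ratio_shift = -1.0),
    ratio_noise_sd = 0.25, seed = 19
  )
  co <- generate_cohort(spec)
  rt_m <- compute_ratios(co$tables$metabolite_D1, co$tables$metabolite_D7,
                         co$metadata)
  rt_p <- compute_ratios(co$tables$protein_D1, co$tables$protein_D7,
                         co$metadata)
  rt_c <- compute_ratios(co$tables$clinical_D1, co$tables$clinical_D7,
                         co$metadata)
  rk <- cascade_rank(rt_m, rt_p, rt_c, rt_m$group)
  # the redundancy penalty may defer the last planted protein a little,
  # but the top of tier 2 is dominated by the planted layer
  expect_gte(sum(head(rk$tier2$feature_id, 4) %in% planted), 3)
  expect_true(all(planted %in% head(rk$tier2$feature_id, 8)))
  expect_true(head(rk$tier2$feature_id, 1) %in% planted)
  # a pure-noise clinical layer leaves tier-3 top ranks to carryovers
  expect_gte(sum(head(rk$tier3$feature_id, 10) %in%
                   head(rk$tier2$feature_id, 20)), 6)
})
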