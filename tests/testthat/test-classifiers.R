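test_that("the stratified split follows half-up rounding and the seed", {
  fx <- split_fixture(9, 8, seed = 4)
  sp <- fx$split
  grp <- fx$md$group[match(sp$train, fx$md$sample_id)]
  expect_equal(sum(grp == "S"), 6)
  expect_equal(sum(grp == "NS"), 5)
  expect_length(sp$test, 6)
  expect_identical(make_split(fx$md, seed = 4), sp)
  expect_false(identical(make_split(fx$md, seed = 5)$train, sp$train))
  expect_error(make_split(tiny_metadata(1, 5)), "fewer than 2")
})

test_that("an overwhelming penalty leaves only the prevalence intercept", {
  d <- separable_data(seed = 2)
  sp <- make_split(d$md, seed = 2)
  m <- fit_elastic_net(d$x, d$y, sp, lambda = c(1e6, 9e5), n_repetitions = 2)
  co <- m$coefficients$A
  expect_equal(unname(co[-1]), rep(0, ncol(d$x)))
  ytr <- as.numeric(d$y[sp$train] == "NS")
  expect_equal(unname(co[1]), stats::qlogis(mean(ytr)), tolerance = 1e-6)
})

test_that("both minimal-deviance strategies recover planted features with correct signs", {
  d <- separable_data(n_s = 30, n_ns = 30, p = 20, p_signal = 3,
                      shift = 2, seed = 3)
  sp <- make_split(d$md, seed = 3)
  zs <- zscore(d$x[sp$train, ], test = d$x[sp$test, ])
  x <- rbind(zs$train, zs$test)[names(d$y), ]
  m <- fit_elastic_net(x, d$y, sp, n_repetitions = 10, seed = 3)
  for (strategy in c("A", "B")) {
    co <- m$coefficients[[strategy]][-1]
    expect_true(all(co[c("f1", "f2", "f3")] > 0),
                info = paste("strategy", strategy))
  }
  # a 2-sigma shift on 3 of 20 features leaves a little Bayes error
  expect_gte(m$correct$A, m$total - 2)
  expect_gte(m$correct$B, m$total - 2)
})

test_that("coefficient L1 norm shrinks monotonically along the lambda path", {
  d <- separable_data(seed = 6)
  sp <- make_split(d$md, seed = 6)
  m <- fit_elastic_net(d$x, d$y, sp, n_repetitions = 2, seed = 6)
  beta <- as.matrix(m$refit$beta)      # p x n_lambda, lambda decreasing
  l1 <- colSums(abs(beta))
  expect_true(all(diff(l1) >= -1e-8))  # nondecreasing as lambda decreases
})

test_that("strategy B's refit beats the intercept-only model on training deviance", {
  d <- separable_data(seed = 8)
  sp <- make_split(d$md, seed = 8)
  m <- fit_elastic_net(d$x, d$y, sp, n_repetitions = 5, seed = 8)
  xtr <- d$x[sp$train, ]
  ytr <- as.numeric(d$y[sp$train] == "NS")
  dev_fit <- oracle_deviance(xtr, ytr, m$coefficients$B)
  dev_null <- oracle_deviance(xtr, ytr,
                              c(stats::qlogis(mean(ytr)), rep(0, ncol(xtr))))
  expect_lte(dev_fit, dev_null + 1e-8)
})

test_that("1-D LDA places the boundary midway between class means", {
  set.seed(10)
  md <- tiny_metadata(20, 20)
  x <- matrix(c(rnorm(20, 0, 1), rnorm(20, 4, 1)), ncol = 1,
              dimnames = list(md$sample_id, "f"))
  y <- stats::setNames(md$group, md$sample_id)
  sp <- make_split(md, seed = 10)
  m <- fit_lda(x, y, sp)
  m0 <- mean(x[intersect(sp$train, md$sample_id[md$group == "S"]), ])
  m1 <- mean(x[intersect(sp$train, md$sample_id[md$group == "NS"]), ])
  threshold <- -m$coefficients["(Intercept)"] / m$coefficients["f"]
  expect_equal(unname(threshold), (m0 + m1) / 2, tolerance = 1e-10)
})

test_that("LDA errors on rank deficiency without shrinkage and negates under class swap", {
  d <- separable_data(p = 4, seed = 12)
  sp <- make_split(d$md, seed = 12)
  x_dup <- cbind(d$x, dup = d$x[, 1])
  expect_error(fit_lda(x_dup, d$y, sp, shrinkage = 0), "singular")
  m <- fit_lda(d$x, d$y, sp, shrinkage = 0.2)
  y_swapped <- stats::setNames(ifelse(d$y == "S", "NS", "S"), names(d$y))
  m_swap <- fit_lda(d$x, y_swapped, sp, shrinkage = 0.2)
  expect_equal(m_swap$coefficients, -m$coefficients, tolerance = 1e-10)
})

test_that("LDA agrees with the reference implementation on well-conditioned data", {
  skip_if_not_installed("MASS")
  d <- separable_data(n_s = 25, n_ns = 25, p = 3, p_signal = 2, seed = 14)
  sp <- make_split(d$md, seed = 14)
  m <- fit_lda(d$x, d$y, sp, shrinkage = 0, priors = "proportional")
  ref <- MASS::lda(d$x[sp$train, ],
                   grouping = factor(as.numeric(d$y[sp$train] == "NS")))
  ref_pred <- as.numeric(as.character(
    stats::predict(ref, d$x[sp$test, ])$class
  ))
  expect_equal(unname(m$predicted[sp$test]), ref_pred)
})

test_that("weighted centering reduces to mean centering for balanced classes", {
  d <- separable_data(n_s = 20, n_ns = 20, seed = 16)
  sp <- make_split(d$md, seed = 16)
  m <- fit_plsda(d$x, d$y, sp)
  xtr <- d$x[sp$train, ]
  expect_lt(max(abs(m$center - colMeans(xtr))), 1e-12)
})

test_that("VIP scores satisfy the mean-square identity and symmetry", {
  d <- separable_data(seed = 18)
  sp <- make_split(d$md, seed = 18)
  m <- fit_plsda(d$x, d$y, sp, n_components = 3)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-10)
  # a mirrored duplicate gets an identical VIP
  x2 <- cbind(d$x, mirror = -d$x[, 1])
  m2 <- fit_plsda(x2, d$y, sp, n_components = 3)
  expect_equal(unname(m2$vip["mirror"]), unname(m2$vip["f1"]),
               tolerance = 1e-10)
  expect_error(fit_plsda(d$x, d$y, sp, n_components = 50), "n_components")
})

test_that("PLS-DA and LDA both classify well-separated data perfectly", {
  d <- separable_data(n_s = 20, n_ns = 16, p = 8, p_signal = 4,
                      shift = 3, seed = 20)
  sp <- make_split(d$md, seed = 20)
  zs <- zscore(d$x[sp$train, ], test = d$x[sp$test, ])
  x <- rbind(zs$train, zs$test)[names(d$y), ]
  m_lda <- fit_lda(x, d$y, sp)
  m_pls <- fit_plsda(x, d$y, sp)
  expect_equal(m_lda$correct, m_lda$total)
  expect_equal(m_pls$correct, m_pls$total)
  expect_equal(m_lda$predicted, m_pls$predicted)
})

test_that("the consensus table tracks membership, gaps and unanimity", {
  d <- separable_data(n_s = 20, n_ns = 16, p = 8, p_signal = 4,
                      shift = 3, seed = 22)
  sp <- make_split(d$md, seed = 22)
  zs <- zscore(d$x[sp$train, ], test = d$x[sp$test, ])
  x <- rbind(zs$train, zs$test)[names(d$y), ]
  m_lda <- fit_lda(x, d$y, sp)
  m_pls <- fit_plsda(x, d$y, sp)
  # third model fitted on a reduced tier missing f8
  m_small <- fit_lda(x[, 1:7], d$y, sp)
  cons <- compare_models(list(lda = m_lda, plsda = m_pls, small = m_small))
  f8 <- cons[cons$feature_id == "f8", ]
  expect_true(is.na(f8$selected_small))
  expect_false(f8$selected_by_all)
  # a strong signal feature is selected everywhere
  f1 <- cons[cons$feature_id == "f1", ]
  expect_true(f1$selected_lda && f1$selected_plsda && f1$selected_small)
  expect_equal(f1$n_applicable, 3)
  expect_error(compare_models(list(m_lda)), "2")
})
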