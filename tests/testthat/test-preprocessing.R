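make_filter_fixture <- function(vals_d1, vals_d7, mask_d1, mask_d7, md) {
  list(
    d1 = tiny_table(vals_d1, "metabolite", "D1", below_lod_mask = mask_d1),
    d7 = tiny_table(vals_d7, "metabolite", "D7", below_lod_mask = mask_d7),
    md = md
  )
}

test_that("metabolite retention rules match their definitions", {
  md <- tiny_metadata(9, 8)
  ids <- md$sample_id
  feats <- c("drop_miss", "keep_lod", "keep_clean")
  v1 <- named_matrix(runif(17 * 3, 1, 10), ids, feats)
  v7 <- v1 + 0.5
  # drop_miss: missing in 3 of 9 S samples at D1 (3/18 = 17% pooled is fine,
  # so also blank the same patients at D7 -> 6/18 = 33%)
  v1[1:3, "drop_miss"] <- NA
  v7[1:3, "drop_miss"] <- NA
  m1 <- matrix(FALSE, 17, 3, dimnames = dimnames(v1))
  m7 <- m1
  # keep_lod: 40% of all 34 values below LOD -> 60% above, retained
  m1[1:14, "keep_lod"] <- TRUE
  fx <- make_filter_fixture(v1, v7, m1, m7, md)
  res <- filter_metabolites(fx$d1, fx$d7, fx$md)
  expect_setequal(res$retained, c("keep_lod", "keep_clean"))
  rep_row <- res$report[res$report$feature_id == "drop_miss", ]
  expect_false(rep_row$retained)
  expect_match(rep_row$reasons, "missingness_rule")
  # counts reconcile
  expect_equal(attr(res$report, "n_retained") + attr(res$report, "n_excluded"),
               nrow(res$report))
})

test_that("the LOD rule needs a mask unless disabled", {
  md <- tiny_metadata(2, 2)
  v <- named_matrix(runif(8, 1, 2), md$sample_id, c("a", "b"))
  d1 <- tiny_table(v, "metabolite", "D1")
  d7 <- tiny_table(v + 1, "metabolite", "D7")
  expect_error(filter_metabolites(d1, d7, md), "mask")
  res <- filter_metabolites(d1, d7, md, min_above_lod_frac = 0)
  expect_setequal(res$retained, c("a", "b"))
})

test_that("the preset's designed QC truth is recovered exactly", {
  co <- septic_shock_cohort(seed = 8)
  res <- filter_metabolites(co$tables$metabolite_D1, co$tables$metabolite_D7,
                            co$metadata)
  expect_length(res$retained, 137)
  expect_setequal(res$retained, co$truth$qc$pass)
  excluded <- res$report[!res$report$retained, ]
  expect_true(all(
    co$truth$qc$fail_missing %in%
      excluded$feature_id[grepl("missingness_rule", excluded$reasons)]
  ))
  expect_true(all(
    co$truth$qc$fail_lod %in%
      excluded$feature_id[grepl("lod_rule", excluded$reasons)]
  ))
})

test_that("protein selection rules and LOESS normalization behave", {
  sim <- simulate_protein_experiment(n_samples = 12, n_proteins = 40,
                                     bias_amplitude = 0, n_partial = 3,
                                     n_lowpep = 2, n_contaminant = 2,
                                     seed = 4)
  res <- normalize_proteins(sim$raw, sim$evidence)
  rep <- res$report
  expect_equal(sum(!rep$retained), 7)
  expect_match(rep$reasons[rep$feature_id == "PROT_038"], "evidence_rule")
  expect_match(rep$reasons[rep$feature_id == "PROT_034"], "contaminant_rule")
  expect_equal(ncol(res$table$values), 33)
  # nonpositive intensities are rejected with the cell location
  bad <- sim$raw
  bad[2, 3] <- 0
  expect_error(normalize_proteins(bad, sim$evidence), "PROT_003")
})

test_that("LOESS normalization is a near-identity on unbiased data and removes an injected bias", {
  clean <- simulate_protein_experiment(n_samples = 16, n_proteins = 200,
                                       bias_amplitude = 0, seed = 10)
  res <- normalize_proteins(clean$raw, clean$evidence)
  # unbiased data: the fitted correction is a wiggle around 0
  expect_lt(max(abs(res$table$values - log2(clean$raw))), 0.35)

  biased <- simulate_protein_experiment(n_samples = 16, n_proteins = 200,
                                        bias_amplitude = 2, seed = 10)
  res_b <- normalize_proteins(biased$raw, biased$evidence)
  # amplitude of the smooth per-sample intensity-dependent trend,
  # before and after normalization
  trend_amplitude <- function(mat) {
    ref <- colMeans(mat)
    mean(vapply(seq_len(nrow(mat)), function(i) {
      fit <- stats::loess((mat[i, ] - ref) ~ ref, span = 0.75, degree = 1)
      mean(abs(stats::fitted(fit)))
    }, numeric(1)))
  }
  amp_pre <- trend_amplitude(log2(biased$raw))
  amp_post <- trend_amplitude(res_b$table$values)
  expect_lt(amp_post, 0.1 * amp_pre)
  # and the cell-level distortion shrinks substantially towards the truth
  truth <- log2(biased$raw) - biased$bias
  expect_lt(mean(abs(res_b$table$values - truth)),
            0.3 * mean(abs(biased$bias)))
})

test_that("a sample already equal to the reference is left unchanged", {
  mu <- seq(12, 18, length.out = 120)
  raw <- rbind(matrix(2^(rep(mu, each = 7) +
                           rnorm(7 * 120, 0, 0.4)), 7, byrow = FALSE),
               2^mu)
  # fixed point of the reference: the mean of the other rows
  raw[8, ] <- 2^colMeans(log2(raw[1:7, , drop = FALSE]))
  dimnames(raw) <- list(sprintf("P%02d", 1:8), sprintf("PROT_%03d", 1:120))
  ev <- protein_evidence(colnames(raw),
                         matrix(TRUE, 120, 6), rep(3L, 120),
                         rep(FALSE, 120))
  res <- normalize_proteins(raw, ev)
  expect_lt(max(abs(res$table$values[8, ] - log2(raw[8, ]))), 1e-8)
})

test_that("D7/D1 ratios follow their definition and equivariances", {
  md <- tiny_metadata(2, 2)
  ids <- md$sample_id
  v1 <- named_matrix(c(2, 2, 2, 2, 4, 4, 4, 4), ids, c("a", "b"))
  v7 <- named_matrix(c(1, 1, 1, 1, 4, 4, 4, 4), ids, c("a", "b"))
  rt <- compute_ratios(tiny_table(v1, "clinical", "D1"),
                       tiny_table(v7, "clinical", "D7"), md)
  expect_equal(unname(rt$values[, "a"]), rep(0.5, 4))
  expect_equal(unname(rt$values[, "b"]), rep(1, 4))

  # scaling all D7 values of a feature by c scales its ratios by c
  v7c <- v7
  v7c[, "a"] <- v7[, "a"] * 3
  rt_c <- compute_ratios(tiny_table(v1, "clinical", "D1"),
                         tiny_table(v7c, "clinical", "D7"), md)
  expect_equal(rt_c$values[, "a"], rt$values[, "a"] * 3, tolerance = 1e-12)

  # a patient present at one time point only is an error naming it
  v7m <- v7[-1, , drop = FALSE]
  expect_error(
    compute_ratios(tiny_table(v1, "clinical", "D1"),
                   tiny_table(v7m, "clinical", "D7"), md),
    ids[1]
  )
})

test_that("a planted shift of -1 halves the NS median ratio", {
  spec <- clean_spec(
    n_survivors = 300, n_nonsurvivors = 300, n_metabolites = 4,
    n_proteins = 2, n_clinical = 2,
    planted_features = list(planted_effect("MET_002", "metabolite", -1)),
    seed = 21
  )
  co <- generate_cohort(spec)
  rt <- compute_ratios(co$tables$metabolite_D1, co$tables$metabolite_D7,
                       co$metadata)
  grp <- rt$group[rownames(rt$values)]
  ratio_of_medians <- stats::median(rt$values[grp == "NS", "MET_002"]) /
    stats::median(rt$values[grp == "S", "MET_002"])
  expect_gt(ratio_of_medians, 0.45)
  expect_lt(ratio_of_medians, 0.55)
})

test_that("censored cells are imputed at half LOD before division", {
  md <- tiny_metadata(2, 1)
  ids <- md$sample_id
  v1 <- named_matrix(c(10, 0.4, 10), ids, "a")
  v7 <- named_matrix(c(10, 10, 10), ids, "a")
  m1 <- named_matrix(c(FALSE, TRUE, FALSE), ids, "a")
  d1 <- tiny_table(v1, "metabolite", "D1", below_lod_mask = m1,
                   lod = c(a = 1))
  d7 <- tiny_table(v7, "metabolite", "D7",
                   below_lod_mask = named_matrix(rep(FALSE, 3), ids, "a"),
                   lod = c(a = 1))
  rt <- compute_ratios(d1, d7, md)
  expect_equal(unname(rt$values[2, "a"]), 10 / 0.5)
  # strict mode drops the feature instead
  rt_drop <- compute_ratios(d1, d7, md, lod_impute = "drop")
  expect_equal(ncol(rt_drop$values), 0)
  expect_match(rt_drop$report$reasons[1], "zero_denominator")
})

test_that("z-scoring fits on training rows and applies elsewhere", {
  tr <- named_matrix(c(1, 2, 3, 10, 20, 30), c("a", "b", "c"),
                     c("f1", "f2"))
  te <- named_matrix(c(2, 20), "d", c("f1", "f2"))
  zs <- zscore(tr, test = te)
  expect_equal(unname(zs$train[, "f1"]), c(-1, 0, 1))
  expect_equal(unname(zs$test[1, "f1"]), 0)
  # idempotence on an already standardized column
  zs2 <- zscore(zs$train)
  expect_equal(zs2$train, zs$train, tolerance = 1e-12)
  # constant columns are dropped with a warning
  tr_const <- cbind(tr, const = c(7, 7, 7))
  expect_warning(zs3 <- zscore(tr_const), "const")
  expect_false("const" %in% colnames(zs3$train))
})

test_that("filters are order-independent", {
  co <- septic_shock_cohort(seed = 12)
  d1 <- co$tables$metabolite_D1
  d7 <- co$tables$metabolite_D7
  both <- filter_metabolites(d1, d7, co$metadata)
  only_miss <- filter_metabolites(d1, d7, co$metadata, min_above_lod_frac = 0)
  only_lod <- filter_metabolites(d1, d7, co$metadata, max_missing_frac = 1 + 1e-9)
  expect_setequal(both$retained,
                  intersect(only_miss$retained, only_lod$retained))
})
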