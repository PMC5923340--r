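#' Composition of the targeted metabolite panel
#'
#' Class composition of the 186-analyte targeted assay the generator
#' emulates: amino acids and biogenic amines, acylcarnitines,
#' glycerophospholipids, sphingomyelins and one monosaccharide.
#'
#' @return Data frame with columns `class`, `prefix`, `n`.
#' @export
metabolite_panel_composition <- function() {
  data.frame(
    class = c("amino_acids_biogenic_amines", "acylcarnitines",
              "glycerophospholipids", "sphingomyelins", "hexoses"),
    prefix = c("AA", "AC", "GPL", "SM", "HEX"),
    n = c(40L, 40L, 90L, 15L, 1L)
  )
}

#' Continuous clinical variables of the cohort
#'
#' The 17 continuous clinical and laboratory variables carried by the
#' clinical layer, on their natural scales: hemodynamics (heart rate,
#' mean arterial and central venous pressure, urine output), ventilation
#' (PEEP, FiO2), blood-gas analysis (ScvO2, venous/arterial CO2 and O2
#' partial pressures, arterial and venous pH) and laboratory values
#' (creatinine, bilirubin, lactate, platelet count). Organ-failure scores
#' are deliberately absent: they are derived from these variables and
#' would only add redundancy.
#'
#' @return Data frame with columns `name`, `unit`, `mean`, `sd`, `lower`
#'   (truncation bound keeping simulated values physiological).
#' @export
clinical_variables <- function() {
  data.frame(
    name = c("heart_rate", "MAP", "CVP", "urine_output", "PEEP", "FiO2",
             "ScvO2", "PvCO2", "PaCO2", "PaO2", "PvO2", "pHa", "pHv",
             "creatinine", "bilirubin", "lactate", "platelets"),
    unit = c("bpm", "mmHg", "mmHg", "mL/day", "cmH2O", "%", "%", "mmHg",
             "mmHg", "mmHg", "mmHg", "pH", "pH", "mg/dL", "mg/dL",
             "mmol/L", "1e3/mm3"),
    mean = c(100, 75, 11, 2200, 8, 55, 75, 47, 43, 110, 44, 7.35, 7.33,
             2.2, 3.0, 3.5, 75),
    sd = c(20, 13, 4.5, 1100, 3, 15, 9, 5.5, 6, 45, 6, 0.07, 0.07,
           1.0, 2.5, 1.9, 45),
    lower = c(35, 35, 1, 100, 1, 21, 40, 20, 20, 40, 20, 6.8, 6.8,
              0.2, 0.1, 0.3, 5)
  )
}

#' Describe a planted group effect
#'
#' A planted effect shifts the expected log2(D7/D1) ratio of one feature
#' in non-survivors relative to survivors, emulating a discriminative
#' time-trend (for instance the reduction over time of circulating
#' phosphatidylcholine species in non-survivors).
#'
#' @param feature_id Feature the effect is planted on; must exist in the
#'   generated layer.
#' @param layer One of `"metabolite"`, `"protein"`, `"clinical"`.
#' @param log2_ratio_shift Difference in expected log2(D7/D1) between
#'   non-survivors and survivors.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(feature_id, layer, log2_ratio_shift) {
  layer <- match.arg(layer, c("metabolite", "protein", "clinical"))
  stopifnot(is.numeric(log2_ratio_shift), length(log2_ratio_shift) == 1L)
  structure(
    list(feature_id = as.character(feature_id), layer = layer,
         log2_ratio_shift = log2_ratio_shift,
         direction = sign(log2_ratio_shift)),
    class = "planted_effect"
  )
}

#' Specify a synthetic two-group longitudinal cohort
#'
#' Describes the statistical structure of a cohort measured at D1 and D7:
#' group sizes, features per layer, proteomics batch structure, planted
#' group-discriminative D7/D1 effects, block correlation, censoring and
#' missingness. Defaults emulate a severe septic shock cohort stratified
#' by 28-day mortality.
#'
#' @param n_survivors,n_nonsurvivors Patients per outcome group.
#' @param n_metabolites,n_proteins,n_clinical Features per layer
#'   (`n_clinical` is capped at the 17 variables of
#'   [clinical_variables()]).
#' @param n_batches Number of iTRAQ runs the patients are multiplexed in.
#' @param planted_features List of [planted_effect()] objects (may be
#'   empty).
#' @param block_rho Within-block correlation of the latent Gaussian
#'   factors, in `[0, 1)`; omics features come in correlated blocks the
#'   way lipid species of one class co-vary.
#' @param block_size Number of consecutive features sharing one latent
#'   factor.
#' @param lod_quantile Fraction of each metabolite's values flagged as
#'   below the limit of detection, in `[0, 1)`.
#' @param missing_rate_per_group Per-group probability that a metabolite
#'   measurement is missing completely at random, in `[0, 1)`.
#' @param ratio_noise_sd Standard deviation of the log2(D7/D1) noise; a
#'   planted shift of `3 * ratio_noise_sd` is a 3-sigma effect.
#' @param qc_design Optional list with integer counts `fail_missing` and
#'   `fail_lod`: that many metabolites are constructed to violate the
#'   missingness rule and the LOD rule respectively, so the QC filter has
#'   a known ground truth to recover.
#' @param seed Integer seed; identical spec and seed give bit-identical
#'   cohorts.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_survivors = 9L, n_nonsurvivors = 8L,
                        n_metabolites = 137L, n_proteins = 132L,
                        n_clinical = 17L, n_batches = 6L,
                        planted_features = list(),
                        block_rho = 0.5, block_size = 5L,
                        lod_quantile = 0.05,
                        missing_rate_per_group = 0.02,
                        ratio_noise_sd = 0.25,
                        qc_design = NULL,
                        seed = 1L) {
  spec <- list(
    n_survivors = as.integer(n_survivors),
    n_nonsurvivors = as.integer(n_nonsurvivors),
    n_metabolites = as.integer(n_metabolites),
    n_proteins = as.integer(n_proteins),
    n_clinical = as.integer(n_clinical),
    n_batches = as.integer(n_batches),
    planted_features = planted_features,
    block_rho = block_rho, block_size = as.integer(block_size),
    lod_quantile = lod_quantile,
    missing_rate_per_group = missing_rate_per_group,
    ratio_noise_sd = ratio_noise_sd,
    qc_design = qc_design,
    seed = as.integer(seed)
  )
  counts <- c("n_survivors", "n_nonsurvivors", "n_metabolites",
              "n_proteins", "n_clinical", "n_batches", "block_size")
  for (f in counts) {
    if (is.na(spec[[f]]) || spec[[f]] < 1L) {
      stop("invalid cohort spec: `", f, "` must be a count >= 1")
    }
  }
  for (f in c("lod_quantile", "missing_rate_per_group")) {
    if (!is.numeric(spec[[f]]) || spec[[f]] < 0 || spec[[f]] >= 1) {
      stop("invalid cohort spec: `", f, "` must lie in [0, 1)")
    }
  }
  if (!is.numeric(block_rho) || block_rho < 0 || block_rho >= 1) {
    stop("invalid cohort spec: `block_rho` must lie in [0, 1)")
  }
  if (!is.numeric(ratio_noise_sd) || ratio_noise_sd <= 0) {
    stop("invalid cohort spec: `ratio_noise_sd` must be > 0")
  }
  if (spec$n_clinical > nrow(clinical_variables())) {
    stop("invalid cohort spec: `n_clinical` exceeds the ",
         nrow(clinical_variables()), " available clinical variables")
  }
  for (pf in planted_features) {
    if (!inherits(pf, "planted_effect")) {
      stop("invalid cohort spec: `planted_features` must contain planted_effect objects")
    }
  }
  class(spec) <- "cohort_spec"
  spec
}

metabolite_ids <- function(n) {
  if (n == 186L) {
    comp <- metabolite_panel_composition()
    unlist(mapply(function(p, k) sprintf("%s_%02d", p, seq_len(k)),
                  comp$prefix, comp$n, SIMPLIFY = FALSE), use.names = FALSE)
  } else {
    sprintf("MET_%03d", seq_len(n))
  }
}

# block-correlated standard normal draws: features in consecutive blocks of
# `size` share a latent factor with loading sqrt(rho)
block_normal <- function(n_samples, n_features, rho, size) {
  blocks <- ceiling(seq_len(n_features) / size)
  u <- matrix(stats::rnorm(n_samples * max(blocks)), n_samples)
  e <- matrix(stats::rnorm(n_samples * n_features), n_samples)
  sqrt(rho) * u[, blocks, drop = FALSE] + sqrt(1 - rho) * e
}

#' Generate a synthetic two-group longitudinal cohort
#'
#' Draws D1 feature levels (lognormal concentrations for metabolites,
#' Gaussian log2 intensities with per-batch offsets for proteins, natural
#' scales for clinical variables), then sets
#' `D7 = D1 * 2^(shift + noise)` where the shift differs between outcome
#' groups for planted features only. Features within a block share a
#' latent Gaussian factor both at baseline and in the ratio noise, so the
#' D7/D1 modeling substrate carries the strong feature-feature
#' correlation that motivates elastic-net and mRMR machinery downstream.
#' Metabolite values below the per-feature `lod_quantile` quantile are
#' flagged censored (not deleted), and per-group missingness is applied
#' completely at random to the metabolite layer.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `tables` (named list of [omics_table()] objects,
#'   one per layer per time point), `metadata` ([cohort_metadata()]) and
#'   `truth` (planted effects and QC ground truth for recovery tests).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  set.seed(spec$seed)
  n_s <- spec$n_survivors; n_ns <- spec$n_nonsurvivors
  n <- n_s + n_ns
  ids <- c(sprintf("S%02d", seq_len(n_s)), sprintf("NS%02d", seq_len(n_ns)))
  group <- c(rep("S", n_s), rep("NS", n_ns))
  batch <- rep_len(seq_len(spec$n_batches), n)
  metadata <- cohort_metadata(data.frame(
    sample_id = ids, group = group, batch_id = batch
  ))
  ns_ind <- as.numeric(group == "NS")

  shift_vec <- function(layer, feat_ids) {
    sh <- stats::setNames(rep(0, length(feat_ids)), feat_ids)
    for (pf in spec$planted_features) {
      if (pf$layer != layer) next
      if (!pf$feature_id %in% feat_ids) {
        stop("planted feature '", pf$feature_id,
             "' does not exist in the ", layer, " layer")
      }
      sh[pf$feature_id] <- pf$log2_ratio_shift
    }
    sh
  }
  ## --- metabolites -------------------------------------------------------
  p_m <- spec$n_metabolites
  met_ids <- metabolite_ids(p_m)
  mu <- stats::runif(p_m, log(0.1), log(100))
  sdev <- stats::runif(p_m, 0.3, 0.8)
  z <- block_normal(n, p_m, spec$block_rho, spec$block_size)
  d1_met <- exp(sweep(sweep(z, 2L, sdev, "*"), 2L, mu, "+"))
  dimnames(d1_met) <- list(ids, met_ids)
  sh_m <- shift_vec("metabolite", met_ids)
  l2r <- spec$ratio_noise_sd * block_normal(n, p_m, spec$block_rho, spec$block_size) +
    outer(ns_ind, sh_m)
  d7_met <- d1_met * 2^l2r
  dimnames(d7_met) <- dimnames(d1_met)

  # censoring: per-feature LOD at the lod_quantile quantile of all values
  pooled <- rbind(d1_met, d7_met)
  lod <- apply(pooled, 2L, stats::quantile, probs = spec$lod_quantile,
               type = 7, names = FALSE)
  names(lod) <- met_ids
  mask_d1 <- sweep(d1_met, 2L, lod, "<")
  mask_d7 <- sweep(d7_met, 2L, lod, "<")

  # per-group MCAR missingness (metabolite layer: non-detectable peaks)
  miss_d1 <- matrix(stats::runif(n * p_m) < spec$missing_rate_per_group, n,
                    dimnames = dimnames(d1_met))
  miss_d7 <- matrix(stats::runif(n * p_m) < spec$missing_rate_per_group, n,
                    dimnames = dimnames(d1_met))

  qc_truth <- NULL
  if (!is.null(spec$qc_design)) {
    nf_miss <- spec$qc_design$fail_missing %||% 0L
    nf_lod <- spec$qc_design$fail_lod %||% 0L
    if (nf_miss + nf_lod > p_m) stop("qc_design exceeds number of metabolites")
    fail_miss_ids <- met_ids[seq_len(nf_miss)]
    fail_lod_ids <- met_ids[nf_miss + seq_len(nf_lod)]
    pass_ids <- setdiff(met_ids, c(fail_miss_ids, fail_lod_ids))
    # designed failures of the missingness rule: >= 20% missing in group S
    need <- ceiling(0.2 * 2 * n_s) + 1L
    s_rows <- which(group == "S")
    for (f in fail_miss_ids) {
      take <- rep(s_rows, 2L)[seq_len(need)]
      tp <- rep(c(1L, 2L), each = length(s_rows))[seq_len(need)]
      miss_d1[take[tp == 1L], f] <- TRUE
      miss_d7[take[tp == 2L], f] <- TRUE
    }
    # designed failures of the LOD rule: < 50% of all values above LOD
    need_lod <- ceiling(0.5 * 2 * n) + 1L
    for (f in fail_lod_ids) {
      cells <- seq_len(need_lod)
      for (ci in cells) {
        if (ci <= n) mask_d1[ci, f] <- TRUE else mask_d7[ci - n, f] <- TRUE
      }
    }
    # designed passes: cap random missingness under the 20% rule
    cap <- max(0L, ceiling(0.2 * 2 * min(n_s, n_ns)) - 1L)
    for (g in c("S", "NS")) {
      rows <- which(group == g)
      for (f in pass_ids) {
        hit <- c(which(miss_d1[rows, f]), n + which(miss_d7[rows, f]))
        if (length(hit) > cap) {
          drop <- hit[-seq_len(cap)]
          miss_d1[rows[drop[drop <= n]], f] <- FALSE
          d7drop <- drop[drop > n] - n
          miss_d7[rows[d7drop], f] <- FALSE
        }
      }
    }
    qc_truth <- list(fail_missing = fail_miss_ids, fail_lod = fail_lod_ids,
                     pass = pass_ids)
  }
  d1_met[miss_d1] <- NA_real_
  d7_met[miss_d7] <- NA_real_
  mask_d1[miss_d1] <- FALSE
  mask_d7[miss_d7] <- FALSE

  ## --- proteins ----------------------------------------------------------
  p_p <- spec$n_proteins
  prot_ids <- sprintf("PROT_%03d", seq_len(p_p))
  mu_p <- stats::runif(p_p, 12, 18)
  sd_p <- stats::runif(p_p, 0.3, 0.8)
  zp <- block_normal(n, p_p, spec$block_rho, spec$block_size)
  batch_off <- stats::rnorm(spec$n_batches, 0, 0.3)
  d1_prot <- sweep(sweep(zp, 2L, sd_p, "*"), 2L, mu_p, "+") + batch_off[batch]
  dimnames(d1_prot) <- list(ids, prot_ids)
  sh_p <- shift_vec("protein", prot_ids)
  l2r_p <- spec$ratio_noise_sd * block_normal(n, p_p, spec$block_rho, spec$block_size) +
    outer(ns_ind, sh_p)
  # intensities are stored on log2 scale; a log2-ratio shift moves the
  # stored value additively
  d7_prot <- d1_prot + l2r_p
  dimnames(d7_prot) <- dimnames(d1_prot)

  ## --- clinical ----------------------------------------------------------
  cv <- clinical_variables()[seq_len(spec$n_clinical), ]
  zc <- block_normal(n, spec$n_clinical, 0, 1L)
  d1_clin <- sweep(sweep(zc, 2L, cv$sd, "*"), 2L, cv$mean, "+")
  d1_clin <- pmax(d1_clin, matrix(cv$lower, n, spec$n_clinical, byrow = TRUE))
  dimnames(d1_clin) <- list(ids, cv$name)
  sh_c <- shift_vec("clinical", cv$name)
  l2r_c <- spec$ratio_noise_sd * matrix(stats::rnorm(n * spec$n_clinical), n) +
    outer(ns_ind, sh_c)
  d7_clin <- d1_clin * 2^l2r_c
  dimnames(d7_clin) <- dimnames(d1_clin)

  tables <- list(
    metabolite_D1 = omics_table(d1_met, "metabolite", "D1",
                                below_lod_mask = mask_d1, lod = lod),
    metabolite_D7 = omics_table(d7_met, "metabolite", "D7",
                                below_lod_mask = mask_d7, lod = lod),
    protein_D1 = omics_table(d1_prot, "protein", "D1"),
    protein_D7 = omics_table(d7_prot, "protein", "D7"),
    clinical_D1 = omics_table(d1_clin, "clinical", "D1"),
    clinical_D7 = omics_table(d7_clin, "clinical", "D7")
  )
  validate_cohort(tables, metadata)
  list(tables = tables, metadata = metadata,
       truth = list(planted = spec$planted_features, qc = qc_truth,
                    spec = spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset cohort mirroring the study population
#'
#' Convenience preset for a 17-patient severe septic shock cohort: 9
#' survivors and 8 non-survivors, a 186-analyte metabolite panel of which
#' exactly 137 pass the quality-control filters, 132 proteins from 6
#' iTRAQ runs, the 17 continuous clinical variables, and about ten
#' planted 3-sigma D7/D1 effects split across layers (6 metabolites, 4
#' proteins, 2 clinical). Metadata additionally carries a `source_of_infection`
#' covariate with the group-specific frequencies typical of such a
#' cohort (lungs dominating among non-survivors, genitourinary sources
#' among survivors).
#'
#' @param seed Integer seed.
#' @return Same structure as [generate_cohort()].
#' @export
septic_shock_cohort <- function(seed = 1L) {
  met_ids <- metabolite_ids(186L)
  # metabolites 1..49 are the designed QC failures; plant on passing
  # features in distinct correlation blocks
  pass_ids <- met_ids[-seq_len(49L)]
  planted <- c(
    lapply(seq_len(6L), function(i) {
      planted_effect(pass_ids[1L + (i - 1L) * 10L], "metabolite",
                     if (i == 4L) 0.75 else -0.75)
    }),
    lapply(seq_len(4L), function(i) {
      planted_effect(sprintf("PROT_%03d", 1L + (i - 1L) * 10L), "protein",
                     if (i == 3L) 0.75 else -0.75)
    }),
    list(planted_effect("MAP", "clinical", -0.75),
         planted_effect("CVP", "clinical", 0.75))
  )
  spec <- cohort_spec(
    n_survivors = 9L, n_nonsurvivors = 8L,
    n_metabolites = 186L, n_proteins = 132L, n_clinical = 17L,
    n_batches = 6L, planted_features = planted,
    qc_design = list(fail_missing = 25L, fail_lod = 24L),
    seed = seed
  )
  cohort <- generate_cohort(spec)
  cohort$metadata$source_of_infection <- c(
    # 9 survivors: genitourinary-dominated; 8 non-survivors: lungs-dominated
    rep("genitourinary", 5L), rep("abdomen", 3L), "lungs",
    rep("lungs", 5L), rep("abdomen", 2L), "other"
  )
  cohort
}

#' Simulate a raw multi-batch iTRAQ protein experiment
#'
#' Produces positive raw peak intensities with a known smooth
#' intensity-dependent bias injected per sample, plus the protein
#' evidence (per-batch detection, unique peptide counts, contaminant
#' flags) the selection rules act on. Used to exercise the LOESS
#' normalization: the injected bias is the ground truth the
#' normalization must remove.
#'
#' @param n_samples,n_proteins,n_batches Experiment dimensions.
#' @param bias_amplitude Amplitude (log2 units) of the per-sample smooth
#'   bias as a function of mean log2 intensity; 0 disables the bias.
#' @param n_partial Proteins detected in only a subset of batches.
#' @param n_lowpep Proteins quantified with a single unique peptide.
#' @param n_contaminant Proteins flagged as depletion-target contaminants.
#' @param seed Integer seed.
#' @return List with `raw` (samples x proteins positive intensities),
#'   `evidence` (a [protein_evidence()] object), `batch` (per-sample
#'   batch id) and `bias` (the injected per-cell log2 bias).
#' @export
simulate_protein_experiment <- function(n_samples = 17L, n_proteins = 60L,
                                        n_batches = 6L, bias_amplitude = 0,
                                        n_partial = 0L, n_lowpep = 0L,
                                        n_contaminant = 0L, seed = 1L) {
  set.seed(seed)
  prot_ids <- sprintf("PROT_%03d", seq_len(n_proteins))
  ids <- sprintf("P%02d", seq_len(n_samples))
  mu <- stats::runif(n_proteins, 12, 18)
  log2_true <- sweep(matrix(stats::rnorm(n_samples * n_proteins, 0, 0.5),
                            n_samples), 2L, mu, "+")
  # smooth per-sample bias as a function of protein abundance level
  rng <- range(mu)
  coefs <- stats::runif(n_samples, -1, 1)
  rel <- (mu - rng[1L]) / diff(rng)
  bias <- bias_amplitude * outer(coefs, sin(pi * rel))
  log2_obs <- log2_true + bias
  raw <- 2^log2_obs
  dimnames(raw) <- list(ids, prot_ids)
  detected <- matrix(TRUE, n_proteins, n_batches,
                     dimnames = list(prot_ids, NULL))
  unique_peptides <- stats::rpois(n_proteins, 6L) + 2L
  is_contaminant <- rep(FALSE, n_proteins)
  idx <- seq_len(n_proteins)
  if (n_partial > 0L) {
    take <- utils::tail(idx, n_partial)
    for (i in take) detected[i, sample.int(n_batches, 1L)] <- FALSE
    idx <- setdiff(idx, take)
  }
  if (n_lowpep > 0L) {
    take <- utils::tail(idx, n_lowpep)
    unique_peptides[take] <- 1L
    idx <- setdiff(idx, take)
  }
  if (n_contaminant > 0L) {
    is_contaminant[utils::tail(idx, n_contaminant)] <- TRUE
  }
  list(
    raw = raw,
    evidence = protein_evidence(prot_ids, detected, unique_peptides,
                                is_contaminant),
    batch = rep_len(seq_len(n_batches), n_samples),
    bias = bias
  )
}

#' Protein identification evidence
#'
#' Bookkeeping the protein selection rules operate on: in which iTRAQ
#' runs a protein was detected, how many unique peptides supported its
#' quantification, and whether it is a known depletion-target
#' contaminant.
#'
#' @param protein_id Character vector of protein ids.
#' @param detected Logical matrix, proteins x batches.
#' @param unique_peptides Non-negative integer vector.
#' @param is_contaminant Logical vector.
#' @return A `protein_evidence` object.
#' @export
protein_evidence <- function(protein_id, detected, unique_peptides,
                             is_contaminant) {
  protein_id <- as.character(protein_id)
  p <- length(protein_id)
  if (!is.matrix(detected) || nrow(detected) != p) {
    stop("`detected` must be a proteins x batches logical matrix")
  }
  if (length(unique_peptides) != p || any(unique_peptides < 0)) {
    stop("`unique_peptides` must be non-negative, one per protein")
  }
  if (length(is_contaminant) != p) {
    stop("`is_contaminant` must have one flag per protein")
  }
  rownames(detected) <- protein_id
  structure(
    list(protein_id = protein_id, detected = detected,
         unique_peptides = stats::setNames(unique_peptides, protein_id),
         is_contaminant = stats::setNames(is_contaminant, protein_id)),
    class = "protein_evidence"
  )
}
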