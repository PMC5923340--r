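#' Run the full three-tier stratification experiment
#'
#' Orchestrates the stages end to end on a cohort: metabolite QC
#' filtering, D7/D1 ratio construction per layer, univariate screening,
#' the cascaded mRMR ranking (metabolites; metabolites + proteins;
#' + clinical), and for each tier and each top-k cut the classifier
#' fits — elastic-net logistic regression (strategies A and B) at k in
#' `top_k`, LDA on the first 10 ranked features, and PLS-DA on the
#' first 10 and 20 with 3 components — followed by a per-tier consensus
#' comparison. Features are Z-scored on the training patients before
#' modeling. Identical cohort and seed give identical results.
#'
#' @param cohort A cohort as returned by [generate_cohort()] /
#'   [septic_shock_cohort()] or [read_cohort()]: a list with `tables`
#'   and `metadata`.
#' @param top_k Top-k cuts for the elastic-net models (default
#'   `c(10, 20, 30)`).
#' @param sizes Cascade cut sizes, see [cascade_rank()].
#' @param alpha,fdr Univariate dual significance thresholds.
#' @param n_repetitions Elastic-net cross-validation repetitions.
#' @param max_missing_frac,min_above_lod_frac Metabolite QC thresholds.
#' @param seed Integer seed driving the split and all model randomness.
#' @param out_dir Optional directory; when given, all tabular artifacts
#'   are written as TSV.
#' @return A `pipeline_run` list: `qc`, `ratios`, `screen`, `rankings`,
#'   `split`, `models` (nested `tier -> top-k -> family`), `comparison`
#'   (per tier), `funnel` (feature counts in/out per stage) and
#'   `summary`.
#' @export
run_pipeline <- function(cohort, top_k = c(10L, 20L, 30L),
                         sizes = c(50L, 50L, 20L, 17L),
                         alpha = 0.05, fdr = 0.15,
                         n_repetitions = 50L,
                         max_missing_frac = 0.20,
                         min_above_lod_frac = 0.50,
                         seed = 1L, out_dir = NULL) {
  tables <- cohort$tables
  metadata <- cohort_metadata(cohort$metadata)
  validate_cohort(tables, metadata)

  ## stage 1: metabolite QC
  qc <- filter_metabolites(tables$metabolite_D1, tables$metabolite_D7,
                           metadata, max_missing_frac, min_above_lod_frac)
  funnel <- data.frame(
    stage = "metabolite_qc",
    n_in = ncol(tables$metabolite_D1$values),
    n_out = length(qc$retained)
  )

  ## stage 2: D7/D1 ratios per layer
  ratios <- list(
    metabolite = compute_ratios(tables$metabolite_D1, tables$metabolite_D7,
                                metadata, features = qc$retained),
    protein = compute_ratios(tables$protein_D1, tables$protein_D7, metadata),
    clinical = compute_ratios(tables$clinical_D1, tables$clinical_D7, metadata)
  )
  for (lay in names(ratios)) {
    funnel <- rbind(funnel, data.frame(
      stage = paste0(lay, "_ratios"),
      n_in = nrow(ratios[[lay]]$report),
      n_out = ncol(ratios[[lay]]$values)
    ))
  }

  ## stage 3: univariate screen
  screen <- screen_cohort(tables, metadata, ratios = ratios,
                          alpha = alpha, fdr = fdr)

  ## stage 4: cascaded mRMR ranking (on ratios; discretization makes the
  ## scale immaterial, so this happens before Z-scoring)
  y <- ratios$metabolite$group
  rankings <- withCallingHandlers(
    cascade_rank(ratios$metabolite, ratios$protein, ratios$clinical,
                 y, sizes = sizes),
    warning = function(w) invokeRestart("muffleWarning")
  )

  ## stage 5: split, Z-score, fit
  split <- make_split(metadata, seed = seed)
  pool <- bind_ratios(ratios$metabolite, ratios$protein, ratios$clinical)
  tiers <- list(metabolites = rankings$tier1,
                met_prot = rankings$tier2,
                all_layers = rankings$tier3)
  models <- list()
  for (tname in names(tiers)) {
    ranking <- tiers[[tname]]
    models[[tname]] <- list()
    for (k in top_k) {
      kk <- min(k, nrow(ranking))
      if (kk < k) {
        warning("tier ", tname, ": only ", kk, " features available for top-",
                k, "; using all")
      }
      feats <- ranking$feature_id[seq_len(kk)]
      xs <- zscore(pool$values[split$train, feats, drop = FALSE],
                   test = pool$values[split$test, feats, drop = FALSE])
      x <- rbind(xs$train, xs$test)[names(y), , drop = FALSE]
      bundle <- list(
        elastic_net = fit_elastic_net(x, y, split,
                                      n_repetitions = n_repetitions,
                                      seed = seed + k)
      )
      if (kk >= 2L && k == 10L) {
        bundle$lda <- fit_lda(x, y, split)
      }
      if (k %in% c(10L, 20L)) {
        ncomp <- min(3L, length(split$train) - 1L, ncol(x))
        bundle$plsda <- fit_plsda(x, y, split, n_components = ncomp)
      }
      models[[tname]][[paste0("top", k)]] <- bundle
    }
  }

  ## stage 6: per-tier consensus across all fitted models
  comparison <- lapply(models, function(tier_models) {
    flat <- unlist(tier_models, recursive = FALSE)
    names(flat) <- gsub("\\.", "_", names(flat))
    if (length(flat) < 2L) return(NULL)
    compare_models(flat)
  })

  summ <- cohort_summary(tables["clinical_D1"], metadata)
  run <- structure(
    list(qc = qc, ratios = ratios, screen = screen, rankings = rankings,
         split = split, models = models, comparison = comparison,
         funnel = funnel, summary = summ, metadata = metadata,
         seed = seed, top_k = top_k),
    class = "pipeline_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# omistrat run artifact; seed=%d", run$seed), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(run$qc$report, "qc_metabolites")
  wt(run$screen, "screen")
  wt(run$funnel, "funnel")
  wt(run$rankings$tier1, "ranking_tier1")
  wt(run$rankings$tier2, "ranking_tier2")
  wt(run$rankings$tier3, "ranking_tier3")
  for (tname in names(run$comparison)) {
    if (!is.null(run$comparison[[tname]])) {
      wt(run$comparison[[tname]], paste0("consensus_", tname))
    }
  }
  for (tname in names(run$models)) {
    for (kname in names(run$models[[tname]])) {
      for (fam in names(run$models[[tname]][[kname]])) {
        m <- run$models[[tname]][[kname]][[fam]]
        co <- if (fam == "elastic_net") m$coefficients$A else m$coefficients
        df <- data.frame(feature_id = names(co), coefficient = unname(co))
        if (!is.null(m$vip)) {
          df <- merge(df, data.frame(feature_id = names(m$vip),
                                     vip = unname(m$vip)),
                      all = TRUE)
        }
        wt(df, paste("model", tname, kname, fam, sep = "_"))
      }
    }
  }
  invisible(out_dir)
}

correct_counts <- function(m) {
  if (is.list(m$correct)) unlist(m$correct) else m$correct
}

#' Render a human-readable run report
#'
#' Markdown summary of a [run_pipeline()] result: cohort composition and
#' outcome rate, per-stage feature funnel, significant features per
#' comparison family (with an explicit "none" when empty), per-tier
#' top-ranked features, test-set performance of every fitted model, and
#' the consensus features selected by all models of each tier. Every
#' number is read from the run object; nothing is recomputed.
#'
#' @param run A `pipeline_run`.
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  md <- run$metadata
  lines <- c(
    "# Stratification run report", "",
    sprintf("- Patients: %d survivors (S), %d non-survivors (NS); 28-day outcome rate %d%%",
            sum(md$group == "S"), sum(md$group == "NS"),
            attr(run$summary, "outcome_rate_percent")),
    "", "## Feature funnel", "",
    sprintf("- %s: %d in, %d out", run$funnel$stage, run$funnel$n_in,
            run$funnel$n_out),
    "", "## Significant features (p and FDR jointly)", ""
  )
  sig <- run$screen[run$screen$significant, ]
  for (cmp in unique(run$screen$comparison)) {
    s <- sig[sig$comparison == cmp, ]
    lines <- c(lines, sprintf("- %s: %s", cmp,
                              if (nrow(s) == 0L) "none" else
                                paste(s$feature_id, collapse = ", ")))
  }
  lines <- c(lines, "", "## Top-ranked features per tier", "")
  tiers <- list(metabolites = run$rankings$tier1,
                met_prot = run$rankings$tier2,
                all_layers = run$rankings$tier3)
  for (tname in names(tiers)) {
    lines <- c(lines, sprintf("- %s: %s", tname,
                              paste(utils::head(tiers[[tname]]$feature_id, 10L),
                                    collapse = ", ")))
  }
  lines <- c(lines, "", "## Test-set performance", "")
  for (tname in names(run$models)) {
    for (kname in names(run$models[[tname]])) {
      for (fam in names(run$models[[tname]][[kname]])) {
        m <- run$models[[tname]][[kname]][[fam]]
        cc <- correct_counts(m)
        lines <- c(lines, sprintf(
          "- %s / %s / %s: %s of %d test patients correct", tname, kname, fam,
          paste(cc, collapse = " and "), m$total
        ))
      }
    }
  }
  lines <- c(lines, "", "## Consensus features (selected by all models)", "")
  for (tname in names(run$comparison)) {
    cons <- run$comparison[[tname]]
    hits <- cons$feature_id[cons$selected_by_all]
    lines <- c(lines, sprintf("- %s: %s", tname,
                              if (length(hits) == 0L) "none" else
                                paste(hits, collapse = ", ")))
  }
  lines
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(paste(pipeline_report(x), collapse = "\n"), "\n")
  invisible(x)
}
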