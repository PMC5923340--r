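# Small in-code fixtures shared across test files.

tiny_metadata <- function(n_s = 3L, n_ns = 3L) {
  cohort_metadata(data.frame(
    sample_id = c(sprintf("S%02d", seq_len(n_s)),
                  sprintf("NS%02d", seq_len(n_ns))),
    group = c(rep("S", n_s), rep("NS", n_ns))
  ))
}

tiny_table <- function(values, layer = "metabolite", timepoint = "D1", ...) {
  omics_table(values, layer, timepoint, ...)
}

named_matrix <- function(data, sample_ids, feature_ids) {
  matrix(data, nrow = length(sample_ids),
         dimnames = list(sample_ids, feature_ids))
}

split_fixture <- function(n_s = 9, n_ns = 8, seed = 1) {
  md <- tiny_metadata(n_s, n_ns)
  list(md = md, split = make_split(md, seed = seed))
}

# Gaussian two-class data with a mean shift on the first p_signal features.
separable_data <- function(n_s = 30, n_ns = 30, p = 6, p_signal = 3,
                           shift = 2, seed = 1) {
  set.seed(seed)
  md <- tiny_metadata(n_s, n_ns)
  x <- matrix(rnorm((n_s + n_ns) * p), n_s + n_ns,
              dimnames = list(md$sample_id, paste0("f", seq_len(p))))
  y <- stats::setNames(md$group, md$sample_id)
  x[y == "NS", seq_len(p_signal)] <- x[y == "NS", seq_len(p_signal)] + shift
  list(x = x, y = y, md = md)
}

# A clean cohort spec (no censoring, no missingness) for moment and
# calibration checks.
clean_spec <- function(...) {
  args <- list(...)
  defaults <- list(lod_quantile = 0, missing_rate_per_group = 0,
                   block_rho = 0, block_size = 1L)
  do.call(cohort_spec, utils::modifyList(defaults, args))
}

log2_ratio_matrix <- function(cohort, layer = "metabolite") {
  d1 <- cohort$tables[[paste0(layer, "_D1")]]$values
  d7 <- cohort$tables[[paste0(layer, "_D7")]]$values
  if (layer == "protein") d7 - d1 else log2(d7 / d1)
}
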