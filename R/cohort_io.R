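#' Feature table for one omics layer at one time point
#'
#' An `omics_table` holds a samples x features matrix for a single layer
#' (metabolite, protein or clinical) at a single sampling time point (D1 or
#' D7), together with the semantics of its values and, for metabolite
#' layers, an optional below-limit-of-detection (LOD) mask and per-feature
#' LOD values.
#'
#' Value semantics are layer-specific: metabolite concentrations are
#' absolute (micromolar) and strictly positive where observed, protein
#' values are log2-scale normalized peak intensities, and clinical
#' variables live on their natural scales (mmHg, mmol/L, ...). Missing
#' measurements are stored as `NA`, never as zero.
#'
#' @param values Numeric matrix, samples in rows, features in columns. Row
#'   and column names are required and must be unique.
#' @param layer One of `"metabolite"`, `"protein"`, `"clinical"`.
#' @param timepoint One of `"D1"`, `"D7"`.
#' @param value_semantics One of `"concentration_uM"`, `"log2_intensity"`,
#'   `"clinical_native"`. Defaults to the conventional semantics of the
#'   layer.
#' @param below_lod_mask Optional logical matrix of the same shape as
#'   `values` flagging censored (below-LOD) metabolite measurements.
#' @param lod Optional named numeric vector of per-feature LOD values
#'   (metabolite layers only).
#'
#' @return An object of class `omics_table`.
#' @export
omics_table <- function(values, layer, timepoint,
                        value_semantics = NULL,
                        below_lod_mask = NULL,
                        lod = NULL) {
  layer <- match.arg(layer, c("metabolite", "protein", "clinical"))
  timepoint <- match.arg(timepoint, c("D1", "D7"))
  if (is.null(value_semantics)) {
    value_semantics <- switch(layer,
      metabolite = "concentration_uM",
      protein = "log2_intensity",
      clinical = "clinical_native"
    )
  }
  value_semantics <- match.arg(
    value_semantics,
    c("concentration_uM", "log2_intensity", "clinical_native")
  )
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x features)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry sample ids as rownames and feature ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample id: ", rownames(values)[duplicated(rownames(values))][1L])
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate feature id: ", colnames(values)[duplicated(colnames(values))][1L])
  }
  if (value_semantics == "concentration_uM") {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad)) {
      stop("concentration values must be > 0 or missing; offending cell [",
           rownames(values)[row(values)[bad[1L]]], ", ",
           colnames(values)[col(values)[bad[1L]]], "]")
    }
  }
  if (!is.null(below_lod_mask)) {
    if (!is.logical(below_lod_mask) || !identical(dim(below_lod_mask), dim(values))) {
      stop("`below_lod_mask` must be a logical matrix with the shape of `values`")
    }
    dimnames(below_lod_mask) <- dimnames(values)
  }
  if (!is.null(lod)) {
    lod <- lod[colnames(values)]
    names(lod) <- colnames(values)
  }
  structure(
    list(values = values, layer = layer, timepoint = timepoint,
         value_semantics = value_semantics,
         below_lod_mask = below_lod_mask, lod = lod),
    class = "omics_table"
  )
}

#' @export
dim.omics_table <- function(x) dim(x$values)

#' @export
print.omics_table <- function(x, ...) {
  cat(sprintf("<omics_table> %s @ %s: %d samples x %d features (%s)\n",
              x$layer, x$timepoint, nrow(x$values), ncol(x$values),
              x$value_semantics))
  if (!is.null(x$below_lod_mask)) {
    cat(sprintf("  below-LOD cells: %d\n", sum(x$below_lod_mask, na.rm = TRUE)))
  }
  invisible(x)
}

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

#' Cohort metadata: outcome labels and batch structure
#'
#' One row per patient with the 28-day mortality group (`S` survivor /
#' `NS` non-survivor), the iTRAQ proteomics batch the patient's samples
#' were multiplexed in, and optional per-patient covariates (age, BMI,
#' source of infection, ...).
#'
#' @param df Data frame with at least columns `sample_id` and `group`;
#'   `batch_id` and further covariate columns are optional.
#'
#' @return A validated `cohort_metadata` data frame.
#' @export
cohort_metadata <- function(df) {
  if (!is.data.frame(df)) stop("metadata must be a data frame")
  required <- c("sample_id", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("metadata lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$group <- as.character(df$group)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  }
  bad <- setdiff(unique(df$group), c("S", "NS"))
  if (length(bad)) {
    stop("group labels must be 'S' or 'NS'; found '", bad[1L], "'")
  }
  class(df) <- c("cohort_metadata", "data.frame")
  df
}

#' Check that a set of omics tables is consistent with its metadata
#'
#' Every sample appearing in any table must appear exactly once in the
#' metadata, and both outcome groups must be non-empty.
#'
#' @param tables List of `omics_table` objects.
#' @param metadata A `cohort_metadata` data frame.
#' @return Invisibly `TRUE`; errors name the offending sample otherwise.
#' @export
validate_cohort <- function(tables, metadata) {
  metadata <- cohort_metadata(metadata)
  for (tab in tables) {
    unknown <- setdiff(sample_ids(tab), metadata$sample_id)
    if (length(unknown)) {
      stop("sample '", unknown[1L], "' in ", tab$layer, "/", tab$timepoint,
           " table is absent from metadata")
    }
  }
  if (!all(c("S", "NS") %in% metadata$group)) {
    stop("both groups (S and NS) must be non-empty")
  }
  invisible(TRUE)
}

layer_key <- function(tab) paste0(tab$layer, "_", tab$timepoint)

#' Write a cohort to wide TSV files
#'
#' One wide TSV per layer per time point (samples as rows), one metadata
#' TSV, and for metabolite layers with censoring information one mask TSV
#' and one LOD TSV. Every file starts with `#`-prefixed provenance header
#' lines. Missing values are written as the `na` token, never as 0.
#'
#' @param tables List of `omics_table` objects.
#' @param metadata A `cohort_metadata` data frame.
#' @param dir Output directory (created if needed).
#' @param na Token used for missing cells (default `"NA"`).
#' @return Invisibly, the character vector of files written.
#' @export
write_cohort <- function(tables, metadata, dir, na = "NA") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(df, path, extra = character(0)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# omistrat cohort file, written %s",
                         format(Sys.time(), "%Y-%m-%d")), extra), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, na = na,
                       row.names = FALSE)
    path
  }
  for (tab in tables) {
    key <- layer_key(tab)
    df <- data.frame(sample_id = sample_ids(tab), tab$values,
                     check.names = FALSE)
    written <- c(written, emit(
      df, file.path(dir, paste0(key, ".tsv")),
      sprintf("# layer=%s timepoint=%s semantics=%s",
              tab$layer, tab$timepoint, tab$value_semantics)
    ))
    if (!is.null(tab$below_lod_mask)) {
      mdf <- data.frame(sample_id = sample_ids(tab),
                        tab$below_lod_mask * 1L, check.names = FALSE)
      written <- c(written, emit(mdf, file.path(dir, paste0(key, "_lodmask.tsv"))))
    }
    if (!is.null(tab$lod)) {
      ldf <- data.frame(feature_id = names(tab$lod), lod = unname(tab$lod))
      written <- c(written, emit(ldf, file.path(dir, paste0(key, "_lod.tsv"))))
    }
  }
  written <- c(written, emit(as.data.frame(metadata),
                             file.path(dir, "metadata.tsv")))
  invisible(written)
}

read_tsv_headered <- function(path, na = "NA") {
  utils::read.delim(path, comment.char = "#", na.strings = na,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the TSV files.
#' @param na Missing-value token used at write time.
#' @return A list with elements `tables` (named list of `omics_table`) and
#'   `metadata` (`cohort_metadata`), validated against the container
#'   invariants.
#' @export
read_cohort <- function(dir, na = "NA") {
  meta_path <- file.path(dir, "metadata.tsv")
  if (!file.exists(meta_path)) stop("no metadata.tsv under ", dir)
  metadata <- cohort_metadata(read_tsv_headered(meta_path, na))
  files <- list.files(dir, pattern = "^(metabolite|protein|clinical)_D[17]\\.tsv$")
  tables <- list()
  for (f in files) {
    key <- sub("\\.tsv$", "", f)
    parts <- strsplit(key, "_")[[1L]]
    df <- read_tsv_headered(file.path(dir, f), na)
    if (anyDuplicated(df$sample_id)) {
      stop("duplicate sample id '", df$sample_id[duplicated(df$sample_id)][1L],
           "' in file ", f)
    }
    vals <- as.matrix(df[, -1L, drop = FALSE])
    rownames(vals) <- df$sample_id
    mask <- NULL
    mask_path <- file.path(dir, paste0(key, "_lodmask.tsv"))
    if (file.exists(mask_path)) {
      mdf <- read_tsv_headered(mask_path, na)
      mask <- as.matrix(mdf[, -1L, drop = FALSE]) == 1L
      rownames(mask) <- mdf$sample_id
      mask <- mask[rownames(vals), colnames(vals), drop = FALSE]
    }
    lod <- NULL
    lod_path <- file.path(dir, paste0(key, "_lod.tsv"))
    if (file.exists(lod_path)) {
      ldf <- read_tsv_headered(lod_path, na)
      lod <- stats::setNames(ldf$lod, ldf$feature_id)
    }
    tables[[key]] <- omics_table(vals, layer = parts[1L], timepoint = parts[2L],
                                 below_lod_mask = mask, lod = lod)
  }
  validate_cohort(tables, metadata)
  list(tables = tables, metadata = metadata)
}

round_half_up <- function(x) floor(x + 0.5)

#' Per-group descriptive summary of a cohort
#'
#' One row per variable per time point with mean, SD, median and quartiles
#' in each outcome group. Quartiles use linear interpolation (inclusive,
#' `stats::quantile` type 7); the convention is recorded in the
#' `quartile_rule` attribute. The 28-day outcome rate is reported as
#' `100 * n_NS / n_total`, rounded half-up to the nearest integer percent.
#'
#' @param tables List of `omics_table` objects.
#' @param metadata A `cohort_metadata` data frame.
#' @return A data frame of summaries with attributes `n_S`, `n_NS` and
#'   `outcome_rate_percent`.
#' @export
cohort_summary <- function(tables, metadata) {
  metadata <- cohort_metadata(metadata)
  validate_cohort(tables, metadata)
  n_s <- sum(metadata$group == "S")
  n_ns <- sum(metadata$group == "NS")
  if (n_s == 0L || n_ns == 0L) stop("both groups must be non-empty")
  rows <- list()
  for (tab in tables) {
    grp <- metadata$group[match(sample_ids(tab), metadata$sample_id)]
    for (j in seq_len(ncol(tab$values))) {
      v <- tab$values[, j]
      one <- function(g) {
        x <- v[grp == g]
        x <- x[!is.na(x)]
        q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
        c(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0,
          q25 = q[1L], median = q[2L], q75 = q[3L])
      }
      s <- one("S"); ns <- one("NS")
      rows[[length(rows) + 1L]] <- data.frame(
        variable = colnames(tab$values)[j], layer = tab$layer,
        timepoint = tab$timepoint,
        mean_S = s["mean"], sd_S = s["sd"],
        median_S = s["median"], q25_S = s["q25"], q75_S = s["q75"],
        mean_NS = ns["mean"], sd_NS = ns["sd"],
        median_NS = ns["median"], q25_NS = ns["q25"], q75_NS = ns["q75"],
        row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_S") <- n_s
  attr(out, "n_NS") <- n_ns
  attr(out, "outcome_rate_percent") <- as.integer(round_half_up(100 * n_ns / (n_s + n_ns)))
  attr(out, "quartile_rule") <- "linear interpolation (type 7)"
  out
}

#' Per-group frequencies of a categorical covariate
#'
#' Counts and half-up-rounded integer percents of each level of a
#' metadata covariate within each outcome group, matching the
#' `n (percent)` presentation of clinical baseline tables.
#'
#' @param metadata A `cohort_metadata` data frame.
#' @param variable Name of a categorical column of `metadata`.
#' @return Data frame with columns `level`, `group`, `n`, `percent`.
#' @export
group_frequencies <- function(metadata, variable) {
  metadata <- cohort_metadata(metadata)
  if (!variable %in% names(metadata)) {
    stop("no column '", variable, "' in metadata")
  }
  v <- as.character(metadata[[variable]])
  out <- list()
  for (g in c("S", "NS")) {
    vg <- v[metadata$group == g]
    n_g <- length(vg)
    for (lev in sort(unique(v))) {
      n <- sum(vg == lev, na.rm = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        level = lev, group = g, n = n,
        percent = as.integer(round_half_up(100 * n / n_g))
      )
    }
  }
  do.call(rbind, out)
}
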