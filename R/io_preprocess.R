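## Reading, phenotype derivation, normalization, filtering, group splitting.

#' Construct an intensity table
#'
#' Container for a samples x metabolites non-negative intensity matrix plus
#' per-metabolite annotation flags.
#'
#' @param values Numeric matrix, samples in rows (rownames = sample IDs),
#'   metabolites in columns (colnames = metabolite IDs).
#' @param annotated Logical vector named by metabolite ID; defaults to all
#'   `FALSE`.
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(values, annotated = NULL) {
  assert_that(is.matrix(values) && is.numeric(values),
              "values must be a numeric matrix")
  assert_that(!is.null(rownames(values)) && !is.null(colnames(values)),
              "values must carry sample and metabolite IDs as dimnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample_id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicated metabolite_id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(values < 0, na.rm = TRUE))
    stop("negative intensity values are not allowed", call. = FALSE)
  if (is.null(annotated))
    annotated <- stats::setNames(rep(FALSE, ncol(values)), colnames(values))
  assert_that(all(colnames(values) %in% names(annotated)),
              "annotation flags must cover all metabolites")
  structure(list(values = values, annotated = annotated[colnames(values)]),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d samples x %d metabolites (%d annotated)\n",
              nrow(x$values), ncol(x$values), sum(x$annotated)))
  invisible(x)
}

#' Read an intensity table from TSV
#'
#' Expects a header row, a `sample_id` first column, and one numeric column
#' per metabolite.
#'
#' @param path TSV file.
#' @param annotation_path Optional TSV with columns `metabolite_id`,
#'   `annotated` (and optionally `compound_id`).
#' @return An `intensity_table`.
#' @export
read_intensity_table <- function(path, annotation_path = NULL) {
  tb <- read_tsv_strict(path)
  assert_that("sample_id" %in% names(tb), "intensity TSV needs a sample_id column")
  vals <- as.matrix(tb[, setdiff(names(tb), "sample_id"), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(tb$sample_id)
  ann <- NULL
  if (!is.null(annotation_path)) {
    at <- read_tsv_strict(annotation_path)
    ann <- stats::setNames(as.logical(at$annotated), at$metabolite_id)
  }
  intensity_table(vals, annotated = ann)
}

#' Read sample metadata from TSV
#'
#' Requires columns sample_id, animal_id, breed, batch, pen, time_point,
#' sampling_age; validates uniqueness and time-point coding, and (when an
#' intensity table is supplied) cross-references sample IDs.
#'
#' @param path TSV file.
#' @param intensities Optional `intensity_table` to cross-reference.
#' @return A data.frame.
#' @export
read_metadata <- function(path, intensities = NULL) {
  md <- read_tsv_strict(path)
  need <- c("sample_id", "animal_id", "breed", "batch", "pen",
            "time_point", "sampling_age")
  miss <- setdiff(need, names(md))
  assert_that(length(miss) == 0,
              paste("metadata missing columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(md$sample_id))
    stop("duplicated sample_id in metadata: ",
         md$sample_id[duplicated(md$sample_id)][1], call. = FALSE)
  key <- paste(md$animal_id, md$time_point)
  assert_that(!anyDuplicated(key), "duplicated (animal_id, time_point) pair")
  assert_that(all(md$time_point %in% c(1, 2)),
              "time_point must be coded 1 or 2")
  if (!is.null(intensities)) {
    missing_samp <- setdiff(md$sample_id, rownames(intensities$values))
    assert_that(length(missing_samp) == 0,
                paste("metadata samples missing from intensities:",
                      paste(utils::head(missing_samp, 5), collapse = ", ")))
  }
  md
}

#' Read raw per-animal weight-and-feed records from TSV
#'
#' @param path TSV with columns animal_id, breed, start_weight, end_weight,
#'   FC, age_at_start, age_at_end (optionally birth_weight).
#' @return A data.frame of raw records for [compute_phenotypes()].
#' @export
read_phenotype_inputs <- function(path) {
  ph <- read_tsv_strict(path)
  need <- c("animal_id", "breed", "start_weight", "end_weight", "FC",
            "age_at_start", "age_at_end")
  miss <- setdiff(need, names(ph))
  assert_that(length(miss) == 0,
              paste("phenotype inputs missing columns:",
                    paste(miss, collapse = ", ")))
  assert_that(!anyDuplicated(ph$animal_id), "duplicated animal_id")
  ph
}

#' Derive feed-efficiency phenotypes from raw weight and feed records
#'
#' Computes, per animal: delta weight `DW = end_weight - start_weight`; feed
#' efficiency `FE = DW / FC`; daily gains `EDG = (start_weight -
#' birth_weight) / age_at_start` (birth weight taken as 0 when absent),
#' `TDG = DW / test_days`, `DG = (end_weight - birth_weight) / age_at_end`;
#' daily feed intake `DFI = FC / test_days`; predicted intake `pDFI` from a
#' within-breed ordinary least squares regression of DFI on TDG and mean
#' metabolic weight `((start_weight + end_weight)/2)^0.75`; and residual
#' feed intake `RFI = DFI - pDFI`.  RFI therefore averages zero within each
#' breed by the OLS residual property.
#'
#' @param records Data.frame as returned by [read_phenotype_inputs()].
#' @param use_metabolic_weight Include the metabolic-weight predictor in the
#'   pDFI regression (default `TRUE`).
#' @param use_tdg Include TDG in the pDFI regression (default `TRUE`).
#' @return A data.frame (`phenotype_table`) with one row per animal.
#' @export
compute_phenotypes <- function(records, use_metabolic_weight = TRUE,
                               use_tdg = TRUE) {
  assert_that(all(records$FC > 0), "FC must be positive")
  test_days <- records$age_at_end - records$age_at_start
  assert_that(all(test_days > 0), "test duration must be positive")
  bw <- if ("birth_weight" %in% names(records)) records$birth_weight else 0
  ph <- data.frame(animal_id = records$animal_id, breed = records$breed,
                   start_weight = records$start_weight,
                   end_weight = records$end_weight,
                   FC = records$FC,
                   age_at_start = records$age_at_start,
                   age_at_end = records$age_at_end,
                   test_days = test_days,
                   stringsAsFactors = FALSE)
  ph$DW <- records$end_weight - records$start_weight
  ph$FE <- ph$DW / ph$FC
  ph$EDG <- (records$start_weight - bw) / records$age_at_start
  ph$TDG <- ph$DW / test_days
  ph$DG <- (records$end_weight - bw) / records$age_at_end
  ph$DFI <- ph$FC / test_days
  ph$metabolic_weight <- ((records$start_weight + records$end_weight) / 2)^0.75
  ph$pDFI <- NA_real_
  for (b in unique(ph$breed)) {
    idx <- which(ph$breed == b)
    assert_that(length(idx) >= 3,
                paste0("breed '", b, "' has fewer than 3 animals; ",
                       "pDFI regression underdetermined"))
    preds <- matrix(1, length(idx), 1, dimnames = list(NULL, "(Intercept)"))
    if (use_tdg) preds <- cbind(preds, TDG = ph$TDG[idx])
    if (use_metabolic_weight)
      preds <- cbind(preds, MW = ph$metabolic_weight[idx])
    fit <- stats::lm.fit(preds, ph$DFI[idx])
    ph$pDFI[idx] <- ph$DFI[idx] - fit$residuals
  }
  ph$RFI <- ph$DFI - ph$pDFI
  class(ph) <- c("phenotype_table", "data.frame")
  ph
}

#' Total-ion-intensity normalization
#'
#' Scales each sample so that all sample totals equal the grand mean of the
#' original totals: `x_s * mean(totals) / total_s`.  Idempotent.
#'
#' @param table An `intensity_table` of raw counts.
#' @return A normalized `intensity_table`.
#' @export
tii_normalize <- function(table) {
  totals <- rowSums(table$values)
  if (any(totals <= 0))
    stop("sample(s) with non-positive total intensity: ",
         paste(utils::head(rownames(table$values)[totals <= 0], 5),
               collapse = ", "), call. = FALSE)
  out <- table$values * (mean(totals) / totals)
  intensity_table(out, table$annotated)
}

#' Relative-standard-deviation filter
#'
#' Per metabolite, within the given sample subset and on the *raw* counts,
#' computes RSD = sd / mean (sample sd, n-1 denominator) and keeps
#' metabolites with RSD strictly greater than the threshold.  Low-RSD
#' features carry essentially no biological variation.
#'
#' @param table An `intensity_table` of raw counts.
#' @param sample_ids Samples defining the group (default: all).
#' @param threshold RSD cutoff, default 0.15; kept iff RSD > threshold.
#' @return List with `kept` (metabolite IDs) and `report` (data.frame
#'   metabolite_id, rsd, kept).
#' @export
rsd_filter <- function(table, sample_ids = rownames(table$values),
                       threshold = 0.15) {
  sub <- table$values[sample_ids, , drop = FALSE]
  assert_that(nrow(sub) >= 2, "RSD filter needs at least 2 samples")
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, stats::sd)
  rsd <- ifelse(mu == 0, Inf, sdv / mu)   # all-zero feature: no signal, Inf RSD
  rsd[mu == 0 & sdv == 0] <- 0
  kept <- rsd > threshold
  list(kept = colnames(sub)[kept],
       report = data.frame(metabolite_id = colnames(sub), rsd = unname(rsd),
                           kept = unname(kept), stringsAsFactors = FALSE))
}

#' Log-transform intensities
#'
#' Natural log of value + offset, where the offset is half the smallest
#' positive value in the matrix when zeros are present and 0 otherwise
#' (preserves ordering, avoids -Inf).
#'
#' @param table An `intensity_table` (normalized intensities).
#' @return List-like `intensity_table` whose `values` are log scale; the
#'   offset used is attached as attribute `offset`.
#' @export
log_transform <- function(table) {
  v <- table$values
  assert_that(all(v >= 0), "negative input to log_transform")
  offset <- 0
  if (any(v == 0)) {
    pos <- v[v > 0]
    assert_that(length(pos) > 0, "all-zero matrix cannot be log-transformed")
    offset <- min(pos) / 2
  }
  out <- intensity_table(log(v + offset), table$annotated)
  attr(out, "offset") <- offset
  out
}

#' Split a study into breed x time-point analysis groups
#'
#' Builds six groups: each breed at time point 1, at time point 2, and with
#' both time points combined.  The RSD filter is applied independently
#' within each group on the raw counts.
#'
#' @param table An `intensity_table` of raw counts.
#' @param metadata Sample metadata (see [read_metadata()]).
#' @param rsd_threshold RSD cutoff passed to [rsd_filter()].
#' @return Named list of `analysis_group` objects, each with `label`,
#'   `breed`, `time_points`, `sample_ids`, `metabolites` (kept IDs) and
#'   `filter_report`.
#' @export
split_groups <- function(table, metadata, rsd_threshold = 0.15) {
  breeds <- unique(metadata$breed)
  groups <- list()
  for (b in breeds) {
    for (tp in list(1L, 2L, c(1L, 2L))) {
      lab <- paste0(b, "_TP", paste(tp, collapse = ""))
      sel <- metadata$sample_id[metadata$breed == b &
                                  metadata$time_point %in% tp]
      if (length(sel) == 0)
        stop("breed '", b, "' has no samples at time point ",
             paste(tp, collapse = ","), call. = FALSE)
      flt <- rsd_filter(table, sel, rsd_threshold)
      groups[[lab]] <- structure(
        list(label = lab, breed = b, time_points = tp, sample_ids = sel,
             metabolites = flt$kept, filter_report = flt$report),
        class = "analysis_group")
    }
  }
  groups
}

#' @export
print.analysis_group <- function(x, ...) {
  cat(sprintf("analysis_group %s: %d samples, %d/%d metabolites kept\n",
              x$label, length(x$sample_ids), length(x$metabolites),
              nrow(x$filter_report)))
  invisible(x)
}

#' PCA overview of samples
#'
#' Centers (and by default unit-scales) the columns and returns the first
#' two principal-component scores with percent variance explained.  Sign
#' convention: within each component the largest-magnitude loading is made
#' positive, so scores are reproducible across platforms.
#'
#' @param table An `intensity_table` (log scale recommended).
#' @param metadata Optional metadata merged onto the scores.
#' @param scale. Unit-scale columns (default `TRUE`); zero-variance columns
#'   are dropped with a message.
#' @return List with `scores` (data.frame sample_id, PC1, PC2, metadata
#'   columns) and `var_explained` (length-2 percentages).
#' @export
pca_overview <- function(table, metadata = NULL, scale. = TRUE) {
  v <- table$values
  assert_that(nrow(v) >= 3, "PCA needs at least 3 samples")
  sds <- apply(v, 2, stats::sd)
  if (all(sds == 0)) stop("zero-variance matrix", call. = FALSE)
  if (any(sds == 0)) {
    log_stage("pca", sum(sds == 0), " zero-variance metabolites dropped")
    v <- v[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(v, center = TRUE, scale. = scale.)
  for (k in 1:2) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(sample_id = rownames(v), PC1 = pc$x[, 1],
                       PC2 = pc$x[, 2], stringsAsFactors = FALSE)
  if (!is.null(metadata))
    scores <- merge(scores, metadata, by = "sample_id", sort = FALSE)
  list(scores = scores, var_explained = ve[1:2])
}
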