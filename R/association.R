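## Per-metabolite trait association, global KS signal test, FDR,
## TP1 -> TP2 temporal stability.

TRAITS <- c("FE", "EDG", "TDG", "DG", "RFI")

#' Associate each metabolite with a phenotype
#'
#' Per metabolite, ordinary least squares of the phenotype on an intercept,
#' the adjusted metabolite concentration, and the animal's sampling age in
#' days; the reported p-value is the two-sided t-test of the metabolite
#' slope.  Sampling age enters here (and only here) because age is itself
#' correlated with the growth phenotypes; adjusting it out of the
#' metabolites beforehand would bias the associations.
#'
#' @param adjusted An `adjusted_matrix` (samples x metabolites).
#' @param phenotypes A `phenotype_table`.
#' @param trait One of `r paste(TRAITS, collapse = ", ")`.
#' @param metadata Sample metadata mapping samples to animals and sampling
#'   ages.
#' @param include_age Include the sampling-age covariate (default `TRUE`).
#' @return An `association_table` data.frame: metabolite_id, slope, se,
#'   p_value, q_value (Benjamini-Hochberg within this call), n_used,
#'   flagged (metabolite collinear with age).
#' @export
associate_trait <- function(adjusted, phenotypes, trait, metadata,
                            include_age = TRUE) {
  assert_that(trait %in% TRAITS,
              paste("unknown trait:", trait))
  md <- metadata[match(rownames(adjusted), metadata$sample_id), , drop = FALSE]
  y <- phenotypes[[trait]][match(md$animal_id, phenotypes$animal_id)]
  age <- md$sampling_age
  keep <- !is.na(y) & !is.na(age)
  n_dropped <- sum(!keep)
  y <- y[keep]; age <- age[keep]
  M <- unclass(adjusted)[keep, , drop = FALSE]
  n <- length(y)
  assert_that(n >= 5, "fewer than 5 usable observations")
  X0 <- if (include_age) cbind(1, age) else matrix(1, n, 1)
  q0 <- ncol(X0) + 1L     # intercept (+ age) + metabolite
  df_resid <- n - q0
  assert_that(df_resid >= 1, "no residual degrees of freedom")

  ## residualize y and each metabolite on [intercept, age]; the metabolite
  ## slope/t of the full model equals the slope/t of the residual regression
  ## (Frisch-Waugh), computed vectorized across metabolites
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, y)
  RM <- qr.resid(qr0, M)
  mss <- colSums(RM^2)
  age_r <- if (include_age) suppressWarnings(stats::cor(M, age)) else
    rep(0, ncol(M))
  flagged <- !is.na(age_r) & abs(age_r) > 0.999
  sxy <- colSums(RM * ry)
  slope <- sxy / mss
  rss <- pmax(sum(ry^2) - sxy^2 / mss, 0)
  sigma2 <- rss / df_resid
  se <- sqrt(sigma2 / mss)
  tstat <- slope / se
  pv <- 2 * stats::pt(abs(tstat), df_resid, lower.tail = FALSE)
  pv[flagged | mss < .Machine$double.eps * n] <- NA_real_
  slope[mss < .Machine$double.eps * n] <- NA_real_
  out <- data.frame(metabolite_id = colnames(M), trait = trait,
                    slope = unname(slope), se = unname(se),
                    p_value = unname(pv),
                    q_value = bh_fdr(pv),
                    n_used = n, n_dropped = n_dropped,
                    flagged = unname(flagged), stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Kolmogorov-Smirnov test of p-value uniformity
#'
#' One-sample two-sided KS test of a set of p-values against Uniform(0,1):
#' the global signal test for whether a trait shows any overall relation to
#' the metabolome.  Exact null distribution for n <= 50, asymptotic
#' otherwise.
#'
#' @param pvalues Numeric vector of p-values (non-finite entries dropped).
#' @return List (class `ks_result`): `statistic` (D), `p_value`, `n`.
#' @export
ks_uniformity_test <- function(pvalues) {
  p <- pvalues[is.finite(pvalues)]
  assert_that(length(p) >= 1, "no finite p-values")
  assert_that(all(p >= 0 & p <= 1), "p-values outside [0, 1]")
  kt <- suppressWarnings(stats::ks.test(p, "punif", exact = length(p) <= 50))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value), n = length(p)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS uniformity test: D = %.4f, p = %.3g (n = %d)\n",
              x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, clipped at 1.  `NA` p-values
#' propagate as `NA` and do not count toward the number of tests.
#'
#' @param pvalues Numeric p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  assert_that(all(pvalues[ok] >= 0 & pvalues[ok] <= 1),
              "p-values outside [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

#' Temporal stability of metabolite levels between time points
#'
#' Per metabolite, OLS of the TP2 log value on the TP1 log value across the
#' animals present at both time points; reports the slope p-value and the
#' fraction of metabolites with p below `alpha`.  A high fraction indicates
#' that relative metabolite concentrations are stable and predictable over
#' the test phase.
#'
#' @param tp1,tp2 Log-scale matrices (samples x metabolites) for the two
#'   time points, or `intensity_table`s; rownames are sample IDs.
#' @param metadata Sample metadata used to pair samples by animal.
#' @param alpha Significance level for the summary fraction (default 0.05).
#' @return List (class `temporal_stability`): `table` (per-metabolite slope,
#'   p_value, exact_fit flag), `fraction_significant`, `n_animals`.
#' @export
temporal_stability <- function(tp1, tp2, metadata, alpha = 0.05) {
  V1 <- if (inherits(tp1, "intensity_table")) tp1$values else tp1
  V2 <- if (inherits(tp2, "intensity_table")) tp2$values else tp2
  a1 <- metadata$animal_id[match(rownames(V1), metadata$sample_id)]
  a2 <- metadata$animal_id[match(rownames(V2), metadata$sample_id)]
  shared <- intersect(a1, a2)
  assert_that(length(shared) >= 5,
              "fewer than 5 animals present at both time points")
  V1 <- V1[match(shared, a1), , drop = FALSE]
  V2 <- V2[match(shared, a2), , drop = FALSE]
  mets <- intersect(colnames(V1), colnames(V2))
  V1 <- V1[, mets, drop = FALSE]; V2 <- V2[, mets, drop = FALSE]
  n <- length(shared)
  x1c <- scale(V1, scale = FALSE)
  x2c <- scale(V2, scale = FALSE)
  sxx <- colSums(x1c^2)
  sxy <- colSums(x1c * x2c)
  slope <- sxy / sxx
  rss <- pmax(colSums(x2c^2) - sxy^2 / sxx, 0)
  sigma2 <- rss / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tstat <- slope / se
  pv <- 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  exact <- rss <= .Machine$double.eps * colSums(x2c^2) * n
  pv[exact] <- .Machine$double.xmin
  tab <- data.frame(metabolite_id = mets, slope = unname(slope),
                    se = unname(se), p_value = unname(pv),
                    exact_fit = unname(exact), stringsAsFactors = FALSE)
  structure(list(table = tab,
                 fraction_significant = mean(tab$p_value < alpha, na.rm = TRUE),
                 n_animals = n, alpha = alpha),
            class = "temporal_stability")
}

#' @export
print.temporal_stability <- function(x, ...) {
  cat(sprintf("temporal stability: %.1f%% of %d metabolites with p < %g (n = %d animals)\n",
              100 * x$fraction_significant, nrow(x$table), x$alpha, x$n_animals))
  invisible(x)
}

#' Select significant metabolites from an association table
#'
#' Inclusive threshold: metabolites with p <= alpha.  The annotated subset
#' is reported separately when annotation flags are supplied.
#'
#' @param table An `association_table`.
#' @param alpha Significance level (default 0.05, inclusive).
#' @param annotated Optional logical vector named by metabolite ID.
#' @param use_q Threshold the q-value instead of the p-value.
#' @return List: `metabolites` (IDs), `annotated` (IDs), `n`, `n_annotated`.
#' @export
significant_set <- function(table, alpha = 0.05, annotated = NULL,
                            use_q = FALSE) {
  val <- if (use_q) table$q_value else table$p_value
  sel <- table$metabolite_id[!is.na(val) & val <= alpha]
  ann <- if (!is.null(annotated))
    sel[annotated[sel] %in% TRUE] else character(0)
  list(metabolites = sel, annotated = ann,
       n = length(sel), n_annotated = length(ann))
}
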