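## Per-metabolite design-effect adjustment.
##
## Each metabolite's log concentration is modeled with breed (when the group
## contains more than one breed) and instrument batch as fixed effects and
## pen as a random intercept, fitted by REML (lme4).  Pen falls back to a
## fixed effect when it has fewer than 3 levels or REML fails to converge;
## the path taken is recorded per metabolite.  The adjusted value is the
## observation minus all estimated design effects (intercept plus residual),
## which is what enters the trait-association and network stages.  Sampling
## age is deliberately NOT part of this model: age is correlated with the
## growth phenotypes (slow growers are sampled older), so removing it here
## would bias the downstream associations; it enters only as a covariate in
## the association model.

#' Fit per-metabolite design-effect models
#'
#' @param log_table An `intensity_table` on log scale (or a samples x
#'   metabolites numeric matrix).
#' @param metadata Sample metadata covering the table's samples.
#' @param include_breed,include_batch,include_timepoint Logical or `"auto"`:
#'   include the factor when it has at least 2 levels among the samples.
#'   Time point is only relevant for combined-time-point groups.
#' @param pen_method `"reml"` (random pen intercept, lme4 REML, BLUP
#'   predictions) or `"fixed"` (pen absorbed as a sum-to-zero fixed effect).
#' @return An `effects_model`: list with per-sample effect predictions
#'   (`effects`, samples x metabolites, excluding the intercept),
#'   `intercept`, per-factor coefficient matrices (`coefficients`),
#'   variance components, and per-metabolite `method`/`converged`/`singular`
#'   flags.
#' @export
fit_effects_model <- function(log_table, metadata,
                              include_breed = "auto",
                              include_batch = "auto",
                              include_timepoint = "auto",
                              pen_method = c("reml", "fixed")) {
  pen_method <- match.arg(pen_method)
  Y <- if (inherits(log_table, "intensity_table")) log_table$values else log_table
  assert_that(is.matrix(Y), "log_table must be an intensity_table or matrix")
  md <- metadata[match(rownames(Y), metadata$sample_id), , drop = FALSE]
  assert_that(!anyNA(md$sample_id), "metadata does not cover all samples")

  use <- function(flag, var) {
    nlev <- length(unique(md[[var]]))
    if (identical(flag, "auto")) nlev >= 2 else isTRUE(flag) && nlev >= 2
  }
  terms <- c(if (use(include_breed, "breed")) "breed",
             if (use(include_batch, "batch")) "batch",
             if (use(include_timepoint, "time_point")) "time_point")
  pen <- factor(md$pen)
  if (nlevels(pen) < 3 && pen_method == "reml") {
    log_stage("adjustment", "pen has <3 levels; treating pen as fixed")
    pen_method <- "fixed"
  }
  if (nlevels(pen) == nrow(md) && pen_method == "reml") {
    log_stage("adjustment", "pen unique per sample; treating pen as fixed")
    pen_method <- "fixed"
  }

  df <- data.frame(row.names = rownames(Y))
  for (v in terms) df[[v]] <- factor(md[[v]])
  df$pen <- pen
  fixed_terms <- terms
  if (pen_method == "fixed" && nlevels(pen) >= 2) fixed_terms <- c(terms, "pen")
  rhs <- if (length(fixed_terms) == 0) "1" else paste(fixed_terms, collapse = " + ")
  contr <- stats::setNames(
    rep(list("contr.sum"), length(fixed_terms)), fixed_terms)
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), df,
                           contrasts.arg = if (length(contr)) contr)
  p <- ncol(Y)

  model <- list(terms = terms, pen_method = pen_method,
                metadata = md, design = X, pen = pen,
                fixed_terms = fixed_terms, rhs = rhs,
                factor_levels = c(lapply(df[fixed_terms], levels),
                                  list(.pen = levels(pen))),
                metabolite_ids = colnames(Y))

  if (pen_method == "fixed") {
    fit <- stats::lm.fit(X, Y)
    beta <- fit$coefficients
    if (is.vector(beta)) beta <- matrix(beta, ncol = p,
                                        dimnames = list(names(beta), colnames(Y)))
    singular <- fit$rank < ncol(X)
    beta_use <- beta
    beta_use[is.na(beta_use)] <- 0
    eff <- X[, -1, drop = FALSE] %*% beta_use[-1, , drop = FALSE]
    model$intercept <- beta_use[1, ]
    model$coefficients <- beta
    model$effects <- eff
    model$resid_variance <- colSums((Y - X %*% beta_use)^2) /
      max(nrow(Y) - fit$rank, 1)
    model$pen_variance <- rep(NA_real_, p)
    model$method <- rep("fixed", p)
    model$converged <- rep(TRUE, p)
    model$singular <- rep(singular, p)
    if (singular)
      warning("confounded design: rank-deficient fixed-effect model; ",
              "aliased effects set to zero", call. = FALSE)
  } else {
    eff <- matrix(0, nrow(Y), p, dimnames = dimnames(Y))
    pen_blups <- matrix(0, nlevels(pen), p,
                        dimnames = list(levels(pen), colnames(Y)))
    intercept <- numeric(p)
    pen_var <- resid_var <- rep(NA_real_, p)
    method <- rep("reml", p)
    converged <- rep(TRUE, p)
    coefs <- matrix(NA_real_, ncol(X), p,
                    dimnames = list(colnames(X), colnames(Y)))
    base_fit <- NULL
    fml <- stats::as.formula(paste("y ~", rhs, "+ (1 | pen)"))
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    Zi <- stats::model.matrix(~ 0 + pen, df)  # pen indicator for BLUP expansion
    for (j in seq_len(p)) {
      dfj <- df
      dfj$y <- Y[, j]
      fit_j <- tryCatch({
        if (is.null(base_fit)) {
          base_fit <- suppressMessages(suppressWarnings(
            lme4::lmer(fml, dfj, REML = TRUE, control = ctrl,
                       contrasts = if (length(contr)) contr)))
          base_fit
        } else suppressMessages(suppressWarnings(lme4::refit(base_fit, Y[, j])))
      }, error = function(e) NULL)
      if (is.null(fit_j) ||
          (length(fit_j@optinfo$conv$lme4) > 0 &&
           !is.null(fit_j@optinfo$conv$lme4$code) &&
           fit_j@optinfo$conv$lme4$code < 0)) {
        ## REML failure: absorb pen as fixed for this metabolite
        Xf <- cbind(X, stats::model.matrix(~ pen, df,
                                           contrasts.arg = list(pen = "contr.sum"))[, -1, drop = FALSE])
        fb <- stats::lm.fit(Xf, Y[, j])
        bu <- fb$coefficients
        bu[is.na(bu)] <- 0
        eff[, j] <- Xf[, -1, drop = FALSE] %*% bu[-1]
        intercept[j] <- bu[1]
        resid_var[j] <- sum((Y[, j] - Xf %*% bu)^2) / max(nrow(Y) - fb$rank, 1)
        method[j] <- "fixed_fallback"
        converged[j] <- FALSE
        next
      }
      fe <- lme4::fixef(fit_j)
      coefs[names(fe), j] <- fe
      re <- lme4::ranef(fit_j)$pen
      blup <- stats::setNames(re[, 1], rownames(re))
      pen_blups[names(blup), j] <- blup
      eff[, j] <- X[, -1, drop = FALSE] %*% fe[-1] +
        Zi %*% pen_blups[levels(pen), j]
      intercept[j] <- fe[1]
      vc <- as.data.frame(lme4::VarCorr(fit_j))
      pen_var[j] <- vc$vcov[vc$grp == "pen"][1]
      resid_var[j] <- vc$vcov[vc$grp == "Residual"][1]
    }
    model$intercept <- stats::setNames(intercept, colnames(Y))
    model$coefficients <- coefs
    model$effects <- eff
    model$pen_variance <- pen_var
    model$resid_variance <- resid_var
    model$pen_blups <- pen_blups
    model$method <- method
    model$converged <- converged
    model$singular <- rep(FALSE, p)
  }
  structure(model, class = "effects_model")
}

#' @export
print.effects_model <- function(x, ...) {
  cat(sprintf("effects_model: %d metabolites; fixed terms: %s; pen: %s\n",
              length(x$metabolite_ids),
              if (length(x$terms)) paste(x$terms, collapse = ", ") else "none",
              x$pen_method))
  invisible(x)
}

#' Remove estimated design effects from the log matrix
#'
#' Returns the adjusted concentrations: each observation minus its estimated
#' breed, batch, (time-point) and pen contributions, i.e. intercept plus
#' residual.  Sampling age is untouched by construction.
#'
#' @param model An `effects_model` fitted on the same samples.
#' @param log_table The log-scale `intensity_table` (or matrix) the model
#'   was fitted on.
#' @return A samples x metabolites matrix of class `adjusted_matrix` with
#'   provenance attributes.
#' @export
adjust_metabolites <- function(model, log_table) {
  Y <- if (inherits(log_table, "intensity_table")) log_table$values else log_table
  assert_that(identical(dim(Y), dim(model$effects)),
              "log_table shape does not match the fitted model")
  assert_that(identical(rownames(Y), rownames(model$effects)),
              "sample order does not match the fitted model")
  out <- Y - model$effects
  structure(out, class = c("adjusted_matrix", class(out)),
            terms = model$terms, pen_method = model$pen_method)
}

#' Adjust an independent cohort with a fitted effects model
#'
#' Applies the design effects estimated by [fit_effects_model()] to new
#' samples sharing the same factor levels (e.g. a validation cohort run in
#' the same batches and pens).  Unseen pen levels receive a zero prediction.
#'
#' @param model An `effects_model`.
#' @param log_table Log-scale matrix or `intensity_table` for the new
#'   samples (same metabolites as the model).
#' @param metadata Metadata covering the new samples.
#' @return An `adjusted_matrix` for the new samples.
#' @export
adjust_new_samples <- function(model, log_table, metadata) {
  Y <- if (inherits(log_table, "intensity_table")) log_table$values else log_table
  assert_that(identical(colnames(Y), model$metabolite_ids),
              "metabolite set does not match the fitted model")
  md <- metadata[match(rownames(Y), metadata$sample_id), , drop = FALSE]
  assert_that(!anyNA(md$sample_id), "metadata does not cover the new samples")
  df <- data.frame(row.names = rownames(Y))
  for (v in model$fixed_terms) {
    lev <- model$factor_levels[[v]]
    vals <- as.character(md[[if (v == "pen") "pen" else v]])
    extra <- setdiff(unique(vals), lev)
    assert_that(length(extra) == 0,
                paste0("unseen ", v, " level(s): ",
                       paste(extra, collapse = ", ")))
    df[[v]] <- factor(vals, levels = lev)
  }
  contr <- stats::setNames(rep(list("contr.sum"), length(model$fixed_terms)),
                           model$fixed_terms)
  X <- stats::model.matrix(stats::as.formula(paste("~", model$rhs)), df,
                           contrasts.arg = if (length(contr)) contr)
  beta <- model$coefficients
  beta[is.na(beta)] <- 0
  eff <- X[, rownames(beta)[-1], drop = FALSE] %*% beta[-1, , drop = FALSE]
  if (!is.null(model$pen_blups)) {
    pen_new <- as.character(md$pen)
    known <- pen_new %in% rownames(model$pen_blups)
    eff[known, ] <- eff[known, , drop = FALSE] +
      model$pen_blups[pen_new[known], , drop = FALSE]
  }
  out <- Y - eff
  structure(out, class = c("adjusted_matrix", class(out)),
            terms = model$terms, pen_method = model$pen_method)
}

#' Vectorized one-way F-test of each column on a factor
#' @keywords internal
oneway_f_pvalues <- function(Y, fac) {
  fac <- factor(fac)
  k <- nlevels(fac)
  n <- nrow(Y)
  if (k < 2 || n - k < 1) return(rep(NA_real_, ncol(Y)))
  gm <- colMeans(Y)
  sums <- rowsum(Y, fac)
  cnt <- as.vector(table(fac))
  means <- sums / cnt
  ssb <- colSums(cnt * (means - rep(gm, each = k))^2)
  sst <- colSums((Y - rep(gm, each = n))^2)
  ssw <- pmax(sst - ssb, 0)
  Fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(Fstat, k - 1, n - k, lower.tail = FALSE)
}

#' Residual-confounding diagnostics on an adjusted matrix
#'
#' Scans each requested design factor against every metabolite of the
#' adjusted matrix with a one-way F-test, applies Benjamini-Hochberg within
#' factor, and summarizes whether any structure survives adjustment.
#'
#' @param adjusted An `adjusted_matrix` (or matrix).
#' @param metadata Sample metadata.
#' @param factors Factor columns to scan; defaults to the design factors.
#' @param q_threshold FDR level for the flag (default 0.05).
#' @return Data.frame per factor: metabolites tested, number significant
#'   after FDR, minimum p, KS uniformity p of the p-values, and a `flagged`
#'   column.
#' @export
check_effect_removal <- function(adjusted, metadata,
                                 factors = c("breed", "batch", "pen",
                                             "time_point"),
                                 q_threshold = 0.05) {
  factors <- intersect(factors, names(metadata))
  md <- metadata[match(rownames(adjusted), metadata$sample_id), , drop = FALSE]
  rows <- list()
  for (f in factors) {
    fac <- factor(md[[f]])
    if (nlevels(fac) < 2) next
    pv <- oneway_f_pvalues(unclass(adjusted), fac)
    pv <- pv[is.finite(pv)]
    if (length(pv) == 0) next
    qv <- bh_fdr(pv)
    ks <- ks_uniformity_test(pv)
    rows[[f]] <- data.frame(factor = f, n_tested = length(pv),
                            n_significant_fdr = sum(qv <= q_threshold),
                            min_p = min(pv), ks_p = ks$p_value,
                            flagged = sum(qv <= q_threshold) > 0,
                            stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(factor = character(), n_tested = integer(),
                      n_significant_fdr = integer(), min_p = numeric(),
                      ks_p = numeric(), flagged = logical()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
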