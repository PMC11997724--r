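#' @include phenotype.R
NULL

#' Assemble the per-patient analysis table
#'
#' Joins phenotype labels, tract burdens and covariates into the flat table
#' the statistical layer consumes; excluded patients are dropped.
#'
#' @param strata data.frame from \code{\link{classifyCohort}}.
#' @param burdens data.frame with patient_id, uf_burden, fornix_burden,
#'   total_lesion_volume.
#' @param covariates data.frame with patient_id, age, sex,
#'   total_brain_volume_mm3 (optionally race).
#' @param promis optional data.frame with patient_id, promis_physical,
#'   promis_emotional.
#' @return data.frame, one row per included patient.
#' @export
buildAnalysisTable <- function(strata, burdens, covariates, promis = NULL) {
  tab <- merge(strata, burdens, by = "patient_id")
  tab <- merge(tab, covariates, by = "patient_id")
  if (!is.null(promis)) tab <- merge(tab, promis, by = "patient_id", all.x = TRUE)
  tab <- tab[tab$anxiety != "excluded", ]
  tab$sex <- factor(tab$sex)
  rownames(tab) <- NULL
  tab
}

gamFormula <- function(outcome, term, k = 4, fx = FALSE) {
  # a cubic regression spline needs k >= 3; below that the smooth
  # degenerates to a linear age term (and the GAM to ordinary least squares)
  ageTerm <- if (k <= 2) "age" else
    sprintf("s(age, bs = 'cr', k = %d, fx = %s)", k,
            if (fx) "TRUE" else "FALSE")
  stats::as.formula(sprintf("%s ~ %s + sex + total_brain_volume_mm3 + %s",
                            outcome, term, ageTerm))
}

rsqGam <- function(fit, y) {
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}

#' Fit the covariate-adjusted burden GAM
#'
#' Fits \code{outcome ~ predictor + sex + total_brain_volume + s(age)} with
#' a penalized cubic regression spline of age (REML smoothing) via
#' \pkg{mgcv}, and reports the Wald statistics of the parametric predictor
#' term together with its Cohen f2 (full model vs the same model without
#' the predictor).
#'
#' @param table analysis table from \code{\link{buildAnalysisTable}}.
#' @param outcome column name of the outcome (e.g. "uf_burden").
#' @param predictor one of "diagnosis_binary" (severe vs none; mild rows
#'   dropped), "severity_ordinal" (0/1/2 linear severity score),
#'   "severity_factor" (group factor; statistics reported for the severe
#'   contrast) or "depression_binary".
#' @param bootstrapB bootstrap replicates for the f2 percentile CI; 0
#'   disables the CI.
#' @param seed seed for the bootstrap resampling.
#' @param splineK basis dimension of the age spline (default 4).
#' @param splineFixed if TRUE the spline penalty is dropped (fixed degrees
#'   of freedom); with \code{splineK = 2} this collapses to a linear age
#'   term and the fit matches ordinary least squares.
#' @return list of class \code{ModelResult}: term, estimate, T, p,
#'   cohens_f2, f2_ci, n, formula_descriptor, and the fitted \code{gam}.
#' @export
fitBurdenGAM <- function(table, outcome, predictor = "severity_ordinal",
                         bootstrapB = 0, seed = 1L, splineK = 4,
                         splineFixed = FALSE) {
  prep <- prepareGamData(table, outcome, predictor)
  res <- fitGamCore(prep$data, outcome, prep$term, k = splineK,
                    fx = splineFixed)
  ci <- c(NA_real_, NA_real_)
  if (bootstrapB > 0)
    ci <- bootstrapF2CI(prep$data, outcome, prep$term, B = bootstrapB,
                        seed = seed)
  structure(list(term = prep$label, estimate = res$estimate, T = res$T,
                 p = res$p, cohens_f2 = res$f2, f2_ci = ci, n = nrow(prep$data),
                 formula_descriptor = res$descriptor, fit = res$fit),
            class = "ModelResult")
}

prepareGamData <- function(table, outcome, predictor) {
  d <- table[!is.na(table[[outcome]]), ]
  if (predictor == "diagnosis_binary") {
    d <- d[d$anxiety %in% c("none", "severe"), ]
    d$pred <- as.numeric(d$anxiety == "severe")
    label <- "anxiety_diagnosis"
  } else if (predictor == "severity_ordinal") {
    d$pred <- d$severity
    label <- "anxiety_severity"
  } else if (predictor == "severity_factor") {
    d$pred <- factor(d$anxiety, levels = c("none", "mild", "severe"))
    label <- "anxiety_severity_factor"
  } else if (predictor == "depression_binary") {
    d <- d[d$depression %in% c("no_depression", "depression"), ]
    d$pred <- as.numeric(d$depression == "depression")
    label <- "depression_diagnosis"
  } else stop("unknown predictor: ", predictor)
  if (length(unique(d$pred)) < 2L)
    stop("fewer than 2 predictor groups after subsetting")
  list(data = d, term = "pred", label = label)
}

fitGamCore <- function(d, outcome, term, k = 4, fx = FALSE) {
  f <- gamFormula(outcome, term, k = k, fx = fx)
  fit <- mgcv::gam(f, data = d, method = "REML")
  pt <- summary(fit)$p.table
  row <- grep(paste0("^", term), rownames(pt))
  row <- row[length(row)]          # factor coding: report the last contrast
  red <- mgcv::gam(stats::update(f, paste(". ~ . -", term)), data = d,
                   method = "REML")
  f2 <- cohensF2(rsqGam(fit, d[[outcome]]), rsqGam(red, d[[outcome]]))
  list(estimate = pt[row, 1], T = pt[row, 3], p = pt[row, 4], f2 = f2,
       fit = fit,
       descriptor = paste(deparse(f), collapse = " "))
}

#' Cohen's f2 from full and reduced R-squared
#'
#' f2 = (R2_full - R2_reduced) / (1 - R2_full).
#'
#' @param r2Full,r2Reduced coefficients of determination of the nested
#'   models.
#' @return nonnegative effect size (negative differences are floored at 0).
#' @export
cohensF2 <- function(r2Full, r2Reduced) {
  stopifnot(r2Full <= 1, r2Reduced <= 1)
  if (r2Full >= 1) stop("R2 of the full model is 1; f2 undefined")
  max(0, (r2Full - r2Reduced) / (1 - r2Full))
}

#' Percentile bootstrap CI for Cohen's f2
#'
#' Resamples patients with replacement, refits full and reduced GAMs and
#' returns the percentile interval of the resulting f2 values.
#'
#' @param data prepared model data (must contain the \code{term} column).
#' @param outcome outcome column name.
#' @param term predictor column name.
#' @param B number of bootstrap replicates.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return numeric(2): lower and upper percentile bounds.
#' @export
bootstrapF2CI <- function(data, outcome, term, B = 1000, seed = 1L,
                          level = 0.95) {
  set.seed(seed %% .Machine$integer.max)
  vals <- vapply(seq_len(B), function(b) {
    d <- data[sample.int(nrow(data), replace = TRUE), ]
    if (length(unique(d[[term]])) < 2L) return(NA_real_)
    tryCatch(fitGamCore(d, outcome, term)$f2, error = function(e) NA_real_)
  }, numeric(1))
  a <- (1 - level) / 2
  stats::quantile(vals, c(a, 1 - a), na.rm = TRUE, names = FALSE)
}

#' @export
print.ModelResult <- function(x, ...) {
  cat(sprintf("%s: estimate %.4g, T = %.3g, p = %.3g, f2 = %.3g", x$term,
              x$estimate, x$T, x$p, x$cohens_f2))
  if (!is.na(x$f2_ci[1]))
    cat(sprintf(" [95%% CI %.3g-%.3g]", x$f2_ci[1], x$f2_ci[2]))
  cat(sprintf(", n = %d\n", x$n))
  invisible(x)
}
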