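#' @include stats-gam.R
NULL

#' Cohen's d for two independent groups
#'
#' (mean(a) - mean(b)) / pooled SD, pooled with n - 1 denominators.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return the standardized mean difference.
#' @export
cohensD <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("pooled SD is zero; Cohen's d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up adjustment with rejection set at level \code{q}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q FDR level.
#' @return list: \code{adjusted} p-values (same order as input) and logical
#'   \code{rejected}.
#' @export
bhFDR <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Demographic comparison battery
#'
#' One-way ANOVA across the three severity groups and a two-group
#' comparison (severe vs none) for continuous variables; Pearson chi-squared
#' for categorical variables; mirrors the usual Table-1 testing scheme.
#'
#' @param table analysis table (needs anxiety, age, phq2, sex and
#'   optionally race columns).
#' @param continuous,categorical variable names to test.
#' @return data.frame: variable, contrast ("severity" or "diagnosis"),
#'   statistic, p.
#' @export
demographicBattery <- function(table, continuous = c("age", "phq2"),
                               categorical = intersect(c("sex", "race"),
                                                       names(table))) {
  stopifnot(length(unique(table$anxiety)) >= 2)
  diag <- table[table$anxiety %in% c("none", "severe"), ]
  rows <- list()
  for (v in continuous) {
    fit <- stats::aov(stats::as.formula(paste(v, "~ anxiety")), data = table)
    s <- summary(fit)[[1]]
    rows[[paste(v, "sev")]] <- data.frame(
      variable = v, contrast = "severity",
      statistic = s[1, "F value"], p = s[1, "Pr(>F)"])
    tt <- stats::t.test(stats::as.formula(paste(v, "~ anxiety")), data = diag,
                        var.equal = TRUE)
    rows[[paste(v, "dx")]] <- data.frame(
      variable = v, contrast = "diagnosis",
      statistic = unname(tt$statistic), p = tt$p.value)
  }
  for (v in categorical) {
    ct <- suppressWarnings(stats::chisq.test(table(table$anxiety, table[[v]])))
    rows[[paste(v, "sev")]] <- data.frame(
      variable = v, contrast = "severity",
      statistic = unname(ct$statistic), p = ct$p.value)
    cd <- suppressWarnings(stats::chisq.test(table(diag$anxiety, diag[[v]])))
    rows[[paste(v, "dx")]] <- data.frame(
      variable = v, contrast = "diagnosis",
      statistic = unname(cd$statistic), p = cd$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PROMIS group comparisons
#'
#' Shapiro-Wilk normality checks per group and measure; unpaired t-tests
#' (severe vs none) per summary measure; paired t-tests (emotional vs
#' physical) within each group; Cohen's d per contrast; BH-FDR over the
#' whole t-test family.
#'
#' @param table analysis table with promis_physical / promis_emotional.
#' @param q FDR level.
#' @return list with \code{shapiro}, \code{contrasts} (data.frame incl.
#'   adjusted p and rejection flags).
#' @export
promisComparisons <- function(table, q = 0.05) {
  d <- table[!is.na(table$promis_physical) & !is.na(table$promis_emotional), ]
  groups <- intersect(c("none", "mild", "severe"), unique(d$anxiety))
  shapiro <- do.call(rbind, lapply(groups, function(g) {
    do.call(rbind, lapply(c("promis_physical", "promis_emotional"),
      function(m) {
        x <- d[[m]][d$anxiety == g]
        if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0)
          return(NULL)
        sw <- stats::shapiro.test(x)
        data.frame(group = g, measure = m, W = unname(sw$statistic),
                   p = sw$p.value)
      }))
  }))
  rows <- list()
  sev <- d[d$anxiety == "severe", ]; none <- d[d$anxiety == "none", ]
  for (m in c("promis_physical", "promis_emotional")) {
    if (nrow(sev) >= 2 && nrow(none) >= 2) {
      tt <- stats::t.test(sev[[m]], none[[m]], var.equal = TRUE)
      rows[[paste0("unpaired_", m)]] <- data.frame(
        contrast = paste0("severe_vs_none_", sub("promis_", "", m)),
        type = "unpaired", T = unname(tt$statistic), p = tt$p.value,
        cohens_d = cohensD(sev[[m]], none[[m]]), n = nrow(sev) + nrow(none))
    }
  }
  for (g in groups) {
    dg <- d[d$anxiety == g, ]
    if (nrow(dg) < 2) next
    diff <- dg$promis_emotional - dg$promis_physical
    if (stats::sd(diff) == 0) {
      tval <- 0; pval <- 1; dd <- 0
    } else {
      tt <- stats::t.test(dg$promis_emotional, dg$promis_physical,
                          paired = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
      dd <- mean(diff) / stats::sd(diff)
    }
    rows[[paste0("paired_", g)]] <- data.frame(
      contrast = paste0(g, "_emotional_vs_physical"), type = "paired",
      T = tval, p = pval, cohens_d = dd, n = nrow(dg))
  }
  contrasts <- do.call(rbind, rows)
  rownames(contrasts) <- NULL
  fdr <- bhFDR(contrasts$p, q)
  contrasts$p_fdr <- fdr$adjusted
  contrasts$significant <- fdr$rejected
  list(shapiro = shapiro, contrasts = contrasts)
}

#' Specificity and sensitivity analyses
#'
#' Re-runs the burden GAM for the control tract and comparator phenotype:
#' fornix burden vs anxiety (diagnosis and severity), UF burden vs
#' depression, and total lesion volume vs anxiety diagnosis, anxiety
#' severity and depression; BH-FDR is applied within this family.
#'
#' @param table analysis table (needs fornix_burden, depression,
#'   total_lesion_volume).
#' @param q FDR level.
#' @return data.frame: outcome, predictor, estimate, T, p, p_fdr,
#'   significant, cohens_f2, n.
#' @export
sensitivitySuite <- function(table, q = 0.05) {
  specs <- list(
    c("fornix_burden", "diagnosis_binary"),
    c("fornix_burden", "severity_ordinal"),
    c("uf_burden", "depression_binary"),
    c("total_lesion_volume", "diagnosis_binary"),
    c("total_lesion_volume", "severity_ordinal"),
    c("total_lesion_volume", "depression_binary"))
  rows <- lapply(specs, function(s) {
    m <- fitBurdenGAM(table, s[1], s[2])
    data.frame(outcome = s[1], predictor = m$term, estimate = m$estimate,
               T = m$T, p = m$p, cohens_f2 = m$cohens_f2, n = m$n)
  })
  out <- do.call(rbind, rows)
  fdr <- bhFDR(out$p, q)
  out$p_fdr <- fdr$adjusted
  out$significant <- fdr$rejected
  rownames(out) <- NULL
  out
}
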