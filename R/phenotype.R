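#' @include io-emr.R
NULL

#' Code dictionaries driving the phenotyping rules
#'
#' The stratification rules depend only on these configurable sets: ICD-10
#' prefixes counting as an anxiety diagnosis, medication names counting as
#' anxiolytics, the psychiatric diagnosis/medication superset used for the
#' asymptomatic criterion, and the analogous depression ruleset. Prefix
#' matching is case-insensitive and ignores the decimal point, so "F41"
#' matches "F41.1". The shipped anxiolytic and antidepressant lists are a
#' pragmatic formulary default and are meant to be replaced by site-specific
#' lists via YAML.
#'
#' @param anxietyDxPrefixes ICD-10 prefixes for anxiety disorders. Default
#'   covers the F40 (phobic) and F41 (other anxiety) blocks.
#' @param anxiolyticMeds medication names treated as anxiolytics.
#' @param psychDxPrefixes prefixes defining "any psychiatric diagnosis"
#'   (default the whole ICD-10 F chapter).
#' @param psychMeds medication superset defining "any psychiatric
#'   medication".
#' @param depressionDxPrefixes prefixes for depressive disorders (F32/F33).
#' @param antidepressantMeds antidepressant names for the depression ruleset.
#' @return a list of class \code{CodeDictionaries}.
#' @export
codeDictionaries <- function(
    anxietyDxPrefixes = c("F40", "F41"),
    anxiolyticMeds = c("lorazepam", "alprazolam", "clonazepam", "diazepam",
                       "buspirone", "hydroxyzine"),
    psychDxPrefixes = "F",
    psychMeds = NULL,
    depressionDxPrefixes = c("F32", "F33"),
    antidepressantMeds = c("sertraline", "fluoxetine", "citalopram",
                           "escitalopram", "paroxetine", "venlafaxine",
                           "duloxetine", "bupropion", "mirtazapine",
                           "amitriptyline")) {
  if (is.null(psychMeds))
    psychMeds <- union(anxiolyticMeds, antidepressantMeds)
  d <- list(anxietyDxPrefixes = toupper(anxietyDxPrefixes),
            anxiolyticMeds = tolower(anxiolyticMeds),
            psychDxPrefixes = toupper(psychDxPrefixes),
            psychMeds = tolower(psychMeds),
            depressionDxPrefixes = toupper(depressionDxPrefixes),
            antidepressantMeds = tolower(antidepressantMeds))
  stopifnot(lengths(d) > 0)
  structure(d, class = "CodeDictionaries")
}

#' Read code dictionaries from YAML
#'
#' @param path YAML file with any subset of the \code{codeDictionaries}
#'   arguments (snake_case keys also accepted).
#' @return a \code{CodeDictionaries} list.
#' @export
readCodeDictionaries <- function(path) {
  y <- yaml::read_yaml(path)
  canon <- function(nm) {
    gsub("_(\\w)", "\\U\\1", nm, perl = TRUE)
  }
  names(y) <- canon(names(y))
  do.call(codeDictionaries, y)
}

normalizeCode <- function(codes) gsub("\\.", "", toupper(trimws(codes)))

validateCodes <- function(codes) {
  norm <- normalizeCode(codes)
  bad <- !grepl("^[A-Z][0-9A-Z]*$", norm) & nzchar(norm)
  bad <- bad | !nzchar(norm)
  if (any(bad))
    stop(sprintf("malformed ICD-10 codes: %s",
                 paste(sQuote(codes[bad]), collapse = ", ")))
  norm
}

matchesPrefix <- function(codes, prefixes) {
  norm <- validateCodes(codes)
  pfx <- normalizeCode(prefixes)
  if (length(norm) == 0L) return(FALSE)
  any(vapply(pfx, function(p) any(startsWith(norm, p)), logical(1)))
}

phqZeroConfirmed <- function(record) {
  pq <- phqObs(record)
  nrow(pq) > 0L && all(pq$score == 0L)
}

psychFree <- function(record, dicts) {
  !matchesPrefix(icd10Codes(record), dicts$psychDxPrefixes) &&
    !any(medications(record) %in% dicts$psychMeds)
}

#' Stratify a patient into anxiety severity groups
#'
#' Implements the three-group EMR stratification: \emph{severe} requires
#' both an anxiety diagnosis and an anxiolytic order; \emph{mild} exactly
#' one of the two; \emph{none} requires no psychiatric diagnoses, no
#' psychiatric medications, and at least one PHQ-2/PHQ-9 observation, all
#' with score 0, to confirm the absence of psychopathology. Psychiatrically
#' quiet records with no PHQ available (or a nonzero PHQ) are
#' \emph{excluded}.
#'
#' @param record a \linkS4class{PatientRecord}.
#' @param dicts a \code{\link{codeDictionaries}} list.
#' @return list with \code{label} in \{"none","mild","severe","excluded"\}
#'   and \code{basis}, a named logical vector of the rules that fired.
#' @export
classifyAnxiety <- function(record, dicts = codeDictionaries()) {
  hasDx <- matchesPrefix(icd10Codes(record), dicts$anxietyDxPrefixes)
  hasMed <- any(medications(record) %in% dicts$anxiolyticMeds)
  pf <- psychFree(record, dicts)
  pz <- phqZeroConfirmed(record)
  label <- if (hasDx && hasMed) "severe"
    else if (hasDx || hasMed) "mild"
    else if (pf && pz) "none"
    else "excluded"
  list(label = label,
       basis = c(has_anx_dx = hasDx, has_anxiolytic = hasMed,
                 psych_free = pf, phq_zero_confirmed = pz))
}

#' Binary depression phenotype
#'
#' A patient is \emph{depression} when a depressive-disorder diagnosis or an
#' antidepressant order is present (both as well); \emph{no_depression}
#' reuses the psychiatrically-asymptomatic criterion (psych-free with a
#' confirmatory all-zero PHQ); anything else is \emph{excluded}.
#'
#' @inheritParams classifyAnxiety
#' @return label string.
#' @export
classifyDepression <- function(record, dicts = codeDictionaries()) {
  hasDx <- matchesPrefix(icd10Codes(record), dicts$depressionDxPrefixes)
  hasMed <- any(medications(record) %in% dicts$antidepressantMeds)
  if (hasDx || hasMed) return("depression")
  if (psychFree(record, dicts) && phqZeroConfirmed(record)) return("no_depression")
  "excluded"
}

PROMIS_PHYSICAL_DOMAINS <- c("physical_health", "physical_activities",
                             "fatigue", "physical_impairment")
PROMIS_EMOTIONAL_DOMAINS <- c("mental_health_mood", "emotional_problems",
                              "quality_of_life", "social_satisfaction",
                              "social_activities", "mental_impairment")

#' PROMIS physical and emotional functioning summaries
#'
#' For each of the 10 PROMIS domains the observation closest in time to the
#' MRI is selected; the physical summary is the mean of 4 physical domains
#' and the emotional summary the mean of 6 emotional/social domains.
#' Domains with no observation are skipped and reflected in the
#' \code{n_*_domains} counts; a summary with zero contributing domains is
#' \code{NA} and flagged.
#'
#' @param record a \linkS4class{PatientRecord} with PROMIS observations.
#' @param mriDate the reference MRI date.
#' @return list with \code{physical}, \code{emotional},
#'   \code{n_physical_domains}, \code{n_emotional_domains},
#'   \code{incomplete} flag.
#' @export
promisSummaries <- function(record, mriDate = selectFirstMri(record)) {
  obs <- promisObs(record)
  if (nrow(obs) == 0L) stop("record has no PROMIS observations")
  mriDate <- as.Date(mriDate)
  pick <- function(domain) {
    d <- obs[obs$domain == domain, ]
    if (nrow(d) == 0L) return(NA_real_)
    dist <- abs(as.numeric(d$date - mriDate))
    d <- d[order(dist, d$date), ]
    d$score[1]
  }
  phys <- vapply(PROMIS_PHYSICAL_DOMAINS, pick, numeric(1))
  emot <- vapply(PROMIS_EMOTIONAL_DOMAINS, pick, numeric(1))
  nP <- sum(!is.na(phys)); nE <- sum(!is.na(emot))
  list(physical = if (nP) mean(phys, na.rm = TRUE) else NA_real_,
       emotional = if (nE) mean(emot, na.rm = TRUE) else NA_real_,
       n_physical_domains = nP, n_emotional_domains = nE,
       incomplete = nP == 0L || nE == 0L)
}

#' Earliest clinical MRI of a record
#'
#' @param record a \linkS4class{PatientRecord}.
#' @return the chronologically first MRI date.
#' @export
selectFirstMri <- function(record) {
  d <- mriDates(record)
  if (length(d) == 0L)
    stop(sprintf("patient %s has no MRI dates", patientId(record)))
  min(d)
}

#' Classify a whole cohort of records
#'
#' @param records list of \linkS4class{PatientRecord}.
#' @param dicts code dictionaries.
#' @return data.frame with patient_id, anxiety label, severity code
#'   (none=0, mild=1, severe=2, NA for excluded), depression label, the
#'   rule basis columns, and min PHQ-2 where observed.
#' @export
classifyCohort <- function(records, dicts = codeDictionaries()) {
  n <- length(records)
  sevMap <- c(none = 0, mild = 1, severe = 2, excluded = NA_real_)
  anx <- dep <- character(n)
  basis <- matrix(NA, n, 4)
  phq2 <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- records[[i]]
    a <- classifyAnxiety(r, dicts)
    anx[i] <- a$label
    dep[i] <- classifyDepression(r, dicts)
    basis[i, ] <- a$basis
    pq <- phqObs(r)
    s2 <- pq$score[pq$instrument == "PHQ2"]
    if (length(s2)) phq2[i] <- max(s2)
  }
  data.frame(patient_id = vapply(records, patientId, character(1)),
             anxiety = anx, severity = unname(sevMap[anx]),
             depression = dep,
             has_anx_dx = basis[, 1], has_anxiolytic = basis[, 2],
             psych_free = basis[, 3], phq_zero_confirmed = basis[, 4],
             phq2 = phq2)
}
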