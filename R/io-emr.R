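#' @include AllClasses.R
NULL

EMR_EVENT_TYPES <- c("icd10", "medication", "phq2", "phq9",
                     "promis_domain", "mri")

#' Construct a PatientRecord
#'
#' @param patientId id string.
#' @param icd10Codes character vector of ICD-10 codes.
#' @param medications character vector of medication names (normalised to
#'   lower case internally).
#' @param phqObs data.frame(instrument, score, date) or NULL.
#' @param promisObs data.frame(domain, score, date) or NULL.
#' @param mriDates Date vector.
#' @param age,sex,totalBrainVolume covariates.
#' @return a \linkS4class{PatientRecord}.
#' @export
patientRecord <- function(patientId, icd10Codes = character(),
                          medications = character(), phqObs = NULL,
                          promisObs = NULL, mriDates = as.Date(character()),
                          age = NA_real_, sex = NA_character_,
                          totalBrainVolume = NA_real_) {
  if (is.null(phqObs))
    phqObs <- data.frame(instrument = character(), score = integer(),
                         date = as.Date(character()))
  if (is.null(promisObs))
    promisObs <- data.frame(domain = character(), score = numeric(),
                            date = as.Date(character()))
  new("PatientRecord", patientId = as.character(patientId),
      icd10Codes = toupper(icd10Codes),
      medications = tolower(medications),
      phqObs = phqObs, promisObs = promisObs,
      mriDates = sort(as.Date(mriDates)),
      age = as.numeric(age), sex = as.character(sex),
      totalBrainVolume = as.numeric(totalBrainVolume))
}

#' Write patient records as a long-format EMR CSV
#'
#' One row per patient-event with columns patient_id, event_type
#' (icd10 / medication / phq2 / phq9 / promis_domain / mri), code_or_name,
#' value, date.
#'
#' @param records list of \linkS4class{PatientRecord}.
#' @param path output CSV path.
#' @export
writeEMR <- function(records, path) {
  rows <- lapply(records, function(r) {
    pid <- patientId(r)
    out <- list()
    if (length(icd10Codes(r)))
      out$codes <- data.frame(patient_id = pid, event_type = "icd10",
                              code_or_name = icd10Codes(r), value = NA_real_,
                              date = NA_character_)
    if (length(medications(r)))
      out$meds <- data.frame(patient_id = pid, event_type = "medication",
                             code_or_name = medications(r), value = NA_real_,
                             date = NA_character_)
    pq <- phqObs(r)
    if (nrow(pq))
      out$phq <- data.frame(patient_id = pid,
                            event_type = tolower(pq$instrument),
                            code_or_name = NA_character_, value = pq$score,
                            date = as.character(pq$date))
    pr <- promisObs(r)
    if (nrow(pr))
      out$promis <- data.frame(patient_id = pid, event_type = "promis_domain",
                               code_or_name = pr$domain, value = pr$score,
                               date = as.character(pr$date))
    if (length(mriDates(r)))
      out$mri <- data.frame(patient_id = pid, event_type = "mri",
                            code_or_name = NA_character_, value = NA_real_,
                            date = as.character(mriDates(r)))
    do.call(rbind, out)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write the covariates CSV
#'
#' @param records list of \linkS4class{PatientRecord}.
#' @param path output CSV path.
#' @param race optional character vector of self-reported race, aligned with
#'   \code{records}.
#' @export
writeCovariates <- function(records, path, race = NULL) {
  df <- data.frame(
    patient_id = vapply(records, patientId, character(1)),
    age = vapply(records, function(r) r@age, numeric(1)),
    sex = vapply(records, function(r) r@sex, character(1)),
    total_brain_volume_mm3 = vapply(records, function(r) r@totalBrainVolume,
                                    numeric(1)))
  if (!is.null(race)) df$race <- race
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an EMR CSV (plus optional covariates) into PatientRecords
#'
#' @param emrPath path to the long-format EMR CSV written by
#'   \code{\link{writeEMR}}.
#' @param covariatesPath optional path to the covariates CSV.
#' @return named list of \linkS4class{PatientRecord}, keyed by patient_id.
#' @export
readEMR <- function(emrPath, covariatesPath = NULL) {
  df <- utils::read.csv(emrPath, colClasses = c(
    patient_id = "character", event_type = "character",
    code_or_name = "character", value = "numeric", date = "character"))
  bad <- !(df$event_type %in% EMR_EVENT_TYPES)
  if (any(bad))
    stop(sprintf("unknown event_type at EMR rows: %s",
                 paste(utils::head(which(bad), 10), collapse = ", ")))
  cov <- NULL
  if (!is.null(covariatesPath)) {
    cov <- utils::read.csv(covariatesPath,
                           colClasses = c(patient_id = "character"))
    rownames(cov) <- cov$patient_id
  }
  split_df <- split(df, df$patient_id)
  recs <- lapply(names(split_df), function(pid) {
    d <- split_df[[pid]]
    phq <- d[d$event_type %in% c("phq2", "phq9"), ]
    promis <- d[d$event_type == "promis_domain", ]
    cv <- if (!is.null(cov) && pid %in% rownames(cov)) cov[pid, ] else NULL
    patientRecord(
      patientId = pid,
      icd10Codes = d$code_or_name[d$event_type == "icd10"],
      medications = d$code_or_name[d$event_type == "medication"],
      phqObs = if (nrow(phq)) data.frame(
        instrument = toupper(phq$event_type),
        score = as.integer(phq$value),
        date = as.Date(phq$date)) else NULL,
      promisObs = if (nrow(promis)) data.frame(
        domain = promis$code_or_name,
        score = promis$value,
        date = as.Date(promis$date)) else NULL,
      mriDates = as.Date(d$date[d$event_type == "mri"]),
      age = if (is.null(cv)) NA_real_ else cv$age,
      sex = if (is.null(cv)) NA_character_ else cv$sex,
      totalBrainVolume = if (is.null(cv)) NA_real_ else
        cv$total_brain_volume_mm3)
  })
  names(recs) <- names(split_df)
  recs
}
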