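#' @include synth-cohort.R stats-tests.R io-nifti.R io-streamlines.R
NULL

#' Build a pipeline run configuration
#'
#' Either a \code{synth} block (a \code{\link{synthConfig}} or list of its
#' arguments) or the three real-input paths (\code{emr}, \code{masksDir},
#' \code{bundlesDir}) must be given.
#'
#' @param outDir output directory.
#' @param synth optional synthetic-cohort block.
#' @param emr,covariates,masksDir,bundlesDir paths to real inputs.
#' @param dicts optional path to a code-dictionary YAML.
#' @param bootstrapB bootstrap replicates for the headline f2 CIs.
#' @param q FDR level for the sensitivity/post-hoc families.
#' @param seed master seed; every stage derives its substream from it.
#' @param logLevel "INFO" or "DEBUG".
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(outDir, synth = NULL, emr = NULL, covariates = NULL,
                      masksDir = NULL, bundlesDir = NULL, dicts = NULL,
                      bootstrapB = 200, q = 0.05, seed = 1L,
                      logLevel = "INFO") {
  if (is.null(synth) && (is.null(emr) || is.null(masksDir) ||
                         is.null(bundlesDir)))
    stop("either a synth block or emr + masksDir + bundlesDir paths are required")
  structure(list(outDir = outDir, synth = synth, emr = emr,
                 covariates = covariates, masksDir = masksDir,
                 bundlesDir = bundlesDir, dicts = dicts,
                 bootstrapB = bootstrapB, q = q, seed = as.integer(seed),
                 logLevel = logLevel),
            class = "RunConfig")
}

#' Read a RunConfig from YAML
#'
#' @param path YAML file with snake_case or camelCase keys mirroring
#'   \code{\link{runConfig}}.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  camel <- function(nm) gsub("_(\\w)", "\\U\\1", nm, perl = TRUE)
  names(y) <- camel(names(y))
  if (!is.null(y$synth)) names(y$synth) <- camel(names(y$synth))
  do.call(runConfig, y)
}

pipeLog <- function(cfg, level, fmt, ...) {
  lv <- c(DEBUG = 1, INFO = 2)
  if (lv[[level]] >= lv[[cfg$logLevel]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

stageFail <- function(stage, msg) {
  stop(sprintf("stage '%s' failed: %s", stage, msg), call. = FALSE)
}

#' Validate pipeline inputs
#'
#' Checks file existence, NIfTI and streamline header sanity and EMR schema
#' conformance without mutating anything.
#'
#' @param config a \code{\link{runConfig}}.
#' @return character vector of diagnostics (empty when all inputs are
#'   sound).
#' @export
validateInputs <- function(config) {
  diags <- character()
  if (!is.null(config$synth)) {
    ok <- tryCatch({
      if (!inherits(config$synth, "SynthConfig"))
        do.call(synthConfig, config$synth)
      TRUE
    }, error = function(e) e$message)
    if (!isTRUE(ok)) diags <- c(diags, paste("synth block:", ok))
    return(diags)
  }
  if (!file.exists(config$emr)) {
    diags <- c(diags, sprintf("EMR file missing: %s", config$emr))
  } else {
    df <- tryCatch(utils::read.csv(config$emr), error = function(e) NULL)
    need <- c("patient_id", "event_type", "code_or_name", "value", "date")
    if (is.null(df) || !all(need %in% names(df))) {
      diags <- c(diags, "EMR CSV lacks the required columns")
    } else {
      bad <- which(!(df$event_type %in% EMR_EVENT_TYPES))
      if (length(bad))
        diags <- c(diags, sprintf("EMR rows with unknown event_type: %s",
                                  paste(utils::head(bad, 10), collapse = ", ")))
    }
  }
  for (dirarg in c("masksDir", "bundlesDir"))
    if (!is.null(config[[dirarg]]) && !dir.exists(config[[dirarg]]))
      diags <- c(diags, sprintf("%s does not exist: %s", dirarg,
                                config[[dirarg]]))
  if (!is.null(config$masksDir) && dir.exists(config$masksDir))
    for (f in list.files(config$masksDir, pattern = "\\.nii(\\.gz)?$",
                         full.names = TRUE)) {
      ok <- tryCatch({ RNifti::niftiHeader(f); TRUE },
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok) diags <- c(diags, sprintf("unreadable NIfTI header: %s", f))
    }
  if (!is.null(config$bundlesDir) && dir.exists(config$bundlesDir))
    for (f in list.files(config$bundlesDir, pattern = "\\.(trk|tck)$",
                         full.names = TRUE)) {
      ok <- tryCatch({
        if (grepl("\\.trk$", f)) readTRK(f) else readTCK(f)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) diags <- c(diags, sprintf("unreadable bundle: %s", f))
    }
  diags
}

#' Score tract burden for a set of masks
#'
#' @param masks named list of \linkS4class{LesionMask} (names = patient
#'   ids).
#' @param bundles named list with UF_left/UF_right/fornix_left/fornix_right.
#' @return data.frame: patient_id, uf_burden, fornix_burden,
#'   total_lesion_volume plus per-side audit volumes.
#' @export
scoreCohortBurden <- function(masks, bundles) {
  # masks generated on one template grid share an affine; precompute each
  # streamline's voxel set once and reuse it across patients
  A0 <- worldAffine(masks[[1]])
  shared <- all(vapply(masks, function(m)
    isTRUE(all.equal(worldAffine(m), A0)) &&
      all(gridShape(m) == gridShape(masks[[1]])), logical(1)))
  if (!shared) {
    rows <- lapply(names(masks), function(pid) {
      uf <- tractBurden(bundles$UF_left, bundles$UF_right, masks[[pid]],
                        tractName = "UF")
      fx <- tractBurden(bundles$fornix_left, bundles$fornix_right,
                        masks[[pid]], tractName = "fornix")
      data.frame(patient_id = pid, uf_burden = uf$burden,
                 fornix_burden = fx$burden,
                 total_lesion_volume = uf$total_lesion_volume,
                 uf_injured_vol_l = uf$injured_vol_l,
                 uf_injured_vol_r = uf$injured_vol_r,
                 uf_canonical_vol_l = uf$canonical_vol_l,
                 uf_canonical_vol_r = uf$canonical_vol_r)
    })
    return(do.call(rbind, rows))
  }
  grid <- maskGrid(masks[[1]])
  step <- minSpacing(grid) / 2
  ids <- lapply(bundles, function(b)
    lapply(streamlines(b), streamlineVoxelIds, grid = grid, step = step))
  vv <- voxelVolume(grid)
  sideStats <- function(slIds, lesion) {
    can <- unique(unlist(slIds))
    inj <- vapply(slIds, function(v) any(v %in% lesion), logical(1))
    injVox <- unique(unlist(slIds[inj]))
    c(can = length(can) * vv, inj = length(injVox) * vv, n = sum(inj))
  }
  rows <- lapply(names(masks), function(pid) {
    lesion <- maskVoxelIds(masks[[pid]])
    ufL <- sideStats(ids$UF_left, lesion)
    ufR <- sideStats(ids$UF_right, lesion)
    fxL <- sideStats(ids$fornix_left, lesion)
    fxR <- sideStats(ids$fornix_right, lesion)
    data.frame(
      patient_id = pid,
      uf_burden = ((ufL["inj"] + ufR["inj"]) / 2) /
        ((ufL["can"] + ufR["can"]) / 2),
      fornix_burden = ((fxL["inj"] + fxR["inj"]) / 2) /
        ((fxL["can"] + fxR["can"]) / 2),
      total_lesion_volume = length(lesion) * voxelVolume(masks[[pid]]),
      uf_injured_vol_l = unname(ufL["inj"]),
      uf_injured_vol_r = unname(ufR["inj"]),
      uf_canonical_vol_l = unname(ufL["can"]),
      uf_canonical_vol_r = unname(ufR["can"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Orchestrates synth (or real-input loading), phenotyping, burden scoring
#' and the statistical layer; writes intermediate CSVs, a JSON + text
#' report and a reproducibility manifest into \code{outDir}.
#'
#' @param config a \code{\link{runConfig}}.
#' @return invisible list with the analysis table, the model report and
#'   output paths.
#' @export
runAll <- function(config) {
  t0 <- Sys.time()
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  dicts <- if (is.null(config$dicts)) codeDictionaries() else
    readCodeDictionaries(config$dicts)

  # --- stage: inputs -------------------------------------------------------
  if (!is.null(config$synth)) {
    sc <- if (inherits(config$synth, "SynthConfig")) config$synth else
      do.call(synthConfig, config$synth)
    sc$seed <- sc$seed + config$seed
    pipeLog(config, "INFO", "synth: generating cohort of %d patients",
            sc$nPatients)
    cohort <- tryCatch(makeCohort(sc),
                       error = function(e) stageFail("synth", e$message))
    records <- cohort$records
    masks <- cohort$masks
    names(masks) <- cohort$covariates$patient_id
    bundles <- cohort$bundles
    covariates <- cohort$covariates
    writeEMR(records, file.path(config$outDir, "emr.csv"))
    utils::write.csv(covariates, file.path(config$outDir, "covariates.csv"),
                     row.names = FALSE)
  } else {
    diags <- validateInputs(config)
    if (length(diags)) stageFail("inputs", paste(diags, collapse = "; "))
    records <- tryCatch(readEMR(config$emr, config$covariates),
                        error = function(e) stageFail("inputs", e$message))
    covariates <- utils::read.csv(config$covariates,
                                  colClasses = c(patient_id = "character"))
    maskFiles <- list.files(config$masksDir, pattern = "\\.nii(\\.gz)?$",
                            full.names = TRUE)
    if (!length(maskFiles)) stageFail("burden", "no NIfTI masks found")
    masks <- lapply(maskFiles, readLesionMask)
    names(masks) <- sub("\\.nii(\\.gz)?$", "", basename(maskFiles))
    bundleNames <- c("UF_left", "UF_right", "fornix_left", "fornix_right")
    bundles <- lapply(bundleNames, function(b) {
      f <- file.path(config$bundlesDir, paste0(b, ".trk"))
      if (!file.exists(f)) f <- file.path(config$bundlesDir, paste0(b, ".tck"))
      if (!file.exists(f))
        stageFail("burden", sprintf("bundle '%s' not found in %s", b,
                                    config$bundlesDir))
      if (grepl("\\.trk$", f)) readTRK(f, name = b) else readTCK(f, name = b)
    })
    names(bundles) <- bundleNames
  }

  # --- stage: phenotype ----------------------------------------------------
  strata <- tryCatch(classifyCohort(records, dicts),
                     error = function(e) stageFail("phenotype", e$message))
  pipeLog(config, "INFO", "phenotype: %d records -> %s", length(records),
          paste(names(table(strata$anxiety)), table(strata$anxiety),
                sep = "=", collapse = ", "))
  utils::write.csv(strata, file.path(config$outDir, "strata.csv"),
                   row.names = FALSE)

  # --- stage: burden -------------------------------------------------------
  burdens <- tryCatch(scoreCohortBurden(masks, bundles),
                      error = function(e) stageFail("burden", e$message))
  pipeLog(config, "INFO", "burden: scored %d masks on %d tract bundles",
          nrow(burdens), length(bundles))
  utils::write.csv(burdens, file.path(config$outDir, "burden.csv"),
                   row.names = FALSE)

  # --- stage: stats --------------------------------------------------------
  promis <- do.call(rbind, lapply(records, function(r) {
    if (nrow(promisObs(r)) == 0L || length(mriDates(r)) == 0L) return(NULL)
    s <- promisSummaries(r)
    data.frame(patient_id = patientId(r), promis_physical = s$physical,
               promis_emotional = s$emotional)
  }))
  tab <- buildAnalysisTable(strata, burdens, covariates, promis)
  if (length(unique(tab$anxiety)) < 2)
    stageFail("stats", "fewer than 2 anxiety groups in the analysis table")
  report <- tryCatch(list(
    uf_diagnosis = fitBurdenGAM(tab, "uf_burden", "diagnosis_binary",
                                bootstrapB = config$bootstrapB,
                                seed = config$seed + 17L),
    uf_severity = fitBurdenGAM(tab, "uf_burden", "severity_ordinal",
                               bootstrapB = config$bootstrapB,
                               seed = config$seed + 18L),
    demographics = demographicBattery(tab),
    promis = promisComparisons(tab, q = config$q),
    sensitivity = sensitivitySuite(tab, q = config$q)),
    error = function(e) stageFail("stats", e$message))
  utils::write.csv(tab, file.path(config$outDir, "analysis_table.csv"),
                   row.names = FALSE)

  # --- report + manifest ---------------------------------------------------
  strip <- function(m) m[setdiff(names(m), "fit")]
  jsonReport <- list(
    models = list(uf_diagnosis = strip(report$uf_diagnosis),
                  uf_severity = strip(report$uf_severity)),
    demographics = report$demographics,
    promis = report$promis,
    sensitivity = report$sensitivity,
    n_included = nrow(tab),
    groups = as.list(table(tab$anxiety)))
  jsonlite::write_json(jsonReport, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)
  writeTextReport(jsonReport, file.path(config$outDir, "report.txt"))
  manifest <- list(
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("tractburden")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(writeConfigSnapshot(config))),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeLog(config, "INFO", "pipeline finished in %.1f s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(table = tab, report = report,
                 outDir = normalizePath(config$outDir)))
}

writeConfigSnapshot <- function(config) {
  snap <- config
  snap$outDir <- NULL
  path <- file.path(config$outDir, "config_snapshot.yaml")
  yaml::write_yaml(lapply(snap, function(x)
    if (inherits(x, "SynthConfig")) unclass(x) else x), path)
  path
}

writeTextReport <- function(rep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(fmt, ...) writeLines(sprintf(fmt, ...), con)
  w("Tract lesion burden analysis report")
  w("===================================")
  w("Included patients: %d (%s)", rep$n_included,
    paste(names(rep$groups), unlist(rep$groups), sep = "=", collapse = ", "))
  w("")
  w("Hypothesis-driven models (alpha = .05, unadjusted):")
  for (nm in names(rep$models)) {
    m <- rep$models[[nm]]
    ci <- if (!is.na(m$f2_ci[1]))
      sprintf(" [95%% CI, %.2f-%.2f]", m$f2_ci[1], m$f2_ci[2]) else ""
    w("  %-22s T = %.2f, P = %.3g; Cohen f2, %.2f%s (n = %d)",
      paste0(m$term, " (", nm, ")"), m$T, m$p, m$cohens_f2, ci, m$n)
  }
  w("")
  w("Sensitivity analyses (BH-FDR within family):")
  s <- rep$sensitivity
  for (i in seq_len(nrow(s)))
    w("  %-20s ~ %-20s T = %.2f, P(FDR) = %.3g%s", s$outcome[i],
      s$predictor[i], s$T[i], s$p_fdr[i],
      if (s$significant[i]) " *" else "")
  w("")
  w("PROMIS contrasts (BH-FDR within family):")
  p <- rep$promis$contrasts
  for (i in seq_len(nrow(p)))
    w("  %-32s T = %.2f, P(FDR) = %.3g, d = %.2f%s", p$contrast[i], p$T[i],
      p$p_fdr[i], p$cohens_d[i], if (p$significant[i]) " *" else "")
  invisible(path)
}
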