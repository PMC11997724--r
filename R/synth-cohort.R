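#' @include synth-mask.R synth-bundles.R phenotype.R
NULL

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the motivating cohort: 372
#' patients split 27/67/6 percent into no/mild/severe anxiety, PHQ-2 group
#' means of about 0, 0.57 and 1.16, a positive association of UF-analog
#' lesion burden with anxiety severity, a severity-independent fornix-analog
#' overlap, and more background lesion volume in psychiatrically affected
#' groups.
#'
#' @param nPatients cohort size.
#' @param groupProps proportions of no/mild/severe anxiety (sum to 1).
#' @param burdenMeans target UF burden fraction per group.
#' @param burdenNoiseSd SD of per-patient noise on the burden target.
#' @param fornixBurdenMean group-independent fornix burden target.
#' @param totalLesionExtra per-group background lesion volume, mm^3.
#' @param gridShape template grid (each dimension >= 16).
#' @param voxelSizeMm isotropic voxel edge, mm.
#' @param seed integer master seed.
#' @param promisEffect drop in mean PROMIS emotional T-score per severity
#'   step (physical domains get 40 percent of it).
#' @param phqMissingRate probability that a latent no-anxiety patient has no
#'   recorded PHQ (and is therefore excluded by phenotyping).
#' @param phqMeans PHQ-2 group means for mild/severe (Poisson, capped at 6).
#' @param depressionRate probability that a mild/severe-anxiety patient also
#'   carries a depression diagnosis or antidepressant order.
#' @param nStreamlinesPerSide streamlines per hemisphere in the toy tracts.
#' @return a validated list of class \code{SynthConfig}.
#' @export
synthConfig <- function(nPatients = 372L,
                        groupProps = c(0.27, 0.67, 0.06),
                        burdenMeans = c(0.02, 0.05, 0.10),
                        burdenNoiseSd = 0.04,
                        fornixBurdenMean = 0.05,
                        totalLesionExtra = c(1000, 2500, 4000),
                        gridShape = c(64L, 64L, 64L),
                        voxelSizeMm = 1,
                        seed = 1L,
                        promisEffect = 6,
                        phqMissingRate = 0.1,
                        phqMeans = c(0.57, 1.16),
                        depressionRate = 0.75,
                        nStreamlinesPerSide = 50L) {
  cfg <- list(nPatients = as.integer(nPatients), groupProps = groupProps,
              burdenMeans = burdenMeans, burdenNoiseSd = burdenNoiseSd,
              fornixBurdenMean = fornixBurdenMean,
              totalLesionExtra = totalLesionExtra,
              gridShape = as.integer(gridShape), voxelSizeMm = voxelSizeMm,
              seed = as.integer(seed), promisEffect = promisEffect,
              phqMissingRate = phqMissingRate, phqMeans = phqMeans,
              depressionRate = depressionRate,
              nStreamlinesPerSide = as.integer(nStreamlinesPerSide))
  if (abs(sum(cfg$groupProps) - 1) > 1e-9)
    stop("groupProps must sum to 1")
  if (any(cfg$burdenMeans < 0 | cfg$burdenMeans > 1) ||
      cfg$fornixBurdenMean < 0 || cfg$fornixBurdenMean > 1)
    stop("burden means must lie in [0, 1]")
  if (any(cfg$gridShape < 16L))
    stop("gridShape dimensions must each be >= 16")
  if (cfg$voxelSizeMm <= 0) stop("voxelSizeMm must be positive")
  if (cfg$phqMissingRate < 0 || cfg$phqMissingRate > 1)
    stop("phqMissingRate must be a probability")
  structure(cfg, class = "SynthConfig")
}

#' Read a SynthConfig from YAML
#'
#' @param path YAML file whose keys mirror the \code{\link{synthConfig}}
#'   arguments (snake_case accepted).
#' @return a \code{SynthConfig}.
#' @export
readSynthConfig <- function(path) {
  y <- yaml::read_yaml(path)
  names(y) <- gsub("_(\\w)", "\\U\\1", names(y), perl = TRUE)
  do.call(synthConfig, y)
}

# capped-Poisson PHQ-2 scores on 0..6
rPhq2 <- function(n, lambda) pmin(stats::rpois(n, lambda), 6L)

#' Generate a synthetic cohort
#'
#' Draws a latent anxiety group per patient, writes EMR events so that the
#' phenotyping rules recover the group (no-anxiety patients are
#' psychiatrically quiet with a confirmatory PHQ-2 of 0 unless their PHQ is
#' missing; mild patients carry exactly one of an F40/F41 code or an
#' anxiolytic; severe patients both), plants per-patient lesion masks so the
#' UF-analog burden follows the per-group targets while the fornix-analog
#' overlap is group-independent, and adds per-group background lesion
#' volume away from both tracts. PROMIS emotional scores decrease with
#' severity.
#'
#' @param config a \code{\link{synthConfig}}.
#' @param imaging logical; when FALSE, skips toy tracts and voxel grids and
#'   instead draws the burden variables directly from the same truncated
#'   planting distributions. This is the fast path for Monte-Carlo use of
#'   the statistical layer; the imaging path is the ground truth it mirrors.
#' @return list with elements \code{records} (PatientRecords), \code{masks}
#'   (LesionMasks; NULL when \code{imaging = FALSE}), \code{bundles},
#'   \code{grid}, \code{covariates} (data.frame incl. race),
#'   \code{truth} (data.frame: latent group, planted and, for the imaging
#'   path, recomputed burdens) and \code{config}.
#' @export
makeCohort <- function(config = synthConfig(), imaging = TRUE) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed %% .Machine$integer.max)
  n <- config$nPatients
  group <- sample.int(3L, n, replace = TRUE, prob = config$groupProps)

  bundles <- NULL; grid <- NULL; masks <- NULL
  ufInc <- NULL; fxInc <- NULL
  if (imaging) {
    bundles <- makeToyBundles(config$gridShape, config$voxelSizeMm,
                              config$nStreamlinesPerSide,
                              seed = config$seed + 101L)
    grid <- voxelGrid(config$gridShape, spacing = config$voxelSizeMm)
    ufInc <- tractIncidence(bundles[c("UF_left", "UF_right")], grid)
    fxInc <- tractIncidence(bundles[c("fornix_left", "fornix_right")], grid)
    masks <- vector("list", n)
  }

  dicts <- codeDictionaries()
  age <- pmin(pmax(stats::rnorm(n, 47.7, 11.4), 18), 85)
  sex <- ifelse(stats::runif(n) < 0.80, "F", "M")
  tbv <- stats::rnorm(n, 1.2e6, 1.1e5)
  race <- sample(c("White", "Black", "Asian", "Other", "Unknown"), n,
                 replace = TRUE, prob = c(0.72, 0.20, 0.01, 0.05, 0.02))
  mriDate <- as.Date("2015-01-01") + floor(stats::runif(n, 0, 1500))

  ufTarget <- pmin(1, pmax(0, config$burdenMeans[group] +
                             stats::rnorm(n, 0, config$burdenNoiseSd)))
  fxTarget <- pmin(1, pmax(0, config$fornixBurdenMean +
                             stats::rnorm(n, 0, config$burdenNoiseSd)))
  extraVol <- config$totalLesionExtra[group] *
    stats::runif(n, 0.7, 1.3)

  ufAchieved <- rep(NA_real_, n); fxAchieved <- rep(NA_real_, n)
  records <- vector("list", n)
  promisPhys <- promisEmot <- rep(NA_real_, n)
  phq2 <- rep(NA_integer_, n)

  anxCodePool <- c("F41.1", "F40.0", "F41.0")
  for (i in seq_len(n)) {
    g <- group[i]
    codes <- "G35"
    meds <- character()
    if (g >= 2L) {
      pickDx <- if (g == 3L) TRUE else stats::runif(1) < 0.5
      if (g == 3L || pickDx)
        codes <- c(codes, sample(anxCodePool, 1))
      if (g == 3L || !pickDx)
        meds <- c(meds, sample(dicts$anxiolyticMeds, 1))
      if (stats::runif(1) < config$depressionRate) {
        codes <- c(codes, sample(c("F32.9", "F33.1"), 1))
        meds <- union(meds, sample(dicts$antidepressantMeds, 1))
      }
    }
    phq <- NULL
    if (g == 1L) {
      if (stats::runif(1) >= config$phqMissingRate) {
        phq <- data.frame(instrument = "PHQ2", score = 0L,
                          date = mriDate[i] - 30)
        phq2[i] <- 0L
      }
    } else {
      phq2[i] <- rPhq2(1, config$phqMeans[g - 1L])
      phq <- data.frame(instrument = "PHQ2", score = phq2[i],
                        date = mriDate[i] - 30)
    }
    sev <- g - 1L
    patEff <- stats::rnorm(1, 0, 5)
    pdom <- c(PROMIS_PHYSICAL_DOMAINS, PROMIS_EMOTIONAL_DOMAINS)
    isEmot <- pdom %in% PROMIS_EMOTIONAL_DOMAINS
    mu <- 50 + patEff - ifelse(isEmot, config$promisEffect,
                               0.4 * config$promisEffect) * sev
    pscore <- stats::rnorm(length(pdom), mu, 8)
    promis <- data.frame(domain = pdom, score = pscore,
                         date = mriDate[i] + sample(-60:60, length(pdom),
                                                    replace = TRUE))
    promisPhys[i] <- mean(pscore[!isEmot])
    promisEmot[i] <- mean(pscore[isEmot])

    records[[i]] <- patientRecord(
      patientId = sprintf("P%04d", i), icd10Codes = codes,
      medications = meds, phqObs = phq, promisObs = promis,
      mriDates = mriDate[i], age = age[i], sex = sex[i],
      totalBrainVolume = tbv[i])

    if (imaging) {
      ufPlan <- plantCore(ufInc, ufTarget[i], tolerance = 0.05)
      fxPlan <- plantCore(fxInc, fxTarget[i], tolerance = 0.05)
      arr <- array(0L, dim = config$gridShape)
      arr[ufPlan$voxels] <- 1L
      arr[fxPlan$voxels] <- 1L
      nBg <- round(extraVol[i] / (config$voxelSizeMm^3))
      arr <- addBackgroundLesion(arr, nBg,
                                 union(ufInc$allVox, fxInc$allVox),
                                 stats::runif)
      masks[[i]] <- new("LesionMask", grid = arr,
                        affine = worldAffine(grid),
                        voxelVolume = voxelVolume(grid))
      ufAchieved[i] <- ufPlan$burden
      fxAchieved[i] <- fxPlan$burden
    }
  }

  if (!imaging) {
    # fast path: burden realisations follow the planting distribution
    ufAchieved <- ufTarget
    fxAchieved <- fxTarget
  }

  covariates <- data.frame(
    patient_id = vapply(records, patientId, character(1)),
    age = age, sex = sex, total_brain_volume_mm3 = tbv, race = race)
  truth <- data.frame(
    patient_id = covariates$patient_id,
    group = c("none", "mild", "severe")[group],
    severity = group - 1L,
    uf_target = ufTarget, uf_burden = ufAchieved,
    fornix_target = fxTarget, fornix_burden = fxAchieved,
    background_lesion_mm3 = extraVol,
    promis_physical = promisPhys, promis_emotional = promisEmot,
    phq2 = phq2)
  list(records = records, masks = masks, bundles = bundles, grid = grid,
       covariates = covariates, truth = truth, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Emits the EMR CSV, covariates CSV, per-patient NIfTI lesion masks, and
#' the four toy bundles as both TRK and TCK.
#'
#' @param cohort result of \code{\link{makeCohort}} (imaging path).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(dir, "bundles"), showWarnings = FALSE)
  writeEMR(cohort$records, file.path(dir, "emr.csv"))
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$masks))
    for (i in seq_along(cohort$masks))
      writeLesionMask(cohort$masks[[i]],
                      file.path(dir, "masks",
                                sprintf("%s.nii.gz",
                                        patientId(cohort$records[[i]]))))
  if (!is.null(cohort$bundles))
    for (b in cohort$bundles) {
      writeTRK(b, file.path(dir, "bundles", paste0(bundleName(b), ".trk")))
      writeTCK(b, file.path(dir, "bundles", paste0(bundleName(b), ".tck")))
    }
  invisible(dir)
}
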