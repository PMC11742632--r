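# End-to-end orchestration: per-subject composition of the analysis chain
# (T1 map -> gain -> concentration -> slope -> sinus normalization) and
# cohort-level runs (control reference -> scoring -> group report). All
# stages are deterministic given their inputs.

#' Run the per-subject quantification chain to a normalized slope map
#'
#' Composition: VFA T1/M0 fit, dynamic gain calibration, signal-to-
#' concentration conversion, late-window slope fit, sinus reference,
#' normalization.
#'
#' @param dyn a [DynamicSeries-class].
#' @param vfa list of VFA [VolumeGrid-class] volumes.
#' @param protocol an [AcquisitionProtocol-class].
#' @param sinusRoi sinus ROI mask.
#' @param concMode `"spgr_inversion"` (default) or `"linear_delta_s"`.
#' @param windowStartMin slope-window start, minutes post injection
#'   (default 6).
#' @param keepIntermediates return T1 maps, gain, concentration and raw
#'   slope map alongside the normalized map.
#' @return A [NormalizedSlopeMap-class], or (with `keepIntermediates`) a
#'   list of all intermediates.
#' @export
subjectNormalizedSlopes <- function(dyn, vfa, protocol, sinusRoi,
                                    concMode = "spgr_inversion",
                                    windowStartMin = 6,
                                    keepIntermediates = FALSE) {
  maps <- vfaT1Maps(vfa, protocol)
  gain <- calibrateGain(dyn, maps, protocol)
  conc <- signalToConcentration(dyn, maps, gain, protocol, mode = concMode)
  slopes <- fitLinearSlope(conc, protocol, windowStartMin)
  ref <- sinusReference(slopes, sinusRoi)
  nmap <- normalizeSlopes(slopes, ref)
  if (keepIntermediates) {
    list(nslope = nmap, t1maps = maps, gain = gain, conc = conc,
         slopes = slopes)
  } else {
    nmap
  }
}

#' Run and score a single subject against a frozen reference
#'
#' @inheritParams subjectNormalizedSlopes
#' @param brainMask brain mask.
#' @param atlas a [BrainAtlas-class].
#' @param reference a [ControlReference-class].
#' @param subjectId identifier used in the result and error messages.
#' @return A [SubjectResult-class].
#' @export
runSubject <- function(dyn, vfa, protocol, brainMask, sinusRoi, atlas,
                       reference, subjectId = "subject",
                       concMode = "spgr_inversion", windowStartMin = 6) {
  nmap <- withCallingHandlers(
    subjectNormalizedSlopes(dyn, vfa, protocol, sinusRoi, concMode,
                            windowStartMin),
    error = function(e) {
      stop("subject '", subjectId, "': ", conditionMessage(e), call. = FALSE)
    })
  scoreSubject(nmap, brainMask, atlas, reference, subjectId, concMode)
}

#' Run a full cohort: reference from controls, score everyone, group report
#'
#' The control reference (pooled percentile threshold + per-region
#' median/MAD) is built from controls only; every subject is then scored
#' against it. With `looControls = TRUE` each control's regional z is
#' instead computed against a reference built from the other controls
#' (threshold stays pooled over all controls). When at least 2 patients are
#' present, a group report is produced: patients-vs-controls Mann-Whitney on
#' whole-brain BBBD percent, per-region comparisons with BH-FDR, and
#' hemispheric asymmetry of the mean patient regional z.
#'
#' @param subjects list of subjects: each a list with `id`, `group`
#'   (`"control"`/`"patient"`), `dynamic`, `vfa` (as from [makeCohortList()]).
#' @param geometry list with `atlas`, `brainMask`, `sinusRoi`.
#' @param protocol an [AcquisitionProtocol-class].
#' @param percentile,madScale,deviation,flagCutoff reference parameters, see
#'   [buildControlReference()].
#' @param concMode,windowStartMin see [subjectNormalizedSlopes()].
#' @param looControls leave-one-out regional scoring for controls
#'   (default `FALSE`).
#' @param verbose emit per-stage progress to `message()`.
#' @return List: `reference` ([ControlReference-class]), `results` (named
#'   list of [SubjectResult-class]), `table` ([resultsTable()] data.frame),
#'   `report` (list with `wholeBrain`, `regions`, `asymmetry`; `NULL`
#'   without patients).
#' @export
runCohort <- function(subjects, geometry, protocol,
                      percentile = 0.95, madScale = 0.6745,
                      deviation = "median_mad", flagCutoff = 2,
                      concMode = "spgr_inversion", windowStartMin = 6,
                      looControls = FALSE, verbose = FALSE) {
  ids <- vapply(subjects, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("subject ids must be unique", call. = FALSE)
  groups <- vapply(subjects, function(s) s$group, character(1))
  isCtrl <- groups == "control"
  if (sum(isCtrl) < 3L) {
    stop("need at least 3 controls to build a reference", call. = FALSE)
  }
  # deterministic processing order regardless of manifest order
  ord <- order(ids)
  nmaps <- vector("list", length(subjects))
  names(nmaps) <- ids
  for (i in ord) {
    s <- subjects[[i]]
    if (verbose) message("[", s$id, "] quantifying normalized slopes")
    nmaps[[s$id]] <- subjectNormalizedSlopes(s$dynamic, s$vfa, protocol,
                                             geometry$sinusRoi, concMode,
                                             windowStartMin)
  }
  ctrlIds <- sort(ids[isCtrl])
  patIds <- sort(ids[!isCtrl])
  reference <- buildControlReference(nmaps[ctrlIds], geometry$brainMask,
                                     geometry$atlas, percentile, madScale,
                                     deviation, flagCutoff)
  results <- list()
  for (id in c(ctrlIds, patIds)) {
    ref <- reference
    if (looControls && id %in% ctrlIds && length(ctrlIds) > 3L) {
      ref <- buildControlReference(nmaps[setdiff(ctrlIds, id)],
                                   geometry$brainMask, geometry$atlas,
                                   percentile, madScale, deviation,
                                   flagCutoff)
      # keep the pooled all-controls threshold; only regional stats are LOO
      ref@threshold <- reference@threshold
    }
    results[[id]] <- scoreSubject(nmaps[[id]], geometry$brainMask,
                                  geometry$atlas, ref, id, concMode)
  }
  report <- NULL
  if (length(patIds) >= 2L) {
    bbbCtrl <- vapply(results[ctrlIds], bbbPercent, numeric(1))
    bbbPat <- vapply(results[patIds], bbbPercent, numeric(1))
    wholeBrain <- compareGroups(bbbPat, bbbCtrl, "mann_whitney")
    regIds <- geometry$atlas@table$region_id
    pctOf <- function(idset) {
      t(vapply(results[idset], function(r) r@regions$percent,
               numeric(length(regIds))))
    }
    regions <- regionComparisonReport(pctOf(ctrlIds), pctOf(patIds), regIds)
    zMat <- t(vapply(results[patIds], function(r) r@regions$z,
                     numeric(length(regIds))))
    zMat[!is.finite(zMat)] <- NA_real_
    meanZ <- setNames(colMeans(zMat, na.rm = TRUE), as.character(regIds))
    asymmetry <- tryCatch(hemisphericAsymmetry(meanZ, geometry$atlas),
                          error = function(e) NULL)
    report <- list(wholeBrain = wholeBrain, regions = regions,
                   asymmetry = asymmetry)
  } else if (length(patIds) > 0L) {
    warning("fewer than 2 patients: group comparisons skipped")
  } else {
    warning("cohort contains controls only: group comparisons skipped")
  }
  list(reference = reference, results = results,
       table = resultsTable(results), report = report)
}

#' Run a cohort from an on-disk study directory
#'
#' Reads the layout written by [makeCohort()] (manifest TSV, protocol YAML,
#' shared atlas/masks, per-subject NIfTI volumes) and delegates to
#' [runCohort()].
#'
#' @param dir study directory.
#' @param ... passed to [runCohort()].
#' @return See [runCohort()].
#' @export
runCohortDir <- function(dir, ...) {
  manifest <- read.delim(file.path(dir, "manifest.tsv"),
                         stringsAsFactors = FALSE)
  protocol <- readProtocol(file.path(dir, "protocol.yaml"))
  labVol <- readVolume(file.path(dir, "atlas.nii.gz"))
  labTab <- readLabelTable(file.path(dir, "atlas_labels.tsv"))
  atlas <- new("BrainAtlas", labels = labVol@voxels, table = labTab,
               affine = labVol@affine)
  geometry <- list(atlas = atlas,
                   brainMask = readVolume(file.path(dir, "brain_mask.nii.gz")),
                   sinusRoi = readVolume(file.path(dir, "sinus_roi.nii.gz")))
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    vfaPaths <- strsplit(row$vfa, ";", fixed = TRUE)[[1]]
    list(id = row$subject_id, group = row$group,
         dynamic = readDynamic(file.path(dir, row$dynamic), protocol),
         vfa = lapply(file.path(dir, vfaPaths), readVolume))
  })
  runCohort(subjects, geometry, protocol, ...)
}
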