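#' Single 3D image volume on a world-anchored grid
#'
#' A scalar voxel lattice together with its 4x4 voxel-to-world affine (mm).
#' All masks, atlases and maps belonging to one study must share shape and
#' affine (checked to 1e-4 mm wherever volumes are combined).
#'
#' @slot voxels 3D numeric/integer/logical array.
#' @slot affine 4x4 voxel-to-world transform (mm), invertible.
#' @export
setClass("VolumeGrid",
  representation(voxels = "array", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L) {
      return("voxels must be a 3D array")
    }
    ok <- tryCatch({ .checkAffine(object@affine); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    TRUE
  })

#' Construct a VolumeGrid
#'
#' @param voxels 3D array.
#' @param affine 4x4 voxel-to-world matrix; defaults to identity.
#' @return A [VolumeGrid-class] object.
#' @export
volumeGrid <- function(voxels, affine = diag(4)) {
  new("VolumeGrid", voxels = voxels, affine = affine)
}

#' @describeIn VolumeGrid-class voxel array accessor
#' @param object,x a `VolumeGrid`
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname VolumeGrid-class
#' @export
setMethod("voxels", "VolumeGrid", function(x) x@voxels)

#' @describeIn VolumeGrid-class affine accessor
#' @export
setGeneric("affine", function(x) standardGeneric("affine"))

#' @rdname VolumeGrid-class
#' @export
setMethod("affine", "VolumeGrid", function(x) x@affine)

setMethod("dim", "VolumeGrid", function(x) dim(x@voxels))

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid", paste(dim(object@voxels), collapse = " x "),
      sprintf("| range [%.4g, %.4g]\n",
              suppressWarnings(min(object@voxels, na.rm = TRUE)),
              suppressWarnings(max(object@voxels, na.rm = TRUE))))
})

#' Dynamic 4D contrast-enhanced series
#'
#' The acquired DCE-MRI signal: a sequence of frames on a common grid with
#' frame times (seconds from acquisition start) and the contrast injection
#' time.
#'
#' @slot data 4D array (x, y, z, frame), signal intensity in a.u.
#' @slot affine 4x4 voxel-to-world transform (mm).
#' @slot frameTimes seconds from acquisition start, strictly increasing.
#' @slot injectionTime injection time in seconds, within `[0, last frame)`.
#' @export
setClass("DynamicSeries",
  representation(data = "array", affine = "matrix",
                 frameTimes = "numeric", injectionTime = "numeric"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array")
    if (d[4] < 2L) return("a dynamic series needs at least 2 frames")
    if (length(object@frameTimes) != d[4]) {
      return("frameTimes length must equal the number of frames")
    }
    if (any(diff(object@frameTimes) <= 0)) {
      return("frameTimes must be strictly increasing")
    }
    it <- object@injectionTime
    if (length(it) != 1L || it < 0 ||
        it >= object@frameTimes[length(object@frameTimes)]) {
      return("injectionTime must lie in [0, last frame time)")
    }
    ok <- tryCatch({ .checkAffine(object@affine); TRUE },
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) return(ok)
    TRUE
  })

#' Construct a DynamicSeries
#'
#' @param data 4D array (x, y, z, frame).
#' @param frameTimes numeric vector of frame times (s).
#' @param injectionTime injection time (s).
#' @param affine 4x4 matrix.
#' @return A [DynamicSeries-class] object.
#' @export
dynamicSeries <- function(data, frameTimes, injectionTime, affine = diag(4)) {
  new("DynamicSeries", data = data, affine = affine,
      frameTimes = as.numeric(frameTimes),
      injectionTime = as.numeric(injectionTime))
}

setMethod("show", "DynamicSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicSeries %s | %d frames, t = %.1f..%.1f s, injection %.1f s\n",
              paste(d[1:3], collapse = " x "), d[4],
              object@frameTimes[1], object@frameTimes[d[4]],
              object@injectionTime))
})

#' DCE acquisition protocol
#'
#' Site-specific acquisition parameters governing the signal-concentration
#' conversion: dynamic-series TR/TE/flip angle, the variable-flip-angle (VFA)
#' T1-mapping angles and TR, frame interval, duration, contrast-agent
#' longitudinal relaxivity, and injection timing. Four site presets are
#' available via [protocolPreset()].
#'
#' @slot siteName site identifier.
#' @slot trMs dynamic repetition time (ms).
#' @slot teMs dynamic echo time (ms).
#' @slot faDeg dynamic flip angle (degrees).
#' @slot vfaDeg variable flip angles (degrees), at least two.
#' @slot vfaTrMs VFA repetition time (ms).
#' @slot vfaTeMs VFA echo time (ms).
#' @slot dtS frame interval (s).
#' @slot durationMin acquisition duration (min).
#' @slot r1Relaxivity contrast-agent relaxivity (1/(mM s)).
#' @slot contrastAgent agent name.
#' @slot nFrames number of dynamic frames.
#' @slot injectionTimeS injection time relative to acquisition start (s).
#' @slot nBaselineFrames pre-injection frame count; `NA` means "all frames
#'   strictly before injection" (minimum 1).
#' @export
setClass("AcquisitionProtocol",
  representation(siteName = "character", trMs = "numeric", teMs = "numeric",
                 faDeg = "numeric", vfaDeg = "numeric", vfaTrMs = "numeric",
                 vfaTeMs = "numeric", dtS = "numeric", durationMin = "numeric",
                 r1Relaxivity = "numeric", contrastAgent = "character",
                 nFrames = "numeric", injectionTimeS = "numeric",
                 nBaselineFrames = "numeric"),
  validity = function(object) {
    if (object@trMs <= 0 || object@vfaTrMs <= 0) return("TR must be > 0")
    if (object@faDeg <= 0 || object@faDeg > 90) {
      return("dynamic flip angle must be in (0, 90] degrees")
    }
    if (length(object@vfaDeg) < 2L) return("need at least 2 variable flip angles")
    if (any(object@vfaDeg <= 0 | object@vfaDeg > 90)) {
      return("variable flip angles must be in (0, 90] degrees")
    }
    if (anyDuplicated(object@vfaDeg)) return("variable flip angles must be distinct")
    if (object@r1Relaxivity <= 0) return("relaxivity must be > 0")
    if (object@dtS <= 0) return("frame interval dtS must be > 0")
    if (object@injectionTimeS < 0) return("injectionTimeS must be >= 0")
    if (!is.na(object@nBaselineFrames) && object@nBaselineFrames < 1) {
      return("nBaselineFrames must be >= 1")
    }
    TRUE
  })

setMethod("show", "AcquisitionProtocol", function(object) {
  cat(sprintf("AcquisitionProtocol '%s'\n", object@siteName))
  cat(sprintf("  dynamic: TE/TR %.3g/%.3g ms, FA %.3g deg, dt %.3g s, %d frames (%.3g min)\n",
              object@teMs, object@trMs, object@faDeg, object@dtS,
              as.integer(object@nFrames), object@durationMin))
  cat(sprintf("  VFA: %s deg, TE/TR %.3g/%.3g ms\n",
              paste(object@vfaDeg, collapse = "-"), object@vfaTeMs, object@vfaTrMs))
  cat(sprintf("  contrast: %s, r1 = %.3g 1/(mM s); injection at %.3g s\n",
              object@contrastAgent, object@r1Relaxivity, object@injectionTimeS))
})

#' Pre-contrast T1 and M0 maps
#'
#' Output of variable-flip-angle (DESPOT1) relaxometry: longitudinal
#' relaxation time T1 (ms), equilibrium signal M0 (a.u., absorbing TE/T2*
#' decay and coil gain), and a per-voxel fit-success mask.
#'
#' @slot t1Ms 3D array of T1 (ms).
#' @slot m0 3D array of M0 (a.u.).
#' @slot fitOK 3D logical array.
#' @slot affine 4x4 matrix.
#' @export
setClass("T1Maps",
  representation(t1Ms = "array", m0 = "array", fitOK = "array",
                 affine = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@t1Ms), dim(object@m0)) ||
        !identical(dim(object@t1Ms), dim(object@fitOK))) {
      return("t1Ms, m0 and fitOK must share dimensions")
    }
    if (!is.logical(object@fitOK)) return("fitOK must be logical")
    ok <- object@fitOK
    if (any(ok) && (any(object@t1Ms[ok] <= 0) || any(object@t1Ms[ok] > 10000) ||
                    any(object@m0[ok] <= 0))) {
      return("where fitOK: t1Ms must be in (0, 10000] ms and m0 > 0")
    }
    TRUE
  })

setMethod("show", "T1Maps", function(object) {
  ok <- object@fitOK
  cat(sprintf("T1Maps %s | %d/%d voxels fitted; median T1 %.0f ms\n",
              paste(dim(object@t1Ms), collapse = " x "),
              sum(ok), length(ok),
              if (any(ok)) median(object@t1Ms[ok]) else NA_real_))
})

#' Voxelwise contrast-agent concentration time series
#'
#' Concentration (mM, or relative signal change in `linear_delta_s` mode)
#' per voxel and frame, with per-voxel validity.
#'
#' @slot conc 4D array (x, y, z, frame).
#' @slot frameTimes seconds.
#' @slot injectionTime seconds.
#' @slot valid 3D logical array.
#' @slot mode `"spgr_inversion"` or `"linear_delta_s"`.
#' @slot affine 4x4 matrix.
#' @export
setClass("ConcentrationSeries",
  representation(conc = "array", frameTimes = "numeric",
                 injectionTime = "numeric", valid = "array",
                 mode = "character", affine = "matrix"),
  validity = function(object) {
    d <- dim(object@conc)
    if (length(d) != 4L) return("conc must be a 4D array")
    if (length(object@frameTimes) != d[4]) {
      return("frameTimes length must equal number of frames")
    }
    if (!identical(dim(object@valid), d[1:3])) {
      return("valid mask must match the spatial grid")
    }
    if (!is.logical(object@valid)) return("valid must be logical")
    if (!object@mode %in% c("spgr_inversion", "linear_delta_s")) {
      return("mode must be 'spgr_inversion' or 'linear_delta_s'")
    }
    TRUE
  })

#' Voxelwise leakage-slope map
#'
#' Ordinary-least-squares slope of concentration against time (minutes) over
#' the late post-injection window.
#'
#' @slot slope 3D array (mM/min; a.u./min in `linear_delta_s` mode).
#' @slot nFramesUsed integer count of frames in the fitted window.
#' @slot valid 3D logical array.
#' @slot affine 4x4 matrix.
#' @export
setClass("SlopeMap",
  representation(slope = "array", nFramesUsed = "integer", valid = "array",
                 affine = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@slope), dim(object@valid))) {
      return("slope and valid must share dimensions")
    }
    if (!is.logical(object@valid)) return("valid must be logical")
    if (object@nFramesUsed < 3L) return("slope fits need >= 3 frames")
    if (any(object@valid) && !all(is.finite(object@slope[object@valid]))) {
      return("slope must be finite where valid")
    }
    TRUE
  })

#' Sinus-normalized slope map
#'
#' The pipeline's central quantity: per-voxel leakage slope divided by the
#' superior-sagittal-sinus reference slope, making values dimensionless and
#' comparable across subjects and sites.
#'
#' @slot nslope 3D array (dimensionless).
#' @slot sinusSlope scalar reference slope (> 0, same units as SlopeMap).
#' @slot valid 3D logical array.
#' @slot affine 4x4 matrix.
#' @export
setClass("NormalizedSlopeMap",
  representation(nslope = "array", sinusSlope = "numeric", valid = "array",
                 affine = "matrix"),
  validity = function(object) {
    if (!identical(dim(object@nslope), dim(object@valid))) {
      return("nslope and valid must share dimensions")
    }
    if (!is.logical(object@valid)) return("valid must be logical")
    if (length(object@sinusSlope) != 1L || !is.finite(object@sinusSlope) ||
        object@sinusSlope <= 0) {
      return("sinusSlope must be a positive scalar")
    }
    TRUE
  })

setMethod("show", "NormalizedSlopeMap", function(object) {
  v <- object@valid
  cat(sprintf("NormalizedSlopeMap %s | %d valid voxels, sinus slope %.4g, median nslope %.4g\n",
              paste(dim(object@nslope), collapse = " x "),
              sum(v), object@sinusSlope,
              if (any(v)) median(object@nslope[v]) else NA_real_))
})

#' Integer-labeled brain parcellation
#'
#' A label volume (0 = background) plus a region table giving each region's
#' name, hemisphere (`L`, `R` or `midline`) and lobe. The default study
#' parcellation has 124 regions.
#'
#' @slot labels 3D integer array of region ids (0 = background).
#' @slot table data.frame with columns `region_id`, `name`, `hemisphere`,
#'   `lobe`.
#' @slot affine 4x4 matrix.
#' @export
setClass("BrainAtlas",
  representation(labels = "array", table = "data.frame", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    need <- c("region_id", "name", "hemisphere", "lobe")
    if (!all(need %in% names(object@table))) {
      return(paste("region table needs columns:", paste(need, collapse = ", ")))
    }
    if (anyDuplicated(object@table$region_id)) {
      return("region_ids must be unique")
    }
    if (!all(object@table$hemisphere %in% c("L", "R", "midline"))) {
      return("hemisphere must be L, R or midline")
    }
    present <- unique(as.vector(object@labels))
    present <- present[present != 0]
    if (!all(present %in% object@table$region_id)) {
      return("every nonzero label must appear in the region table")
    }
    TRUE
  })

#' @describeIn BrainAtlas-class region table accessor
#' @param x a `BrainAtlas`
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))

#' @rdname BrainAtlas-class
#' @export
setMethod("regionTable", "BrainAtlas", function(x) x@table)

setMethod("show", "BrainAtlas", function(object) {
  cat(sprintf("BrainAtlas %s | %d regions (%d L / %d R / %d midline)\n",
              paste(dim(object@labels), collapse = " x "),
              nrow(object@table),
              sum(object@table$hemisphere == "L"),
              sum(object@table$hemisphere == "R"),
              sum(object@table$hemisphere == "midline")))
})

#' Frozen healthy-control reference
#'
#' The supra-threshold cutoff (the chosen percentile, default 95th, of the
#' pooled normalized slopes of all control voxels) together with per-region
#' control location/spread statistics used for the modified z-score, so
#' patient cohorts can be scored against a frozen reference.
#'
#' @slot threshold pooled percentile cutoff on normalized slope.
#' @slot percentile percentile used (fraction, default 0.95).
#' @slot percentileMethod textual record of the quantile convention.
#' @slot madScale modified z-score constant (default 0.6745).
#' @slot deviation `"median_mad"` or `"mean_ad"`.
#' @slot flagCutoff z cutoff above which a region is flagged (default 2).
#' @slot regionStats data.frame: `region_id`, `center`, `spread`,
#'   `spread_fallback`, `unstable`, `n`.
#' @slot nControls number of control subjects.
#' @export
setClass("ControlReference",
  representation(threshold = "numeric", percentile = "numeric",
                 percentileMethod = "character", madScale = "numeric",
                 deviation = "character", flagCutoff = "numeric",
                 regionStats = "data.frame", nControls = "integer"),
  validity = function(object) {
    if (!is.finite(object@threshold)) return("threshold must be finite")
    if (object@percentile <= 0 || object@percentile > 1) {
      return("percentile must be in (0, 1]")
    }
    need <- c("region_id", "center", "spread", "spread_fallback", "unstable", "n")
    if (!all(need %in% names(object@regionStats))) {
      return(paste("regionStats needs columns:", paste(need, collapse = ", ")))
    }
    if (any(object@regionStats$spread < 0, na.rm = TRUE)) {
      return("spread must be >= 0")
    }
    if (!object@deviation %in% c("median_mad", "mean_ad")) {
      return("deviation must be 'median_mad' or 'mean_ad'")
    }
    TRUE
  })

#' @describeIn ControlReference-class supra-threshold cutoff accessor
#' @param x a `ControlReference`
#' @export
setGeneric("bbbdThreshold", function(x) standardGeneric("bbbdThreshold"))

#' @rdname ControlReference-class
#' @export
setMethod("bbbdThreshold", "ControlReference", function(x) x@threshold)

setMethod("show", "ControlReference", function(object) {
  cat(sprintf("ControlReference | threshold %.5g (percentile %.3g, %s) from %d controls\n",
              object@threshold, object@percentile, object@percentileMethod,
              object@nControls))
  cat(sprintf("  modified z: %s, scale %.4g, flag cutoff %.3g; %d regions (%d unstable)\n",
              object@deviation, object@madScale, object@flagCutoff,
              nrow(object@regionStats), sum(object@regionStats$unstable)))
})

#' Per-subject BBBD scoring result
#'
#' Whole-brain percent volume with supra-threshold normalized slope, plus a
#' per-region table of supra-threshold percentage, modified z-score against
#' the control reference, and the resulting flag.
#'
#' @slot subjectId subject identifier.
#' @slot bbbPercent percent of valid brain voxels above threshold, in
#'   `[0, 100]`.
#' @slot regions data.frame: `region_id`, `percent`, `z`, `flag`, `unstable`.
#' @slot nRegionsFlagged flagged-region count.
#' @slot sinusSlope the subject's sinus reference slope.
#' @slot concMode concentration mode used upstream.
#' @export
setClass("SubjectResult",
  representation(subjectId = "character", bbbPercent = "numeric",
                 regions = "data.frame", nRegionsFlagged = "integer",
                 sinusSlope = "numeric", concMode = "character"),
  validity = function(object) {
    if (object@bbbPercent < 0 || object@bbbPercent > 100) {
      return("bbbPercent must be in [0, 100]")
    }
    need <- c("region_id", "percent", "z", "flag", "unstable")
    if (!all(need %in% names(object@regions))) {
      return(paste("regions needs columns:", paste(need, collapse = ", ")))
    }
    p <- object@regions$percent
    if (any(p < 0 | p > 100, na.rm = TRUE)) {
      return("regional percentages must be in [0, 100]")
    }
    if (!identical(object@nRegionsFlagged,
                   as.integer(sum(object@regions$flag, na.rm = TRUE)))) {
      return("nRegionsFlagged must equal the number of flagged regions")
    }
    TRUE
  })

#' @describeIn SubjectResult-class whole-brain BBBD percent accessor
#' @param x a `SubjectResult`
#' @export
setGeneric("bbbPercent", function(x) standardGeneric("bbbPercent"))

#' @rdname SubjectResult-class
#' @export
setMethod("bbbPercent", "SubjectResult", function(x) x@bbbPercent)

#' @describeIn SubjectResult-class per-region table accessor
#' @export
setGeneric("regionResults", function(x) standardGeneric("regionResults"))

#' @rdname SubjectResult-class
#' @export
setMethod("regionResults", "SubjectResult", function(x) x@regions)

setMethod("show", "SubjectResult", function(object) {
  cat(sprintf("SubjectResult '%s' | %.2f%% brain volume with BBBD; %d/%d regions flagged\n",
              object@subjectId, object@bbbPercent, object@nRegionsFlagged,
              nrow(object@regions)))
})

#' Two-group nonparametric comparison result
#'
#' @slot test test used.
#' @slot statistic test statistic.
#' @slot pValue two-sided p value.
#' @slot pAdjusted adjusted p (NA unless set by a multiple-testing pass).
#' @slot effectSizeD Cohen's d (pooled-SD for unpaired, mean/SD of
#'   differences for paired).
#' @slot groupSizes sizes of the two groups.
#' @slot method textual record (e.g. exact vs normal approximation).
#' @export
setClass("GroupComparison",
  representation(test = "character", statistic = "numeric",
                 pValue = "numeric", pAdjusted = "numeric",
                 effectSizeD = "numeric", groupSizes = "integer",
                 method = "character"),
  validity = function(object) {
    if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1)) {
      return("pValue must be in [0, 1]")
    }
    if (!is.na(object@pAdjusted) && object@pAdjusted < object@pValue) {
      return("pAdjusted must be >= pValue")
    }
    TRUE
  })

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison [%s] n = %s | statistic %.4g, p = %.4g, d = %.3g (%s)\n",
              object@test, paste(object@groupSizes, collapse = "/"),
              object@statistic, object@pValue, object@effectSizeD,
              object@method))
})
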