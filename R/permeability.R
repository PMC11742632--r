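# Late-window linear leakage slope and superior-sagittal-sinus
# normalization. The slope of concentration against time from 6 minutes
# after injection until the last frame quantifies slow BBB leakage; dividing
# by the sinus slope cancels subject-level differences in contrast delivery.

#' Fit the late-phase linear leakage slope per voxel
#'
#' Ordinary-least-squares slope of concentration against time (in minutes)
#' over all frames at or after `injection time + windowStartMin`. Voxels
#' invalid in the concentration series stay invalid.
#'
#' @param conc a [ConcentrationSeries-class].
#' @param protocol an [AcquisitionProtocol-class] (supplies the injection
#'   time; the series' own injection time is used when they agree or the
#'   protocol is missing).
#' @param windowStartMin window start in minutes after injection
#'   (default 6).
#' @return A [SlopeMap-class] (slope units: concentration per minute).
#' @export
fitLinearSlope <- function(conc, protocol = NULL, windowStartMin = 6) {
  stopifnot(is(conc, "ConcentrationSeries"))
  tInj <- if (!is.null(protocol)) protocol@injectionTimeS else conc@injectionTime
  sel <- conc@frameTimes >= tInj + windowStartMin * 60
  if (sum(sel) < 3L) {
    stop("need at least 3 frames in the fitting window (have ", sum(sel), ")",
         call. = FALSE)
  }
  tMin <- conc@frameTimes[sel] / 60
  C <- .asVoxelMatrix(conc@conc)[, sel, drop = FALSE]
  tc <- tMin - mean(tMin)
  slope <- as.vector(C %*% tc) / sum(tc * tc)
  valid <- conc@valid & is.finite(array(slope, dim(conc@valid)))
  slope[!as.vector(valid)] <- NA_real_
  new("SlopeMap", slope = array(slope, dim(conc@valid)),
      nFramesUsed = as.integer(sum(sel)), valid = valid,
      affine = conc@affine)
}

#' Superior-sagittal-sinus reference slope
#'
#' Summary of the slopes inside the sinus ROI (median by default, for
#' robustness to partial-volume voxels). A non-positive reference signals an
#' unusable scan and is an error.
#'
#' @param slopes a [SlopeMap-class].
#' @param sinusRoi logical/0-1 mask ([VolumeGrid-class] or array) on the
#'   same grid.
#' @param stat `"median"` (default) or `"mean"`.
#' @return Scalar reference slope (> 0).
#' @export
sinusReference <- function(slopes, sinusRoi, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  stopifnot(is(slopes, "SlopeMap"))
  assertSameGrid(volumeGrid(slopes@slope, slopes@affine), sinusRoi,
                 "slope map and sinus ROI")
  roi <- .vox(sinusRoi) != 0 & slopes@valid
  if (!any(roi)) {
    stop("sinus ROI contains no valid voxels", call. = FALSE)
  }
  ref <- if (stat == "median") median(slopes@slope[roi]) else mean(slopes@slope[roi])
  if (!is.finite(ref) || ref <= 0) {
    stop("non-positive sinus reference slope (", format(ref),
         "): scan unusable for normalization", call. = FALSE)
  }
  ref
}

#' Normalize a slope map to the sinus reference
#'
#' @param slopes a [SlopeMap-class].
#' @param ref positive scalar reference slope (from [sinusReference()]).
#' @return A [NormalizedSlopeMap-class]; `nslope = slope / ref` voxelwise,
#'   validity propagated.
#' @export
normalizeSlopes <- function(slopes, ref) {
  stopifnot(is(slopes, "SlopeMap"))
  if (length(ref) != 1L || !is.finite(ref) || ref <= 0) {
    stop("reference slope must be a positive scalar", call. = FALSE)
  }
  new("NormalizedSlopeMap", nslope = slopes@slope / ref,
      sinusSlope = ref, valid = slopes@valid, affine = slopes@affine)
}
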