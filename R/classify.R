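# Control reference construction and subject classification: pooled
# 95th-percentile threshold on normalized slopes, whole-brain and per-region
# supra-threshold percentages, and modified z-scores against the control
# cohort's per-region distribution.

#' Pooled percentile of control normalized slopes
#'
#' Linear-interpolation percentile (type-7 quantile) of the pooled multiset
#' of all valid in-mask normalized slopes across controls.
#'
#' @param maps list of [NormalizedSlopeMap-class] (one per control), or a
#'   single map.
#' @param masks list of brain masks (arrays or [VolumeGrid-class]) matching
#'   `maps`, or a single mask recycled for all.
#' @param percentile fraction in (0, 1], default 0.95.
#' @return Scalar threshold.
#' @export
pooledPercentile <- function(maps, masks, percentile = 0.95) {
  if (is(maps, "NormalizedSlopeMap")) maps <- list(maps)
  if (!is.list(masks)) masks <- rep(list(masks), length(maps))
  if (length(masks) == 1L) masks <- rep(masks, length(maps))
  stopifnot(length(maps) == length(masks), percentile > 0, percentile <= 1)
  pool <- unlist(lapply(seq_along(maps), function(i) {
    m <- maps[[i]]
    sel <- m@valid & (.vox(masks[[i]]) != 0)
    m@nslope[sel]
  }), use.names = FALSE)
  pool <- pool[is.finite(pool)]
  if (length(pool) == 0L) stop("empty control voxel pool", call. = FALSE)
  if (length(pool) < 20L) {
    warning("pooled control voxel count < 20; percentile threshold unstable")
  }
  unname(quantile(pool, percentile, type = 7, names = FALSE))
}

#' Whole-brain percent volume with BBBD
#'
#' `100 * (#valid in-mask voxels with nslope > threshold) / (#valid in-mask
#' voxels)` — the subject's overall BBBD load.
#'
#' @param map a [NormalizedSlopeMap-class].
#' @param brainMask mask (array or [VolumeGrid-class]).
#' @param threshold scalar supra-threshold cutoff.
#' @return Percent in `[0, 100]`.
#' @export
brainBBBDPercent <- function(map, brainMask, threshold) {
  stopifnot(is(map, "NormalizedSlopeMap"))
  assertSameGrid(volumeGrid(map@nslope, map@affine), brainMask,
                 "slope map and brain mask")
  sel <- map@valid & (.vox(brainMask) != 0)
  n <- sum(sel)
  if (n == 0L) stop("no valid in-mask voxels", call. = FALSE)
  100 * sum(map@nslope[sel] > threshold) / n
}

#' Per-region percent of supra-threshold voxels
#'
#' For every region of the atlas, the percentage of that region's valid
#' voxels whose normalized slope exceeds the threshold. Regions with zero
#' valid voxels get `NA` (never 0).
#'
#' @param map a [NormalizedSlopeMap-class].
#' @param atlas a [BrainAtlas-class] on the same grid.
#' @param threshold scalar cutoff.
#' @return Named numeric vector (names = region ids, in region-table order).
#' @export
regionalPercent <- function(map, atlas, threshold) {
  stopifnot(is(map, "NormalizedSlopeMap"), is(atlas, "BrainAtlas"))
  assertSameGrid(volumeGrid(map@nslope, map@affine),
                 volumeGrid(atlas@labels, atlas@affine),
                 "slope map and atlas")
  ids <- atlas@table$region_id
  lab <- as.vector(atlas@labels)
  sel <- lab > 0 & as.vector(map@valid)
  nb <- max(ids)
  nValid <- tabulate(lab[sel], nbins = nb)
  above <- sel & as.vector(map@nslope > threshold)
  above[is.na(above)] <- FALSE
  nAbove <- tabulate(lab[above], nbins = nb)
  pct <- 100 * nAbove / nValid
  pct[nValid == 0L] <- NA_real_
  setNames(pct[ids], as.character(ids))
}

#' Modified z-scores of regional percentages against a control reference
#'
#' `z_r = madScale * (x_r - center_r) / spread_r` with, in the default
#' `median_mad` mode, center = control median and spread = control MAD
#' (unscaled median absolute deviation). Regions whose MAD is zero fall back
#' to the control mean absolute deviation from the median; if that is also
#' zero the region is an unstable reference and `z = +Inf` when
#' `x > center`, else 0. Flagging is one-sided: `z > flagCutoff`.
#'
#' @param regionPercent named vector from [regionalPercent()].
#' @param reference a [ControlReference-class] built on the same atlas.
#' @return data.frame: `region_id`, `percent`, `z`, `flag`, `unstable`.
#' @export
modifiedZ <- function(regionPercent, reference) {
  stopifnot(is(reference, "ControlReference"))
  rs <- reference@regionStats
  if (length(regionPercent) != nrow(rs) ||
      !identical(as.integer(names(regionPercent)), as.integer(rs$region_id))) {
    stop("region ids of the percentages and the reference must match",
         call. = FALSE)
  }
  x <- unname(regionPercent)
  scale <- if (reference@deviation == "median_mad") reference@madScale else 1
  spread <- ifelse(rs$spread > 0, rs$spread, rs$spread_fallback)
  z <- scale * (x - rs$center) / spread
  degenerate <- rs$spread == 0 & rs$spread_fallback == 0
  z[degenerate] <- ifelse(x[degenerate] > rs$center[degenerate], Inf, 0)
  flag <- !is.na(z) & z > reference@flagCutoff
  data.frame(region_id = rs$region_id, percent = x, z = z, flag = flag,
             unstable = rs$unstable | degenerate)
}

#' Build the healthy-control reference
#'
#' Pools all valid in-mask control voxels for the percentile threshold, then
#' computes each control's per-region supra-threshold percentages and
#' summarizes them per region (median and MAD in the default mode; mean and
#' mean absolute deviation in `mean_ad` mode).
#'
#' @param maps list of control [NormalizedSlopeMap-class] objects.
#' @param masks brain mask(s), recycled as in [pooledPercentile()].
#' @param atlas a [BrainAtlas-class].
#' @param percentile threshold percentile (default 0.95).
#' @param madScale modified z constant (default 0.6745).
#' @param deviation `"median_mad"` (default) or `"mean_ad"`.
#' @param flagCutoff region flag cutoff on z (default 2).
#' @return A [ControlReference-class].
#' @export
buildControlReference <- function(maps, masks, atlas, percentile = 0.95,
                                  madScale = 0.6745,
                                  deviation = c("median_mad", "mean_ad"),
                                  flagCutoff = 2) {
  deviation <- match.arg(deviation)
  if (is(maps, "NormalizedSlopeMap")) maps <- list(maps)
  if (length(maps) == 0L) stop("empty control set", call. = FALSE)
  if (length(maps) < 10L) {
    warning("fewer than 10 controls: regional MADs will be noisy")
  }
  if (!is.list(masks)) masks <- rep(list(masks), length(maps))
  if (length(masks) == 1L) masks <- rep(masks, length(maps))
  threshold <- pooledPercentile(maps, masks, percentile)
  pct <- vapply(seq_along(maps),
                function(i) regionalPercent(maps[[i]], atlas, threshold),
                numeric(nrow(atlas@table)))
  pct <- t(pct)  # controls x regions
  rs <- .regionStatsFrom(pct, atlas@table$region_id, deviation)
  new("ControlReference", threshold = threshold, percentile = percentile,
      percentileMethod = "pooled voxels, linear interpolation (type 7)",
      madScale = madScale, deviation = deviation, flagCutoff = flagCutoff,
      regionStats = rs, nControls = length(maps))
}

# Per-region center/spread summaries of a (controls x regions) percent matrix.
.regionStatsFrom <- function(pct, regionIds, deviation) {
  center <- spread <- fallback <- n <- numeric(ncol(pct))
  for (j in seq_len(ncol(pct))) {
    x <- pct[, j]
    x <- x[!is.na(x)]
    n[j] <- length(x)
    if (length(x) == 0L) {
      center[j] <- spread[j] <- fallback[j] <- NA_real_
      next
    }
    if (deviation == "median_mad") {
      center[j] <- median(x)
      spread[j] <- median(abs(x - center[j]))
      fallback[j] <- mean(abs(x - center[j]))
    } else {
      center[j] <- mean(x)
      spread[j] <- mean(abs(x - center[j]))
      fallback[j] <- spread[j]
    }
  }
  data.frame(region_id = regionIds, center = center, spread = spread,
             spread_fallback = fallback,
             unstable = !is.na(spread) & spread == 0 & fallback == 0,
             n = as.integer(n))
}

#' Score one subject against a frozen control reference
#'
#' @param map the subject's [NormalizedSlopeMap-class].
#' @param brainMask brain mask.
#' @param atlas a [BrainAtlas-class].
#' @param reference a [ControlReference-class].
#' @param subjectId identifier.
#' @param concMode textual record of the concentration mode used upstream.
#' @return A [SubjectResult-class].
#' @export
scoreSubject <- function(map, brainMask, atlas, reference,
                         subjectId = "subject", concMode = "spgr_inversion") {
  bbb <- brainBBBDPercent(map, brainMask, reference@threshold)
  pct <- regionalPercent(map, atlas, reference@threshold)
  reg <- modifiedZ(pct, reference)
  new("SubjectResult", subjectId = subjectId, bbbPercent = bbb,
      regions = reg, nRegionsFlagged = as.integer(sum(reg$flag, na.rm = TRUE)),
      sinusSlope = map@sinusSlope, concMode = concMode)
}

#' Serialize / restore a control reference as JSON
#'
#' Freezing the reference lets patient cohorts be scored later, bit-exactly,
#' against the same threshold and regional statistics.
#'
#' @param reference a [ControlReference-class].
#' @param path JSON path.
#' @return `writeControlReference` returns `path` invisibly;
#'   `readControlReference` the restored [ControlReference-class].
#' @export
writeControlReference <- function(reference, path) {
  stopifnot(is(reference, "ControlReference"))
  obj <- list(threshold = reference@threshold,
              percentile = reference@percentile,
              percentile_method = reference@percentileMethod,
              mad_scale = reference@madScale,
              deviation = reference@deviation,
              flag_cutoff = reference@flagCutoff,
              n_controls = reference@nControls,
              region_stats = reference@regionStats)
  # 17 significant digits so doubles round-trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname writeControlReference
#' @export
readControlReference <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rs <- as.data.frame(obj$region_stats)
  rs$region_id <- as.integer(rs$region_id)
  rs$unstable <- as.logical(rs$unstable)
  rs$n <- as.integer(rs$n)
  new("ControlReference", threshold = obj$threshold,
      percentile = obj$percentile, percentileMethod = obj$percentile_method,
      madScale = obj$mad_scale, deviation = obj$deviation,
      flagCutoff = obj$flag_cutoff, regionStats = rs,
      nControls = as.integer(obj$n_controls))
}
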