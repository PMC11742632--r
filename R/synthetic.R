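# Synthetic study generator: a deterministic digital phantom (brain mask,
# 124-region parcellation, sinus ROI) plus per-subject VFA volumes and
# dynamic series synthesized through the SPGR forward model from known
# ground-truth leakage slopes, for control and patient cohorts. Every
# pipeline stage is thereby testable by parameter recovery without any
# external data.

#' Synthetic cohort specification
#'
#' The generator's defaults are the cohort conditions the pipeline is
#' validated under: 58 controls and 50 patients, a 124-region parcellation,
#' the SUMC acquisition protocol, a homogeneous control distribution of true
#' normalized slopes, and patients with 20 affected regions whose true
#' slopes are raised by 4 control-MADs (MAD of the control voxel-slope
#' distribution, `0.6745 * controlSlopeSd`).
#'
#' @slot gridShape volume dimensions, default `c(32, 32, 8)`.
#' @slot nRegions parcellation size, default 124.
#' @slot nControls,nPatients cohort sizes, defaults 58 and 50.
#' @slot protocol an [AcquisitionProtocol-class] preset.
#' @slot controlSlopeMean,controlSlopeSd true normalized-slope distribution
#'   of healthy tissue (dimensionless), defaults 0.05 and 0.02.
#' @slot effectNRegions number of affected regions per patient (default 20).
#' @slot effectMode `"mad_units"` (additive, in control voxel-slope MADs) or
#'   `"multiplier"`.
#' @slot effectSize default 4 (MAD units).
#' @slot sinusTrueSlope true sinus slope (mM/min), default 0.4.
#' @slot tissueT1Ms,bloodT1Ms pre-contrast T1 (ms), defaults 1300 and 1700.
#' @slot tissueM0 equilibrium signal (a.u.), default 1000.
#' @slot bolusAmpTissue,bolusAmpSinus first-pass bolus amplitude (mM),
#'   defaults 0.05 and 1.
#' @slot noiseSd additive Gaussian signal noise (a.u.), default 0.05
#'   (about 1% of the baseline tissue signal at the defaults).
#' @slot seed master seed.
#' @export
setClass("SyntheticCohortSpec",
  representation(gridShape = "integer", nRegions = "integer",
                 nControls = "integer", nPatients = "integer",
                 protocol = "AcquisitionProtocol",
                 controlSlopeMean = "numeric", controlSlopeSd = "numeric",
                 effectNRegions = "integer", effectMode = "character",
                 effectSize = "numeric", sinusTrueSlope = "numeric",
                 tissueT1Ms = "numeric", bloodT1Ms = "numeric",
                 tissueM0 = "numeric", bolusAmpTissue = "numeric",
                 bolusAmpSinus = "numeric", noiseSd = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@gridShape) != 3L || any(object@gridShape < 4L)) {
      return("gridShape must be 3 dimensions, each >= 4")
    }
    if (object@nRegions < 2L) return("need at least 2 regions")
    if (object@nControls < 1L || object@nPatients < 0L) {
      return("cohort sizes must be positive")
    }
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@effectNRegions > object@nRegions) {
      return("affected regions must be a subset of atlas regions")
    }
    if (!object@effectMode %in% c("mad_units", "multiplier")) {
      return("effectMode must be 'mad_units' or 'multiplier'")
    }
    if (object@sinusTrueSlope <= 0) return("sinusTrueSlope must be > 0")
    TRUE
  })

#' @rdname SyntheticCohortSpec-class
#' @param gridShape,nRegions,nControls,nPatients,protocol,controlSlopeMean,controlSlopeSd
#'   see slot documentation.
#' @param effectNRegions,effectMode,effectSize,sinusTrueSlope,tissueT1Ms,bloodT1Ms
#'   see slot documentation.
#' @param tissueM0,bolusAmpTissue,bolusAmpSinus,noiseSd,seed see slot
#'   documentation.
#' @return A `SyntheticCohortSpec`.
#' @export
cohortSpec <- function(gridShape = c(32L, 32L, 8L), nRegions = 124L,
                       nControls = 58L, nPatients = 50L,
                       protocol = protocolPreset("SUMC"),
                       controlSlopeMean = 0.05, controlSlopeSd = 0.02,
                       effectNRegions = 20L,
                       effectMode = "mad_units", effectSize = 4,
                       sinusTrueSlope = 0.4,
                       tissueT1Ms = 1300, bloodT1Ms = 1700,
                       tissueM0 = 1000, bolusAmpTissue = 0.05,
                       bolusAmpSinus = 1, noiseSd = 0.05, seed = 20240101L) {
  new("SyntheticCohortSpec",
      gridShape = as.integer(gridShape), nRegions = as.integer(nRegions),
      nControls = as.integer(nControls), nPatients = as.integer(nPatients),
      protocol = protocol, controlSlopeMean = controlSlopeMean,
      controlSlopeSd = controlSlopeSd,
      effectNRegions = as.integer(effectNRegions),
      effectMode = effectMode, effectSize = effectSize,
      sinusTrueSlope = sinusTrueSlope, tissueT1Ms = tissueT1Ms,
      bloodT1Ms = bloodT1Ms, tissueM0 = tissueM0,
      bolusAmpTissue = bolusAmpTissue, bolusAmpSinus = bolusAmpSinus,
      noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "SyntheticCohortSpec", function(object) {
  cat(sprintf("SyntheticCohortSpec | grid %s, %d regions, %d controls + %d patients\n",
              paste(object@gridShape, collapse = "x"), object@nRegions,
              object@nControls, object@nPatients))
  cat(sprintf("  control nslope ~ N(%.3g, %.3g); patient effect: %d regions, %s %.3g\n",
              object@controlSlopeMean, object@controlSlopeSd,
              object@effectNRegions, object@effectMode, object@effectSize))
})

.syntheticAffine <- function() diag(c(2, 2, 6, 1))

#' Build the synthetic parcellation, brain mask and sinus ROI
#'
#' Deterministic (seed-free) construction: an ellipsoidal brain mask split
#' at the midline into left/right hemispheres, each partitioned into
#' `nRegions/2` near-equal contiguous voxel blocks (ordered by slice, row,
#' column) with homologous names `roi_<k>_L` / `roi_<k>_R`; the sinus ROI is
#' a posterior midline strip outside the brain mask.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return List: `atlas` ([BrainAtlas-class]), `brainMask` and `sinusRoi`
#'   (integer [VolumeGrid-class] masks).
#' @export
makeAtlas <- function(spec) {
  d <- spec@gridShape
  if (spec@nRegions > prod(d) / 4) {
    stop("grid too small for the requested number of regions", call. = FALSE)
  }
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  rx <- 0.42 * d[1]; ry <- 0.42 * d[2]; rz <- 0.45 * d[3]
  ix <- slice.index(array(0, d), 1L)
  iy <- slice.index(array(0, d), 2L)
  iz <- slice.index(array(0, d), 3L)
  brain <- ((ix - cx) / rx)^2 + ((iy - cy) / ry)^2 + ((iz - cz) / rz)^2 <= 1
  # posterior midline venous strip, outside the brain
  midX <- c(floor(cx), ceiling(cx))
  sinus <- ix %in% midX & iy >= d[2] - 1 & iz >= max(1, floor(cz) - 1) &
    iz <= min(d[3], ceiling(cz) + 1) & !brain
  if (!any(sinus)) stop("grid too small to place a sinus ROI", call. = FALSE)
  nPerHemi <- spec@nRegions %/% 2L
  if (2L * nPerHemi != spec@nRegions) {
    stop("nRegions must be even (equal left/right split)", call. = FALSE)
  }
  labels <- array(0L, d)
  for (hemi in c("L", "R")) {
    inHemi <- brain & if (hemi == "L") ix <= floor(d[1] / 2) else ix > floor(d[1] / 2)
    idx <- which(inHemi)
    ord <- order(iz[idx], iy[idx], ix[idx])
    chunks <- cut(seq_along(idx), breaks = nPerHemi, labels = FALSE)
    offset <- if (hemi == "L") 0L else nPerHemi
    labels[idx[ord]] <- offset + chunks
  }
  lobeNames <- c("frontal", "parietal", "temporal", "occipital")
  tab <- do.call(rbind, lapply(seq_len(spec@nRegions), function(r) {
    hemi <- if (r <= nPerHemi) "L" else "R"
    k <- if (r <= nPerHemi) r else r - nPerHemi
    vox <- which(labels == r)
    yc <- mean(iy[vox])
    lobe <- lobeNames[pmin(4L, 1L + floor(4 * (yc - 1) / d[2]))]
    data.frame(region_id = r, name = sprintf("roi_%03d_%s", k, hemi),
               hemisphere = hemi, lobe = lobe, stringsAsFactors = FALSE)
  }))
  aff <- .syntheticAffine()
  list(atlas = new("BrainAtlas", labels = labels, table = tab, affine = aff),
       brainMask = volumeGrid(array(as.integer(brain), d), aff),
       sinusRoi = volumeGrid(array(as.integer(sinus), d), aff))
}

# Smooth gamma-variate first-pass bolus template, unit peak at tPeak after
# injection, numerically zero well before the 6-min fitting window opens.
.bolusTemplate <- function(tS, tInjS, tPeakS = 30, shape = 3) {
  tt <- pmax(0, tS - tInjS) / tPeakS
  (tt^shape) * exp(shape * (1 - tt))
}

#' Synthesize one subject
#'
#' Draws the true normalized-slope field from the control distribution (for
#' patients, raises the chosen affected regions per the effect mode), builds
#' voxelwise concentration curves `C(t) = amp * bolus(t) + k * (t - t_inj)`
#' (slope k in mM/min; sinus voxels carry the true sinus slope and a large
#' blood bolus), synthesizes the SPGR signal with the true T1/M0 plus
#' additive Gaussian noise, and renders the matching VFA volumes.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param geometry output of [makeAtlas()] for this spec.
#' @param group `"control"` or `"patient"`.
#' @param seed subject seed (integer).
#' @return List: `dynamic` ([DynamicSeries-class]), `vfa` (list of
#'   [VolumeGrid-class]), `groundTruth` (list with `nslopeTrue`, `kTrue`,
#'   `affectedRegions`, `sinusTrueSlope`, `t1Ms`, `m0`).
#' @export
makeSubject <- function(spec, geometry, group = c("control", "patient"),
                        seed = spec@seed) {
  group <- match.arg(group)
  p <- spec@protocol
  d <- spec@gridShape
  brain <- .vox(geometry$brainMask) != 0
  sinus <- .vox(geometry$sinusRoi) != 0
  labels <- geometry$atlas@labels
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  nslopeTrue <- array(0, d)
  nslopeTrue[brain] <- rnorm(sum(brain), spec@controlSlopeMean,
                             spec@controlSlopeSd)
  affected <- integer(0)
  if (group == "patient" && spec@effectNRegions > 0L) {
    affected <- sort(sample(geometry$atlas@table$region_id,
                            spec@effectNRegions))
    sel <- labels %in% affected
    if (spec@effectMode == "mad_units") {
      # MAD of N(mu, sd) is 0.6745 sd; effect adds effectSize of those MADs
      nslopeTrue[sel] <- nslopeTrue[sel] +
        spec@effectSize * 0.6745 * spec@controlSlopeSd
    } else {
      nslopeTrue[sel] <- nslopeTrue[sel] * spec@effectSize
    }
  }
  nslopeTrue[sinus] <- 1
  kTrue <- nslopeTrue * spec@sinusTrueSlope  # mM/min
  kTrue[!brain & !sinus] <- 0
  amp <- array(0, d)
  amp[brain] <- spec@bolusAmpTissue
  amp[sinus] <- spec@bolusAmpSinus
  t1 <- array(spec@tissueT1Ms, d)
  t1[sinus] <- spec@bloodT1Ms
  m0 <- array(spec@tissueM0, d)
  m0[!brain & !sinus] <- 0.3 * spec@tissueM0
  tS <- protocolFrameTimes(p)
  f <- .bolusTemplate(tS, p@injectionTimeS)
  late <- pmax(0, tS - p@injectionTimeS) / 60  # minutes post injection
  nv <- prod(d)
  conc <- outer(as.vector(amp), f) + outer(as.vector(kTrue), late)
  S <- synthesizeSignal(conc, t1, m0, p)
  if (spec@noiseSd > 0) {
    S <- S + rnorm(length(S), 0, spec@noiseSd)
  }
  dyn <- dynamicSeries(.asVolume4D(S, d), tS, p@injectionTimeS,
                       .syntheticAffine())
  vfa <- lapply(p@vfaDeg, function(ang) {
    v <- spgrSignal(m0, t1, ang, p@vfaTrMs)
    if (spec@noiseSd > 0) v <- v + array(rnorm(nv, 0, spec@noiseSd), d)
    volumeGrid(v, .syntheticAffine())
  })
  list(dynamic = dyn, vfa = vfa,
       groundTruth = list(nslopeTrue = nslopeTrue, kTrue = kTrue,
                          affectedRegions = affected,
                          sinusTrueSlope = spec@sinusTrueSlope,
                          t1Ms = t1, m0 = m0))
}

# Per-subject seeds derived from the master seed; kept below 2^31.
.subjectSeed <- function(masterSeed, i) {
  as.integer((as.numeric(masterSeed) + 7919 * i) %% 2147483647)
}

#' Generate a cohort in memory
#'
#' Controls first, then patients, each with a seed derived from the master
#' seed, plus a manifest recording group membership, seeds and affected
#' regions.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param geometry optional precomputed [makeAtlas()] output.
#' @return List: `geometry`, `subjects` (list of [makeSubject()] outputs
#'   with `$id` and `$group` added), `manifest` (data.frame).
#' @export
makeCohortList <- function(spec, geometry = makeAtlas(spec)) {
  ids <- c(sprintf("ctrl%03d", seq_len(spec@nControls)),
           sprintf("pat%03d", seq_len(spec@nPatients)))
  groups <- c(rep("control", spec@nControls), rep("patient", spec@nPatients))
  subjects <- lapply(seq_along(ids), function(i) {
    s <- makeSubject(spec, geometry, groups[i], .subjectSeed(spec@seed, i))
    s$id <- ids[i]; s$group <- groups[i]
    s
  })
  manifest <- data.frame(
    subject_id = ids, group = groups,
    seed = vapply(seq_along(ids), function(i) .subjectSeed(spec@seed, i),
                  integer(1)),
    affected_regions = vapply(subjects, function(s) {
      paste(s$groundTruth$affectedRegions, collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  list(geometry = geometry, subjects = subjects, manifest = manifest)
}

#' Write a complete synthetic study to disk
#'
#' Emits the exact input layout the pipeline consumes: per-subject dynamic
#' 4D NIfTI and VFA volumes, shared atlas/brain-mask/sinus-ROI volumes and
#' label table, the protocol YAML, a manifest TSV and a ground-truth table.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param dir output directory (created if missing).
#' @return The manifest data.frame (with file paths), invisibly the
#'   directory path as attribute `dir`.
#' @export
makeCohort <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create study directory: ", dir,
                             call. = FALSE)
  geometry <- makeAtlas(spec)
  writeVolume(volumeGrid(geometry$atlas@labels, geometry$atlas@affine),
              file.path(dir, "atlas.nii.gz"))
  writeLabelTable(geometry$atlas@table, file.path(dir, "atlas_labels.tsv"))
  writeVolume(geometry$brainMask, file.path(dir, "brain_mask.nii.gz"))
  writeVolume(geometry$sinusRoi, file.path(dir, "sinus_roi.nii.gz"))
  writeProtocol(spec@protocol, file.path(dir, "protocol.yaml"))
  cohort <- makeCohortList(spec, geometry)
  manifest <- cohort$manifest
  manifest$dynamic <- NA_character_
  manifest$vfa <- NA_character_
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    sdir <- file.path(dir, s$id)
    dir.create(sdir, showWarnings = FALSE)
    writeDynamic(s$dynamic, file.path(sdir, "dce.nii.gz"))
    vfaPaths <- vapply(seq_along(s$vfa), function(k) {
      pth <- file.path(sdir, sprintf("vfa_%02d.nii.gz", k))
      writeVolume(s$vfa[[k]], pth)
      pth
    }, character(1))
    manifest$dynamic[i] <- file.path(s$id, "dce.nii.gz")
    manifest$vfa[i] <- paste(file.path(s$id, basename(vfaPaths)),
                             collapse = ";")
  }
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}
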