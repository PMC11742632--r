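# Small in-code fixtures shared across the suite. The tiny grid keeps unit
# tests fast; cohort-scale checks use the full default configuration.

tinySpec <- function(...) {
  defaults <- list(gridShape = c(16L, 16L, 6L), nRegions = 20L,
                   nControls = 4L, nPatients = 2L, effectNRegions = 4L,
                   seed = 123L)
  do.call(cohortSpec, utils::modifyList(defaults, list(...)))
}

# Geometry is deterministic, so cache one per grid configuration.
.geomCache <- new.env(parent = emptyenv())
tinyGeom <- function(spec = tinySpec()) {
  key <- paste(spec@gridShape, spec@nRegions, collapse = "_")
  if (is.null(.geomCache[[key]])) .geomCache[[key]] <- makeAtlas(spec)
  .geomCache[[key]]
}

# A NormalizedSlopeMap with prescribed values on a minimal grid.
nslopeMapOf <- function(values, shape = NULL, sinusSlope = 1) {
  if (is.null(shape)) shape <- c(length(values), 1L, 1L)
  new("NormalizedSlopeMap", nslope = array(values, shape),
      sinusSlope = sinusSlope, valid = array(TRUE, shape),
      affine = diag(4))
}

allOnesMask <- function(shape) array(1L, shape)

# A ConcentrationSeries built directly from a (voxels x frames) matrix.
concSeriesOf <- function(C, frameTimes, injectionTime = 0,
                         shape = c(nrow(C), 1L, 1L)) {
  arr <- C
  dim(arr) <- c(shape, ncol(C))
  new("ConcentrationSeries", conc = arr, frameTimes = frameTimes,
      injectionTime = injectionTime, valid = array(TRUE, shape),
      mode = "spgr_inversion", affine = diag(4))
}
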