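test_that("pooled percentile uses linear interpolation between order statistics", {
  m <- nslopeMapOf(as.numeric(1:100), shape = c(100, 1, 1))
  mask <- allOnesMask(c(100, 1, 1))
  expect_equal(pooledPercentile(m, mask, 0.95), 95.05)
  expect_equal(pooledPercentile(m, mask, 1.0), 100)
  mc <- nslopeMapOf(rep(3.2, 50), shape = c(50, 1, 1))
  expect_equal(pooledPercentile(mc, allOnesMask(c(50, 1, 1)), 0.95), 3.2)
  # pooling across subjects is a single multiset
  m1 <- nslopeMapOf(as.numeric(1:50), shape = c(50, 1, 1))
  m2 <- nslopeMapOf(as.numeric(51:100), shape = c(50, 1, 1))
  expect_equal(pooledPercentile(list(m1, m2), allOnesMask(c(50, 1, 1)), 0.95),
               95.05)
  mEmpty <- nslopeMapOf(1, shape = c(1, 1, 1))
  expect_error(pooledPercentile(mEmpty, array(0L, c(1, 1, 1))), "empty")
})

test_that("by construction at most 5% of pooled control voxels exceed the threshold", {
  set.seed(11)
  vals <- rnorm(3000)
  m <- nslopeMapOf(vals, shape = c(3000, 1, 1))
  thr <- pooledPercentile(m, allOnesMask(c(3000, 1, 1)), 0.95)
  frac <- mean(vals > thr)
  expect_lte(frac, 0.05)
  expect_gte(frac, 0.05 - 1 / length(vals))
})

test_that("whole-brain BBBD percent counts valid supra-threshold voxels", {
  vals <- c(rep(0, 190), rep(10, 10))
  m <- nslopeMapOf(vals, shape = c(200, 1, 1))
  mask <- allOnesMask(c(200, 1, 1))
  expect_equal(brainBBBDPercent(m, mask, 5), 5.0)
  expect_equal(brainBBBDPercent(m, mask, 100), 0.0)
  expect_equal(brainBBBDPercent(m, mask, -1), 100.0)
  # invalid voxels are excluded from numerator and denominator
  m@valid[1:100, 1, 1] <- FALSE
  expect_equal(brainBBBDPercent(m, mask, 5), 10.0)
})

test_that("regional percentages respect atlas membership and missing regions", {
  shape <- c(16, 1, 1)
  lab <- array(0L, shape)
  lab[1:10] <- 1L; lab[11:15] <- 2L  # region 3 absent from the volume
  tab <- data.frame(region_id = 1:3, name = c("a_L", "a_R", "b_L"),
                    hemisphere = c("L", "R", "L"), lobe = "frontal")
  atlas <- new("BrainAtlas", labels = lab, table = tab, affine = diag(4))
  vals <- c(rep(1, 3), rep(0, 7), rep(0, 5), 9)
  m <- nslopeMapOf(vals, shape = shape)
  pct <- regionalPercent(m, atlas, 0.5)
  expect_equal(unname(pct[1]), 30.0)
  expect_equal(unname(pct[2]), 0.0)
  expect_true(is.na(pct[3]))
  # a fully supra-threshold region reaches 100
  expect_equal(unname(regionalPercent(m, atlas, -1)[1]), 100.0)
})

test_that("modified z-score matches its arithmetic definition and flags one-sided", {
  ctrl <- matrix(c(1, 2, 3, 4, 5), ncol = 1)  # median 3, MAD 1
  rs <- .regionStatsFrom(ctrl, 1L, "median_mad")
  ref <- new("ControlReference", threshold = 0, percentile = 0.95,
             percentileMethod = "test", madScale = 0.6745,
             deviation = "median_mad", flagCutoff = 2,
             regionStats = rs, nControls = 5L)
  res <- modifiedZ(c(`1` = 6), ref)
  expect_equal(res$z, 2.0235, tolerance = 1e-12)
  expect_true(res$flag)
  # centered value scores zero and is never flagged
  expect_equal(modifiedZ(c(`1` = 3), ref)$z, 0)
  expect_false(modifiedZ(c(`1` = 3), ref)$flag)
  # below-median values score negative and are never flagged (one-sided)
  below <- modifiedZ(c(`1` = 0), ref)
  expect_lt(below$z, 0)
  expect_false(below$flag)
})

test_that("zero-MAD regions fall back to mean absolute deviation, then Inf", {
  # MAD 0 but mean AD > 0: {0, 5, 5, 5, 10}
  rs <- .regionStatsFrom(matrix(c(0, 5, 5, 5, 10), ncol = 1), 1L, "median_mad")
  expect_equal(rs$spread, 0)
  expect_equal(rs$spread_fallback, 2)
  ref <- new("ControlReference", threshold = 0, percentile = 0.95,
             percentileMethod = "test", madScale = 0.6745,
             deviation = "median_mad", flagCutoff = 2,
             regionStats = rs, nControls = 5L)
  expect_equal(modifiedZ(c(`1` = 9), ref)$z, 0.6745 * 4 / 2)
  # all controls identical: unstable reference, Inf above / 0 at-or-below
  rs2 <- .regionStatsFrom(matrix(rep(5, 5), ncol = 1), 1L, "median_mad")
  ref2 <- new("ControlReference", threshold = 0, percentile = 0.95,
              percentileMethod = "test", madScale = 0.6745,
              deviation = "median_mad", flagCutoff = 2,
              regionStats = rs2, nControls = 5L)
  up <- modifiedZ(c(`1` = 6), ref2)
  expect_identical(up$z, Inf)
  expect_true(up$flag)
  expect_true(up$unstable)
  expect_identical(modifiedZ(c(`1` = 5), ref2)$z, 0)
})

test_that("control reference construction is permutation invariant", {
  set.seed(12)
  spec <- tinySpec()
  geom <- tinyGeom(spec)
  maps <- lapply(1:4, function(i) {
    vals <- array(rnorm(prod(spec@gridShape), 0.05, 0.02), spec@gridShape)
    new("NormalizedSlopeMap", nslope = vals, sinusSlope = 0.4,
        valid = array(TRUE, spec@gridShape), affine = geom$atlas@affine)
  })
  refA <- suppressWarnings(
    buildControlReference(maps, geom$brainMask, geom$atlas))
  refB <- suppressWarnings(
    buildControlReference(maps[c(3, 1, 4, 2)], geom$brainMask, geom$atlas))
  expect_identical(refA@threshold, refB@threshold)
  expect_identical(refA@regionStats, refB@regionStats)
  # identical controls give zero MADs and their own percentile as threshold
  refC <- suppressWarnings(
    buildControlReference(maps[c(1, 1, 1)], geom$brainMask, geom$atlas))
  expect_true(all(refC@regionStats$spread == 0))
})

test_that("adding a constant to every map shifts the threshold but not the scores", {
  set.seed(13)
  spec <- tinySpec()
  geom <- tinyGeom(spec)
  mkMaps <- function(delta) lapply(1:5, function(i) {
    set.seed(100 + i)
    vals <- array(rnorm(prod(spec@gridShape), 0.05, 0.02) + delta,
                  spec@gridShape)
    new("NormalizedSlopeMap", nslope = vals, sinusSlope = 0.4,
        valid = array(TRUE, spec@gridShape), affine = geom$atlas@affine)
  })
  m0 <- mkMaps(0); m1 <- mkMaps(1)
  r0 <- suppressWarnings(buildControlReference(m0[1:4], geom$brainMask, geom$atlas))
  r1 <- suppressWarnings(buildControlReference(m1[1:4], geom$brainMask, geom$atlas))
  expect_equal(r1@threshold - r0@threshold, 1, tolerance = 1e-12)
  s0 <- scoreSubject(m0[[5]], geom$brainMask, geom$atlas, r0, "s")
  s1 <- scoreSubject(m1[[5]], geom$brainMask, geom$atlas, r1, "s")
  expect_equal(bbbPercent(s1), bbbPercent(s0), tolerance = 1e-9)
  expect_equal(regionResults(s1)$z, regionResults(s0)$z, tolerance = 1e-9)
})

test_that("control references round-trip through JSON", {
  set.seed(14)
  spec <- tinySpec()
  geom <- tinyGeom(spec)
  maps <- lapply(1:4, function(i) {
    vals <- array(rnorm(prod(spec@gridShape), 0.05, 0.02), spec@gridShape)
    new("NormalizedSlopeMap", nslope = vals, sinusSlope = 0.4,
        valid = array(TRUE, spec@gridShape), affine = geom$atlas@affine)
  })
  ref <- suppressWarnings(
    buildControlReference(maps, geom$brainMask, geom$atlas))
  path <- tempfile(fileext = ".json")
  writeControlReference(ref, path)
  back <- readControlReference(path)
  expect_equal(back@threshold, ref@threshold)
  expect_equal(back@regionStats$center, ref@regionStats$center)
  expect_equal(back@regionStats$spread, ref@regionStats$spread)
  expect_identical(back@nControls, ref@nControls)
  # scoring against the restored reference reproduces results bit-exactly
  sA <- scoreSubject(maps[[1]], geom$brainMask, geom$atlas, ref, "s")
  sB <- scoreSubject(maps[[1]], geom$brainMask, geom$atlas, back, "s")
  expect_identical(regionResults(sA), regionResults(sB))
  expect_identical(bbbPercent(sA), bbbPercent(sB))
})
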