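# SPGR signal model: forward signal equation, variable-flip-angle (DESPOT1)
# T1/M0 mapping, dynamic-series gain calibration, and inversion of the
# dynamic signal to gadolinium concentration via the agent's relaxivity.
# TE-dependent T2* decay is a static multiplicative factor absorbed into M0
# and the gain (contrast-induced T2* change is neglected in the
# low-concentration late-leakage regime).

#' Steady-state spoiled gradient-echo signal
#'
#' \deqn{S = M_0 \sin\alpha \, (1 - E_1) / (1 - \cos\alpha \, E_1)},
#' with \eqn{E_1 = \exp(-TR/T_1)}. Vectorized over all arguments.
#'
#' @param m0 equilibrium signal (a.u.; absorbs T2* decay and coil gain).
#' @param t1Ms longitudinal relaxation time (ms), > 0.
#' @param faDeg flip angle (degrees), in (0, 90].
#' @param trMs repetition time (ms), > 0.
#' @return Signal in a.u.
#' @examples
#' spgrSignal(1000, 1000, 15, 10)
#' @export
spgrSignal <- function(m0, t1Ms, faDeg, trMs) {
  stopifnot(all(t1Ms > 0), all(faDeg > 0 & faDeg <= 90), all(trMs > 0))
  a <- deg2rad(faDeg)
  e1 <- exp(-trMs / t1Ms)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' Variable-flip-angle (DESPOT1) T1 and M0 fit
#'
#' Linearizes the SPGR equation as \eqn{S/\sin\alpha = E_1 \, S/\tan\alpha +
#' M_0 (1 - E_1)} and fits per voxel by ordinary least squares across flip
#' angles: the slope is \eqn{E_1}, giving \eqn{T_1 = -TR/\log E_1}, and the
#' intercept gives \eqn{M_0}. Voxels whose slope falls outside (0, 1), whose
#' design is degenerate, or whose recovered T1 exceeds 10 s are marked
#' `fitOK = FALSE`.
#'
#' @param signals matrix (voxels x angles) or numeric vector of per-angle
#'   signals for a single voxel.
#' @param vfaDeg flip angles (degrees), at least two, distinct.
#' @param trMs VFA repetition time (ms).
#' @return List with `t1Ms`, `m0`, `fitOK`, each of length `nrow(signals)`.
#' @export
fitT1Vfa <- function(signals, vfaDeg, trMs) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1L)
  nAng <- length(vfaDeg)
  if (nAng < 2L) stop("need at least 2 flip angles", call. = FALSE)
  if (anyDuplicated(vfaDeg)) stop("flip angles must be distinct", call. = FALSE)
  if (ncol(signals) != nAng) {
    stop("signals must have one column per flip angle", call. = FALSE)
  }
  a <- deg2rad(vfaDeg)
  y <- sweep(signals, 2L, sin(a), "/")
  x <- sweep(signals, 2L, tan(a), "/")
  xm <- rowMeans(x); ym <- rowMeans(y)
  xc <- x - xm
  sxx <- rowSums(xc * xc)
  sxy <- rowSums(xc * (y - ym))
  e1 <- sxy / sxx
  b <- ym - e1 * xm
  t1 <- -trMs / log(e1)
  m0 <- b / (1 - e1)
  ok <- is.finite(e1) & e1 > 0 & e1 < 1 & sxx > 0 &
    is.finite(t1) & t1 > 0 & t1 <= 10000 & is.finite(m0) & m0 > 0 &
    rowSums(signals != 0) > 0
  t1[!ok] <- NA_real_
  m0[!ok] <- NA_real_
  list(t1Ms = t1, m0 = m0, fitOK = ok)
}

#' T1/M0 maps from a set of VFA volumes
#'
#' @param vfaVolumes list of [VolumeGrid-class] (or 3D arrays), one per flip
#'   angle, on a common grid.
#' @param protocol an [AcquisitionProtocol-class]; supplies `vfaDeg` and
#'   `vfaTrMs`.
#' @return A [T1Maps-class].
#' @export
vfaT1Maps <- function(vfaVolumes, protocol) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  if (length(vfaVolumes) != length(protocol@vfaDeg)) {
    stop("need one VFA volume per protocol flip angle", call. = FALSE)
  }
  for (v in vfaVolumes[-1]) assertSameGrid(vfaVolumes[[1]], v, "VFA volumes")
  shape <- dim(.vox(vfaVolumes[[1]]))
  sig <- vapply(vfaVolumes, function(v) as.vector(.vox(v)),
                numeric(prod(shape)))
  fit <- fitT1Vfa(sig, protocol@vfaDeg, protocol@vfaTrMs)
  t1 <- array(fit$t1Ms, shape)
  m0 <- array(fit$m0, shape)
  ok <- array(fit$fitOK, shape)
  new("T1Maps", t1Ms = t1, m0 = m0, fitOK = ok,
      affine = .affineOf(vfaVolumes[[1]]))
}

#' Dynamic-series gain calibration
#'
#' Bridges the VFA-derived M0 scale to the dynamic-series signal scale:
#' per voxel, `gain = mean pre-injection dynamic signal / predicted SPGR
#' baseline signal` at the dynamic flip angle and TR. Voxels with a failed
#' T1 fit or non-positive predicted/observed baseline are invalid (`NA`).
#'
#' @param dyn a [DynamicSeries-class].
#' @param maps a [T1Maps-class] on the same grid.
#' @param protocol an [AcquisitionProtocol-class].
#' @return A [VolumeGrid-class] of gains (`NA` where invalid).
#' @export
calibrateGain <- function(dyn, maps, protocol) {
  stopifnot(is(dyn, "DynamicSeries"), is(maps, "T1Maps"))
  assertSameGrid(volumeGrid(maps@t1Ms, maps@affine),
                 volumeGrid(array(dyn@data[, , , 1L], dim(dyn@data)[1:3]),
                            dyn@affine),
                 "dynamic series and T1 maps")
  base <- .baselineFrames(protocol, dyn@frameTimes)
  S <- .asVoxelMatrix(dyn@data)
  s0 <- rowMeans(S[, base, drop = FALSE])
  ok <- as.vector(maps@fitOK)
  pred <- rep(NA_real_, length(s0))
  pred[ok] <- spgrSignal(as.vector(maps@m0)[ok], as.vector(maps@t1Ms)[ok],
                         protocol@faDeg, protocol@trMs)
  gain <- s0 / pred
  gain[!ok | !is.finite(gain) | gain <= 0 | pred <= 0] <- NA_real_
  volumeGrid(array(gain, dim(maps@t1Ms)), maps@affine)
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' In `"spgr_inversion"` mode the SPGR equation is inverted exactly per
#' frame and voxel:
#' \eqn{E_1(t) = (g M_0 \sin\alpha - S(t)) / (g M_0 \sin\alpha - S(t)\cos\alpha)},
#' \eqn{R_1(t) = -\log E_1(t) / TR}, and
#' \eqn{C(t) = (R_1(t) - 1/T_1) / r_1} with the relaxivity \eqn{r_1} in
#' 1/(mM s). Voxels where \eqn{E_1(t)} leaves (0, 1) at any frame are
#' invalidated. In `"linear_delta_s"` mode the first-order approximation
#' \eqn{C(t) \propto (S(t) - S_0)/S_0} is used instead (arbitrary units;
#' slopes remain comparable after sinus normalization).
#'
#' @param dyn a [DynamicSeries-class].
#' @param maps a [T1Maps-class].
#' @param gain gain [VolumeGrid-class] from [calibrateGain()].
#' @param protocol an [AcquisitionProtocol-class].
#' @param mode `"spgr_inversion"` (default) or `"linear_delta_s"`.
#' @return A [ConcentrationSeries-class] (mM in inversion mode).
#' @export
signalToConcentration <- function(dyn, maps, gain, protocol,
                                  mode = c("spgr_inversion", "linear_delta_s")) {
  mode <- match.arg(mode)
  stopifnot(is(dyn, "DynamicSeries"), is(maps, "T1Maps"))
  shape <- dim(maps@t1Ms)
  S <- .asVoxelMatrix(dyn@data)
  nf <- ncol(S)
  if (mode == "linear_delta_s") {
    base <- .baselineFrames(protocol, dyn@frameTimes)
    s0 <- rowMeans(S[, base, drop = FALSE])
    valid <- is.finite(s0) & s0 > 0
    conc <- (S / s0) - 1
    conc[!valid, ] <- NA_real_
  } else {
    g <- as.vector(.vox(gain))
    m0 <- as.vector(maps@m0)
    t1 <- as.vector(maps@t1Ms)
    ok <- as.vector(maps@fitOK) & is.finite(g) & g > 0
    a <- deg2rad(protocol@faDeg)
    trS <- protocol@trMs / 1000
    gm <- g * m0 * sin(a)
    # E1(t) = (g M0 sin a - S) / (g M0 sin a - S cos a); gm recycles down columns
    e1 <- (gm - S) / (gm - S * cos(a))
    inDomain <- e1 > 0 & e1 < 1
    valid <- ok & rowSums(!inDomain) == 0L
    r1 <- -log(e1) / trS
    conc <- (r1 - 1 / (t1 / 1000)) / protocol@r1Relaxivity
    conc[!valid, ] <- NA_real_
  }
  new("ConcentrationSeries",
      conc = .asVolume4D(conc, shape),
      frameTimes = dyn@frameTimes, injectionTime = dyn@injectionTime,
      valid = array(valid, shape), mode = mode, affine = maps@affine)
}

#' Synthesize an SPGR dynamic series from known concentration
#'
#' Forward model used by the synthetic-data generator and round-trip tests:
#' \eqn{R_1(t) = 1/T_1 + r_1 C(t)}, then the SPGR signal at the dynamic flip
#' angle and TR (gain 1).
#'
#' @param conc matrix (voxels x frames) or 4D array of concentration (mM).
#' @param t1Ms,m0 per-voxel baseline T1 (ms) and M0 (a.u.).
#' @param protocol an [AcquisitionProtocol-class].
#' @return Same shape as `conc`: signal in a.u.
#' @export
synthesizeSignal <- function(conc, t1Ms, m0, protocol) {
  shape4 <- dim(conc)
  C <- if (length(shape4) == 4L) .asVoxelMatrix(conc) else conc
  a <- deg2rad(protocol@faDeg)
  trS <- protocol@trMs / 1000
  r1 <- 1 / (as.vector(t1Ms) / 1000) + protocol@r1Relaxivity * C
  e1 <- exp(-trS * r1)
  S <- as.vector(m0) * sin(a) * (1 - e1) / (1 - cos(a) * e1)
  if (length(shape4) == 4L) S <- .asVolume4D(S, shape4[1:3])
  S
}
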