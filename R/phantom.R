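## Digital mouse phantom and forward imaging simulator.

.ifftshiftMat <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((n1 - floor(n1 / 2) + 1):n1, seq_len(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, seq_len(n2 - floor(n2 / 2)))]
}

#' Construct a phantom definition
#'
#' @param gridSize integer `(ny, nx)` fine simulation grid.
#' @param pitchMM fine-grid pitch (mm).
#' @param regions named list of disjoint logical masks; must include
#'   `vessel` and `tumor`.
#' @param perfusion named per-region bolus amplitude scaling.
#' @param params named list of [PKParams-class] per region.
#' @param noiseSD complex-channel noise sd per reconstructed frame.
#' @param seed default RNG seed for [forwardImage()].
#' @return a [PhantomDef-class] object.
#' @export
phantomDef <- function(gridSize, pitchMM, regions, perfusion, params,
                       noiseSD = 0.002, seed = 1) {
  new("PhantomDef", gridSize = as.integer(gridSize),
      pitchMM = as.numeric(pitchMM), regions = regions,
      perfusion = unlist(perfusion)[names(regions)],
      params = params[names(regions)], noiseSD = as.numeric(noiseSD),
      seed = as.integer(seed))
}

#' Default digital mouse phantom
#'
#' A 32 mm field of view on a 1 mm fine grid holding a high-perfusion,
#' low-k_PL vessel strip and an adjacent moderate-perfusion, high-k_PL tumor
#' disc, separated by roughly one nominal 4 mm voxel. Tumor k_PL defaults to
#' 0.05 1/s, the standard simulation value, and lies inside the
#' physiological range reported for implanted tumors (0.02-0.11 1/s).
#' Geometry and perfusion contrast are synthetic package constants chosen so
#' the vascular-bleed phenomenon is robust across noise seeds; they are not
#' measured values.
#'
#' @param seed default RNG seed carried by the phantom.
#' @param noiseSD complex-channel noise sd per frame.
#' @param tumorKpl tumor conversion rate (1/s).
#' @return a [PhantomDef-class] object.
#' @examples
#' makeDefaultPhantom()
#' @export
makeDefaultPhantom <- function(seed = 1, noiseSD = 0.002, tumorKpl = 0.05) {
  n <- 32L; pitch <- 1
  xc <- (seq_len(n) - 0.5) * pitch
  yc <- (seq_len(n) - 0.5) * pitch
  X <- matrix(xc, n, n, byrow = TRUE)
  Y <- matrix(yc, n, n)
  vessel <- X > 4 & X <= 8 & Y > 8 & Y <= 24
  tumor <- (X - 18)^2 + (Y - 16)^2 <= 6^2
  background <- !(vessel | tumor)
  phantomDef(
    gridSize = c(n, n), pitchMM = pitch,
    regions = list(vessel = vessel, tumor = tumor, background = background),
    perfusion = c(vessel = 1.75, tumor = 1, background = 0),
    params = list(vessel = pkParams(kpl = 0.014),
                  tumor = pkParams(kpl = tumorKpl),
                  background = pkParams(kpl = 0)),
    noiseSD = noiseSD, seed = seed)
}

## Downsample a fine logical mask to the protocol matrix by block coverage.
.coarseMask <- function(mask, coarseDim, frac = 0.5) {
  by <- nrow(mask) / coarseDim[1]; bx <- ncol(mask) / coarseDim[2]
  out <- matrix(FALSE, coarseDim[1], coarseDim[2])
  for (r in seq_len(coarseDim[1])) for (c in seq_len(coarseDim[2])) {
    blk <- mask[round((r - 1) * by) + seq_len(round(by)),
                round((c - 1) * bx) + seq_len(round(bx))]
    out[r, c] <- mean(blk) >= frac
  }
  out
}

#' Region mask at the acquisition resolution
#'
#' @param phantom a [PhantomDef-class] object.
#' @param protocol an [AcquisitionProtocol-class] object.
#' @param region region name.
#' @param frac minimum fine-grid coverage for a coarse voxel to be inside.
#' @return logical matrix at the protocol matrix size.
#' @export
coarseRegionMask <- function(phantom, protocol, region, frac = 0.5) {
  stopifnot(region %in% names(phantom@regions))
  .coarseMask(phantom@regions[[region]], protocol@matrixSize, frac)
}

## Noise mask: coarse voxels whose fine block lies in background and at
## least `marginMM` away from any object voxel.
.noiseMaskFor <- function(phantom, coarseDim, marginMM = 6) {
  obj <- !phantom@regions$background
  n1 <- nrow(obj); n2 <- ncol(obj)
  objIdx <- which(obj, arr.ind = TRUE)
  pitch <- phantom@pitchMM
  by <- n1 / coarseDim[1] * pitch; bx <- n2 / coarseDim[2] * pitch
  out <- matrix(FALSE, coarseDim[1], coarseDim[2])
  for (r in seq_len(coarseDim[1])) for (c in seq_len(coarseDim[2])) {
    yc <- (r - 0.5) * by; xc <- (c - 0.5) * bx
    d <- sqrt((objIdx[, 1] * pitch - pitch / 2 - yc)^2 +
              (objIdx[, 2] * pitch - pitch / 2 - xc)^2)
    out[r, c] <- min(d) >= marginMM
  }
  out
}

## k-space truncation of a fine image to the coarse matrix, preserving
## per-voxel integral scaling (signal proportional to voxel area).
.ktruncate <- function(img, coarseDim) {
  kf <- .fftshiftMat(stats::fft(img))
  nyf <- nrow(img); nxf <- ncol(img)
  nyc <- coarseDim[1]; nxc <- coarseDim[2]
  r0 <- floor(nyf / 2) - floor(nyc / 2)
  c0 <- floor(nxf / 2) - floor(nxc / 2)
  kc <- kf[r0 + seq_len(nyc), c0 + seq_len(nxc)]
  stats::fft(.ifftshiftMat(kc), inverse = TRUE) / (nyc * nxc)
}

## Sample one centred k-space index of a fine image on the coarse grid.
.ksample <- function(img, coarseDim, row, col) {
  kf <- .fftshiftMat(stats::fft(img))
  r0 <- floor(nrow(img) / 2) - floor(coarseDim[1] / 2)
  c0 <- floor(ncol(img) / 2) - floor(coarseDim[2] / 2)
  kf[r0 + row, c0 + col]
}

#' Forward-simulate a dynamic image series from a phantom
#'
#' Evolves every fine-grid voxel under the two-pool model with its region's
#' kinetic parameters and a perfusion-scaled bolus, and forms images the way
#' the encoding does. For single-shot EPI each metabolite frame is the
#' instantaneous transverse image at its excitation time, band-limited to
#' the protocol matrix (flat k-space weighting). For CSI each frame's
#' k-space is assembled encode by encode from the DFT of the evolving object
#' at that encode's acquisition time (centric or linear order), so the
#' hyperpolarized decay and metabolic conversion across the phase-encode
#' train apodize k-space; the frame is then the inverse DFT. Complex
#' Gaussian noise of sd `noiseSD` is added per frame and the magnitude
#' taken (Rician statistics). Voxel values scale with voxel area, so
#' coarser acquisition matrices collect more signal per voxel.
#'
#' @param phantom a [PhantomDef-class] object.
#' @param protocol an [AcquisitionProtocol-class]; its FOV must match the
#'   phantom extent and its matrix must not exceed the phantom grid.
#' @param input an [InputFunction-class] bolus (scaled per region).
#' @param seed RNG seed; defaults to the phantom's.
#' @return a [DynamicImageSeries-class] with `pyruvate` and `lactate`
#'   channels.
#' @examples
#' ph <- makeDefaultPhantom()
#' ser <- forwardImage(ph, epiProtocol(matrixSize = c(8, 8)), inputFunction())
#' @export
forwardImage <- function(phantom, protocol, input, seed = NULL) {
  stopifnot(is(phantom, "PhantomDef"), is(protocol, "AcquisitionProtocol"),
            is(input, "InputFunction"))
  fovMM <- phantom@gridSize * phantom@pitchMM
  if (any(abs(protocol@fov - fovMM) > 1e-9))
    stop(sprintf("protocol FOV (%g x %g mm) must match the phantom extent (%g x %g mm)",
                 protocol@fov[1], protocol@fov[2], fovMM[1], fovMM[2]))
  if (any(protocol@matrixSize > phantom@gridSize))
    stop("protocol matrix exceeds the phantom grid")
  if (is.null(seed)) seed <- phantom@seed
  set.seed(seed)
  nyf <- phantom@gridSize[1]; nxf <- phantom@gridSize[2]
  cd <- protocol@matrixSize
  nT <- protocol@nTimepoints
  perfMap <- matrix(0, nyf, nxf)
  for (r in names(phantom@regions))
    perfMap[phantom@regions[[r]]] <- phantom@perfusion[[r]]
  ## per-region closed-form propagation over a fixed dt
  coefMaps <- function(dt) {
    a <- b <- g <- matrix(0, nyf, nxf)
    for (r in names(phantom@regions)) {
      cf <- .longCoefParams(phantom@params[[r]], dt)
      m <- phantom@regions[[r]]
      a[m] <- cf["a"]; b[m] <- cf["b"]; g[m] <- cf["g"]
    }
    list(a = a, b = b, g = g)
  }
  stepState <- function(st, cf, uInc) {
    l <- st$l * cf$b + st$p * cf$g
    p <- st$p * cf$a + perfMap * uInc
    list(p = p, l = l)
  }
  addNoiseMag <- function(cimg) {
    Mod(cimg + matrix(stats::rnorm(prod(cd), sd = phantom@noiseSD), cd[1], cd[2]) +
          1i * matrix(stats::rnorm(prod(cd), sd = phantom@noiseSD), cd[1], cd[2]))
  }
  st <- list(p = matrix(0, nyf, nxf), l = matrix(0, nyf, nxf))
  times <- (seq_len(nT) - 1) * protocol@temporalResolution
  dat <- array(0, c(2, nT, cd[1], cd[2]))
  if (protocol@encoding == "epi_singleshot") {
    aP <- protocol@flips[["pyruvate"]] * pi / 180
    aL <- protocol@flips[["lactate"]] * pi / 180
    cf1 <- coefMaps(protocol@intraTR)
    cf2 <- coefMaps(protocol@temporalResolution - protocol@intraTR)
    ## inflow for each inter-timepoint interval, lumped at timepoint start
    U <- diff(.inputCDF(input, c(times[1] - protocol@temporalResolution,
                                 times)))
    for (n in seq_len(nT)) {
      st$p <- st$p + perfMap * U[n]
      dat[1, n, , ] <- addNoiseMag(.ktruncate(sin(aP) * st$p, cd))
      st$p <- st$p * cos(aP)
      st <- stepState(st, cf1, 0)
      dat[2, n, , ] <- addNoiseMag(.ktruncate(sin(aL) * st$l, cd))
      st$l <- st$l * cos(aL)
      st <- stepState(st, cf2, 0)
    }
    flips <- protocol@flips[c("pyruvate", "lactate")]
  } else {
    a <- protocol@flips[[1]] * pi / 180
    enc <- orderPhaseEncodes(cd, protocol@ordering)
    cfE <- coefMaps(protocol@csiTR)
    frameGap <- protocol@temporalResolution - protocol@csiTR * nrow(enc)
    cfGap <- if (frameGap > 1e-9) coefMaps(frameGap) else NULL
    U0 <- .inputCDF(input, times[1])
    st$p <- st$p + perfMap * U0
    tNow <- times[1]
    for (n in seq_len(nT)) {
      kP <- matrix(0i, cd[1], cd[2]); kL <- matrix(0i, cd[1], cd[2])
      for (j in seq_len(nrow(enc))) {
        kP[enc$row[j], enc$col[j]] <- .ksample(sin(a) * st$p, cd,
                                               enc$row[j], enc$col[j])
        kL[enc$row[j], enc$col[j]] <- .ksample(sin(a) * st$l, cd,
                                               enc$row[j], enc$col[j])
        st$p <- st$p * cos(a); st$l <- st$l * cos(a)
        uInc <- .inputCDF(input, tNow + protocol@csiTR) - .inputCDF(input, tNow)
        st <- stepState(st, cfE, uInc)
        tNow <- tNow + protocol@csiTR
      }
      recon <- function(k) stats::fft(.ifftshiftMat(k), inverse = TRUE) /
        (cd[1] * cd[2])
      dat[1, n, , ] <- addNoiseMag(recon(kP))
      dat[2, n, , ] <- addNoiseMag(recon(kL))
      if (!is.null(cfGap)) {
        uInc <- .inputCDF(input, tNow + frameGap) - .inputCDF(input, tNow)
        st <- stepState(st, cfGap, uInc)
        tNow <- tNow + frameGap
      }
    }
    flips <- c(pyruvate = protocol@flips[[1]], lactate = protocol@flips[[1]])
  }
  new("DynamicImageSeries", data = dat,
      metabolites = c("pyruvate", "lactate"), times = times, flips = flips,
      noiseMask = .noiseMaskFor(phantom, cd),
      voxelMM = protocol@fov[2] / cd[2], seed = as.numeric(seed))
}

## Local maxima with topographic prominence (fraction of profile max).
.countPeaks <- function(v, prominenceFrac) {
  n <- length(v)
  if (n < 3 || max(v) <= min(v)) return(0L)
  thr <- prominenceFrac * max(v)
  count <- 0L
  for (i in 2:(n - 1)) {
    if (!(v[i] > v[i - 1] && v[i] >= v[i + 1])) next
    ## walk each side until higher ground; prominence from the deeper saddle
    leftMin <- v[i]
    j <- i - 1
    while (j >= 1 && v[j] <= v[i]) { leftMin <- min(leftMin, v[j]); j <- j - 1 }
    rightMin <- v[i]
    j <- i + 1
    while (j <= n && v[j] <= v[i]) { rightMin <- min(rightMin, v[j]); j <- j + 1 }
    prom <- v[i] - max(leftMin, rightMin)
    if (prom >= thr) count <- count + 1L
  }
  count
}

#' Lactate bleed line profile
#'
#' Extracts the lactate AUC values along an image row crossing both the
#' vessel and the tumor, and counts the local maxima whose topographic
#' prominence exceeds `prominence` times the profile maximum. Two distinct
#' peaks mean vessel and tumor are resolved; a single merged peak is the
#' signature of vascular signal bleeding into the tumor.
#'
#' @param series a [DynamicImageSeries-class] from [forwardImage()].
#' @param phantom the [PhantomDef-class] the series was simulated from.
#' @param row image row (1-based, at acquisition resolution); default is the
#'   row through the tumor centre.
#' @param prominence prominence threshold as a fraction of the profile max.
#' @return a [LineProfile-class] object.
#' @export
bleedProfile <- function(series, phantom, row = NULL, prominence = 0.25) {
  stopifnot(is(series, "DynamicImageSeries"), is(phantom, "PhantomDef"))
  cd <- dim(series@data)[3:4]
  tumorC <- .coarseMask(phantom@regions$tumor, cd, frac = 0.25)
  vesselC <- .coarseMask(phantom@regions$vessel, cd, frac = 0.25)
  if (is.null(row)) {
    cover <- rowSums(tumorC * 1)
    row <- which.max(cover)
  }
  if (!any(tumorC[row, ]) || !any(vesselC[row, ]))
    stop("line does not intersect both the vessel and the tumor")
  auc <- aucMap(series)
  v <- auc["lactate", row, ]
  new("LineProfile",
      positions = (seq_len(cd[2]) - 0.5) * series@voxelMM,
      values = v, peakCount = .countPeaks(v, prominence),
      prominence = prominence)
}
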