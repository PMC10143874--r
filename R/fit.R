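## Inputless one-compartment k_PL fitting.

## Predicted pre-pulse longitudinal lactate series given measured pyruvate.
## The measured pyruvate drives the lactate equation: within each
## inter-timepoint interval pyruvate is taken to decay mono-exponentially at
## rate kpl + R1P from its measured post-pulse value, and the lactate gain is
## the exact solution of dMLz/dt = kpl*MPz - R1L*MLz over the interval.
## Two segments per interval account for the lactate excitation sitting
## intraTR after the pyruvate excitation. Bolus inflow needs no explicit
## model: it deposits at timepoint starts, where pyruvate is re-measured.
.predictLactate <- function(k, pPost, lPre1, times, intraTR, sinL, cosL,
                            R1P, R1L) {
  n <- length(pPost)
  lPre <- numeric(n)
  lPre[1] <- lPre1
  for (m in seq_len(n - 1)) {
    dt <- times[m + 1] - times[m]
    c1 <- .longCoef(k, R1P, R1L, intraTR)
    c2 <- .longCoef(k, R1P, R1L, dt - intraTR)
    pAtL <- pPost[m] * c1["a"]
    lMid <- (lPre[m] * cosL) * c2["b"] + pAtL * c2["g"]
    lPre[m + 1] <- lMid * c1["b"] + pPost[m + 1] * c1["g"]
  }
  lPre
}

#' Inputless k_PL fit to pyruvate/lactate timecourses
#'
#' Fits the apparent conversion rate k_PL by bounded scalar least squares,
#' using the measured pyruvate signal as the driving input of the lactate
#' equation (no arterial input function is modelled). Flip angles are
#' accounted for: measured signals are converted to longitudinal estimates
#' through `sin(flip)`, and each excitation costs a `cos(flip)` factor.
#' The first lactate point initializes the predicted lactate; the remaining
#' points form the residual. T1 values are fixed, not fitted.
#'
#' @param pyr,lac measured signal magnitude timecourses.
#' @param flips named flip angles in degrees (`pyruvate`, `lactate`).
#' @param times pyruvate excitation times (s), >= 3 timepoints.
#' @param intraTR delay between the pyruvate and lactate excitations of a
#'   timepoint (s).
#' @param t1Lac,t1Pyr fixed relaxation times (s) of the fit model.
#' @param bounds k_PL search interval (1/s).
#' @return a [KplFitResult-class] object. An estimate within 1e-4 of a bound
#'   is flagged as not converged (pinned), not an error.
#' @examples
#' tc <- simulateEPIDynamics(epiProtocol(), pkParams(), inputFunction())
#' fitKpl(tc@pyr, tc@lac, flips = c(pyruvate = 10, lactate = 30),
#'        times = tc@times)
#' @export
fitKpl <- function(pyr, lac, flips, times, intraTR = 0.13, t1Lac = 30,
                   t1Pyr = 20, bounds = c(0, 1)) {
  n <- length(times)
  if (n < 3) stop("need at least 3 timepoints to fit k_PL")
  if (length(pyr) != n || length(lac) != n)
    stop("'pyr', 'lac' and 'times' must have equal length")
  if (!all(c("pyruvate", "lactate") %in% names(flips)))
    stop("'flips' must name both 'pyruvate' and 'lactate'")
  if (all(pyr == 0))
    stop("pyruvate timecourse is identically zero: k_PL is unidentifiable")
  aP <- flips[["pyruvate"]] * pi / 180
  aL <- flips[["lactate"]] * pi / 180
  pPost <- pyr / sin(aP) * cos(aP)
  lPre1 <- lac[1] / sin(aL)
  obj <- function(k) {
    pred <- .predictLactate(k, pPost, lPre1, times, intraTR, sin(aL),
                            cos(aL), 1 / t1Pyr, 1 / t1Lac) * sin(aL)
    sum((pred[-1] - lac[-1])^2)
  }
  opt <- stats::optimize(obj, interval = bounds, tol = 1e-8)
  pinned <- opt$minimum < bounds[1] + 1e-4 || opt$minimum > bounds[2] - 1e-4
  new("KplFitResult", kplHat = opt$minimum, residualNorm = opt$objective,
      converged = !pinned, nPointsUsed = n - 1L)
}

#' Normalize a dynamic series by its noise-region mean
#'
#' Divides all data by the mean, over time, space and metabolite channels,
#' of the voxels inside the noise mask (a region outside the subject). After
#' normalization the noise-region mean is 1, putting signal in units of the
#' noise floor.
#'
#' @param series a [DynamicImageSeries-class] object with a non-empty noise
#'   mask.
#' @return a list with `series` (normalized) and `noiseLevel` (the scalar
#'   divided out).
#' @export
noiseNormalize <- function(series) {
  stopifnot(is(series, "DynamicImageSeries"))
  if (!any(series@noiseMask)) stop("noise mask is empty")
  d <- dim(series@data)
  flat <- matrix(series@data, prod(d[1:2]), prod(d[3:4]))
  m <- mean(flat[, as.vector(series@noiseMask)])
  if (m <= 0) stop("noise-region mean is not positive; cannot normalize")
  series@data <- series@data / m
  list(series = series, noiseLevel = m)
}

#' Voxelwise and ROI-average k_PL maps
#'
#' Normalizes the series by its noise-region mean (when a noise mask is
#' present), fits k_PL once to the ROI-mean timecourses, and once per ROI
#' voxel. Voxels whose peak lactate signal falls below `snrFloor` times the
#' normalized noise level are masked out of the map (they would return
#' bound-pinned garbage).
#'
#' @param series a [DynamicImageSeries-class] containing `pyruvate` and
#'   `lactate` channels.
#' @param roiMask logical `(y, x)` region of interest, non-empty, disjoint
#'   from the noise mask.
#' @param snrFloor minimum peak lactate, in units of the normalized noise
#'   level, for a voxel to be fitted.
#' @param intraTR,t1Lac,t1Pyr,bounds passed to [fitKpl()].
#' @return a list with `map` (k_PL matrix, NA outside the ROI and below the
#'   SNR floor), `roiFit` (a [KplFitResult-class]), `noiseLevel`, and
#'   `nBelowFloor`.
#' @export
fitKplMap <- function(series, roiMask, snrFloor = 3, intraTR = 0.13,
                      t1Lac = 30, t1Pyr = 20, bounds = c(0, 1)) {
  stopifnot(is(series, "DynamicImageSeries"))
  if (!any(roiMask)) stop("ROI mask is empty")
  if (any(roiMask & series@noiseMask))
    stop("ROI mask overlaps the noise mask")
  noiseLevel <- 0
  if (any(series@noiseMask)) {
    nn <- noiseNormalize(series)
    series <- nn$series
    noiseLevel <- 1  # in normalized units
  }
  ip <- match("pyruvate", series@metabolites)
  il <- match("lactate", series@metabolites)
  if (is.na(ip) || is.na(il))
    stop("series must contain 'pyruvate' and 'lactate' channels")
  flips <- series@flips[c("pyruvate", "lactate")]
  doFit <- function(p, l) fitKpl(p, l, flips = flips, times = series@times,
                                 intraTR = intraTR, t1Lac = t1Lac,
                                 t1Pyr = t1Pyr, bounds = bounds)
  vox <- which(roiMask, arr.ind = TRUE)
  nT <- length(series@times)
  getTC <- function(met, y, x) series@data[met, , y, x]
  pMean <- rowMeans(matrix(apply(vox, 1, function(v) getTC(ip, v[1], v[2])),
                           nrow = nT))
  lMean <- rowMeans(matrix(apply(vox, 1, function(v) getTC(il, v[1], v[2])),
                           nrow = nT))
  roiFit <- doFit(pMean, lMean)
  map <- matrix(NA_real_, dim(series@data)[3], dim(series@data)[4])
  nBelow <- 0L
  for (i in seq_len(nrow(vox))) {
    y <- vox[i, 1]; x <- vox[i, 2]
    l <- getTC(il, y, x)
    if (noiseLevel > 0 && max(l) < snrFloor * noiseLevel) {
      nBelow <- nBelow + 1L
      next
    }
    map[y, x] <- fitKpl(getTC(ip, y, x), l, flips = flips,
                        times = series@times, intraTR = intraTR,
                        t1Lac = t1Lac, t1Pyr = t1Pyr, bounds = bounds)@kplHat
  }
  list(map = map, roiFit = roiFit, noiseLevel = noiseLevel,
       nBelowFloor = nBelow)
}

#' Area-under-the-curve maps
#'
#' Per-voxel sum of the magnitude signal over all timepoints, one map per
#' metabolite.
#'
#' @param series a [DynamicImageSeries-class] object.
#' @return a 3-D array `[metabolite, y, x]` with metabolite dimnames.
#' @export
aucMap <- function(series) {
  stopifnot(is(series, "DynamicImageSeries"))
  out <- apply(series@data, c(1, 3, 4), sum)
  dimnames(out) <- list(series@metabolites, NULL, NULL)
  out
}
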