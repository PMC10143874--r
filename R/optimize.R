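## Flip-angle / temporal-resolution protocol optimization.

#' Relative SNR of a simulated timecourse
#'
#' Relative SNR is approximated as the sum of the modelled magnitude signal
#' over all timepoints, per metabolite.
#'
#' @param timecourse a [SignalTimecourse-class] object.
#' @return named vector `c(pyr = ..., lac = ...)`.
#' @export
relativeSNR <- function(timecourse) {
  stopifnot(is(timecourse, "SignalTimecourse"))
  c(pyr = sum(timecourse@pyr), lac = sum(timecourse@lac))
}

#' Relative-SNR grid over flip angles and temporal resolutions
#'
#' Runs the dynamic EPI simulator for every (pyruvate flip, lactate flip,
#' temporal resolution) combination and stores the per-metabolite relative
#' SNR. Cells are independent simulations (fill order is irrelevant). The
#' k_PL-precision slot is left NA; fill it for the (sub)grid of interest
#' with [fillKplSD()].
#'
#' @param params a [PKParams-class] object.
#' @param input an [InputFunction-class] object.
#' @param pyrFlips,lacFlips flip-angle axes in degrees; default 1-90 in
#'   1-degree steps.
#' @param temporalResolutions temporal-resolution axis (s).
#' @param template an EPI [AcquisitionProtocol-class] supplying timing and
#'   timepoint count; flips and temporal resolution are overridden per cell.
#' @return an [OptimizationGrid-class] object.
#' @examples
#' g <- snrGrid(pkParams(), inputFunction(), pyrFlips = c(5, 10, 20),
#'              lacFlips = c(20, 30), temporalResolutions = 3)
#' @export
snrGrid <- function(params, input, pyrFlips = 1:90, lacFlips = 1:90,
                    temporalResolutions = c(2, 3, 4, 5),
                    template = epiProtocol()) {
  stopifnot(is(params, "PKParams"), is(input, "InputFunction"),
            length(pyrFlips) > 0, length(lacFlips) > 0,
            length(temporalResolutions) > 0)
  nP <- length(pyrFlips); nL <- length(lacFlips)
  nT <- length(temporalResolutions)
  pyrSNR <- array(0, c(nP, nL, nT))
  lacSNR <- array(0, c(nP, nL, nT))
  kplSD <- array(NA_real_, c(nP, nL, nT))
  nTp <- template@nTimepoints
  R1P <- 1 / params@t1Pyr; R1L <- 1 / params@t1Lac
  for (it in seq_len(nT)) {
    tres <- temporalResolutions[it]
    times <- (seq_len(nTp) - 1) * tres
    U <- diff(.inputCDF(input, c(-tres, times)))
    for (ip in seq_len(nP)) for (il in seq_len(nL)) {
      sig <- .epiCore(pyrFlips[ip], lacFlips[il], tres, template@intraTR,
                      nTp, params@kpl, R1P, R1L, U)
      pyrSNR[ip, il, it] <- sum(sig$P)
      lacSNR[ip, il, it] <- sum(sig$L)
    }
  }
  new("OptimizationGrid", pyrFlips = as.numeric(pyrFlips),
      lacFlips = as.numeric(lacFlips),
      temporalResolutions = as.numeric(temporalResolutions),
      pyrSNR = pyrSNR, lacSNR = lacSNR, kplSD = kplSD)
}

#' Monte Carlo precision of the k_PL fit for one protocol
#'
#' Simulates the noiseless dynamic curves once, then adds independent
#' zero-mean Gaussian noise to the pyruvate and lactate magnitude
#' timecourses in each iteration, refits k_PL with [fitKpl()], and reports
#' the standard deviation of the estimates as the precision measure.
#' Deterministic given the seed. Bound-pinned fits are counted and excluded
#' from the sd; a warning is raised when more than 5% of iterations pin.
#'
#' @param protocol an EPI [AcquisitionProtocol-class].
#' @param params a [PKParams-class] object (truth).
#' @param input an [InputFunction-class] object.
#' @param mc a [MonteCarloConfig-class]; with `noiseSD = NA` the noise sd is
#'   set to (peak noiseless pyruvate signal) / 50, i.e. peak pyruvate SNR of
#'   about 50, a typical preclinical value.
#' @param t1LacFit,t1PyrFit fixed T1 values used by the fit.
#' @return a list with `sd`, `mean`, `estimates`, `nPinned` and `noiseSD`.
#' @examples
#' montecarloKplSD(epiProtocol(), pkParams(), inputFunction(),
#'                 monteCarloConfig(nIterations = 25, seed = 7))
#' @export
montecarloKplSD <- function(protocol, params, input,
                            mc = monteCarloConfig(), t1LacFit = params@t1Lac,
                            t1PyrFit = params@t1Pyr) {
  stopifnot(is(mc, "MonteCarloConfig"))
  if (mc@nIterations < 2) stop("need >= 2 iterations for a defined sd")
  tc <- simulateEPIDynamics(protocol, params, input)
  noiseSD <- if (is.na(mc@noiseSD)) max(tc@pyr) / 50 else mc@noiseSD
  flips <- protocol@flips[c("pyruvate", "lactate")]
  n <- length(tc@times)
  set.seed(mc@seed)
  est <- numeric(mc@nIterations)
  pinned <- logical(mc@nIterations)
  for (i in seq_len(mc@nIterations)) {
    p <- tc@pyr + stats::rnorm(n, sd = noiseSD)
    l <- tc@lac + stats::rnorm(n, sd = noiseSD)
    fit <- fitKpl(p, l, flips = flips, times = tc@times,
                  intraTR = protocol@intraTR, t1Lac = t1LacFit,
                  t1Pyr = t1PyrFit)
    est[i] <- fit@kplHat
    pinned[i] <- !fit@converged
  }
  if (mean(pinned) > 0.05)
    warning(sprintf("%.1f%% of Monte Carlo fits pinned at an optimizer bound",
                    100 * mean(pinned)))
  ok <- est[!pinned]
  list(sd = stats::sd(ok), mean = mean(ok), estimates = est,
       nPinned = sum(pinned), noiseSD = noiseSD)
}

#' Fill the k_PL-precision slot of an optimization grid
#'
#' Runs [montecarloKplSD()] for every cell of the grid (use coarse axes:
#' this is the expensive stage). The same seed is used per cell so cells
#' remain independent and the grid reproducible.
#'
#' @param grid an [OptimizationGrid-class] from [snrGrid()].
#' @param params,input,mc,template as in [snrGrid()] / [montecarloKplSD()].
#' @return the grid with `kplSD` filled.
#' @export
fillKplSD <- function(grid, params, input, mc = monteCarloConfig(),
                      template = epiProtocol()) {
  stopifnot(is(grid, "OptimizationGrid"))
  for (it in seq_along(grid@temporalResolutions))
    for (ip in seq_along(grid@pyrFlips))
      for (il in seq_along(grid@lacFlips)) {
        proto <- epiProtocol(
          flips = c(pyruvate = grid@pyrFlips[ip], lactate = grid@lacFlips[il]),
          temporalResolution = grid@temporalResolutions[it],
          nTimepoints = template@nTimepoints, intraTR = template@intraTR,
          matrixSize = template@matrixSize, fov = template@fov)
        grid@kplSD[ip, il, it] <-
          suppressWarnings(montecarloKplSD(proto, params, input, mc)$sd)
      }
  grid
}

#' Recommend a protocol from an optimization grid
#'
#' Returns the grid cell maximizing lactate SNR subject to (i) pyruvate SNR
#' at least `minPyrSNRFrac` of the grid-wide pyruvate-SNR maximum and (ii)
#' k_PL-fit sd at most `maxKplSD` (cells with unfilled sd fail this
#' constraint only when `maxKplSD` is finite).
#'
#' @param grid an [OptimizationGrid-class].
#' @param minPyrSNRFrac minimum pyruvate SNR as a fraction of the grid max.
#' @param maxKplSD maximum admissible Monte Carlo k_PL sd (1/s).
#' @return a one-row data.frame (`pyrFlip`, `lacFlip`,
#'   `temporalResolution`, `pyrSNR`, `lacSNR`, `kplSD`), or a zero-row
#'   data.frame when the constraints are infeasible.
#' @export
recommendProtocol <- function(grid, minPyrSNRFrac = 0, maxKplSD = Inf) {
  stopifnot(is(grid, "OptimizationGrid"))
  feas <- grid@pyrSNR >= minPyrSNRFrac * max(grid@pyrSNR)
  if (is.finite(maxKplSD))
    feas <- feas & !is.na(grid@kplSD) & grid@kplSD <= maxKplSD
  empty <- data.frame(pyrFlip = numeric(0), lacFlip = numeric(0),
                      temporalResolution = numeric(0), pyrSNR = numeric(0),
                      lacSNR = numeric(0), kplSD = numeric(0))
  if (!any(feas)) return(empty)
  lac <- grid@lacSNR
  lac[!feas] <- -Inf
  i <- which(lac == max(lac), arr.ind = TRUE)[1, ]
  data.frame(pyrFlip = grid@pyrFlips[i[1]], lacFlip = grid@lacFlips[i[2]],
             temporalResolution = grid@temporalResolutions[i[3]],
             pyrSNR = grid@pyrSNR[i[1], i[2], i[3]],
             lacSNR = grid@lacSNR[i[1], i[2], i[3]],
             kplSD = grid@kplSD[i[1], i[2], i[3]])
}

#' Long-format view of an optimization grid
#'
#' @param grid an [OptimizationGrid-class].
#' @return a data.frame with one row per grid cell and columns
#'   `pyr_flip_deg`, `lac_flip_deg`, `temporal_resolution_s`, `pyr_snr`,
#'   `lac_snr`, `kpl_sd_per_s`.
#' @export
gridToLong <- function(grid) {
  stopifnot(is(grid, "OptimizationGrid"))
  g <- expand.grid(pyr_flip_deg = grid@pyrFlips, lac_flip_deg = grid@lacFlips,
                   temporal_resolution_s = grid@temporalResolutions,
                   KEEP.OUT.ATTRS = FALSE)
  g$pyr_snr <- as.vector(grid@pyrSNR)
  g$lac_snr <- as.vector(grid@lacSNR)
  g$kpl_sd_per_s <- as.vector(grid@kplSD)
  g
}
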