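## Two-chemical-pool, one-physical-compartment magnetization model.
## State vectors are ordered (MPx, MPy, MPz, MLx, MLy, MLz).

PYR_IDX <- 1:3
LAC_IDX <- 4:6

.checkPool <- function(pool) {
  if (!pool %in% c("pyruvate", "lactate", "both"))
    stop("unknown pool '", pool, "': must be \"pyruvate\", \"lactate\" or \"both\"")
  pool
}

#' Construct a magnetization state vector
#'
#' @param pyrZ,lacZ longitudinal magnetizations.
#' @param pyrXY,lacXY transverse (x) magnetizations.
#' @return a named numeric 6-vector `(MPx, MPy, MPz, MLx, MLy, MLz)`.
#' @examples
#' magState(pyrZ = 1)
#' @export
magState <- function(pyrZ = 0, lacZ = 0, pyrXY = 0, lacXY = 0) {
  c(MPx = pyrXY, MPy = 0, MPz = pyrZ, MLx = lacXY, MLy = 0, MLz = lacZ)
}

#' Relaxation/exchange rate matrix
#'
#' The 6x6 rate matrix of unidirectional two-site exchange acting on the
#' longitudinal components: `dMPz/dt = -(kPL + R1P) MPz` and
#' `dMLz/dt = kPL MPz - R1L MLz`. Transverse rows are zero: transverse
#' magnetization is eliminated by spoiling every TR and T2* decay is
#' deliberately not modelled (short single-shot readout).
#'
#' @param params a [PKParams-class] object.
#' @return a 6x6 matrix `R` such that `dM/dt = R %*% M`.
#' @export
exchangeRateMatrix <- function(params) {
  stopifnot(is(params, "PKParams"))
  R <- matrix(0, 6, 6)
  R[3, 3] <- -(params@kpl + 1 / params@t1Pyr)
  R[6, 3] <- params@kpl
  R[6, 6] <- -1 / params@t1Lac
  R
}

#' Relaxation and exchange propagator over an interval
#'
#' Returns `expm(R * dt)` for the rate matrix of [exchangeRateMatrix()]:
#' the linear map taking the magnetization state across a free-evolution
#' interval of length `dt`.
#'
#' @param params a [PKParams-class] object.
#' @param dt interval length (s), non-negative.
#' @return a 6x6 propagation matrix.
#' @examples
#' P <- relaxationExchangePropagator(pkParams(), dt = 1)
#' P %*% magState(pyrZ = 1)
#' @export
relaxationExchangePropagator <- function(params, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt < 0)
    stop("'dt' must be a single finite non-negative duration in seconds")
  as.matrix(Matrix::expm(exchangeRateMatrix(params) * dt))
}

## Closed-form longitudinal propagation over dt:
##   MPz' = a * MPz ; MLz' = b * MLz + g * MPz
.longCoef <- function(kpl, R1P, R1L, dt) {
  a <- exp(-(kpl + R1P) * dt)
  b <- exp(-R1L * dt)
  d <- (kpl + R1P) - R1L
  g <- if (abs(d) < 1e-12) kpl * dt * b else kpl * (b - a) / d
  c(a = a, b = b, g = g)
}

.longCoefParams <- function(params, dt)
  .longCoef(params@kpl, 1 / params@t1Pyr, 1 / params@t1Lac, dt)

#' RF rotation matrix for a spectrally selective pulse
#'
#' Rotates the selected pool's magnetization by `flip` degrees about the x
#' axis (z into transverse); the unselected pool is untouched, emulating the
#' spectral selectivity of a spectral-spatial pulse. The rotation axis is a
#' fixed convention: after magnitude detection the transverse phase carries
#' no information.
#'
#' @param flip flip angle in degrees.
#' @param pool `"pyruvate"`, `"lactate"` or `"both"`.
#' @return a 6x6 rotation matrix.
#' @examples
#' rfRotation(90, "pyruvate") %*% magState(pyrZ = 1, lacZ = 1)
#' @export
rfRotation <- function(flip, pool = "both") {
  if (!is.numeric(flip) || length(flip) != 1 || !is.finite(flip))
    stop("'flip' must be a single finite angle in degrees")
  .checkPool(pool)
  a <- flip * pi / 180
  rot3 <- matrix(c(1, 0, 0,
                   0, cos(a), sin(a),
                   0, -sin(a), cos(a)), 3, 3, byrow = TRUE)
  M <- diag(6)
  if (pool %in% c("pyruvate", "both")) M[PYR_IDX, PYR_IDX] <- rot3
  if (pool %in% c("lactate", "both")) M[LAC_IDX, LAC_IDX] <- rot3
  M
}

#' Spoiler matrix
#'
#' Eliminates the transverse components (Mx, My) of the selected pool(s),
#' leaving longitudinal magnetization unchanged. Idempotent.
#'
#' @param pool `"pyruvate"`, `"lactate"` or `"both"`.
#' @return a 6x6 diagonal matrix.
#' @export
spoilMatrix <- function(pool = "both") {
  .checkPool(pool)
  d <- rep(1, 6)
  if (pool %in% c("pyruvate", "both")) d[1:2] <- 0
  if (pool %in% c("lactate", "both")) d[4:5] <- 0
  diag(d)
}

#' Propagate a magnetization state across one TR
#'
#' Applies, right to left, free evolution over the TR, spoiling, then the RF
#' rotation: `M_n = rot(flip) %*% spoil %*% expm(R * tr) %*% M_{n-1}`. The
#' transverse components of the returned state are the acquirable signal of
#' this excitation.
#'
#' @param state numeric 6-vector `(MPx, MPy, MPz, MLx, MLy, MLz)`.
#' @param flip flip angle in degrees.
#' @param params a [PKParams-class] object.
#' @param tr repetition time (s).
#' @param pool which pool the RF pulse excites.
#' @param spoilPool which pool the spoiler acts on (default both).
#' @return the state vector after the excitation.
#' @examples
#' propagateTR(magState(pyrZ = 1), flip = 10, pkParams(), tr = 0.0664,
#'             pool = "pyruvate")
#' @export
propagateTR <- function(state, flip, params, tr, pool = "both",
                        spoilPool = "both") {
  if (length(state) != 6 || !all(is.finite(state)))
    stop("'state' must be a finite 6-vector")
  out <- rfRotation(flip, pool) %*% spoilMatrix(spoilPool) %*%
    relaxationExchangePropagator(params, tr) %*% state
  stats::setNames(as.vector(out), names(magState()))
}

#' Transverse signal magnitudes of a state
#'
#' @param state numeric 6-vector.
#' @return named vector `c(pyr = |MPxy|, lac = |MLxy|)`.
#' @export
transverseMagnitude <- function(state) {
  c(pyr = sqrt(state[[1]]^2 + state[[2]]^2),
    lac = sqrt(state[[4]]^2 + state[[5]]^2))
}
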