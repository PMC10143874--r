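# Independent oracles used across the suite.

# Two-pool longitudinal ODE integrated with deSolve (independent of the
# package's matrix-exponential / closed-form paths).
odeTwoPool <- function(pyr0, lac0, kpl, t1p, t1l, tEnd) {
  rhs <- function(t, y, p) {
    list(c(-(p$k + 1 / p$t1p) * y[1],
           p$k * y[1] - y[2] / p$t1l))
  }
  out <- deSolve::ode(y = c(P = pyr0, L = lac0), times = c(0, tEnd),
                      func = rhs, parms = list(k = kpl, t1p = t1p, t1l = t1l),
                      method = "ode45", atol = 1e-12, rtol = 1e-12)
  out[nrow(out), c("P", "L")]
}

# Matrix-operator EPI dynamics: composes the exported 6x6 operators exactly
# as the per-timepoint update is defined. Oracle for simulateEPIDynamics.
matrixEpiDynamics <- function(protocol, params, input) {
  nT <- protocol@nTimepoints
  tres <- protocol@temporalResolution
  times <- (seq_len(nT) - 1) * tres
  U <- sampleInput(input, if (nT > 1) times else c(times, times + tres))[seq_len(nT)]
  rotP <- rfRotation(protocol@flips[["pyruvate"]], "pyruvate")
  rotL <- rfRotation(protocol@flips[["lactate"]], "lactate")
  sp <- spoilMatrix("both")
  E1 <- relaxationExchangePropagator(params, protocol@intraTR)
  E2 <- relaxationExchangePropagator(params, tres - protocol@intraTR)
  M <- magState()
  P <- L <- numeric(nT)
  for (n in seq_len(nT)) {
    M[3] <- M[3] + U[n]
    M <- as.vector(rotP %*% sp %*% M)
    P[n] <- sqrt(M[1]^2 + M[2]^2)
    M <- as.vector(rotL %*% sp %*% E1 %*% M)
    L[n] <- sqrt(M[4]^2 + M[5]^2)
    M <- as.vector(E2 %*% M)
  }
  list(times = times, P = P, L = L)
}

# Dense numeric evaluation of the periodic-sinc magnitude profile and its
# width metrics (linear interpolation on a very fine grid).
dirichletMetrics <- function(n, voxelMM, dx = 1e-4) {
  fov <- n * voxelMM
  x <- seq(0, fov / 2 - dx, by = dx)
  y <- dirichletKernel(x, n, voxelMM)
  crossOut <- function(th) {
    below <- which(y < th)
    # innermost crossing for fwhm (first drop), outermost for width10
    list(first = x[below[1] - 1] + dx * (y[below[1] - 1] - th) /
           (y[below[1] - 1] - y[below[1]]),
         last = {
           above <- which(y >= th)
           i <- max(above)
           x[i] + dx * (y[i] - th) / (y[i] - y[i + 1])
         })
  }
  c(fwhm = 2 * crossOut(0.5)$first, width10 = 2 * crossOut(0.1)$last)
}

defaultFlips <- c(pyruvate = 10, lactate = 30)
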