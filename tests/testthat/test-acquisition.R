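test_that("EPI dynamics agree with the explicit 6x6 operator composition", {
  proto <- epiProtocol(flips = c(pyruvate = 15, lactate = 40),
                       temporalResolution = 4, nTimepoints = 12)
  params <- pkParams(kpl = 0.07, t1Pyr = 18, t1Lac = 28)
  inp <- inputFunction(fwhm = 8)
  tc <- simulateEPIDynamics(proto, params, inp)
  ref <- matrixEpiDynamics(proto, params, inp)
  expect_equal(tc@pyr, ref$P, tolerance = 1e-10)
  expect_equal(tc@lac, ref$L, tolerance = 1e-10)
  expect_equal(tc@times, ref$times)
})

test_that("EPI dynamics basic physics", {
  inp <- inputFunction()
  # no conversion -> no lactate signal at any timepoint
  tc0 <- simulateEPIDynamics(epiProtocol(), pkParams(kpl = 0), inp)
  expect_identical(tc0@lac, rep(0, 18))
  # pyruvate signal never sees the lactate flip angle
  tcA <- simulateEPIDynamics(epiProtocol(flips = c(pyruvate = 10, lactate = 20)),
                             pkParams(), inp)
  tcB <- simulateEPIDynamics(epiProtocol(flips = c(pyruvate = 10, lactate = 80)),
                             pkParams(), inp)
  expect_equal(tcA@pyr, tcB@pyr, tolerance = 1e-12)
  # 18 timepoints every 3 s span ~a minute of acquisition
  expect_equal(max(tcA@times), 51)
  expect_length(tcA@times, 18)
})

test_that("EPI signal is exactly linear in input amplitude", {
  p <- pkParams()
  t1 <- simulateEPIDynamics(epiProtocol(), p, inputFunction(amplitude = 1))
  t2 <- simulateEPIDynamics(epiProtocol(), p, inputFunction(amplitude = 2))
  expect_equal(t2@pyr, 2 * t1@pyr, tolerance = 1e-10)
  expect_equal(t2@lac, 2 * t1@lac, tolerance = 1e-10)
})

test_that("urea is simulated as an independent pool when acquired", {
  proto <- epiProtocol(metabolites = c("urea", "pyruvate", "lactate"),
                       flips = c(urea = 10, pyruvate = 10, lactate = 30))
  tc <- simulateEPIDynamics(proto, pkParams(), inputFunction())
  expect_length(tc@urea, 18)
  expect_true(all(tc@urea >= 0))
  # urea presence does not perturb the exchange pair
  ref <- simulateEPIDynamics(epiProtocol(), pkParams(), inputFunction())
  expect_equal(tc@pyr, ref@pyr)
  expect_equal(tc@lac, ref@lac)
})

test_that("centric ordering starts at the centre and is a verified permutation", {
  for (ny in c(1, 2, 3, 5, 8, 9)) for (nx in c(1, 3, 4, 8, 9)) {
    enc <- orderPhaseEncodes(c(ny, nx), "centric")
    expect_equal(nrow(enc), ny * nx)
    # bijection over the grid
    expect_equal(sort(enc$row + (enc$col - 1) * ny), seq_len(ny * nx))
    # brute-force check: distances non-decreasing, angle breaks ties
    d <- sqrt(enc$ky^2 + enc$kx^2)
    expect_true(all(diff(d) > -1e-12))
    ang <- atan2(enc$ky, enc$kx) %% (2 * pi)
    ties <- which(abs(diff(d)) < 1e-12)
    expect_true(all(ang[ties + 1] > ang[ties]))
  }
  expect_equal(unlist(orderPhaseEncodes(c(8, 8), "centric")[1, c("ky", "kx")]),
               c(ky = 0, kx = 0))
  # 3x3: the 4 edge-adjacent neighbours precede the 4 corners
  enc3 <- orderPhaseEncodes(c(3, 3), "centric")
  expect_equal(sqrt(enc3$ky^2 + enc3$kx^2)[2:5], rep(1, 4))
  expect_equal(sqrt(enc3$ky^2 + enc3$kx^2)[6:9], rep(sqrt(2), 4))
  expect_error(orderPhaseEncodes(c(4, 4), "spiral"), "unknown ordering")
})

test_that("linear ordering is row-major", {
  enc <- orderPhaseEncodes(c(2, 3), "linear")
  expect_equal(enc$row, c(1, 1, 1, 2, 2, 2))
  expect_equal(enc$col, c(1, 2, 3, 1, 2, 3))
})

test_that("CSI weights follow the closed-form cosine product without decay", {
  # no relaxation, no exchange, no inflow: n-th acquired encode weight is
  # sin(a) * cos(a)^(n-1)
  proto <- csiProtocol()
  pInf <- pkParams(kpl = 0, t1Pyr = Inf, t1Lac = Inf)
  w <- simulateCSIFrameWeights(proto, pInf, inputFunction(amplitude = 0),
                               startState = magState(pyrZ = 1))
  enc <- orderPhaseEncodes(c(8, 8), "centric")
  a <- 10 * pi / 180
  got <- weightMatrix(w$pyruvate)[cbind(enc$row, enc$col)]
  expect_equal(got, sin(a) * cos(a)^(seq_len(64) - 1), tolerance = 1e-12)
  # longitudinal consumed across the 64 encodes: cos(10 deg)^64 ~ 0.375
  expect_equal(got[64] / got[1], cos(a)^63, tolerance = 1e-12)
  expect_true(all(weightMatrix(w$lactate) == 0))
})

test_that("CSI pyruvate weights decay monotonically along centric order without inflow", {
  w <- simulateCSIFrameWeights(csiProtocol(), pkParams(),
                               inputFunction(amplitude = 0),
                               startState = magState(pyrZ = 1, lacZ = 0.2))
  enc <- orderPhaseEncodes(c(8, 8), "centric")
  seqP <- weightMatrix(w$pyruvate)[cbind(enc$row, enc$col)]
  expect_true(all(diff(seqP) < 0))
})

test_that("CSI frame validation", {
  expect_error(simulateCSIFrameWeights(epiProtocol(), pkParams(),
                                       inputFunction()), "csi")
  bad <- csiProtocol()
  bad@csiTR <- -1
  expect_error(simulateCSIFrameWeights(bad, pkParams(), inputFunction()),
               "csiTR")
})

test_that("EPI frame weights are flat and parameter-independent", {
  w16 <- epiFrameWeights(epiProtocol(matrixSize = c(16, 16)))
  expect_equal(weightMatrix(w16), matrix(1, 16, 16))
  w8 <- epiFrameWeights(epiProtocol(matrixSize = c(8, 8),
                                    flips = c(pyruvate = 77, lactate = 3)))
  expect_equal(weightMatrix(w8), matrix(1, 8, 8))
})

test_that("flip=0 CSI weights vanish", {
  w <- simulateCSIFrameWeights(csiProtocol(flips = c(all = 0)), pkParams(),
                               inputFunction())
  expect_true(all(weightMatrix(w$pyruvate) == 0))
  expect_true(all(weightMatrix(w$lactate) == 0))
})
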