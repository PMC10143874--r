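test_that("noiseless closed-loop recovery is exact across conditions", {
  for (tres in c(2, 3, 5)) for (k in c(0.01, 0.05, 0.1)) {
    proto <- epiProtocol(temporalResolution = tres)
    tc <- simulateEPIDynamics(proto, pkParams(kpl = k), inputFunction())
    fit <- fitKpl(tc@pyr, tc@lac, defaultFlips, tc@times,
                  intraTR = proto@intraTR)
    expect_lt(abs(kplHat(fit) - k), 1e-3)
    expect_true(fit@converged || k < 1e-4)
  }
})

test_that("estimate is invariant to signal scale and to flip-angle choice", {
  tc <- simulateEPIDynamics(epiProtocol(), pkParams(), inputFunction())
  f1 <- fitKpl(tc@pyr, tc@lac, defaultFlips, tc@times)
  f2 <- fitKpl(100 * tc@pyr, 100 * tc@lac, defaultFlips, tc@times)
  expect_equal(kplHat(f1), kplHat(f2), tolerance = 1e-6)
  # different excitation schedules, same kinetics
  pA <- epiProtocol(flips = c(pyruvate = 15, lactate = 30))
  pB <- epiProtocol(flips = c(pyruvate = 20, lactate = 50))
  tA <- simulateEPIDynamics(pA, pkParams(), inputFunction())
  tB <- simulateEPIDynamics(pB, pkParams(), inputFunction())
  kA <- kplHat(fitKpl(tA@pyr, tA@lac, c(pyruvate = 15, lactate = 30), tA@times))
  kB <- kplHat(fitKpl(tB@pyr, tB@lac, c(pyruvate = 20, lactate = 50), tB@times))
  expect_lt(abs(kA - kB) / kA, 0.05)
})

test_that("degenerate inputs are handled as specified", {
  tc <- simulateEPIDynamics(epiProtocol(), pkParams(), inputFunction())
  # zero lactate pins the estimate at the lower bound without erroring
  f0 <- fitKpl(tc@pyr, rep(0, 18), defaultFlips, tc@times)
  expect_lt(kplHat(f0), 1e-3)
  expect_false(f0@converged)
  expect_error(fitKpl(rep(0, 18), tc@lac, defaultFlips, tc@times),
               "unidentifiable")
  expect_error(fitKpl(tc@pyr[1:2], tc@lac[1:2], defaultFlips, tc@times[1:2]),
               "3 timepoints")
})

test_that("estimate increases with true kpl and degrades gracefully with noise", {
  ks <- c(0.01, 0.03, 0.05, 0.08, 0.1)
  est <- vapply(ks, function(k) {
    tc <- simulateEPIDynamics(epiProtocol(), pkParams(kpl = k),
                              inputFunction())
    kplHat(fitKpl(tc@pyr, tc@lac, defaultFlips, tc@times))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  # bias and sd shrink with the noise level, for several true rates
  for (k in c(0.01, 0.05, 0.1)) {
    p <- pkParams(kpl = k)
    res <- lapply(c(2e-3, 5e-4), function(ns) {
      montecarloKplSD(epiProtocol(), p, inputFunction(),
                      monteCarloConfig(nIterations = 60, noiseSD = ns,
                                       seed = 42))
    })
    expect_lt(res[[2]]$sd, res[[1]]$sd)
    expect_lt(abs(res[[2]]$mean - k), abs(res[[1]]$mean - k) + 2e-3)
  }
})

test_that("noise normalization scales by the noise-region mean", {
  dat <- array(2, c(2, 3, 6, 6))
  mask <- matrix(FALSE, 6, 6); mask[1:2, ] <- TRUE
  ser <- new("DynamicImageSeries", data = dat,
             metabolites = c("pyruvate", "lactate"), times = c(0, 3, 6),
             flips = defaultFlips, noiseMask = mask, voxelMM = 4)
  nn <- noiseNormalize(ser)
  expect_equal(nn$noiseLevel, 2)
  expect_true(all(nn$series@data == 1))
  # idempotent up to the returned scalar
  nn2 <- noiseNormalize(nn$series)
  expect_equal(nn2$noiseLevel, 1)
  ser@noiseMask <- matrix(FALSE, 6, 6)
  expect_error(noiseNormalize(ser), "empty")
})

test_that("AUC maps sum over time and ignore time order", {
  dat <- array(stats::runif(2 * 4 * 3 * 3), c(2, 4, 3, 3))
  ser <- new("DynamicImageSeries", data = dat,
             metabolites = c("pyruvate", "lactate"),
             times = c(0, 3, 6, 9), flips = defaultFlips,
             noiseMask = matrix(FALSE, 3, 3), voxelMM = 4)
  a <- aucMap(ser)
  expect_equal(unname(a["pyruvate", 2, 3]), sum(dat[1, , 2, 3]))
  serPerm <- ser
  serPerm@data <- dat[, c(3, 1, 4, 2), , , drop = FALSE]
  expect_equal(aucMap(serPerm), a)
  ser1 <- ser
  ser1@data <- dat[, 1, , , drop = FALSE]; ser1@times <- 0
  expect_equal(aucMap(ser1)["lactate", , ], dat[2, 1, , ])
})

test_that("voxelwise maps match the ROI average on a homogeneous phantom", {
  # uniform tumor-only phantom, noiseless: every voxel equals the ROI fit
  n <- 16L
  tumor <- matrix(TRUE, n, n)
  ph <- phantomDef(c(n, n), 2, regions = list(
    vessel = matrix(FALSE, n, n), tumor = tumor,
    background = matrix(FALSE, n, n)),
    perfusion = c(vessel = 0, tumor = 1, background = 0),
    params = list(vessel = pkParams(), tumor = pkParams(kpl = 0.06),
                  background = pkParams(kpl = 0)),
    noiseSD = 0, seed = 1)
  proto <- epiProtocol(matrixSize = c(8, 8), fov = 32)
  ser <- forwardImage(ph, proto, inputFunction())
  roi <- matrix(TRUE, 8, 8)
  res <- fitKplMap(ser, roi)
  expect_equal(unname(res$map), matrix(res$roiFit@kplHat, 8, 8),
               tolerance = 1e-6)
  expect_lt(abs(res$roiFit@kplHat - 0.06) / 0.06, 0.01)
  expect_error(fitKplMap(ser, matrix(FALSE, 8, 8)), "empty")
})

test_that("two-region phantom recovers both rates within 10% at default noise", {
  n <- 32L
  xc <- (seq_len(n) - 0.5)
  X <- matrix(xc, n, n, byrow = TRUE); Y <- matrix(xc, n, n)
  slow <- (X - 9)^2 + (Y - 16)^2 <= 5.5^2
  fast <- (X - 23)^2 + (Y - 16)^2 <= 5.5^2
  ph <- phantomDef(c(n, n), 1, regions = list(
    vessel = slow, tumor = fast, background = !(slow | fast)),
    perfusion = c(vessel = 1, tumor = 1, background = 0),
    params = list(vessel = pkParams(kpl = 0.02), tumor = pkParams(kpl = 0.1),
                  background = pkParams(kpl = 0)),
    noiseSD = 0.002, seed = 11)
  proto <- epiProtocol(matrixSize = c(8, 8), fov = 32)
  ser <- forwardImage(ph, proto, inputFunction())
  for (cs in list(list(region = "vessel", k = 0.02),
                  list(region = "tumor", k = 0.1))) {
    roi <- coarseRegionMask(ph, proto, cs$region)
    est <- suppressWarnings(fitKplMap(ser, roi))
    expect_lt(abs(mean(est$map[roi], na.rm = TRUE) - cs$k) / cs$k, 0.1)
  }
})
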