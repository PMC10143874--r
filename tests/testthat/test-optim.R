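test_that("relative SNR is the per-metabolite magnitude sum", {
  tc0 <- simulateEPIDynamics(epiProtocol(), pkParams(kpl = 0),
                             inputFunction())
  expect_equal(unname(relativeSNR(tc0)[["lac"]]), 0)
  t1 <- simulateEPIDynamics(epiProtocol(), pkParams(), inputFunction())
  t2 <- simulateEPIDynamics(epiProtocol(), pkParams(),
                            inputFunction(amplitude = 2))
  expect_equal(relativeSNR(t2), 2 * relativeSNR(t1), tolerance = 1e-10)
  # lactate collects more signal at 3 s spacing than at 5 s
  s3 <- relativeSNR(simulateEPIDynamics(epiProtocol(temporalResolution = 3),
                                        pkParams(), inputFunction()))
  s5 <- relativeSNR(simulateEPIDynamics(epiProtocol(temporalResolution = 5),
                                        pkParams(), inputFunction()))
  expect_gt(s3[["lac"]], s5[["lac"]])
})

test_that("SNR grid cells are independent simulations with expected structure", {
  g <- snrGrid(pkParams(), inputFunction(), pyrFlips = c(5, 10, 20, 40),
               lacFlips = c(10, 30, 60), temporalResolutions = c(3, 5))
  # pyruvate SNR is flat along the lactate-flip axis
  for (it in 1:2)
    expect_true(all(apply(g@pyrSNR[, , it], 1,
                          function(r) diff(range(r))) < 1e-12))
  # lactate SNR strictly decreases with pyruvate flip (RF consumes substrate)
  expect_true(all(apply(g@lacSNR[, , 1], 2, diff) < 0))
  # cells match standalone simulations (order independence)
  tc <- simulateEPIDynamics(epiProtocol(flips = c(pyruvate = 20, lactate = 60),
                                        temporalResolution = 5),
                            pkParams(), inputFunction())
  expect_equal(g@lacSNR[3, 3, 2], unname(relativeSNR(tc)[["lac"]]),
               tolerance = 1e-12)
  # long view round-trips the cells
  long <- gridToLong(g)
  expect_equal(nrow(long), 4 * 3 * 2)
  expect_equal(long$lac_snr[long$pyr_flip_deg == 20 & long$lac_flip_deg == 60 &
                              long$temporal_resolution_s == 5],
               g@lacSNR[3, 3, 2])
})

test_that("Monte Carlo kpl precision is seeded, unbiased and noise-scaled", {
  proto <- epiProtocol()
  mc0 <- montecarloKplSD(proto, pkParams(), inputFunction(),
                         monteCarloConfig(nIterations = 5, noiseSD = 0,
                                          seed = 3))
  expect_equal(mc0$sd, 0, tolerance = 1e-7)
  expect_equal(mc0$mean, 0.05, tolerance = 1e-4)
  a <- montecarloKplSD(proto, pkParams(), inputFunction(),
                       monteCarloConfig(nIterations = 40, seed = 9))
  b <- montecarloKplSD(proto, pkParams(), inputFunction(),
                       monteCarloConfig(nIterations = 40, seed = 9))
  expect_identical(a$estimates, b$estimates)  # bit-identical given the seed
  # default noise targets peak pyruvate SNR of about 50
  tc <- simulateEPIDynamics(proto, pkParams(), inputFunction())
  expect_equal(a$noiseSD, max(tc@pyr) / 50)
  # sd roughly halves when the noise halves (small-noise linearity)
  s1 <- montecarloKplSD(proto, pkParams(), inputFunction(),
                        monteCarloConfig(nIterations = 150,
                                         noiseSD = 1e-3, seed = 5))
  s2 <- montecarloKplSD(proto, pkParams(), inputFunction(),
                        monteCarloConfig(nIterations = 150,
                                         noiseSD = 5e-4, seed = 5))
  expect_gt(s1$sd / s2$sd, 1.6)
  expect_lt(s1$sd / s2$sd, 2.4)
})

test_that("Monte Carlo estimates are unbiased at moderate noise", {
  mc <- montecarloKplSD(epiProtocol(), pkParams(), inputFunction(),
                        monteCarloConfig(nIterations = 2000, seed = 17))
  expect_lt(abs(mc$mean - 0.05), 2 * mc$sd / sqrt(2000 - mc$nPinned))
})

test_that("protocol recommendation honours its constraints", {
  g <- snrGrid(pkParams(), inputFunction(), pyrFlips = seq(5, 45, by = 5),
               lacFlips = seq(10, 60, by = 10),
               temporalResolutions = c(2, 3, 4, 5))
  best <- recommendProtocol(g)
  # unconstrained: the pure lactate-SNR argmax, at 3 s temporal resolution
  i <- which(g@lacSNR == max(g@lacSNR), arr.ind = TRUE)[1, ]
  expect_equal(best$lacFlip, g@lacFlips[i[2]])
  expect_equal(best$temporalResolution, 3)
  # pyruvate-SNR constraint moves the optimum to a larger pyruvate flip
  con <- recommendProtocol(g, minPyrSNRFrac = 0.8)
  expect_gt(con$pyrFlip, best$pyrFlip)
  expect_true(con$pyrSNR >= 0.8 * max(g@pyrSNR))
  # infeasible constraints yield an explicit empty result
  expect_equal(nrow(recommendProtocol(g, minPyrSNRFrac = 0.8, maxKplSD = 0)),
               0)
})

test_that("kpl-sd grid filling populates every cell reproducibly", {
  g <- snrGrid(pkParams(), inputFunction(), pyrFlips = c(10, 20),
               lacFlips = c(30), temporalResolutions = 3)
  g <- fillKplSD(g, pkParams(), inputFunction(),
                 monteCarloConfig(nIterations = 25, seed = 2))
  expect_true(all(is.finite(g@kplSD)))
  expect_true(all(g@kplSD > 0))
  g2 <- fillKplSD(snrGrid(pkParams(), inputFunction(), c(10, 20), 30, 3),
                  pkParams(), inputFunction(),
                  monteCarloConfig(nIterations = 25, seed = 2))
  expect_identical(g@kplSD, g2@kplSD)
})
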