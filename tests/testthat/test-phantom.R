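epi8 <- function(...) epiProtocol(matrixSize = c(8, 8), fov = 32, ...)

test_that("default phantom is well-formed and reproducible", {
  ph <- makeDefaultPhantom()
  masks <- regionMasks(ph)
  expect_setequal(names(masks), c("vessel", "tumor", "background"))
  expect_true(all(vapply(masks[c("vessel", "tumor")], sum, 0L) > 0))
  overlap <- masks$vessel & masks$tumor
  expect_false(any(overlap))
  expect_equal(kpl(ph@params$tumor), 0.05)  # the standard simulation value
  expect_gt(ph@perfusion[["vessel"]], ph@perfusion[["tumor"]])
  expect_lt(kpl(ph@params$vessel), kpl(ph@params$tumor))
  # identical seeds give bit-identical series
  s1 <- forwardImage(ph, epi8(), inputFunction(), seed = 4)
  s2 <- forwardImage(ph, epi8(), inputFunction(), seed = 4)
  expect_identical(seriesData(s1), seriesData(s2))
  s3 <- forwardImage(ph, epi8(), inputFunction(), seed = 5)
  expect_false(identical(seriesData(s1), seriesData(s3)))
})

test_that("geometry validation rejects mismatched protocols", {
  ph <- makeDefaultPhantom()
  expect_error(forwardImage(ph, epiProtocol(matrixSize = c(8, 8), fov = 64),
                            inputFunction()), "FOV")
  expect_error(forwardImage(ph, epiProtocol(matrixSize = c(64, 64), fov = 32),
                            inputFunction()), "matrix exceeds")
  expect_error(phantomDef(c(8, 8), 4,
                          regions = list(tumor = matrix(TRUE, 8, 8)),
                          perfusion = c(tumor = 1),
                          params = list(tumor = pkParams())),
               "vessel")
})

test_that("no conversion anywhere leaves lactate frames at the noise floor", {
  ph <- makeDefaultPhantom()
  for (r in names(ph@params)) ph@params[[r]]@kpl <- 0
  ser <- forwardImage(ph, epi8(), inputFunction(), seed = 2)
  lac <- seriesData(ser)[2, , , ]
  pyr <- seriesData(ser)[1, , , ]
  # lactate is pure Rician noise: its mean matches the noise-only level
  expect_lt(mean(lac), 4 * ph@noiseSD)
  expect_gt(max(pyr), 50 * ph@noiseSD)
})

test_that("noiseless EPI frames of a uniform object are uniform inside it", {
  n <- 32L
  ph <- phantomDef(c(n, n), 1, regions = list(
    vessel = matrix(FALSE, n, n), tumor = matrix(TRUE, n, n),
    background = matrix(FALSE, n, n)),
    perfusion = c(vessel = 0, tumor = 1, background = 0),
    params = list(vessel = pkParams(), tumor = pkParams(),
                  background = pkParams(kpl = 0)),
    noiseSD = 0, seed = 1)
  ser <- forwardImage(ph, epi8(), inputFunction())
  fr <- seriesData(ser)[1, 5, , ]
  expect_lt(diff(range(fr)) / mean(fr), 1e-9)
})

test_that("CSI bleeds lactate beyond the vessel while EPI does not", {
  # vessel-only lactate source (tumor conversion off), during the bolus
  # rise: signal growth across the centric encode train weights outer
  # k-space up and throws signal well beyond the vessel
  ph <- makeDefaultPhantom(noiseSD = 0, tumorKpl = 0)
  sE <- forwardImage(ph, epi8(), inputFunction())
  sC <- forwardImage(ph, csiProtocol(), inputFunction())
  vessel <- coarseRegionMask(ph, epi8(), "vessel", frac = 0.25)
  row <- which(rowSums(vessel) > 0)[2]
  colV <- which(vessel[row, ])[1]
  frE <- seriesData(sE)[2, 2, row, ]
  frC <- seriesData(sC)[2, 2, row, ]
  for (offset in c(-1, 2)) {  # one voxel out on each side (col 3 is edge)
    relE <- frE[colV + offset] / max(frE)
    relC <- frC[colV + offset] / max(frC)
    expect_gt(relC, 1.5 * relE)
    expect_lt(relE, 0.3)
    expect_gt(relC, 0.3)
  }
})

test_that("lactate line profile shows two peaks under EPI and one under CSI", {
  ph <- makeDefaultPhantom()
  for (s in 1:3) {
    pe <- bleedProfile(forwardImage(ph, epi8(), inputFunction(), seed = s), ph)
    pc <- bleedProfile(forwardImage(ph, csiProtocol(), inputFunction(),
                                    seed = s), ph)
    expect_equal(pe@peakCount, 2L)
    expect_equal(pc@peakCount, 1L)
  }
  # constant profiles carry no peaks
  expect_equal(hpMRsim:::.countPeaks(rep(1, 8), 0.1), 0L)
  expect_error(bleedProfile(forwardImage(ph, epi8(), inputFunction()), ph,
                            row = 1), "does not intersect")
})

test_that("coarser voxels collect proportionally more signal", {
  ph <- makeDefaultPhantom(noiseSD = 0)
  inp <- inputFunction()
  s4 <- forwardImage(ph, epi8(), inp)
  s2 <- forwardImage(ph, epiProtocol(matrixSize = c(16, 16), fov = 32), inp)
  tum4 <- coarseRegionMask(ph, epi8(), "tumor")
  tum2 <- coarseRegionMask(ph, epiProtocol(matrixSize = c(16, 16), fov = 32),
                           "tumor")
  auc4 <- mean(aucMap(s4)["pyruvate", , ][tum4])
  auc2 <- mean(aucMap(s2)["pyruvate", , ][tum2])
  expect_gt(auc4 / auc2, 2)
})

test_that("noiseless EPI imaging preserves the tumor rate within 5%", {
  ph <- makeDefaultPhantom(noiseSD = 0)
  ser <- forwardImage(ph, epi8(), inputFunction())
  tum <- coarseRegionMask(ph, epi8(), "tumor")
  res <- suppressWarnings(fitKplMap(ser, tum))
  expect_lt(abs(res$roiFit@kplHat - 0.05) / 0.05, 0.05)
})
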