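test_that("CV measurement recovers a constructed plane wave", {
  ## plane wave at exactly 100 cm/s: V(x, t) steps from -80 to +20 as the
  ## front x = v t passes
  m <- buildSlab(40, 4, 1, 300)
  nodes <- meshNodes(m)
  tt <- seq(0, 14, by = 0.2)
  v <- 0.1  # cm/ms = 100 cm/s
  vm <- sapply(tt, function(t) -80 + 100 / (1 + exp(-(v * t - nodes[, 1]) / 0.02)))
  s <- vmSeries(vm, tt, m)
  cv <- measureCV(s, c(0.36, 0.06, 0.015), c(0.84, 0.06, 0.015))
  expect_lt(abs(cv - 100) / 100, 0.01)
  ## probe outside the mesh
  expect_error(measureCV(s, c(-5, 0, 0), c(0.84, 0.06, 0.015)),
               "outside the mesh")
  ## wave direction: reversed probes
  expect_error(measureCV(s, c(0.84, 0.06, 0.015), c(0.36, 0.06, 0.015)),
               "LAT")
  ## never-activating probe: clamp Vm below threshold near the far end
  vm2 <- vm
  vm2[nodes[, 1] > 0.7, ] <- -80
  s2 <- vmSeries(vm2, tt, m)
  expect_error(measureCV(s2, c(0.36, 0.06, 0.015), c(0.84, 0.06, 0.015)),
               "never activates")
})

test_that("target validation rejects unphysiological requests", {
  cm <- makeRegionalCell("RA/PM")
  expect_error(tuneSigmaLongitudinal(0, 0.35, cm), "positive")
  expect_error(tuneSigmaLongitudinal(-5, 0.35, cm), "positive")
  expect_error(tuneSigmaLongitudinal(300, 0.35, cm), "bracket")
})

test_that("re-tuning from its own output converges immediately", {
  fit <- tunedSigma("atrial")
  expect_lte(fit$iterations, 2L)
  expect_lt(abs(fit$achievedCv - 63.3) / 63.3, 0.01)
})

test_that("the shipped conductivity table matches its calibration targets", {
  tab <- conductivityTable()
  expect_setequal(tab$class, c("atrial", "isthmus", "pv", "bundle", "cs"))
  expect_true(all(abs(tab$achievedCv - tab$targetCv) / tab$targetCv < 0.01))
  expect_equal(tab$sigmaT, tab$sigmaL * tab$ratio, tolerance = 1e-9)
  ## monotone: faster tissue classes have larger sigmaL
  o <- order(tab$targetCv)
  expect_true(all(diff(tab$sigmaL[o]) > 0))
})

test_that("region labels resolve to conductivities and cell models", {
  map <- defaultRegionCellMap()
  expect_true(all(regionVocabulary(extended = TRUE) %in% map$region))
  expect_true(all(map$cellRegion %in% regionalScalingTable()$region))
  expect_true(all(map$class %in% conductivityTable()$class))
  expect_error(regionConductivity("NOPE", matrix(c(1, 0, 0), 1)),
               "without class")
})
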