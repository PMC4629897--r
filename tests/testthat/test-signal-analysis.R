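test_that("LAT maps recover a constructed plane wave exactly", {
  ## plane wave at 100 cm/s: LAT increases by 1 ms per mm along x
  m <- buildSlab(30, 4, 1, 300)
  nodes <- meshNodes(m)
  tt <- seq(0, 12, by = 0.25)
  vm <- sapply(tt, function(t)
    -80 + 100 / (1 + exp(-(0.1 * t - nodes[, 1]) / 0.01)))
  s <- vmSeries(vm, tt, m)
  lat <- computeLATMap(s, threshold = -40)
  ok <- !is.na(lat)
  fit <- coef(lm(lat[ok] ~ nodes[ok, 1]))
  expect_equal(unname(fit[2]), 10, tolerance = 0.02)  # 10 ms/cm = 1 ms/mm
  ## a resting series yields no activations
  s0 <- vmSeries(matrix(-80, nNodes(m), 4), 0:3, m)
  expect_true(all(is.na(computeLATMap(s0))))
})

test_that("B-RMS maps satisfy closed forms and homogeneity", {
  tt <- seq(0, 1999)
  z <- matrix(0, length(tt), 2)
  expect_equal(unname(computeBRMSMap(z)), c(0, 0))
  ## sinusoid of amplitude A over integer periods: RMS = A / sqrt(2)
  A <- 0.35
  y <- cbind(A * sin(2 * pi * tt / 100), 2 * A * sin(2 * pi * tt / 200))
  r <- unname(computeBRMSMap(y))
  expect_equal(r, c(A / sqrt(2), 2 * A / sqrt(2)), tolerance = 1e-9)
  expect_equal(unname(computeBRMSMap(-3 * y)), 3 * r, tolerance = 1e-12)
  expect_error(computeBRMSMap(y, window = integer(0)), "empty")
})

test_that("P-wave morphology classes are recovered from constructions", {
  tt <- 0:199
  gauss <- function(mu, sd, a) a * exp(-(tt - mu)^2 / (2 * sd^2))
  ## single positive lobe
  f <- extractPWaveFeatures(gauss(100, 15, 0.2), tt)
  expect_equal(f$morphology, "monophasic+")
  expect_equal(f$amplitude, 0.2, tolerance = 1e-6)
  expect_gt(f$duration, 0)
  ## negative lobe
  expect_equal(extractPWaveFeatures(-gauss(100, 15, 0.2), tt)$morphology,
               "monophasic-")
  ## positive then equal negative lobe
  bi <- gauss(70, 12, 0.2) - gauss(130, 12, 0.2)
  expect_equal(extractPWaveFeatures(bi, tt)$morphology, "biphasic")
  ## two equal positive peaks with a 50 % notch
  mm <- pmax(gauss(70, 14, 0.2), gauss(130, 14, 0.2))
  expect_equal(extractPWaveFeatures(mm, tt)$morphology, "M-shaped")
  ## flat trace is indeterminate with zero amplitude, not an error
  fz <- extractPWaveFeatures(rep(0, 200), tt)
  expect_equal(fz$morphology, "indeterminate")
  expect_equal(fz$amplitude, 0)
})

test_that("region contributions sum exactly to the whole-tissue signal", {
  ## two half-slabs
  m <- buildSlab(10, 4, 1, 900)
  ctr <- elementCenters(m)
  labels <- ifelse(ctr[, 1] < 0.45, "L", "R")
  set.seed(9)
  s <- vmSeries(matrix(rnorm(nNodes(m) * 5, -60, 25), ncol = 5), 0:4, m)
  pts <- observationPoints(c("A", "B"), x = c(3, -2), y = c(2, 3),
                           z = c(4, -4))
  dec <- decomposeRegionContributions(s, labels, pts)
  tot <- traceMatrix(dec$total)
  recon <- traceMatrix(dec$regional$L) + traceMatrix(dec$regional$R)
  expect_lt(max(abs(recon - tot)) / max(abs(tot)), 1e-12)
  expect_equal(sum(dec$shares), 100, tolerance = 1e-6)
  ## single-region decomposition equals the total exactly
  dec1 <- decomposeRegionContributions(s, rep("L", nElements(m)), pts)
  expect_equal(traceMatrix(dec1$regional$L), tot)
  expect_equal(unname(dec1$shares), 100)
  ## B-RMS consistency between the total and the summed regional traces
  expect_equal(computeBRMSMap(tot), computeBRMSMap(recon),
               tolerance = 1e-12)
})

test_that("APD maps are smooth within one region and ordered across two", {
  cm <- makeRegionalCell("RA/PM")
  st <- stabilizedState(cm)
  ## homogeneous strip: away from the paced and sealed ends (which carry
  ## the usual cable-end APD prolongation/shortening) only coupling
  ## smoothing remains and the dispersion is below 3 ms
  m <- buildSlab(40, 4, 1, 900)
  ne <- nElements(m)
  fib <- matrix(rep(c(1, 0, 0), each = ne), ncol = 3)
  cond <- conductivityField(2.6, 0.9, fib)
  stim <- stimulusSet(which(meshNodes(m)[, 1] < 3.5 * 0.09), 0, 2, 52)
  run <- runMonodomain(m, rep("RA/PM", ne), cond, list("RA/PM" = cm), stim,
                       duration = 470, outputDt = 1,
                       initStates = list("RA/PM" = st))
  am <- computeAPDMap(run)
  x <- meshNodes(m)[, 1]
  L <- 40 * 0.09
  interior <- x > 0.2 * L & x < 0.8 * L
  expect_lt(sd(am$apd[interior]), 3)
  expect_equal(sum(am$regional$n), sum(!is.na(am$apd)))
  ## two-region strip: PV half repolarizes before the CT/BB half
  labels2 <- ifelse(elementCenters(m)[, 1] < 0.72, "PV", "CT/BB")
  cells2 <- list(PV = makeRegionalCell("PV"), `CT/BB` = makeRegionalCell("CT/BB"))
  init2 <- list(PV = stabilizedState(cells2$PV),
                `CT/BB` = stabilizedState(cells2$`CT/BB`))
  run2 <- runMonodomain(m, labels2, cond, cells2, stim, duration = 420,
                        outputDt = 1, initStates = init2)
  am2 <- computeAPDMap(run2)
  reg <- am2$regional
  expect_lt(reg$mean[reg$region == "PV"], reg$mean[reg$region == "CT/BB"])
})
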