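test_that("regional parameter sets follow the conductance table", {
  tab <- regionalScalingTable()
  expect_setequal(tab$region,
                  c("RA/PM", "CT/BB", "RAA", "TV", "LA", "PV", "LAA", "MV"))
  ctbb <- makeRegionalCell("CT/BB")
  expect_equal(unname(conductanceScalings(ctbb)), c(0.50, 1.00, 0.50))
  rapm <- makeRegionalCell("RA/PM")
  expect_equal(unname(conductanceScalings(rapm)), c(1, 1, 1))
  ## baseline identity: RA/PM is the unscaled published model
  expect_identical(rapm@constants, maleckarConstants())
  expect_error(makeRegionalCell("VENTRICLE"), "RA/PM.*CT/BB.*RAA.*TV.*LA")
  expect_error(makeRegionalCell("VENTRICLE"), "valid labels")
})

test_that("an unstimulated cell stays at rest", {
  pr <- pacingProtocol(nBeats = 2L, bcl = 500, stimAmplitude = 0)
  tr <- paceSingleCell(makeRegionalCell("RA/PM"), pr, recordBeats = 2L)
  v0 <- maleckarInitialState()["V"]
  expect_lt(max(abs(tr@Vm - v0)), 1)
})

test_that("baseline one-beat integration is reproducible bitwise", {
  pr <- pacingProtocol(nBeats = 1L)
  m1 <- makeRegionalCell("RA/PM")
  m2 <- new("AtrialCellModel", region = "custom",
            scalings = c(gto = 1, gCaL = 1, gKr = 1),
            constants = maleckarConstants(),
            initState = maleckarInitialState())
  t1 <- paceSingleCell(m1, pr)
  t2 <- paceSingleCell(m2, pr)
  expect_identical(t1@Vm, t2@Vm)
  expect_identical(finalState(t1), finalState(t2))
})

test_that("halving dt changes the APD90 by less than 0.5 ms", {
  m <- makeRegionalCell("RA/PM")
  a <- vapply(c(0.02, 0.01), function(dt) {
    pr <- pacingProtocol(nBeats = 20L, dt = dt)
    tail(paceSingleCell(m, pr)@apdPerBeat, 1)
  }, numeric(1))
  expect_lt(abs(a[1] - a[2]), 0.5)
})

test_that("APD measurement matches a linear synthetic beat", {
  ## instantaneous upstroke -80 -> +20 at t = 0, linear repolarization back
  ## to -80 at t = 300 ms; APD90 of this construction is 270 ms
  tt <- c(seq(-10, -0.02, by = 0.5), seq(0, 300, by = 0.5))
  vv <- c(rep(-80, sum(tt < 0)), 20 - 100 * seq(0, 300, by = 0.5) / 300)
  tr <- apTrace(tt, vv)
  expect_equal(measureAPD(tr, 0.9), 270, tolerance = 1e-3)
  ## flat trace: no beat
  expect_error(measureAPD(apTrace(0:100, rep(-80, 101))), "no beat detected")
})

test_that("raising gKr alone never lengthens the APD", {
  pr <- pacingProtocol(nBeats = 40L)
  apds <- vapply(c(0.5, 1, 2, 3.2), function(s) {
    m <- new("AtrialCellModel", region = "custom",
             scalings = c(gto = 1, gCaL = 1, gKr = s),
             constants = maleckarConstants(),
             initState = maleckarInitialState())
    tail(paceSingleCell(m, pr)@apdPerBeat, 1)
  }, numeric(1))
  expect_true(all(diff(apds) < 0))
})

test_that("steady-state check recovers constructed concentration drifts", {
  ## perfectly periodic pre-stimulus concentrations: 0 %
  ps <- matrix(rep(c(8.5, 129.4, 6.5e-5), each = 80), ncol = 3)
  tr <- apTrace(0:10, c(rep(-80, 5), 20, 0, -20, -40, -60, -80), prestim = ps)
  expect_equal(as.numeric(checkSteadyState(tr, 60L)), 0)
  ## linear 1 % drift on one species across the window
  ps2 <- ps
  ps2[, 1] <- ps2[, 1] * (1 + 0.01 * (seq_len(80) - 21) / 59)
  tr2 <- apTrace(0:10, c(rep(-80, 5), 20, 0, -20, -40, -60, -80),
                 prestim = ps2)
  out <- checkSteadyState(tr2, 60L)
  expect_equal(as.numeric(out), 1, tolerance = 1e-9)
  expect_equal(unname(attr(out, "perSpecies")[2:3]), c(0, 0))
  ## window longer than the run errors
  expect_error(checkSteadyState(tr, 500L), "fewer beats")
})

test_that("regional APD90 hierarchy matches the conductance design", {
  ## CT/BB > RA/PM > LA > PV and TV > MV after convergence-stopped pacing
  a <- vapply(c("CT/BB", "RA/PM", "LA", "PV", "TV", "MV"), finalAPD,
              numeric(1))
  expect_true(a["CT/BB"] > a["RA/PM"])
  expect_true(a["RA/PM"] > a["LA"])
  expect_true(a["LA"] > a["PV"])
  expect_true(a["TV"] > a["MV"])
})

test_that("convergence-stopped pacing meets its own drift criterion", {
  tr <- pacedTrace("RA/PM")
  expect_true(tr@converged)
  expect_lt(tr@beatsRun, 3600L)
  a <- tr@apdPerBeat
  n <- length(a)
  expect_lt(abs(a[n] - a[n - 20L]), 0.2)
})
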