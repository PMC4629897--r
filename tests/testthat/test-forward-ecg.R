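test_that("uniform sources produce no extracellular signal", {
  m <- buildSlab(6, 6, 2, 900)
  s <- vmSeries(matrix(-80, nNodes(m), 4), 0:3, m)
  pts <- observationPoints(c("A", "B"), x = c(4, -3), y = c(4, 5),
                           z = c(6, -5))
  tr <- computePseudoEcg(s, pts)
  expect_lt(max(abs(traceMatrix(tr))), 1e-12)
})

test_that("the pseudo-ECG is linear in gamma and in the sources", {
  set.seed(7)
  m <- buildSlab(5, 5, 2, 900)
  s <- vmSeries(matrix(rnorm(nNodes(m) * 3, -60, 20), ncol = 3), 0:2, m)
  pts <- observationPoints("A", 4, 4, 6)
  t1 <- traceMatrix(computePseudoEcg(s, pts, gamma = 1))
  t2 <- traceMatrix(computePseudoEcg(s, pts, gamma = 2))
  expect_equal(t2, 2 * t1)
  ## observation point inside the mesh is a singular kernel
  expect_error(computePseudoEcg(s, observationPoints("X", 0.2, 0.2, 0.05)),
               "singular")
})

test_that("a boundary dipole shows inverse-square far-field decay", {
  ## depolarized ball centred on a mesh face: the clipped half-ball carries
  ## a net dipole moment p = dV * pi R^2, so V(r) = p / (4 pi r^2) on axis
  m <- buildSlab(20, 20, 20, 500)
  nodes <- meshNodes(m)
  bb <- apply(nodes, 2, range)
  c0 <- c(bb[2, 1], mean(bb[, 2]), mean(bb[, 3]))
  R0 <- 0.15
  vm <- matrix(-80, nNodes(m), 1)
  vm[sqrt(rowSums(sweep(nodes, 2, c0)^2)) < R0, 1] <- 20
  s <- vmSeries(vm, 0, m)
  vAt <- function(r) traceMatrix(computePseudoEcg(
    s, observationPoints("P", c0[1] + r, c0[2], c0[3])))[1, 1]
  v4 <- vAt(4); v8 <- vAt(8)
  expect_lt(abs(v4 / v8 - 4) / 4, 0.1)
  expect_lt(abs(abs(v4) - 100 * pi * R0^2 / (4 * pi * 16)) /
              (100 * pi * R0^2 / (4 * pi * 16)), 0.1)
})

test_that("the source integral converges under mesh refinement", {
  ## smooth interior-to-boundary ramp along x: its clipped gradient integral
  ## is resolution independent up to trilinear interpolation error
  field <- function(m) {
    nodes <- meshNodes(m)
    bb <- apply(nodes, 2, range)
    u <- (nodes[, 1] - bb[1, 1]) / diff(bb[, 1])
    w <- exp(-((nodes[, 2] - mean(bb[, 2]))^2 +
                 (nodes[, 3] - mean(bb[, 3]))^2) / 0.08)
    vmSeries(matrix(-80 + 100 * pmin(1, pmax(0, (u - 0.3) / 0.4)) * w,
                    ncol = 1), 0, m)
  }
  pts <- observationPoints("P", 4, 0.5, 0.5)
  vCoarse <- traceMatrix(computePseudoEcg(field(buildSlab(10, 10, 10, 1000)),
                                          pts))[1, 1]
  vFine <- traceMatrix(computePseudoEcg(field(buildSlab(20, 20, 20, 500)),
                                        pts))[1, 1]
  expect_lt(abs(vCoarse - vFine) / abs(vFine), 0.02)
})

test_that("the torso builder labels every element with a known organ", {
  tor <- buildSimplifiedTorso()
  expect_true(all(tor$torso@organ %in% names(tor$conductivities)))
  expect_setequal(unique(tor$torso@organ),
                  c("blood", "myocardium", "lung", "liver", "bone", "chest"))
  ## homogeneous configuration collapses to a single chest compartment
  th <- buildSimplifiedTorso(lungs = FALSE, liver = FALSE, bone = FALSE,
                             ventricle = FALSE, heart = FALSE)
  expect_equal(unique(th$torso@organ), "chest")
  expect_equal(unname(th$conductivities["chest"]), 2.390)
  ## overlapping organ definitions are rejected
  expect_error(buildSimplifiedTorso(lung_centers = list(c(-3, 0, 2),
                                                        c(3, 0, 2))),
               "overlap")
})

test_that("the inner source layer sits at the nominal offset", {
  tor <- buildSimplifiedTorso()
  g <- tor$torso@grid
  d <- AtriaSim:::.ellipsoidRadialDist(
    meshNodes(tor$torso)[tor$torso@innerLayer, , drop = FALSE],
    g$atrial_surface$center, g$atrial_surface$radii)
  expect_true(all(abs(d - g$source_offset) <= g$h / 2 + 1e-9))
})

test_that("the Laplace solver reproduces constant boundary data", {
  tor <- buildSimplifiedTorso()
  V <- solveTorsoLaplace(tor$torso, tor$conductivities,
                         rep(3.7, length(tor$torso@innerLayer)))
  expect_lt(max(abs(V - 3.7)), 1e-9)
  expect_error(solveTorsoLaplace(tor$torso, tor$conductivities,
                                 numeric(0), dirichletNodes = integer(0)),
               "empty Dirichlet")
})

test_that("a two-slab conductivity contrast gives the analytic kink", {
  ## box split at x = 0 into sigma1 = 1 and sigma2 = 2; V fixed to 0 and 1
  ## on the end faces; flux continuity makes V piecewise linear with slope
  ## ratio 2:1
  tor <- buildSimplifiedTorso(box_lo = c(-8, -4, -4), box_hi = c(8, 4, 4),
                              h = 1, lungs = FALSE, liver = FALSE,
                              bone = FALSE, ventricle = FALSE, heart = FALSE)$torso
  ctr <- (tor@nodes[tor@tets[, 1], ] + tor@nodes[tor@tets[, 2], ] +
            tor@nodes[tor@tets[, 3], ] + tor@nodes[tor@tets[, 4], ]) / 4
  organ <- ifelse(ctr[, 1] < 0, "chest", "blood")
  tor2 <- new("TorsoMesh", nodes = tor@nodes, tets = tor@tets, organ = organ,
              innerLayer = tor@innerLayer, outerSurface = tor@outerSurface,
              grid = tor@grid)
  ends <- which(tor@nodes[, 1] %in% c(-8, 8))
  vals <- ifelse(tor@nodes[ends, 1] < 0, 0, 1)
  V <- solveTorsoLaplace(tor2, c(chest = 1, blood = 2), vals,
                         dirichletNodes = ends)
  ## analytic: slopes s1, s2 with s1 sigma1 = s2 sigma2, 8 s1 + 8 s2 = 1
  s1 <- 2 / (8 * 3); s2 <- 1 / (8 * 3)
  x <- tor@nodes[, 1]
  vref <- ifelse(x < 0, (x + 8) * s1, 8 * s1 + x * s2)
  expect_lt(max(abs(V - vref)), 0.01)
})

test_that("the solution obeys the discrete maximum principle", {
  set.seed(11)
  tor <- buildSimplifiedTorso()
  iv <- runif(length(tor$torso@innerLayer), -1, 2)
  V <- solveTorsoLaplace(tor$torso, tor$conductivities, iv)
  expect_gte(min(V), min(iv) - 1e-9)
  expect_lte(max(V), max(iv) + 1e-9)
})

test_that("lead extraction interpolates exactly and forms bipolar leads", {
  tor <- buildSimplifiedTorso()
  nn <- nNodes(tor$torso)
  set.seed(3)
  f1 <- runif(nn); f2 <- runif(nn)
  fields <- cbind(f1, f2)
  ## a lead placed exactly at a mesh node returns the nodal value
  nd <- 1234L
  p <- meshNodes(tor$torso)[nd, ]
  lt <- extractLeads(fields, tor$torso,
                     observationPoints("X", p[1], p[2], p[3]), time = 0:1)
  expect_equal(as.vector(traceMatrix(lt)), c(f1[nd], f2[nd]),
               tolerance = 1e-12)
  ## constant field -> constant trace; D1 = LA - RA samplewise
  std <- standardTorsoLeads(tor$torso)
  cf <- matrix(2.5, nn, 3)
  lt2 <- extractLeads(cf, tor$torso, std$points, time = 0:2,
                      bipolar = std$bipolar)
  tm <- traceMatrix(lt2)
  expect_true(all(abs(tm[, leadNames(lt2) %in% paste0("V", 1:6)] - 2.5) < 1e-12))
  expect_true(all(abs(tm[, leadNames(lt2) == "D1"]) < 1e-12))
  fields3 <- cbind(f1, f2, f1 - f2)
  lt3 <- extractLeads(fields3, tor$torso, std$points, time = 0:2,
                      bipolar = std$bipolar)
  tm3 <- traceMatrix(lt3)
  expect_equal(tm3[, leadNames(lt3) == "D1"],
               tm3[, leadNames(lt3) == "LA"] - tm3[, leadNames(lt3) == "RA"],
               tolerance = 1e-12)
  ## outside the hull
  expect_error(extractLeads(fields, tor$torso,
                            observationPoints("Y", 99, 0, 0), time = 0:1),
               "outside")
})

test_that("torso heterogeneity changes the surface amplitudes", {
  set.seed(5)
  tor <- buildSimplifiedTorso()
  nL <- length(tor$torso@innerLayer)
  ## smooth dipolar source pattern on the layer
  lay <- meshNodes(tor$torso)[tor$torso@innerLayer, ]
  iv <- matrix(0.5 * lay[, 1] / max(abs(lay[, 1])) +
                 0.1 * sin(lay[, 3]), ncol = 1)
  het <- solveTorsoLaplace(tor$torso, tor$conductivities, iv)
  homo <- solveTorsoLaplace(tor$torso,
                            setNames(rep(2.39, 6), names(tor$conductivities)),
                            iv)
  std <- standardTorsoLeads(tor$torso)
  a1 <- traceMatrix(extractLeads(het, tor$torso, std$points, 0))
  a2 <- traceMatrix(extractLeads(homo, tor$torso, std$points, 0))
  relchange <- abs(a1 - a2) / (max(abs(a1)) + 1e-12)
  expect_gt(max(relchange), 0.05)
})
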