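test_that("slab construction gives the expected counts", {
  s <- buildSlab(50, 50, 3, 300)
  expect_equal(nElements(s), 7500L)
  expect_equal(nNodes(s), 51L * 51L * 4L)
  one <- buildSlab(1, 1, 1, 300)
  expect_equal(nElements(one), 1L)
  expect_equal(nNodes(one), 8L)
  expect_error(buildSlab(10, 10, 1, 0), "spacing")
  expect_error(buildSlab(0, 10, 1, 300))
  ## positive volumes on a regular mesh
  expect_true(all(elementVolumes(s) > 0))
})

test_that("the fibre cross-product rule behaves as specified", {
  m <- buildSlab(3, 3, 1, 300)
  lab <- rep("R", nElements(m))
  ## x-hat x z-hat = -y-hat on a flat slab with outward normal z
  f <- assignFibres(m, lab, list(R = c(1, 0, 0)))
  expect_equal(f, matrix(rep(c(0, -1, 0), each = nElements(m)), ncol = 3))
  ## principal parallel to the normal: zero cross product
  expect_error(assignFibres(m, lab, list(R = c(0, 0, 1))),
               "parallel to surface normal")
  ## normalization invariance
  f2 <- assignFibres(m, lab, list(R = c(2, 0, 0)))
  expect_equal(f, f2)
  ## missing region
  expect_error(assignFibres(m, lab, list(Q = c(1, 0, 0))),
               "no principal vector")
})

test_that("the fibre rule is equivariant under rotations", {
  set.seed(42)
  for (rep in 1:5) {
    ## random rotation via QR of a random matrix
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    p <- rnorm(3)
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    m <- buildSlab(1, 1, 1, 300)
    f <- assignFibres(m, "R", list(R = p), normals = matrix(n, 1))
    fr <- assignFibres(m, "R", list(R = as.vector(Q %*% p)),
                       normals = matrix(as.vector(Q %*% n), 1))
    expect_equal(as.vector(fr), as.vector(Q %*% as.vector(f)),
                 tolerance = 1e-12)
  }
})

test_that("the idealized atria carry exactly the 21-region vocabulary", {
  at <- atriaRun()$at
  expect_setequal(unique(at$labels), regionVocabulary())
  expect_length(unique(at$labels), 21L)
  expect_false(anyNA(at$labels))
})

test_that("atrial fibres are unit length and tangent to the wall", {
  at <- atriaRun()$at
  expect_lt(max(abs(sqrt(rowSums(at$fibres^2)) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(at$fibres * at$normals))), 1e-6)
})

test_that("the sinoatrial node patch touches the crista terminalis", {
  at <- atriaRun()$at
  expect_gt(sum(at$labels == "SAN"), 0)
  expect_true(regionsShareFace(at$ijk, at$labels, "SAN", "CT"))
})

test_that("the Bachmann bundle connects the two chambers", {
  at <- atriaRun()$at
  expect_true(regionsShareFace(at$ijk, at$labels, "BBR", "BBL"))
  expect_true(any(vapply(c("RAS", "RLW", "IB", "SCV"), function(r)
    regionsShareFace(at$ijk, at$labels, "BBR", r), logical(1))))
  expect_true(any(vapply(c("LAS", "LSW"), function(r)
    regionsShareFace(at$ijk, at$labels, "BBL", r), logical(1))))
})

test_that("the optional fossa ovalis tract extends the label set to 23", {
  at <- buildIdealizedAtria(includeFo = TRUE)
  expect_setequal(unique(at$labels), regionVocabulary(extended = TRUE))
})

test_that("wall thickness below the spacing is rejected", {
  expect_error(buildIdealizedAtria(wall_thickness = 600, spacing = 900),
               "wall thickness")
})
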