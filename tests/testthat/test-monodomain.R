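test_that("the diffusion operator is symmetric with constant null space", {
  m <- buildSlab(8, 6, 2, 300)
  fib <- matrix(rep(c(1, 0, 0), each = nElements(m)), ncol = 3)
  op <- assembleDiffusion(m, conductivityField(3, 1, fib))
  expect_lt(max(abs(op$K - Matrix::t(op$K))), 1e-12)
  expect_lt(max(abs(Matrix::rowSums(op$K))), 1e-12)
  ## linear fields are reproduced exactly by trilinear elements: the
  ## operator action on V = x vanishes at interior nodes
  x <- meshNodes(m)[, 1]
  r <- as.numeric(op$K %*% x)
  bb <- apply(meshNodes(m), 2, range)
  interior <- apply(meshNodes(m), 1, function(p)
    all(p > bb[1, ] + 1e-9) && all(p < bb[2, ] - 1e-9))
  expect_lt(max(abs(r[interior])), 1e-12)
})

test_that("non-SPD conductivity tensors are rejected with the element", {
  m <- buildSlab(4, 2, 1, 300)
  fib <- matrix(rep(c(1, 0, 0), each = nElements(m)), ncol = 3)
  expect_error(conductivityField(1, 2, fib), "non-SPD")
  sT <- rep(1, nElements(m)); sT[3] <- 0
  expect_error(conductivityField(2, sT, fib), "3")
})

test_that("unstimulated tissue rests within 1 mV over one second", {
  m <- buildSlab(4, 4, 1, 300)
  fib <- matrix(rep(c(1, 0, 0), each = nElements(m)), ncol = 3)
  cond <- conductivityField(3, 1, fib)
  cm <- makeRegionalCell("RA/PM")
  stim <- stimulusSet(1L, start = 2000, duration = 1, amplitude = 0)
  run <- runMonodomain(m, rep("RA/PM", nElements(m)), cond,
                       list("RA/PM" = cm), stim, duration = 1000,
                       outputDt = 50)
  v0 <- maleckarInitialState()["V"]
  expect_lt(max(abs(vmMatrix(run) - v0)), 1)
  expect_true(all(is.na(run@meta$lat)))
})

test_that("a decoupled single element reproduces the 0D trace", {
  m <- buildSlab(1, 1, 1, 300)
  fib <- matrix(c(1, 0, 0), 1)
  cond <- conductivityField(1e-9, 1e-10, fib)
  cm <- makeRegionalCell("RA/PM")
  pr <- pacingProtocol(nBeats = 1L, bcl = 400)
  stim <- stimulusSet(1:8, start = 0, duration = pr@stimDuration,
                      amplitude = pr@stimAmplitude)
  run <- runMonodomain(m, "RA/PM", cond, list("RA/PM" = cm), stim,
                       duration = 400, outputDt = 1)
  tr0 <- paceSingleCell(cm, pr, sampleDt = 1, recordBeats = 1L)
  sel <- match(tr0@time, timePoints(run))
  ok <- !is.na(sel)
  v3d <- vmMatrix(run)[1, sel[ok]]
  v0d <- tr0@Vm[ok]
  expect_lt(sqrt(mean((v3d - v0d)^2)), 0.5)
})

test_that("missing cell models are reported by label", {
  m <- buildSlab(2, 2, 1, 300)
  fib <- matrix(rep(c(1, 0, 0), each = nElements(m)), ncol = 3)
  cond <- conductivityField(3, 1, fib)
  expect_error(
    runMonodomain(m, rep(c("A", "B"), 2), cond,
                  list(A = makeRegionalCell("RA/PM")),
                  stimulusSet(1L), duration = 1),
    "no cell model for label")
})

test_that("mirrored stimulation yields the mirrored activation field", {
  m <- buildSlab(20, 6, 1, 300)
  ne <- nElements(m)
  fib <- matrix(rep(c(1, 0, 0), each = ne), ncol = 3)
  cond <- conductivityField(2.6, 0.9, fib)
  cm <- makeRegionalCell("RA/PM")
  co <- meshNodes(m)
  h <- 0.03
  L <- 20 * h
  runFrom <- function(nodes) {
    runMonodomain(m, rep("RA/PM", ne), cond, list("RA/PM" = cm),
                  stimulusSet(nodes, 0, 2, 52), duration = 18, outputDt = 2)
  }
  left <- runFrom(which(co[, 1] < 3.5 * h))
  right <- runFrom(which(co[, 1] > L - 3.5 * h))
  ## mirror map: node at x -> node at L - x
  mirror <- vapply(seq_len(nrow(co)), function(i) {
    p <- co[i, ]; p[1] <- L - p[1]
    which.min(colSums((t(co) - p)^2))
  }, integer(1))
  la <- left@meta$lat
  lb <- right@meta$lat[mirror]
  ok <- !is.na(la) & !is.na(lb)
  expect_gt(sum(ok), 0.8 * length(la))
  expect_lt(max(abs(la[ok] - lb[ok])), 0.25)
})

test_that("conduction velocity scales as the square root of conductivity", {
  m <- buildSlab(40, 8, 1, 300)
  slab <- list(mesh = m, dims = c(40L, 8L, 1L))
  cm <- makeRegionalCell("RA/PM")
  st <- stabilizedState(cm)
  cv <- vapply(c(0.5, 1, 2), function(k)
    AtriaSim:::.slabCvRun(2.6 * k, 0.35, cm, slab, state0 = st), numeric(1))
  expect_lt(abs(cv[1] / cv[2] - sqrt(0.5)), 0.03 * sqrt(0.5))
  expect_lt(abs(cv[3] / cv[2] - sqrt(2)), 0.03 * sqrt(2))
  ## monotonicity of CV in sigmaL
  expect_true(all(diff(cv) > 0))
})

test_that("isotropic tissue conducts at the same speed in both directions", {
  m <- buildSlab(30, 30, 1, 300)
  slab <- list(mesh = m, dims = c(30L, 30L, 1L))
  cm <- makeRegionalCell("RA/PM")
  st <- stabilizedState(cm)
  cvx <- AtriaSim:::.slabCvRun(2.6, 1, cm, slab, axis = 1L, state0 = st)
  cvy <- AtriaSim:::.slabCvRun(2.6, 1, cm, slab, axis = 2L, state0 = st)
  expect_lt(abs(cvx - cvy) / cvx, 0.03)
})
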