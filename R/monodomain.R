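## Anisotropic monodomain reaction-diffusion solver on regular hex meshes.
##
## Operator splitting (Godunov): one reaction step per node with its
## regional ionic model (compiled kernel), then one implicit diffusion step
## with a trilinear FEM operator (consistent mass, backward Euler, sparse
## Cholesky; a lumped mass vector is also assembled for volume accounting).
## The consistent mass matrix keeps numerical conduction velocities close
## to the continuum dispersion even where slow transverse wavefronts span
## only a couple of elements. Equivalent conductivities sigma (mS/cm) absorb the
## surface-to-volume and capacitance scaling: the diffusion step integrates
## dV/dt = div(sigma/(beta*Cm) grad V) with beta*Cm fixed at 1 uF/cm^3,
## i.e. a diffusivity of 1e-3 * sigma cm^2/ms. Sigma values are therefore
## calibration outputs fixed by conduction-velocity targets.

.KSCALE <- 1e-3  # (mS/cm) -> cm^2/ms under the unit convention above

#' Per-element conductivity field
#'
#' Defines the equivalent conductivity tensor
#' D = sigmaT I + (sigmaL - sigmaT) f f' per element, with f the unit fibre
#' direction. Requires sigmaL >= sigmaT > 0 (isotropy when equal).
#'
#' @slot sigmaL,sigmaT longitudinal and transverse equivalent conductivities
#'   (mS/cm), one per element.
#' @slot fibres E x 3 unit fibre directions.
#' @export
setClass("ConductivityField",
  representation(sigmaL = "numeric", sigmaT = "numeric", fibres = "matrix"))

setValidity("ConductivityField", function(object) {
  msg <- character()
  if (length(object@sigmaL) != length(object@sigmaT) ||
      nrow(object@fibres) != length(object@sigmaL))
    msg <- c(msg, "sigmaL, sigmaT and fibres must agree in length")
  if (length(msg)) msg else TRUE
})

#' Construct a conductivity field
#'
#' @param sigmaL,sigmaT conductivities (mS/cm); scalars are recycled.
#' @param fibres E x 3 unit fibre matrix (any matrix row-normalized here).
#' @param nElements element count used for recycling scalars.
#' @return a [ConductivityField-class].
#' @export
conductivityField <- function(sigmaL, sigmaT, fibres, nElements = nrow(fibres)) {
  sigmaL <- rep_len(sigmaL, nElements)
  sigmaT <- rep_len(sigmaT, nElements)
  fibres <- fibres / sqrt(rowSums(fibres^2))
  bad <- which(!(sigmaT > 0) | sigmaL < sigmaT - 1e-12)
  if (length(bad))
    stop("non-SPD conductivity tensor (need sigmaL >= sigmaT > 0) at ",
         "element(s): ", paste(head(bad, 10L), collapse = ", "))
  new("ConductivityField", sigmaL = sigmaL, sigmaT = sigmaT, fibres = fibres)
}

## reference-element gradients of the 8 trilinear shape functions at the
## 2x2x2 Gauss points (unit weights); local node sign pattern in VTK order
.hexRefGrads <- function() {
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  gp <- 1 / sqrt(3)
  q <- as.matrix(expand.grid(x = c(-gp, gp), y = c(-gp, gp), z = c(-gp, gp)))
  lapply(seq_len(8L), function(iq) {
    xi <- q[iq, ]
    t(vapply(seq_len(8L), function(i) {
      c(s[i, 1] * (1 + s[i, 2] * xi[2]) * (1 + s[i, 3] * xi[3]),
        s[i, 2] * (1 + s[i, 1] * xi[1]) * (1 + s[i, 3] * xi[3]),
        s[i, 3] * (1 + s[i, 1] * xi[1]) * (1 + s[i, 2] * xi[2])) / 8
    }, numeric(3L)))
  })
}

#' Assemble the monodomain diffusion operator
#'
#' Trilinear finite-element discretization of div(D grad .) on a regular
#' hexahedral mesh with homogeneous Neumann (no-flux) boundary, returned as
#' a symmetric sparse stiffness matrix K (so that the operator action is
#' -K V) together with the consistent mass matrix and the lumped mass
#' vector. Constant fields lie in the null space (zero row sums).
#'
#' @param mesh a [HexMesh-class].
#' @param conductivity a [ConductivityField-class] with one entry per element.
#' @return list with \code{K} (sparse dgCMatrix, symmetric), \code{Mc}
#'   (sparse consistent mass, cm^3), \code{mass} (lumped vector, cm^3),
#'   \code{mesh}.
#' @export
assembleDiffusion <- function(mesh, conductivity) {
  stopifnot(is(mesh, "HexMesh"), is(conductivity, "ConductivityField"))
  validObject(conductivity)
  ne <- nElements(mesh)
  if (length(conductivity@sigmaL) != ne)
    stop("conductivity field does not match element count")
  h <- mesh@spacing * 1e-4
  grads <- .hexRefGrads()
  ## A[i,j] = sum_q gq_i . gq_j ; Bq[,i] = f . gq_i per element
  A <- matrix(0, 8L, 8L)
  for (G in grads) A <- A + G %*% t(G)
  f <- conductivity@fibres
  P <- lapply(grads, function(G) f %*% t(G))  # list of E x 8
  sT <- conductivity@sigmaT
  dS <- conductivity@sigmaL - sT
  elems <- mesh@elems
  vals <- vector("list", 64L)
  ii <- vector("list", 64L)
  jj <- vector("list", 64L)
  k <- 0L
  for (i in 1:8) for (j in 1:8) {
    Bij <- 0
    for (q in 1:8) Bij <- Bij + P[[q]][, i] * P[[q]][, j]
    k <- k + 1L
    vals[[k]] <- (h / 2) * (sT * A[i, j] + dS * Bij)
    ii[[k]] <- elems[, i]
    jj[[k]] <- elems[, j]
  }
  K <- sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vals),
                    dims = rep(nNodes(mesh), 2L))
  mass <- tabulate(as.vector(elems), nbins = nNodes(mesh)) * h^3 / 8
  ## consistent mass: tensor product of the 1D element mass [[2,1],[1,2]]/3
  sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
               c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  mi <- vector("list", 64L); mj <- vector("list", 64L); mv <- vector("list", 64L)
  k <- 0L
  for (i in 1:8) for (j in 1:8) {
    nd <- sum(sgn[i, ] != sgn[j, ])
    k <- k + 1L
    mi[[k]] <- elems[, i]
    mj[[k]] <- elems[, j]
    mv[[k]] <- rep((h / 2)^3 * (2 / 3)^(3 - nd) * (1 / 3)^nd, ne)
  }
  Mc <- sparseMatrix(i = unlist(mi), j = unlist(mj), x = unlist(mv),
                     dims = rep(nNodes(mesh), 2L))
  list(K = K, Mc = Mc, mass = mass, mesh = mesh)
}

#' Define a stimulus set
#'
#' Each entry delivers a (possibly periodic) train of current pulses to a
#' node set, as an added depolarizing ionic current in the reaction step.
#'
#' @param nodes node indices.
#' @param start onset of the first pulse (ms).
#' @param duration pulse duration (ms).
#' @param amplitude pulse amplitude (pA/pF).
#' @param period pulse period (ms), NA for a single pulse.
#' @param count number of pulses.
#' @return object of class \code{StimulusSet} (a validated list of entries);
#'   combine entries with \code{c()}.
#' @export
stimulusSet <- function(nodes, start = 0, duration = 2, amplitude = 30,
                        period = NA_real_, count = 1L) {
  stopifnot(length(nodes) >= 1L, duration > 0, is.finite(amplitude))
  if (!is.na(period) && period <= duration)
    stop("pulse period must exceed pulse duration")
  structure(list(list(nodes = as.integer(nodes), start = start,
                      duration = duration, amplitude = amplitude,
                      period = period, count = as.integer(count))),
            class = "StimulusSet")
}

#' @export
c.StimulusSet <- function(...) {
  structure(do.call(c, lapply(list(...), unclass)), class = "StimulusSet")
}

## stimulus current per node at time t (pA/pF)
.stimAt <- function(stimuli, t, nNodes) {
  cur <- NULL
  for (s in stimuli) {
    tt <- t - s$start
    active <- FALSE
    if (is.na(s$period)) {
      active <- tt >= 0 && tt < s$duration
    } else {
      kk <- floor(tt / s$period)
      active <- tt >= 0 && kk < s$count && (tt - kk * s$period) < s$duration
    }
    if (active) {
      if (is.null(cur)) cur <- numeric(nNodes)
      cur[s$nodes] <- cur[s$nodes] + s$amplitude
    }
  }
  cur
}

#' Run a monodomain tissue simulation
#'
#' Integrates the monodomain equation with Godunov operator splitting at a
#' constant time step (default dt = 0.02 ms): a reaction step per node with
#' the regional ionic model, then an implicit (backward Euler) diffusion
#' step solved with a prefactorized sparse Cholesky decomposition. Vm is
#' recorded on the output grid (default every 1 ms); local activation times
#' are additionally tracked at integration resolution and returned in the
#' series metadata.
#'
#' @param mesh a [HexMesh-class].
#' @param labels region label per element (drives the cell model mapping).
#' @param conductivity a [ConductivityField-class].
#' @param cellModels named list mapping every label to an
#'   [AtrialCellModel-class].
#' @param stimuli a \code{StimulusSet} (node-based).
#' @param duration simulated time (ms).
#' @param dt integration step (ms), <= 0.02 recommended.
#' @param outputDt output sampling interval (ms).
#' @param initStates optional named list label -> state vector; by default
#'   each region starts from the model's initial (resting) state. Use
#'   [stabilizedState()] values for paced-to-steady-state tissue.
#' @param latThreshold threshold (mV) for the activation-time tracker.
#' @param stopNodes optional node indices: the run ends \code{stopMargin}
#'   ms after all of them have activated (used by CV calibration).
#' @param stopMargin margin (ms) for \code{stopNodes}.
#' @return a [VmSeries-class]; \code{meta(x)$lat} holds per-node activation
#'   times (ms, NA if never activated) at integration resolution.
#' @export
runMonodomain <- function(mesh, labels, conductivity, cellModels, stimuli,
                          duration, dt = 0.02, outputDt = 1,
                          initStates = NULL, latThreshold = -40,
                          stopNodes = NULL, stopMargin = 2) {
  stopifnot(is(mesh, "HexMesh"), length(labels) == nElements(mesh))
  regions <- sort(unique(labels))
  missing <- regions[!regions %in% names(cellModels)]
  if (length(missing))
    stop("no cell model for label(s): ", paste(missing, collapse = ", "))

  nn <- nNodes(mesh)
  ## node region: majority label of adjacent elements (first listed wins)
  nodeRegion <- integer(nn)
  for (r in seq_along(regions)) {
    idx <- unique(as.vector(mesh@elems[labels == regions[r], ]))
    nodeRegion[idx] <- r
  }
  nodeRegion[nodeRegion == 0L] <- 1L

  scal <- vapply(regions, function(r) unname(cellModels[[r]]@scalings),
                 numeric(3L))
  consts <- cellModels[[regions[1L]]]@constants

  state <- matrix(0, length(maleckarStateNames()), nn)
  for (r in seq_along(regions)) {
    st <- if (!is.null(initStates) && !is.null(initStates[[regions[r]]]))
      initStates[[regions[r]]] else cellModels[[regions[r]]]@initState
    state[, nodeRegion == r] <- st[maleckarStateNames()]
  }

  op <- assembleDiffusion(mesh, conductivity)
  A <- forceSymmetric(op$Mc / dt + .KSCALE * op$K)
  ch <- Matrix::Cholesky(A, LDL = FALSE)
  McOverDt <- op$Mc / dt

  nsteps <- ceiling(duration / dt - 1e-9)
  ostride <- max(1L, round(outputDt / dt))
  nrec <- nsteps %/% ostride
  ## the output grid includes t = 0 so that every node's trace carries its
  ## true diastolic reference (APD mapping needs the pre-stimulus value)
  vm <- matrix(NA_real_, nn, nrec + 1L)
  vm[, 1L] <- state[1L, ]
  tgrid <- numeric(nrec + 1L)
  irec0 <- 1L
  lat <- rep(NA_real_, nn)
  zeroStim <- numeric(nn)
  irec <- 0L
  stopAt <- Inf
  vold <- state[1L, ]

  for (k in seq_len(nsteps)) {
    t0 <- (k - 1L) * dt
    istim <- .stimAt(stimuli, t0, nn)
    bad <- reactionStepCpp(state, consts, scal, nodeRegion,
                           if (is.null(istim)) zeroStim else istim, dt)
    if (bad > 0)
      stop(sprintf("non-finite Vm at node %d, t = %.2f ms", bad, t0 + dt))
    vnew <- as.numeric(Matrix::solve(ch, McOverDt %*% state[1L, ]))
    state[1L, ] <- vnew
    ## activation tracking spans the full step (reaction + diffusion)
    cross <- which(is.na(lat) & vold < latThreshold & vnew >= latThreshold)
    if (length(cross)) {
      frac <- (latThreshold - vold[cross]) / (vnew[cross] - vold[cross])
      lat[cross] <- t0 + frac * dt
      if (!is.null(stopNodes) && is.infinite(stopAt) &&
          all(!is.na(lat[stopNodes])))
        stopAt <- max(lat[stopNodes]) + stopMargin
    }
    vold <- vnew
    if (k %% ostride == 0L) {
      irec <- irec + 1L
      vm[, irec0 + irec] <- vnew
      tgrid[irec0 + irec] <- k * dt
    }
    if (k * dt >= stopAt) break
  }
  keep <- seq_len(irec0 + irec)
  if (length(keep) < ncol(vm)) { vm <- vm[, keep, drop = FALSE]; tgrid <- tgrid[keep] }

  new("VmSeries", vm = vm, time = tgrid, mesh = mesh,
      meta = list(dt = dt, outputDt = outputDt, labels = labels,
                  lat = lat, latThreshold = latThreshold,
                  scheme = "godunov: FE/Rush-Larsen reaction + backward-Euler FEM diffusion (sparse Cholesky)"))
}

#' Construct a VmSeries from raw samples
#'
#' Used for synthetic fields in analyses and tests.
#'
#' @param vm node x time matrix (mV).
#' @param time sample times (ms).
#' @param mesh the carrier mesh.
#' @param meta optional metadata list.
#' @return a [VmSeries-class].
#' @export
vmSeries <- function(vm, time, mesh, meta = list()) {
  new("VmSeries", vm = vm, time = time, mesh = mesh, meta = meta)
}
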