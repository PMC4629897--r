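## Conduction-velocity measurement and calibration of the longitudinal
## equivalent conductivity against target CVs in the reference slab.

#' Measure conduction velocity between two probes
#'
#' Local activation time at each probe is the first upward crossing of the
#' threshold in the probe node's Vm trace, located by linear interpolation
#' in time; CV = distance / (LAT(b) - LAT(a)). Probes are snapped to the
#' nearest mesh node and must lie inside the mesh; for accurate values use
#' an output grid fine enough to resolve the upstroke (or the activation
#' times recorded by the solver at integration resolution via
#' \code{useSolverLat}).
#'
#' @param vm a [VmSeries-class].
#' @param probeA,probeB 3D points (cm), separated along the propagation axis.
#' @param threshold activation threshold (mV).
#' @param useSolverLat if TRUE and the series carries solver-resolution
#'   activation times, use those instead of the output-grid traces.
#' @return velocity in cm/s.
#' @export
measureCV <- function(vm, probeA, probeB, threshold = -40,
                      useSolverLat = FALSE) {
  mesh <- vm@mesh
  snap <- function(p) {
    d2 <- colSums((t(mesh@nodes) - p)^2)
    i <- which.min(d2)
    h <- mesh@spacing * 1e-4
    if (sqrt(d2[i]) > 1.5 * h)
      stop("probe (", paste(signif(p, 3), collapse = ", "),
           ") lies outside the mesh")
    i
  }
  ia <- snap(probeA); ib <- snap(probeB)
  lat1 <- .probeLat(vm, ia, threshold, useSolverLat)
  lat2 <- .probeLat(vm, ib, threshold, useSolverLat)
  if (is.na(lat1) || is.na(lat2))
    stop("probe never activates (no upward crossing of ", threshold, " mV)")
  if (lat2 <= lat1)
    stop("LAT(b) <= LAT(a): wave does not propagate from probe A to B")
  dist <- sqrt(sum((mesh@nodes[ib, ] - mesh@nodes[ia, ])^2))
  dist / ((lat2 - lat1) * 1e-3)   # cm/s
}

.probeLat <- function(vm, node, threshold, useSolverLat) {
  if (useSolverLat && !is.null(vm@meta$lat)) return(vm@meta$lat[node])
  v <- vm@vm[node, ]
  tt <- vm@time
  up <- which(v[-1L] >= threshold & v[-length(v)] < threshold)
  if (!length(up)) return(NA_real_)
  i <- up[1L]
  tt[i] + (threshold - v[i]) / (v[i + 1L] - v[i]) * (tt[i + 1L] - tt[i])
}

## one slab CV evaluation: planar stimulation of one face, probes at 30%
## and 70% of the length along the propagation axis on the mid line.
.slabCvRun <- function(sigmaL, ratio, cellModel, slab, axis = 1L,
                       stimAmplitude = 52, stimDuration = 2,
                       state0 = NULL, latThreshold = -40) {
  mesh <- slab$mesh
  n <- slab$dims + 1L
  h <- mesh@spacing * 1e-4
  L <- slab$dims * h
  fib <- matrix(0, nElements(mesh), 3L)
  fib[, 1L] <- 1
  cond <- conductivityField(sigmaL, sigmaL * ratio, fib)
  coords <- mesh@nodes
  ## stimulate a four-node-deep volume at the face: a single node sheet
  ## loses too much depolarizing charge to diffusion to capture reliably,
  ## especially at bundle-level conductivities
  face <- which(coords[, axis] < 3.5 * h)
  stim <- stimulusSet(face, start = 0, duration = stimDuration,
                      amplitude = stimAmplitude)
  mid <- vapply(1:3, function(d) {
    zs <- sort(unique(coords[, d]))
    zs[ceiling(length(zs) / 2)]
  }, numeric(1L))
  pa <- mid; pa[axis] <- round(0.3 * slab$dims[axis]) * h
  pb <- mid; pb[axis] <- round(0.7 * slab$dims[axis]) * h
  labels <- rep(cellModel@region, nElements(mesh))
  models <- setNames(list(cellModel), cellModel@region)
  init <- if (is.null(state0)) NULL else setNames(list(state0), cellModel@region)
  snap <- function(p) which.min(colSums((t(coords) - p)^2))
  ## generous cap: slowest admissible wave (20 cm/s) crossing the slab,
  ## with early stop once both probes have activated
  run <- runMonodomain(mesh, labels, cond, models, stim,
                       duration = max(60, 65 * L[axis]),
                       outputDt = 1, initStates = init,
                       latThreshold = latThreshold,
                       stopNodes = c(snap(pa), snap(pb)), stopMargin = 1)
  measureCV(run, pa, pb, threshold = latThreshold, useSolverLat = TRUE)
}

#' Tune the longitudinal conductivity to a target conduction velocity
#'
#' Root-finds the longitudinal equivalent conductivity sigmaL such that a
#' planar wave in the reference slab (50 x 50 x 3 elements, 300 um, fibres
#' along the propagation axis) travels at the target CV. Exploits the
#' square-root CV-conductivity relationship of monodomain tissue for fast
#' convergence, with log-space bisection as a safeguard; tolerance 1% in CV.
#'
#' @param targetCv target conduction velocity (cm/s), within 20-200 cm/s.
#' @param anisotropyRatio sigmaT/sigmaL of the tissue class.
#' @param cellModel the regional [AtrialCellModel-class] of the tissue.
#' @param slabDims element counts of the calibration slab.
#' @param spacing slab spacing (um).
#' @param sigmaInit optional starting value (mS/cm).
#' @param tol relative CV tolerance.
#' @param maxIter iteration cap.
#' @param stabilize start tissue from the paced steady state of the cell
#'   model (recommended; the calibrated CV refers to stabilized myocytes).
#' @return list with \code{sigmaL}, \code{sigmaT}, \code{achievedCv},
#'   \code{iterations}, \code{history} (data.frame sigmaL/cv).
#' @export
tuneSigmaLongitudinal <- function(targetCv, anisotropyRatio, cellModel,
                                  slabDims = c(50L, 50L, 3L), spacing = 300,
                                  sigmaInit = NULL, tol = 0.01,
                                  maxIter = 12L, stabilize = TRUE) {
  if (!is.finite(targetCv) || targetCv <= 0)
    stop("target CV must be positive")
  if (targetCv < 20 || targetCv > 200)
    stop("target CV ", targetCv, " cm/s outside the physiological bracket ",
         "(20-200 cm/s)")
  slab <- list(mesh = buildSlab(slabDims[1], slabDims[2], slabDims[3],
                                spacing),
               dims = as.integer(slabDims))
  state0 <- if (stabilize) stabilizedState(cellModel) else NULL
  evalCv <- function(s) .slabCvRun(s, anisotropyRatio, cellModel, slab,
                                   state0 = state0)
  sigma <- if (!is.null(sigmaInit)) sigmaInit else 3
  hist <- data.frame(sigmaL = numeric(), cv = numeric())
  lo <- NA_real_; hi <- NA_real_  # bracket in sigma
  for (it in seq_len(maxIter)) {
    cv <- evalCv(sigma)
    hist <- rbind(hist, data.frame(sigmaL = sigma, cv = cv))
    if (abs(cv - targetCv) <= tol * targetCv) {
      return(list(sigmaL = sigma, sigmaT = sigma * anisotropyRatio,
                  achievedCv = cv, iterations = it, history = hist))
    }
    if (cv < targetCv) lo <- max(lo, sigma, na.rm = TRUE)
    else hi <- min(hi, sigma, na.rm = TRUE)
    ## square-root-law proposal, safeguarded by the bracket
    prop <- sigma * (targetCv / cv)^2
    if (!is.na(lo) && !is.na(hi) && (prop <= lo || prop >= hi))
      prop <- sqrt(lo * hi)
    sigma <- prop
  }
  stop(sprintf(paste0(
    "CV tuning did not converge in %d iterations (target %.1f cm/s; ",
    "bracket sigmaL in [%.3g, %.3g], last CV %.2f cm/s)"),
    maxIter, targetCv, if (is.na(lo)) NA else lo, if (is.na(hi)) NA else hi,
    hist$cv[nrow(hist)]))
}

#' Tissue-class conduction-velocity targets and anisotropy ratios
#'
#' Longitudinal CV targets by tissue class: general right/left atrial
#' tissue 63.3 cm/s (ratio 0.35), isthmus 75.0 cm/s (isotropic) and
#' pulmonary veins 76.6 cm/s (ratio 0.5), and the fast conducting
#' structures from 99.5 to 116.0 cm/s (crista terminalis, Bachmann bundle
#' and pectinate muscles at ratio 0.15, coronary sinus at 0.5, fossa
#' ovalis limb at 0.15). Which bundle takes which end of the printed range
#' is not uniquely determined; the assignment of 116.0 cm/s to CT/BB/PM
#' and 99.5 cm/s to CS/LFO is a documented surrogate choice.
#'
#' @return data.frame: class, targetCv, ratio, cellRegion.
#' @export
defaultCvTargets <- function() {
  data.frame(
    class = c("atrial", "isthmus", "pv", "bundle", "cs"),
    targetCv = c(63.3, 75.0, 76.6, 116.0, 99.5),
    ratio = c(0.35, 1.0, 0.5, 0.15, 0.5),
    cellRegion = c("RA/PM", "RA/PM", "PV", "CT/BB", "LA"),
    stringsAsFactors = FALSE
  )
}

#' Map the 21 (+2) region labels to tissue classes and cell models
#'
#' Surrogate assignment of each anatomical region to one of the eight
#' regional cell models and one conduction tissue class (the full
#' region-by-region table of the source anatomical model is not public).
#'
#' @return data.frame: region, cellRegion, class.
#' @export
defaultRegionCellMap <- function() {
  m <- rbind(
    c("SAN", "RA/PM", "isthmus"),  # isotropic, ratio 1.0
    c("CT",  "CT/BB", "bundle"),
    c("BBR", "CT/BB", "bundle"),
    c("BBL", "CT/BB", "bundle"),
    c("IB",  "RA/PM", "atrial"),
    c("RAS", "RA/PM", "atrial"),
    c("RLW", "RA/PM", "atrial"),
    c("RAA", "RAA",   "atrial"),
    c("PM",  "RA/PM", "bundle"),
    c("IST", "RA/PM", "isthmus"),
    c("SCV", "RA/PM", "atrial"),
    c("ICV", "RA/PM", "atrial"),
    c("TV",  "TV",    "atrial"),
    c("LSW", "LA",    "atrial"),
    c("LAS", "LA",    "atrial"),
    c("LAA", "LAA",   "atrial"),
    c("LPW", "LA",    "atrial"),
    c("MV",  "MV",    "atrial"),
    c("RPV", "PV",    "pv"),
    c("LPV", "PV",    "pv"),
    c("CS",  "LA",    "cs"),
    c("FO",  "RA/PM", "isthmus"),
    c("LFO", "CT/BB", "bundle")
  )
  data.frame(region = m[, 1], cellRegion = m[, 2], class = m[, 3],
             stringsAsFactors = FALSE)
}

#' Calibrate the full conductivity table
#'
#' Runs [tuneSigmaLongitudinal()] for every tissue class and returns the
#' calibrated table (the versioned artifact shipped with the package in
#' \code{inst/extdata/conductivity-table.csv} was produced by this
#' function).
#'
#' @param targets data.frame as [defaultCvTargets()].
#' @param ... passed to [tuneSigmaLongitudinal()].
#' @return data.frame: class, targetCv, ratio, cellRegion, sigmaL, sigmaT,
#'   achievedCv.
#' @export
calibrateConductivities <- function(targets = defaultCvTargets(), ...) {
  res <- lapply(seq_len(nrow(targets)), function(i) {
    fit <- tuneSigmaLongitudinal(targets$targetCv[i], targets$ratio[i],
                                 makeRegionalCell(targets$cellRegion[i]), ...)
    cbind(targets[i, ], sigmaL = fit$sigmaL, sigmaT = fit$sigmaT,
          achievedCv = fit$achievedCv)
  })
  do.call(rbind, res)
}

#' Load the shipped calibrated conductivity table
#'
#' @return data.frame as produced by [calibrateConductivities()].
#' @export
conductivityTable <- function() {
  f <- system.file("extdata", "conductivity-table.csv", package = "AtriaSim",
                   mustWork = TRUE)
  read.csv(f, stringsAsFactors = FALSE)
}

#' Per-element conductivity field for a labelled mesh
#'
#' Combines the region-to-class map with the calibrated class table.
#'
#' @param labels element region labels.
#' @param fibres E x 3 fibre matrix.
#' @param table calibrated class table (default: shipped artifact).
#' @param map region-to-class map (default [defaultRegionCellMap()]).
#' @param isotropic force ratio 1 (keeping sigmaL) for the whole mesh.
#' @return a [ConductivityField-class].
#' @export
regionConductivity <- function(labels, fibres, table = conductivityTable(),
                               map = defaultRegionCellMap(),
                               isotropic = FALSE) {
  cls <- map$class[match(labels, map$region)]
  if (anyNA(cls))
    stop("labels without class mapping: ",
         paste(unique(labels[is.na(cls)]), collapse = ", "))
  i <- match(cls, table$class)
  sl <- table$sigmaL[i]
  st <- if (isotropic) sl else table$sigmaL[i] * table$ratio[i]
  conductivityField(sl, st, fibres)
}
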