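## Central S4 data containers.

#' Regional human atrial cell model
#'
#' Holds the baseline ionic constants of the Maleckar-type human atrial
#' myocyte model together with the regional conductance multipliers for the
#' transient outward current (g_to), the L-type calcium current (g_CaL) and
#' the rapid delayed rectifier (g_Kr). The baseline (all multipliers 1)
#' corresponds to the published model and to the RA/PM regional variant.
#'
#' @slot region regional label, one of the eight variants
#'   (see [regionalScalingTable()]), or a free label for custom models.
#' @slot scalings named numeric of length 3: \code{gto}, \code{gCaL},
#'   \code{gKr}; strictly positive.
#' @slot constants full named constant set, see [maleckarConstants()].
#' @slot initState named state vector, see [maleckarInitialState()].
#' @export
setClass("AtrialCellModel",
  representation(
    region = "character",
    scalings = "numeric",
    constants = "numeric",
    initState = "numeric"
  )
)

setValidity("AtrialCellModel", function(object) {
  msg <- character()
  if (length(object@scalings) != 3L ||
      !identical(names(object@scalings), c("gto", "gCaL", "gKr")))
    msg <- c(msg, "scalings must be named c(gto=, gCaL=, gKr=)")
  if (any(!is.finite(object@scalings)) || any(object@scalings <= 0))
    msg <- c(msg, "conductance scalings must be strictly positive and finite")
  if (!identical(names(object@initState), maleckarStateNames()))
    msg <- c(msg, "initState must follow maleckarStateNames() order")
  if (!all(names(maleckarConstants()) %in% names(object@constants)))
    msg <- c(msg, "constants are incomplete")
  if (length(msg)) msg else TRUE
})

#' Pacing protocol for single-cell or tissue stimulation
#'
#' @slot nBeats number of stimuli.
#' @slot bcl basic cycle length (ms).
#' @slot stimAmplitude stimulus amplitude (pA/pF), positive = depolarizing.
#' @slot stimDuration stimulus duration (ms), must be shorter than bcl.
#' @slot dt integration step (ms).
#' @export
setClass("PacingProtocol",
  representation(
    nBeats = "integer",
    bcl = "numeric",
    stimAmplitude = "numeric",
    stimDuration = "numeric",
    dt = "numeric"
  )
)

setValidity("PacingProtocol", function(object) {
  msg <- character()
  if (object@nBeats < 1L) msg <- c(msg, "nBeats must be >= 1")
  if (!(object@stimDuration < object@bcl))
    msg <- c(msg, "stimDuration must be < bcl")
  if (!(object@dt > 0)) msg <- c(msg, "dt must be > 0")
  if (!is.finite(object@stimAmplitude))
    msg <- c(msg, "stimAmplitude must be finite")
  if (length(msg)) msg else TRUE
})

#' Action potential trace from a pacing run
#'
#' Samples of the transmembrane potential (and intracellular concentrations)
#' over the recorded tail of a pacing run, plus per-beat diagnostics for the
#' whole run: action potential duration per beat and the pre-stimulus
#' intracellular concentrations used by the steady-state check.
#'
#' @slot time sample times (ms), monotone.
#' @slot Vm transmembrane potential samples (mV).
#' @slot conc matrix with columns Na_i, K_i, Ca_i (mM); may have zero rows.
#' @slot prestim per-beat pre-stimulus concentrations (beats x 3).
#' @slot apdPerBeat APD at the protocol fraction for every completed beat (ms).
#' @slot beatsRun number of beats actually integrated.
#' @slot converged whether a convergence-stopped run met its criterion.
#' @slot protocol the pacing protocol used.
#' @slot region regional label of the model that produced the trace.
#' @export
setClass("ActionPotentialTrace",
  representation(
    time = "numeric",
    Vm = "numeric",
    conc = "matrix",
    prestim = "matrix",
    apdPerBeat = "numeric",
    beatsRun = "integer",
    converged = "logical",
    protocol = "PacingProtocol",
    region = "character"
  )
)

setValidity("ActionPotentialTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@Vm))
    msg <- c(msg, "time and Vm must have the same length")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time grid must be strictly increasing")
  if (nrow(object@conc) && nrow(object@conc) != length(object@time))
    msg <- c(msg, "conc must have one row per sample (or none)")
  if (length(msg)) msg else TRUE
})

#' Regular hexahedral mesh
#'
#' Axis-aligned mesh of congruent linear hexahedra (voxels), the geometry
#' carrier for tissue simulations. Coordinates are in cm; the element edge
#' length is recorded in micrometres.
#'
#' @slot nodes N x 3 node coordinates (cm).
#' @slot elems E x 8 node indices per element, VTK hexahedron ordering.
#' @slot spacing element edge length (micrometres).
#' @export
setClass("HexMesh",
  representation(nodes = "matrix", elems = "matrix", spacing = "numeric")
)

setValidity("HexMesh", function(object) {
  msg <- character()
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be N x 3")
  if (ncol(object@elems) != 8L) msg <- c(msg, "elems must be E x 8")
  if (nrow(object@elems) &&
      (min(object@elems) < 1L || max(object@elems) > nrow(object@nodes)))
    msg <- c(msg, "element connectivity out of node range")
  if (!(object@spacing > 0)) msg <- c(msg, "spacing must be positive")
  if (nrow(object@elems)) {
    e1 <- object@elems[1L, ]
    h <- object@spacing * 1e-4
    d <- object@nodes[e1[2L], ] - object@nodes[e1[1L], ]
    if (abs(sqrt(sum(d^2)) - h) > 1e-6 * h)
      msg <- c(msg, "spacing metadata inconsistent with node coordinates")
  }
  if (length(msg)) msg else TRUE
})

#' Transmembrane potential series from a monodomain run
#'
#' @slot vm node x time matrix of Vm (mV) on the output grid.
#' @slot time output sample times (ms).
#' @slot mesh the mesh the simulation ran on.
#' @slot meta solver metadata: dt, scheme, stimulus, region labels, and the
#'   activation times recorded at integration resolution ("lat").
#' @export
setClass("VmSeries",
  representation(vm = "matrix", time = "numeric", mesh = "HexMesh",
                 meta = "list")
)

setValidity("VmSeries", function(object) {
  msg <- character()
  if (ncol(object@vm) != length(object@time))
    msg <- c(msg, "vm must have one column per time sample")
  if (nrow(object@vm) != nrow(object@mesh@nodes))
    msg <- c(msg, "vm must have one row per mesh node")
  if (any(!is.finite(object@vm))) msg <- c(msg, "vm contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Extracellular potential traces at named observation points
#'
#' @slot traces time x lead matrix (mV).
#' @slot time sample times (ms).
#' @slot leads lead names, one per column.
#' @export
setClass("LeadTraces",
  representation(traces = "matrix", time = "numeric", leads = "character")
)

setValidity("LeadTraces", function(object) {
  msg <- character()
  if (nrow(object@traces) != length(object@time))
    msg <- c(msg, "traces must have one row per time sample")
  if (ncol(object@traces) != length(object@leads))
    msg <- c(msg, "one lead name per trace column required")
  if (anyDuplicated(object@leads)) msg <- c(msg, "duplicate lead names")
  if (length(msg)) msg else TRUE
})

#' Tetrahedral torso volume-conductor mesh
#'
#' Structured tetrahedral mesh of a simplified torso with organ labels, a
#' designated inner source layer (nodes at a nominal 0.8 mm offset from the
#' atrial surface, within element-size tolerance) and the outer skin node set.
#'
#' @slot nodes N x 3 coordinates (cm).
#' @slot tets E x 4 node indices.
#' @slot organ organ label per element (must be covered by the conductivity
#'   table used in solves).
#' @slot innerLayer node indices of the source layer.
#' @slot outerSurface node indices on the skin.
#' @slot grid structured-grid metadata (origin, h, dims) for point location.
#' @export
setClass("TorsoMesh",
  representation(nodes = "matrix", tets = "matrix", organ = "character",
                 innerLayer = "integer", outerSurface = "integer",
                 grid = "list")
)

setValidity("TorsoMesh", function(object) {
  msg <- character()
  if (ncol(object@tets) != 4L) msg <- c(msg, "tets must be E x 4")
  if (length(object@organ) != nrow(object@tets))
    msg <- c(msg, "one organ label per element required")
  if (!length(object@innerLayer))
    msg <- c(msg, "inner source layer must be non-empty")
  if (length(msg)) msg else TRUE
})
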