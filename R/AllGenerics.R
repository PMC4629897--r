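## Generics, accessors and show methods.

#' Number of nodes of a mesh
#' @param x a mesh object.
#' @return integer count.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' Number of elements of a mesh
#' @param x a mesh object.
#' @return integer count.
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))

#' Node coordinates of a mesh
#' @param x a mesh object.
#' @return N x 3 matrix (cm).
#' @export
setGeneric("meshNodes", function(x) standardGeneric("meshNodes"))

#' Element connectivity of a mesh
#' @param x a mesh object.
#' @return E x k integer matrix.
#' @export
setGeneric("meshElements", function(x) standardGeneric("meshElements"))

#' Time grid of a time-resolved object
#' @param x object with a time axis.
#' @return numeric vector (ms).
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' Conductance scalings of a regional cell model
#' @param x an AtrialCellModel.
#' @return named numeric (gto, gCaL, gKr).
#' @export
setGeneric("conductanceScalings", function(x) standardGeneric("conductanceScalings"))

#' Regional label of an object
#' @param x object carrying a regional label.
#' @return character scalar.
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' Vm matrix of a monodomain run
#' @param x a VmSeries.
#' @return node x time matrix (mV).
#' @export
setGeneric("vmMatrix", function(x) standardGeneric("vmMatrix"))

#' Trace matrix of lead recordings
#' @param x a LeadTraces.
#' @return time x lead matrix (mV).
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))

#' Lead names
#' @param x a LeadTraces.
#' @return character vector.
#' @export
setGeneric("leadNames", function(x) standardGeneric("leadNames"))

#' @describeIn nNodes hexahedral mesh
#' @export
setMethod("nNodes", "HexMesh", function(x) nrow(x@nodes))
#' @describeIn nElements hexahedral mesh
#' @export
setMethod("nElements", "HexMesh", function(x) nrow(x@elems))
#' @describeIn meshNodes hexahedral mesh
#' @export
setMethod("meshNodes", "HexMesh", function(x) x@nodes)
#' @describeIn meshElements hexahedral mesh
#' @export
setMethod("meshElements", "HexMesh", function(x) x@elems)

#' @describeIn nNodes torso mesh
#' @export
setMethod("nNodes", "TorsoMesh", function(x) nrow(x@nodes))
#' @describeIn nElements torso mesh
#' @export
setMethod("nElements", "TorsoMesh", function(x) nrow(x@tets))
#' @describeIn meshNodes torso mesh
#' @export
setMethod("meshNodes", "TorsoMesh", function(x) x@nodes)
#' @describeIn meshElements torso mesh
#' @export
setMethod("meshElements", "TorsoMesh", function(x) x@tets)

#' @describeIn timePoints action potential trace
#' @export
setMethod("timePoints", "ActionPotentialTrace", function(x) x@time)
#' @describeIn timePoints monodomain Vm series
#' @export
setMethod("timePoints", "VmSeries", function(x) x@time)
#' @describeIn timePoints lead traces
#' @export
setMethod("timePoints", "LeadTraces", function(x) x@time)

#' @describeIn conductanceScalings regional cell model
#' @export
setMethod("conductanceScalings", "AtrialCellModel", function(x) x@scalings)
#' @describeIn regionLabel regional cell model
#' @export
setMethod("regionLabel", "AtrialCellModel", function(x) x@region)
#' @describeIn regionLabel action potential trace
#' @export
setMethod("regionLabel", "ActionPotentialTrace", function(x) x@region)

#' @describeIn vmMatrix monodomain Vm series
#' @export
setMethod("vmMatrix", "VmSeries", function(x) x@vm)
#' @describeIn traceMatrix lead traces
#' @export
setMethod("traceMatrix", "LeadTraces", function(x) x@traces)
#' @describeIn leadNames lead traces
#' @export
setMethod("leadNames", "LeadTraces", function(x) x@leads)

setMethod("show", "AtrialCellModel", function(object) {
  s <- object@scalings
  cat("AtrialCellModel, region ", object@region,
      sprintf(" (gto x%.2f, gCaL x%.2f, gKr x%.2f)\n", s[1], s[2], s[3]),
      sep = "")
})

setMethod("show", "PacingProtocol", function(object) {
  cat(sprintf(
    "PacingProtocol: %d beats, BCL %g ms, stim %g pA/pF x %g ms, dt %g ms\n",
    object@nBeats, object@bcl, object@stimAmplitude, object@stimDuration,
    object@dt))
})

setMethod("show", "ActionPotentialTrace", function(object) {
  cat(sprintf(
    "ActionPotentialTrace (%s): %d samples over %.0f ms, %d beats run%s\n",
    object@region, length(object@time), diff(range(object@time)),
    object@beatsRun,
    if (isTRUE(object@converged)) " (converged)" else ""))
  a <- object@apdPerBeat
  a <- a[is.finite(a)]
  if (length(a)) cat(sprintf("  final-beat APD: %.1f ms\n", tail(a, 1)))
})

setMethod("show", "HexMesh", function(object) {
  cat(sprintf("HexMesh: %d nodes, %d hexahedra, spacing %g um\n",
              nrow(object@nodes), nrow(object@elems), object@spacing))
})

setMethod("show", "VmSeries", function(object) {
  cat(sprintf("VmSeries: %d nodes x %d samples (%.0f..%.0f ms)\n",
              nrow(object@vm), ncol(object@vm), min(object@time),
              max(object@time)))
})

setMethod("show", "LeadTraces", function(object) {
  cat(sprintf("LeadTraces: %d leads x %d samples (%s)\n",
              length(object@leads), length(object@time),
              paste(head(object@leads, 6), collapse = ", ")))
})

setMethod("show", "TorsoMesh", function(object) {
  cat(sprintf(
    "TorsoMesh: %d nodes, %d tets, organs: %s\n  inner layer %d nodes, skin %d nodes\n",
    nrow(object@nodes), nrow(object@tets),
    paste(sort(unique(object@organ)), collapse = ", "),
    length(object@innerLayer), length(object@outerSurface)))
})
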