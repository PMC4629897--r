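## Regional cell models, pacing, APD and steady-state diagnostics.

#' Regional conductance scaling table
#'
#' The eight regional variants of the atrial myocyte model, defined as
#' multipliers of the baseline maximum conductances of the transient outward
#' current (g_to), the L-type calcium current (g_CaL) and the rapid delayed
#' rectifier (g_Kr). RA/PM is the unscaled baseline model; the other rows
#' shorten or lengthen the action potential to match the regional
#' electrophysiology of crista terminalis / Bachmann bundle, right atrial
#' appendage, tricuspid valve ring, left atrium, pulmonary veins, left
#' appendage and mitral valve ring.
#'
#' @return data.frame with columns \code{region}, \code{gto}, \code{gCaL},
#'   \code{gKr}.
#' @export
regionalScalingTable <- function() {
  data.frame(
    region = c("RA/PM", "CT/BB", "RAA", "TV", "LA", "PV", "LAA", "MV"),
    gto  = c(1.00, 0.50, 1.35, 1.35, 1.00, 1.35, 1.35, 1.35),
    gCaL = c(1.00, 1.00, 1.00, 0.80, 0.67, 0.67, 0.67, 0.53),
    gKr  = c(1.00, 0.50, 1.00, 2.00, 1.60, 3.20, 1.60, 3.20),
    stringsAsFactors = FALSE
  )
}

#' Construct a regional atrial cell model
#'
#' Returns the baseline myocyte model with the conductance multipliers of the
#' requested region applied. Deterministic and idempotent: the same region
#' always yields the same parameter set, and \code{"RA/PM"} is identical to
#' the unscaled baseline model.
#'
#' @param region one of the eight regional labels, see
#'   [regionalScalingTable()].
#' @return an [AtrialCellModel-class] object.
#' @examples
#' makeRegionalCell("CT/BB")
#' @export
makeRegionalCell <- function(region) {
  tab <- regionalScalingTable()
  i <- match(region, tab$region)
  if (length(region) != 1L || is.na(i)) {
    stop("unknown region '", paste(region, collapse = ","),
         "'; valid labels: ", paste(tab$region, collapse = ", "))
  }
  new("AtrialCellModel",
      region = region,
      scalings = c(gto = tab$gto[i], gCaL = tab$gCaL[i], gKr = tab$gKr[i]),
      constants = maleckarConstants(),
      initState = maleckarInitialState())
}

#' Define a pacing protocol
#'
#' The reference stabilization protocol is a train of 3600 stimuli of 1 ms
#' duration and 52 pA/pF amplitude at a basic cycle length of 1000 ms,
#' integrated at dt = 0.02 ms.
#'
#' @param nBeats number of stimuli (>= 1).
#' @param bcl basic cycle length (ms).
#' @param stimAmplitude stimulus amplitude (pA/pF).
#' @param stimDuration stimulus duration (ms), must be < bcl.
#' @param dt integration step (ms).
#' @return a [PacingProtocol-class].
#' @export
pacingProtocol <- function(nBeats = 3600L, bcl = 1000, stimAmplitude = 52,
                           stimDuration = 1, dt = 0.02) {
  new("PacingProtocol", nBeats = as.integer(nBeats), bcl = bcl,
      stimAmplitude = stimAmplitude, stimDuration = stimDuration, dt = dt)
}

#' Pace a single cell
#'
#' Integrates the full ionic model under the given pacing protocol (forward
#' Euler for concentrations and fluxes, Rush-Larsen for gating variables).
#' The trace of the final \code{recordBeats} beats is returned at
#' \code{sampleDt} resolution together with per-beat APD and pre-stimulus
#' concentration diagnostics for the whole run.
#'
#' With \code{stopWhenConverged = TRUE} the run ends early once the APD
#' drift over \code{convWindow} beats falls below \code{convTol} ms (never
#' before \code{minBeats} beats, which defaults to 600 beats = 10 minutes of
#' pacing, the point at which these models are effectively at steady state).
#'
#' @param model an [AtrialCellModel-class].
#' @param protocol a [PacingProtocol-class].
#' @param sampleDt output sampling interval (ms).
#' @param recordBeats number of final beats to keep in the trace.
#' @param stopWhenConverged stop early on APD convergence.
#' @param convWindow,convTol convergence window (beats) and tolerance (ms).
#' @param minBeats minimum number of beats before early stopping.
#' @param apdFraction repolarization fraction used for the per-beat APD.
#' @return an [ActionPotentialTrace-class].
#' @export
paceSingleCell <- function(model, protocol, sampleDt = 0.5, recordBeats = 2L,
                           stopWhenConverged = FALSE, convWindow = 20L,
                           convTol = 0.2, minBeats = 600L,
                           apdFraction = 0.9) {
  stopifnot(is(model, "AtrialCellModel"), is(protocol, "PacingProtocol"))
  validObject(model); validObject(protocol)
  res <- paceCellCpp(model@constants, unname(model@scalings),
                     unname(model@initState[maleckarStateNames()]),
                     protocol@nBeats, protocol@bcl, protocol@stimAmplitude,
                     protocol@stimDuration, protocol@dt, sampleDt,
                     as.integer(recordBeats), isTRUE(stopWhenConverged),
                     as.integer(convWindow), convTol,
                     as.integer(min(minBeats, protocol@nBeats)), apdFraction)
  if (res$blowup_time >= 0) {
    stop(sprintf("numerical blow-up (non-finite state) at t = %.2f ms",
                 res$blowup_time))
  }
  conc <- cbind(Na_i = res$Na_i, K_i = res$K_i, Ca_i = res$Ca_i)
  ps <- res$prestim
  colnames(ps) <- c("Na_i", "K_i", "Ca_i")
  tr <- new("ActionPotentialTrace",
            time = res$time, Vm = res$Vm, conc = conc, prestim = ps,
            apdPerBeat = as.numeric(res$apd),
            beatsRun = as.integer(res$beats_run),
            converged = isTRUE(res$converged),
            protocol = protocol, region = model@region)
  attr(tr@prestim, "finalState") <- setNames(res$final_state,
                                             maleckarStateNames())
  tr
}

#' Final ionic state of a paced trace
#'
#' @param trace an [ActionPotentialTrace-class] from [paceSingleCell()].
#' @return named state vector at the end of the run.
#' @export
finalState <- function(trace) {
  st <- attr(trace@prestim, "finalState")
  if (is.null(st)) stop("trace carries no final state")
  st
}

#' Stabilized ionic state of a regional model (cached per session)
#'
#' Paces the model at the given cycle length until the APD convergence
#' criterion is met and returns the end-of-run state. Used to initialise
#' tissue simulations with quasi-steady myocytes.
#'
#' @param model an [AtrialCellModel-class].
#' @param bcl basic cycle length (ms).
#' @param minBeats minimum beats before the convergence stop.
#' @return named state vector.
#' @export
stabilizedState <- function(model, bcl = 1000, minBeats = 200L) {
  key <- paste0("stab:", model@region, ":", bcl, ":", minBeats)
  if (!is.null(.atriaCache[[key]])) return(.atriaCache[[key]])
  pr <- pacingProtocol(nBeats = 3600L, bcl = bcl)
  tr <- paceSingleCell(model, pr, sampleDt = 1, recordBeats = 1L,
                       stopWhenConverged = TRUE, minBeats = minBeats)
  st <- finalState(tr)
  .atriaCache[[key]] <- st
  st
}

#' Measure action potential duration
#'
#' Duration from activation onset (time of maximum dVm/dt within the beat)
#' to the first time Vm repolarizes past
#' \code{peak - fraction * (peak - rest)}, where \code{rest} is the
#' pre-stimulus diastolic Vm at the start of the beat window and crossings
#' are located by linear interpolation between samples. With
#' \code{fraction = 0.9} this is the APD90.
#'
#' The measurement window is the final beat when the trace carries protocol
#' metadata spanning several beats, otherwise the whole trace.
#'
#' @param trace an [ActionPotentialTrace-class], or anything with
#'   \code{time}/\code{Vm} slots.
#' @param fraction repolarization fraction in (0, 1).
#' @return duration in ms.
#' @export
measureAPD <- function(trace, fraction = 0.9) {
  stopifnot(fraction > 0, fraction < 1)
  tt <- trace@time
  vv <- trace@Vm
  ## restrict to the final beat if the trace spans several
  if (trace@beatsRun >= 2L) {
    bcl <- trace@protocol@bcl
    lastStart <- (ceiling((max(tt) + 1e-9) / bcl) - 1) * bcl
    ## a run ending exactly on a beat boundary places the last start at the
    ## trace's final instant; step back one full beat in that case
    if (max(tt) - lastStart < 0.5 * bcl) lastStart <- lastStart - bcl
    keep <- tt >= lastStart - 1e-9
    if (sum(keep) > 10) { tt <- tt[keep]; vv <- vv[keep] }
  }
  apdFromSamples(tt, vv, fraction)
}

## shared kernel: APD from one beat window of samples
apdFromSamples <- function(tt, vv, fraction) {
  n <- length(vv)
  if (n < 3L) stop("no beat detected")
  dv <- diff(vv) / diff(tt)
  onset <- which.max(dv) + 1L
  rest <- vv[1L]
  peakRel <- which.max(vv[onset:n])
  peak <- vv[onset:n][peakRel]
  peakIdx <- onset + peakRel - 1L
  if (peak - rest < 10) stop("no beat detected")
  level <- peak - fraction * (peak - rest)
  below <- which(vv[(peakIdx + 1L):n] <= level)
  if (!length(below)) stop("no repolarization crossing found")
  i <- peakIdx + below[1L]
  frac <- (vv[i - 1L] - level) / (vv[i - 1L] - vv[i])
  tcross <- tt[i - 1L] + frac * (tt[i] - tt[i - 1L])
  tcross - tt[onset]
}

#' Check steady state of intracellular concentrations
#'
#' Compares the pre-stimulus (end-diastolic) intracellular Na+, K+ and Ca2+
#' between the first and last beat of the final \code{windowBeats} beats.
#' Returns the maximum relative variation over the three species (per cent),
#' with the per-species values and their mean attached as attributes. The
#' stabilization criterion used throughout the package is a variation below
#' 2 per cent.
#'
#' @param trace an [ActionPotentialTrace-class] with per-beat pre-stimulus
#'   concentrations.
#' @param windowBeats window length in beats (default 60).
#' @return numeric scalar: max over species of |last - first| / |first| x 100,
#'   with attributes \code{perSpecies} and \code{mean}.
#' @export
checkSteadyState <- function(trace, windowBeats = 60L) {
  ps <- trace@prestim
  if (is.null(ps) || !nrow(ps) || ncol(ps) != 3L)
    stop("trace carries no per-beat concentration samples")
  if (nrow(ps) < windowBeats)
    stop("trace has fewer beats (", nrow(ps), ") than the window (",
         windowBeats, ")")
  w <- ps[(nrow(ps) - windowBeats + 1L):nrow(ps), , drop = FALSE]
  rel <- abs(w[windowBeats, ] - w[1L, ]) / abs(w[1L, ]) * 100
  out <- max(rel)
  attr(out, "perSpecies") <- rel
  attr(out, "mean") <- mean(rel)
  out
}

#' Assemble an action potential trace from raw samples
#'
#' Constructor used for synthetic traces in analyses and tests; pacing
#' metadata defaults to a single-beat protocol spanning the samples.
#'
#' @param time sample times (ms).
#' @param Vm potential samples (mV).
#' @param conc optional matrix with columns Na_i, K_i, Ca_i.
#' @param prestim optional per-beat pre-stimulus concentration matrix.
#' @param region label for bookkeeping.
#' @return an [ActionPotentialTrace-class].
#' @export
apTrace <- function(time, Vm, conc = NULL, prestim = NULL,
                    region = "custom") {
  if (is.null(conc)) conc <- matrix(numeric(), 0L, 3L,
                                    dimnames = list(NULL, c("Na_i", "K_i", "Ca_i")))
  if (is.null(prestim)) prestim <- matrix(numeric(), 0L, 3L)
  span <- max(time) - min(time)
  pr <- pacingProtocol(nBeats = 1L, bcl = max(span + 1, 1), stimAmplitude = 0,
                       stimDuration = min(1, span / 2), dt = 0.02)
  new("ActionPotentialTrace", time = time, Vm = Vm, conc = conc,
      prestim = prestim, apdPerBeat = NA_real_, beatsRun = 1L,
      converged = FALSE, protocol = pr, region = region)
}
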