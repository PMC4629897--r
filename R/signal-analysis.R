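## Derived maps and features: activation times, APD maps, body-surface RMS
## maps, P-wave morphology, per-region source contributions.

#' Local activation time map
#'
#' First upward crossing of the threshold per node, linearly interpolated
#' between output samples; nodes that never cross are NA.
#'
#' @param vm a [VmSeries-class].
#' @param threshold activation threshold (mV), default -40.
#' @param useSolverLat use the activation times recorded by the solver at
#'   integration resolution when available (more accurate than the output
#'   grid).
#' @return numeric vector of LATs (ms) per node, NA = unactivated.
#' @export
computeLATMap <- function(vm, threshold = -40, useSolverLat = FALSE) {
  if (useSolverLat && !is.null(vm@meta$lat) &&
      isTRUE(all.equal(threshold, vm@meta$latThreshold)))
    return(vm@meta$lat)
  v <- vm@vm
  tt <- vm@time
  nT <- ncol(v)
  below <- v < threshold
  lat <- rep(NA_real_, nrow(v))
  pending <- rep(TRUE, nrow(v))
  for (k in seq_len(nT - 1L)) {
    hit <- pending & below[, k] & !below[, k + 1L]
    if (any(hit)) {
      frac <- (threshold - v[hit, k]) / (v[hit, k + 1L] - v[hit, k])
      lat[hit] <- tt[k] + frac * (tt[k + 1L] - tt[k])
      pending[hit] <- FALSE
    }
  }
  lat
}

#' Per-node APD map with per-region statistics
#'
#' Applies the cell-level APD definition to every node trace of a tissue
#' run (activation onset at maximum dVm/dt, repolarization past
#' peak - fraction x amplitude, linear interpolation; the diastolic
#' reference is the node's initial Vm). Non-activated nodes are excluded
#' and counted.
#'
#' @param vm a [VmSeries-class] covering at least one full beat.
#' @param fraction repolarization fraction (default 0.9 for APD90).
#' @param labels optional element region labels (defaults to the labels
#'   stored by the solver) used for the per-region table.
#' @param threshold activation threshold (mV) deciding whether a node
#'   activated at all.
#' @return list: \code{apd} (per node, ms; NA where excluded),
#'   \code{regional} (data.frame region/mean/sd/n),
#'   \code{nExcluded}.
#' @export
computeAPDMap <- function(vm, fraction = 0.9, labels = vm@meta$labels,
                          threshold = -40) {
  v <- vm@vm
  tt <- vm@time
  n <- nrow(v)
  apd <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    vi <- v[i, ]
    if (max(vi) < threshold || max(vi) - vi[1L] < 10) next
    apd[i] <- tryCatch(apdFromSamples(tt, vi, fraction), error = function(e) NA_real_)
  }
  regional <- NULL
  if (!is.null(labels)) {
    ## node region from element labels (first adjacent element wins)
    mesh <- vm@mesh
    nodeLab <- rep(NA_character_, n)
    for (r in unique(labels)) {
      idx <- unique(as.vector(mesh@elems[labels == r, ]))
      nodeLab[idx] <- r
    }
    ok <- !is.na(apd) & !is.na(nodeLab)
    regional <- do.call(rbind, lapply(sort(unique(nodeLab[ok])), function(r) {
      x <- apd[ok & nodeLab == r]
      data.frame(region = r, mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                 n = length(x))
    }))
  }
  list(apd = apd, regional = regional, nExcluded = sum(is.na(apd)))
}

#' Body-surface RMS map
#'
#' Root-mean-square of each surface point's potential trace over the
#' analysis window, without baseline removal.
#'
#' @param traces a [LeadTraces-class] or time x point matrix.
#' @param window indices (or logical) into the time axis; default all.
#' @return named numeric vector of RMS values (mV RMS), one per point.
#' @export
computeBRMSMap <- function(traces, window = NULL) {
  m <- if (is(traces, "LeadTraces")) traces@traces else traces
  leads <- if (is(traces, "LeadTraces")) traces@leads else colnames(m)
  if (is.null(window)) window <- seq_len(nrow(m))
  if (!length(window) || !nrow(m[window, , drop = FALSE]))
    stop("empty analysis window")
  out <- sqrt(colMeans(m[window, , drop = FALSE]^2))
  if (!is.null(leads)) names(out) <- leads
  out
}

#' Decompose the pseudo-ECG into per-region source contributions
#'
#' Computes each region's extracellular signal by restricting the source
#' integral to the region's elements (masking all others). Because the
#' pseudo-ECG is linear in its sources, the per-region traces sum exactly
#' to the whole-tissue trace, and the per-region shares of summed RMS add
#' to 100 per cent.
#'
#' @param vm a [VmSeries-class].
#' @param labels element region labels.
#' @param points observation points.
#' @param gamma,sigmaRatio pseudo-ECG scale factors.
#' @param window time window for the RMS shares (default all samples).
#' @return list: \code{regional} (named list of [LeadTraces-class]),
#'   \code{total} (whole-tissue [LeadTraces-class]), \code{shares}
#'   (named numeric, per cent), \code{brms} (region x point RMS matrix).
#' @export
decomposeRegionContributions <- function(vm, labels, points, gamma = 1,
                                         sigmaRatio = 1, window = NULL) {
  if (length(labels) != nElements(vm@mesh))
    stop("labels must cover every element")
  regs <- sort(unique(labels))
  regional <- lapply(regs, function(r)
    computePseudoEcg(vm, points, gamma, sigmaRatio,
                     elementMask = labels == r))
  names(regional) <- regs
  total <- computePseudoEcg(vm, points, gamma, sigmaRatio)
  brms <- do.call(rbind, lapply(regional, function(tr)
    computeBRMSMap(tr, window)))
  rownames(brms) <- regs
  sums <- rowSums(brms)
  shares <- 100 * sums / sum(sums)
  list(regional = regional, total = total, shares = shares, brms = brms)
}

#' Extract P-wave features from a lead trace
#'
#' Duration is the span where |V| exceeds 5 per cent of the absolute peak;
#' amplitude is peak-to-peak. Morphology is classified from the signed
#' lobes of the waveform: one dominant lobe gives monophasic (+/-), two
#' opposite-sign lobes each above 25 per cent of the peak give biphasic,
#' two same-sign peaks separated by a notch deeper than 25 per cent give
#' M-shaped, anything else (including flat traces) is indeterminate.
#' The 5 and 25 per cent gates are exposed as arguments.
#'
#' @param trace numeric vector (one P-wave window of one lead), or a
#'   one-column [LeadTraces-class].
#' @param time sample times (ms); defaults to 1 ms sampling.
#' @param durationGate fraction of |peak| defining the duration support.
#' @param lobeGate fraction of the peak defining a significant lobe/notch.
#' @return list: \code{duration} (ms), \code{amplitude} (mVpp),
#'   \code{morphology} (one of "monophasic+", "monophasic-", "biphasic",
#'   "M-shaped", "indeterminate").
#' @export
extractPWaveFeatures <- function(trace, time = NULL, durationGate = 0.05,
                                 lobeGate = 0.25) {
  if (is(trace, "LeadTraces")) {
    stopifnot(ncol(trace@traces) == 1L)
    time <- trace@time
    trace <- as.vector(trace@traces)
  }
  if (is.null(time)) time <- seq_along(trace) - 1
  v <- as.numeric(trace)
  pk <- max(abs(v))
  if (pk == 0)
    return(list(duration = 0, amplitude = 0, morphology = "indeterminate"))
  sup <- which(abs(v) > durationGate * pk)
  duration <- if (length(sup)) time[max(sup)] - time[min(sup)] else 0
  amplitude <- max(v) - min(v)

  ## signed-lobe analysis on the support
  vv <- v
  vv[abs(vv) <= durationGate * pk] <- 0
  sgn <- sign(vv)
  runs <- rle(sgn)
  lobes <- data.frame(sign = runs$values, end = cumsum(runs$lengths))
  lobes$start <- lobes$end - runs$lengths + 1L
  lobes <- lobes[lobes$sign != 0, , drop = FALSE]
  lobes$height <- vapply(seq_len(nrow(lobes)), function(i)
    max(abs(v[lobes$start[i]:lobes$end[i]])), numeric(1L))
  big <- lobes[lobes$height > lobeGate * pk, , drop = FALSE]

  morph <- "indeterminate"
  if (nrow(big) == 1L) {
    morph <- if (big$sign[1] > 0) "monophasic+" else "monophasic-"
  } else if (nrow(big) == 2L && prod(big$sign) < 0) {
    morph <- "biphasic"
  } else if (nrow(big) >= 2L && all(big$sign == big$sign[1])) {
    morph <- "M-shaped"
  } else if (nrow(big) == 1L) {
    morph <- "indeterminate"
  }
  ## same-sign double peak within ONE lobe separated by a >25% notch
  if (nrow(big) == 1L) {
    seg <- v[big$start[1]:big$end[1]] * big$sign[1]
    pks <- which(diff(sign(diff(seg))) < 0) + 1L
    if (length(pks) >= 2L) {
      p1 <- pks[1L]; p2 <- pks[length(pks)]
      notch <- min(seg[p1:p2])
      if (min(seg[p1], seg[p2]) > lobeGate * pk &&
          notch < (1 - lobeGate) * min(seg[p1], seg[p2]))
        morph <- "M-shaped"
    }
  }
  list(duration = duration, amplitude = amplitude, morphology = morph)
}
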