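## Infinite-medium extracellular potentials (pseudo-ECG).
##
## V(r) = -(gamma/4pi) (sigma_i/sigma_e) * sum_e grad(Vm)_e . grad'(1/|r'-r|) vol_e
## with element-constant trilinear gradients evaluated at centroids and the
## analytic kernel gradient grad'(1/|r'-r|) = -(r'-r)/|r'-r|^3.

#' Observation points for extracellular recordings
#'
#' @param lead lead names.
#' @param x,y,z coordinates (cm).
#' @return data.frame with columns lead, x, y, z.
#' @export
observationPoints <- function(lead, x, y, z) {
  stopifnot(!anyDuplicated(lead))
  data.frame(lead = as.character(lead), x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

## sparse centroid-gradient operator (3E x N) of a regular hex mesh
.gradOperator <- function(mesh) {
  key <- paste0("gradop:", nNodes(mesh), ":", nElements(mesh), ":",
                mesh@spacing)
  cached <- .atriaCache[[key]]
  if (!is.null(cached)) return(cached)
  h <- mesh@spacing * 1e-4
  s <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
  ne <- nElements(mesh)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (c8 in 1:8) {
    for (d in 1:3) {
      rows <- c(rows, (seq_len(ne) - 1L) * 3L + d)
      cols <- c(cols, mesh@elems[, c8])
      vals <- c(vals, rep(s[c8, d] / (4 * h), ne))
    }
  }
  G <- sparseMatrix(i = rows, j = cols, x = vals,
                    dims = c(3L * ne, nNodes(mesh)))
  .atriaCache[[key]] <- G
  G
}

## dense lead-field rows (P x 3E): weights so that V(p) = W %*% gradVm
.leadField <- function(mesh, points, gamma, sigmaRatio,
                       elementMask = NULL) {
  ctr <- elementCenters(mesh)
  vol <- elementVolumes(mesh)
  h <- mesh@spacing * 1e-4
  ne <- nrow(ctr)
  P <- nrow(points)
  coef <- gamma * sigmaRatio / (4 * pi)
  W <- matrix(0, P, 3L * ne)
  for (p in seq_len(P)) {
    r <- c(points$x[p], points$y[p], points$z[p])
    d <- sweep(ctr, 2L, r)          # r' - r
    dist <- sqrt(rowSums(d^2))
    if (min(dist) < h)
      stop("observation point '", points$lead[p],
           "' lies inside or touches the source mesh (singular kernel)")
    w <- coef * vol * d / dist^3
    if (!is.null(elementMask)) w[!elementMask, ] <- 0
    W[p, ] <- as.vector(t(w))
  }
  W
}

#' Compute the pseudo-ECG at observation points
#'
#' Evaluates the infinite homogeneous-medium extracellular potential from a
#' monodomain Vm series as the volume integral of the transmembrane
#' potential gradient against the gradient of 1/r, with gradients taken
#' constant per element at centroids. The result is linear in Vm and in the
#' scale factor gamma; a spatially uniform Vm yields identically zero.
#'
#' @param vm a [VmSeries-class].
#' @param points observation points (see [observationPoints()]), strictly
#'   outside the source mesh.
#' @param gamma dimensionless scale factor (default 1; only scales
#'   amplitude).
#' @param sigmaRatio intracellular-to-extracellular conductivity ratio
#'   (default 1; only scales amplitude).
#' @param elementMask optional logical per element: restrict the source
#'   integral to a subset of elements (region masking).
#' @return a [LeadTraces-class] (mV, one column per point).
#' @export
computePseudoEcg <- function(vm, points, gamma = 1, sigmaRatio = 1,
                             elementMask = NULL) {
  stopifnot(is(vm, "VmSeries"))
  mesh <- vm@mesh
  G <- .gradOperator(mesh)
  W <- .leadField(mesh, points, gamma, sigmaRatio, elementMask)
  ## traces (T x P) = t(vm) %*% t(W G) ; compute R = G' W' (N x P) first
  R <- Matrix::crossprod(G, Matrix::t(W))
  traces <- as.matrix(Matrix::crossprod(vm@vm, R))
  dimnames(traces) <- NULL
  new("LeadTraces", traces = traces, time = vm@time, leads = points$lead)
}
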