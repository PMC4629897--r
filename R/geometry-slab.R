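## Regular hexahedral meshes: slab builder, voxel meshing, fibre assignment.

#' Build a regular hexahedral slab mesh
#'
#' Axis-aligned slab of \code{nx x ny x nz} congruent linear hexahedra with
#' the given edge length. The reference tissue slab used for conduction
#' velocity calibration is 50 x 50 x 3 elements at 300 um spacing.
#'
#' @param nx,ny,nz element counts along x, y, z (>= 1).
#' @param spacing element edge length in micrometres (> 0).
#' @return a [HexMesh-class]; node count is (nx+1)(ny+1)(nz+1).
#' @examples
#' buildSlab(50, 50, 3, 300)   # 7500 elements
#' @export
buildSlab <- function(nx, ny, nz, spacing = 300) {
  if (any(c(nx, ny, nz) < 1) || spacing <= 0)
    stop("element counts must be >= 1 and spacing > 0")
  nx <- as.integer(nx); ny <- as.integer(ny); nz <- as.integer(nz)
  h <- spacing * 1e-4  # cm
  xs <- (0:nx) * h; ys <- (0:ny) * h; zs <- (0:nz) * h
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  g <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  elems <- cbind(
    nid(g$i,      g$j,      g$k),
    nid(g$i + 1L, g$j,      g$k),
    nid(g$i + 1L, g$j + 1L, g$k),
    nid(g$i,      g$j + 1L, g$k),
    nid(g$i,      g$j,      g$k + 1L),
    nid(g$i + 1L, g$j,      g$k + 1L),
    nid(g$i + 1L, g$j + 1L, g$k + 1L),
    nid(g$i,      g$j + 1L, g$k + 1L)
  )
  storage.mode(elems) <- "integer"
  new("HexMesh", nodes = nodes, elems = elems, spacing = spacing)
}

#' Assemble a hexahedral mesh from voxel indices
#'
#' Internal-facing constructor used by the fixture generators: given integer
#' voxel coordinates (rows of \code{ijk}) on a grid with the given spacing
#' and origin, builds the conforming hexahedral mesh of exactly those voxels.
#'
#' @param ijk V x 3 integer matrix of voxel indices.
#' @param spacing edge length (micrometres).
#' @param origin coordinates (cm) of the corner of voxel (0,0,0).
#' @return a [HexMesh-class] whose element order follows the rows of ijk.
#' @export
voxelMesh <- function(ijk, spacing, origin = c(0, 0, 0)) {
  stopifnot(ncol(ijk) == 3L, nrow(ijk) >= 1L)
  h <- spacing * 1e-4
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  ni <- max(ijk[, 1]) + 2L
  nj <- max(ijk[, 2]) + 2L
  keys <- matrix(0, nrow(ijk), 8L)
  corners <- vector("list", 8L)
  for (c8 in 1:8) {
    ic <- sweep(ijk, 2L, off[c8, ], "+")
    corners[[c8]] <- ic
    keys[, c8] <- ic[, 1] + ni * (ic[, 2] + nj * ic[, 3])
  }
  uk <- sort(unique(as.vector(keys)))
  idx <- matrix(match(as.vector(keys), uk), nrow(ijk), 8L)
  ## reconstruct unique corner coordinates
  k3 <- uk %/% (ni * nj)
  r <- uk %% (ni * nj)
  j3 <- r %/% ni
  i3 <- r %% ni
  nodes <- cbind(origin[1] + i3 * h, origin[2] + j3 * h, origin[3] + k3 * h)
  storage.mode(idx) <- "integer"
  new("HexMesh", nodes = nodes, elems = idx, spacing = spacing)
}

#' Element centroids
#' @param mesh a [HexMesh-class].
#' @return E x 3 matrix (cm).
#' @export
elementCenters <- function(mesh) {
  e <- mesh@elems
  out <- matrix(0, nrow(e), 3L)
  for (c8 in 1:8) out <- out + mesh@nodes[e[, c8], , drop = FALSE]
  out / 8
}

#' Element volumes
#' @param mesh a [HexMesh-class].
#' @return numeric vector (cm^3); constant for regular meshes.
#' @export
elementVolumes <- function(mesh) {
  h <- mesh@spacing * 1e-4
  rep(h^3, nrow(mesh@elems))
}

#' Assign fibre directions from regional principal vectors
#'
#' The longitudinal fibre direction of each element is the normalized cross
#' product of the principal direction vector of the element's region with
#' the outward normal of the external surface at that element. The result is
#' a unit vector tangential to the local wall plane.
#'
#' @param mesh a [HexMesh-class].
#' @param labels region label per element.
#' @param principal named list or matrix mapping each region present in
#'   \code{labels} to a 3-vector (need not be unit length).
#' @param normals E x 3 outward surface normals; defaults to +z for flat
#'   slab meshes (shell builders supply their own).
#' @return E x 3 matrix of unit fibre vectors.
#' @examples
#' m <- buildSlab(4, 4, 1)
#' f <- assignFibres(m, rep("RA", nElements(m)), list(RA = c(1, 0, 0)))
#' f[1, ]   # x-hat x z-hat = -y-hat
#' @export
assignFibres <- function(mesh, labels, principal, normals = NULL) {
  ne <- nElements(mesh)
  stopifnot(length(labels) == ne)
  if (is.null(normals)) normals <- matrix(rep(c(0, 0, 1), each = ne), ne, 3L)
  stopifnot(nrow(normals) == ne, ncol(normals) == 3L)
  if (is.matrix(principal))
    principal <- setNames(lapply(seq_len(nrow(principal)),
                                 function(i) principal[i, ]),
                          rownames(principal))
  miss <- setdiff(unique(labels), names(principal))
  if (length(miss))
    stop("no principal vector for region(s): ", paste(miss, collapse = ", "))
  P <- do.call(rbind, principal[labels])
  dimnames(P) <- NULL
  fib <- cbind(P[, 2] * normals[, 3] - P[, 3] * normals[, 2],
               P[, 3] * normals[, 1] - P[, 1] * normals[, 3],
               P[, 1] * normals[, 2] - P[, 2] * normals[, 1])
  nrm <- sqrt(rowSums(fib^2))
  bad <- which(nrm < 1e-8 * sqrt(rowSums(P^2)) | nrm == 0)
  if (length(bad))
    stop("principal vector parallel to surface normal (zero cross product) ",
         "at element(s): ", paste(head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) sprintf(" (+%d more)", length(bad) - 10L))
  fib <- fib / nrm
  dimnames(fib) <- NULL
  fib
}
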