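## Simplified heterogeneous torso volume conductor: structured tetrahedral
## mesh with embedded organs, quasi-static Laplace solve with Dirichlet
## data on an inner source layer at a nominal 0.8 mm offset from the
## atrial surface, zero-flux skin boundary.

#' Organ conductivity table
#'
#' Isotropic conductivities (mS/cm) of the torso compartments:
#' myocardium 4.589, bone 0.200, liver 0.277, lung 0.389, chest (general
#' torso) 2.390, blood 7.0.
#'
#' @return named numeric vector.
#' @export
organConductivityTable <- function() {
  c(myocardium = 4.589, bone = 0.200, liver = 0.277, lung = 0.389,
    chest = 2.390, blood = 7.0)
}

## default construction parameters of the toy torso
simplifiedTorsoConfig <- function(...) {
  cfg <- list(
    box_lo = c(-18, -13, -26), box_hi = c(18, 13, 18),  # cm, front = -y
    h = 2,                                  # cm, target element size
    atrial_surface = list(center = c(0, 0, 0), radii = c(4.6, 3.2, 3.4)),
    source_offset = 0.08,                   # cm = 0.8 mm
    blood_fraction = 0.78,                  # inner part of the cavity
    lungs = TRUE, liver = TRUE, bone = TRUE, ventricle = TRUE,
    heart = TRUE,
    ventricle_shape = list(center = c(0, -1, -8.5), radii = c(4.5, 3.5, 4)),
    lung_centers = list(c(-10, 0, 2), c(10, 0, 2)),
    lung_radii = c(5, 4.5, 8),
    liver_box = list(lo = c(1, -9, -20), hi = c(13, 7, -13)),
    spine_center = c(0, 10.5), spine_radius = 1.8
  )
  ov <- list(...)
  cfg[names(ov)] <- ov   # top-level replacement (no recursive merging)
  cfg
}

#' Build the simplified torso model
#'
#' Structured tetrahedral mesh (six tetrahedra per grid cube, conforming
#' Kuhn decomposition) of a torso box with embedded simplified organs: two
#' lung ellipsoids, a liver block, a spine column (bone), a passive
#' ventricle ellipsoid (myocardium) and a blood/myocardium shell around the
#' atrial cavity; everything else is general chest. Organ membership is
#' decided at element centroids; overlapping organ definitions are an
#' error. The inner source layer is the set of nodes within half an
#' element size of the nominal 0.8 mm offset surface outside the atrial
#' boundary.
#'
#' @param ... configuration overrides (see source; organ flags
#'   \code{lungs}, \code{liver}, \code{bone}, \code{ventricle},
#'   \code{heart} can be switched off; with all off the torso is a single
#'   homogeneous "chest" compartment).
#' @return list with \code{torso} ([TorsoMesh-class]) and
#'   \code{conductivities} (named vector).
#' @export
buildSimplifiedTorso <- function(...) {
  cfg <- simplifiedTorsoConfig(...)
  h <- cfg$h
  n <- ceiling((cfg$box_hi - cfg$box_lo) / h)
  xs <- cfg$box_lo[1] + (0:n[1]) * h
  ys <- cfg$box_lo[2] + (0:n[2]) * h
  zs <- cfg$box_lo[3] + (0:n[3]) * h
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs,
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) 1L + i + (n[1] + 1L) * (j + (n[2] + 1L) * k)
  g <- expand.grid(i = 0:(n[1] - 1L), j = 0:(n[2] - 1L), k = 0:(n[3] - 1L))
  v <- cbind(nid(g$i, g$j, g$k),           # 000
             nid(g$i + 1L, g$j, g$k),      # 100
             nid(g$i, g$j + 1L, g$k),      # 010
             nid(g$i + 1L, g$j + 1L, g$k), # 110
             nid(g$i, g$j, g$k + 1L),      # 001
             nid(g$i + 1L, g$j, g$k + 1L), # 101
             nid(g$i, g$j + 1L, g$k + 1L), # 011
             nid(g$i + 1L, g$j + 1L, g$k + 1L)) # 111
  ## six tets around the main diagonal 000-111 (conforming across cubes)
  tets <- rbind(
    cbind(v[, 1], v[, 2], v[, 4], v[, 8]),
    cbind(v[, 1], v[, 4], v[, 3], v[, 8]),
    cbind(v[, 1], v[, 3], v[, 7], v[, 8]),
    cbind(v[, 1], v[, 7], v[, 5], v[, 8]),
    cbind(v[, 1], v[, 5], v[, 6], v[, 8]),
    cbind(v[, 1], v[, 6], v[, 2], v[, 8])
  )
  storage.mode(tets) <- "integer"
  ctr <- (nodes[tets[, 1], ] + nodes[tets[, 2], ] + nodes[tets[, 3], ] +
            nodes[tets[, 4], ]) / 4

  inEll <- function(x, centre, radii)
    rowSums(sweep(sweep(x, 2L, centre), 2L, radii, "/")^2) < 1

  claims <- list()
  organ <- rep("chest", nrow(tets))
  if (isTRUE(cfg$heart)) {
    atr <- cfg$atrial_surface
    rho <- sqrt(rowSums(sweep(sweep(ctr, 2L, atr$center), 2L, atr$radii,
                              "/")^2))
    heart <- rho < 1
    claims$heart <- heart
    organ[heart & rho < cfg$blood_fraction] <- "blood"
    organ[heart & rho >= cfg$blood_fraction] <- "myocardium"
  }
  if (isTRUE(cfg$lungs)) {
    lung <- inEll(ctr, cfg$lung_centers[[1]], cfg$lung_radii) |
      inEll(ctr, cfg$lung_centers[[2]], cfg$lung_radii)
    claims$lungs <- lung
    organ[lung] <- "lung"
  }
  if (isTRUE(cfg$liver)) {
    lb <- cfg$liver_box
    liv <- ctr[, 1] > lb$lo[1] & ctr[, 1] < lb$hi[1] &
      ctr[, 2] > lb$lo[2] & ctr[, 2] < lb$hi[2] &
      ctr[, 3] > lb$lo[3] & ctr[, 3] < lb$hi[3]
    claims$liver <- liv
    organ[liv] <- "liver"
  }
  if (isTRUE(cfg$bone)) {
    sp <- (ctr[, 1] - cfg$spine_center[1])^2 +
      (ctr[, 2] - cfg$spine_center[2])^2 < cfg$spine_radius^2
    claims$bone <- sp
    organ[sp] <- "bone"
  }
  if (isTRUE(cfg$ventricle)) {
    ven <- inEll(ctr, cfg$ventricle_shape$center, cfg$ventricle_shape$radii)
    claims$ventricle <- ven
    organ[ven] <- "myocardium"
  }
  if (length(claims) > 1L) {
    overlap <- Reduce(`+`, claims)
    if (any(overlap > 1L))
      stop("organ definitions overlap at ", sum(overlap > 1L),
           " elements; adjust the configuration")
  }

  ## inner source layer: nodes within h/2 of the 0.8 mm offset surface
  atr <- cfg$atrial_surface
  dn <- .ellipsoidRadialDist(nodes, atr$center, atr$radii)
  inner <- which(abs(dn - cfg$source_offset) <= h / 2 + 1e-9)
  onBox <- nodes[, 1] %in% range(xs) | nodes[, 2] %in% range(ys) |
    nodes[, 3] %in% range(zs)

  torso <- new("TorsoMesh", nodes = nodes, tets = tets, organ = organ,
               innerLayer = as.integer(inner),
               outerSurface = as.integer(which(onBox)),
               grid = list(origin = cfg$box_lo, h = h, dims = n,
                           atrial_surface = atr,
                           source_offset = cfg$source_offset))
  list(torso = torso, conductivities = organConductivityTable())
}

## P1 stiffness matrix of the tetrahedral mesh with per-element isotropic
## conductivity (mS/cm); vectorized over elements
.tetStiffness <- function(torso, sigmaByElement) {
  nd <- torso@nodes
  tt <- torso@tets
  p1 <- nd[tt[, 1], , drop = FALSE]
  e1 <- nd[tt[, 2], , drop = FALSE] - p1
  e2 <- nd[tt[, 3], , drop = FALSE] - p1
  e3 <- nd[tt[, 4], , drop = FALSE] - p1
  cx <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  det6 <- rowSums(e1 * cx(e2, e3))          # 6 * signed volume
  vol <- abs(det6) / 6
  if (any(vol <= 0)) stop("degenerate tetrahedra in torso mesh")
  ## gradients of the barycentric shape functions
  g2 <- cx(e2, e3) / det6
  g3 <- cx(e3, e1) / det6
  g4 <- cx(e1, e2) / det6
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)
  nn <- nrow(nd)
  ii <- vector("list", 16L); jj <- vector("list", 16L); vv <- vector("list", 16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    ii[[k]] <- tt[, i]
    jj[[k]] <- tt[, j]
    vv[[k]] <- sigmaByElement * vol * rowSums(G[[i]] * G[[j]])
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
               dims = c(nn, nn))
}

#' Solve the quasi-static torso Laplace problem
#'
#' Finite-element solve of div(D_T grad V_T) = 0 on the torso with the
#' heterogeneous organ conductivities, Dirichlet values on the inner source
#' layer and homogeneous Neumann (zero flux) on the skin. Each time step of
#' the source potentials is solved independently (quasi-static assumption);
#' a matrix of inner values yields a matrix of node potentials.
#'
#' @param torso a [TorsoMesh-class].
#' @param conductivities named conductivity table covering every organ
#'   label (mS/cm).
#' @param innerValues numeric vector (one value per inner-layer node) or
#'   matrix (layer nodes x time steps) of source potentials (mV).
#' @param dirichletNodes node indices carrying the Dirichlet data
#'   (default: the torso's inner layer).
#' @return matrix of potentials, nodes x time steps (a vector input yields
#'   a one-column matrix).
#' @export
solveTorsoLaplace <- function(torso, conductivities = organConductivityTable(),
                              innerValues,
                              dirichletNodes = torso@innerLayer) {
  miss <- setdiff(unique(torso@organ), names(conductivities))
  if (length(miss))
    stop("no conductivity for organ label(s): ", paste(miss, collapse = ", "))
  if (!length(dirichletNodes)) stop("empty Dirichlet set (singular system)")
  iv <- if (is.matrix(innerValues)) innerValues else
    matrix(innerValues, ncol = 1L)
  if (nrow(iv) != length(dirichletNodes))
    stop("innerValues must have one row per Dirichlet node")
  sigma <- unname(conductivities[torso@organ])
  K <- .tetStiffness(torso, sigma)
  nn <- nrow(torso@nodes)
  fixed <- dirichletNodes
  free <- setdiff(seq_len(nn), fixed)
  Kff <- forceSymmetric(K[free, free])
  Kfd <- K[free, fixed, drop = FALSE]
  ch <- Matrix::Cholesky(Kff, LDL = FALSE)
  out <- matrix(0, nn, ncol(iv))
  out[fixed, ] <- iv
  rhs <- -as.matrix(Kfd %*% iv)
  out[free, ] <- as.matrix(Matrix::solve(ch, rhs))
  out
}

#' Standard lead positions on the toy torso
#'
#' Precordial leads V1-V6 on the front chest at heart height, limb-
#' equivalent points RA/LA (shoulders) and LL (lower left trunk), and a
#' 3 x 3 rear grid N1-N9. Bipolar standard leads are formed as
#' D1 = LA - RA, D2 = LL - RA, D3 = LL - LA.
#'
#' @param torso a [TorsoMesh-class] built by [buildSimplifiedTorso()].
#' @return list with \code{points} (data.frame lead/x/y/z) and
#'   \code{bipolar} (named list of (+,-) lead pairs).
#' @export
standardTorsoLeads <- function(torso) {
  g <- torso@grid
  lo <- g$origin; hi <- g$origin + g$h * g$dims
  front <- lo[2]; back <- hi[2]
  zh <- 0   # heart height
  pts <- rbind(
    data.frame(lead = paste0("V", 1:6),
               x = c(-1.5, 1.5, 3.5, 5.5, 7.5, 9.0),
               y = front, z = c(2, 2, 0, -1, -1, -1)),
    data.frame(lead = c("RA", "LA", "LL"),
               x = c(-hi[1] + 1, hi[1] - 1, hi[1] - 3),
               y = c(0, 0, 0), z = c(hi[3] - 1, hi[3] - 1, lo[3] + 1)),
    data.frame(lead = paste0("N", 1:9),
               x = rep(c(-7, 0, 7), 3),
               y = back, z = rep(c(6, 0, -6), each = 3))
  )
  list(points = pts,
       bipolar = list(D1 = c("LA", "RA"), D2 = c("LL", "RA"),
                      D3 = c("LL", "LA")))
}

#' Interpolate lead traces from torso potential fields
#'
#' Barycentric (linear finite-element) interpolation of the node potential
#' field at each observation point, per time step; points must lie inside
#' the torso mesh. Optional bipolar leads are appended as differences of
#' unipolar columns.
#'
#' @param fields nodes x time matrix from [solveTorsoLaplace()].
#' @param torso a [TorsoMesh-class].
#' @param points data.frame lead/x/y/z.
#' @param time time grid (ms) for the output object.
#' @param bipolar named list of c(plus, minus) lead pairs.
#' @return a [LeadTraces-class].
#' @export
extractLeads <- function(fields, torso, points, time = seq_len(ncol(fields)) - 1,
                         bipolar = NULL) {
  g <- torso@grid
  tr <- matrix(0, ncol(fields), nrow(points))
  for (p in seq_len(nrow(points))) {
    r <- c(points$x[p], points$y[p], points$z[p])
    w <- .locatePoint(torso, r)
    if (is.null(w))
      stop("lead '", points$lead[p], "' lies outside the torso mesh")
    tr[, p] <- as.vector(t(fields[w$nodes, , drop = FALSE]) %*% w$bary)
  }
  leads <- points$lead
  if (!is.null(bipolar)) {
    extra <- vapply(bipolar, function(pm) {
      tr[, match(pm[1], leads)] - tr[, match(pm[2], leads)]
    }, numeric(nrow(tr)))
    tr <- cbind(tr, extra)
    leads <- c(leads, names(bipolar))
  }
  new("LeadTraces", traces = tr, time = time, leads = leads)
}

## locate a point in the structured tet mesh: cube lookup, then barycentric
## test of its six tets
.locatePoint <- function(torso, r) {
  g <- torso@grid
  if (any(r < g$origin - 1e-9) || any(r > g$origin + g$h * g$dims + 1e-9))
    return(NULL)
  ## clamp so points exactly on the outer faces fall in the last cube
  ijk <- pmin(pmax(floor((r - g$origin) / g$h), 0), g$dims - 1L)
  n <- g$dims
  cube <- 1L + ijk[1] + n[1] * (ijk[2] + n[2] * ijk[3])
  ncubes <- prod(n)
  cand <- cube + ncubes * (0:5)
  for (e in cand) {
    tt <- torso@tets[e, ]
    p1 <- torso@nodes[tt[1], ]
    M <- cbind(torso@nodes[tt[2], ] - p1, torso@nodes[tt[3], ] - p1,
               torso@nodes[tt[4], ] - p1)
    b <- solve(M, r - p1)
    bary <- c(1 - sum(b), b)
    if (all(bary >= -1e-9)) return(list(nodes = tt, bary = bary))
  }
  NULL
}

#' Couple a monodomain run to the torso model
#'
#' Two-stage forward computation: the infinite-medium integral evaluates
#' the extracellular potential of the atrial sources at the inner torso
#' layer (nominal 0.8 mm offset), those values are imposed as Dirichlet
#' data, and the heterogeneous Laplace problem propagates them to the
#' whole torso per output time step.
#'
#' @param vm a [VmSeries-class] (atrial sources inside the torso cavity).
#' @param torso a [TorsoMesh-class].
#' @param conductivities organ conductivity table (mS/cm).
#' @param gamma,sigmaRatio pseudo-ECG scale factors for the source stage.
#' @return list with \code{fields} (nodes x time) and \code{innerValues}.
#' @export
forwardTorso <- function(vm, torso, conductivities = organConductivityTable(),
                         gamma = 1, sigmaRatio = 1) {
  layer <- torso@innerLayer
  pts <- observationPoints(paste0("L", seq_along(layer)),
                           torso@nodes[layer, 1], torso@nodes[layer, 2],
                           torso@nodes[layer, 3])
  src <- computePseudoEcg(vm, pts, gamma = gamma, sigmaRatio = sigmaRatio)
  inner <- t(src@traces)   # layer nodes x time
  fields <- solveTorsoLaplace(torso, conductivities, inner)
  list(fields = fields, innerValues = inner)
}
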