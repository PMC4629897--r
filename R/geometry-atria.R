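## Idealized bi-atrial surrogate: two ellipsoidal shells with vein/valve
## ostia, 21 anatomical region labels painted by angular sectors, linear
## bundle tracts (crista terminalis, pectinate muscles, Bachmann bundle)
## and fibres assigned by the cross-product rule.
##
## This is a desk-scale geometric surrogate for a full anatomical atrial
## mesh: region shapes, bundle paths and principal directions are plausible
## but synthetic, and are documented as such.

#' The 21-region atrial label vocabulary
#'
#' Right atrium: sinoatrial node (SAN), crista terminalis (CT), Bachmann
#' bundle right limb (BBR), intercaval bundle (IB), septum (RAS), lateral
#' wall (RLW), appendage (RAA), pectinate muscles (PM), isthmus (IST),
#' superior/inferior cava veins (SCV, ICV), tricuspid valve ring (TV).
#' Left atrium: Bachmann bundle left limb (BBL), superior wall (LSW),
#' septum (LAS), appendage (LAA), posterior wall (LPW), mitral valve ring
#' (MV), right/left pulmonary veins (RPV, LPV), coronary sinus (CS).
#' The fossa ovalis and its limb (FO, LFO) are an optional extension
#' (see \code{includeFo} in [buildIdealizedAtria()]).
#'
#' @param extended include FO and LFO.
#' @return character vector of labels.
#' @export
regionVocabulary <- function(extended = FALSE) {
  core <- c("SAN", "CT", "BBR", "BBL", "IB", "RAS", "RLW", "RAA", "PM",
            "IST", "SCV", "ICV", "TV", "LSW", "LAS", "LAA", "LPW", "MV",
            "RPV", "LPV", "CS")
  if (extended) c(core, "FO", "LFO") else core
}

## geometry helpers -----------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))

## radial distance from points x (n x 3) to an ellipsoid surface, along
## the ray from the centre; negative inside.
.ellipsoidRadialDist <- function(x, centre, radii) {
  d <- sweep(x, 2L, centre)
  rr <- sqrt(rowSums(d^2))
  rhat <- d / pmax(rr, 1e-12)
  rdir <- 1 / sqrt(rowSums(sweep(rhat, 2L, radii, "/")^2))
  rr - rdir
}

## outward unit normals of an ellipsoid at points x
.ellipsoidNormal <- function(x, centre, radii) {
  g <- sweep(sweep(x, 2L, centre), 2L, radii^2, "/")
  g / sqrt(rowSums(g^2))
}

.angleTo <- function(n, axis) acos(pmin(1, pmax(-1, n %*% .unit(axis)))) * 180 / pi

## default construction parameters of the surrogate
idealizedAtriaConfig <- function(...) {
  cfg <- list(
    spacing = 900,                 # um
    wall_thickness = 900,          # um, within the 600-900 um band
    ra_center = c(-2.0, 0, 0), ra_radii = c(1.9, 1.7, 1.9),
    la_center = c(2.0, 0, 0),  la_radii = c(1.8, 1.6, 1.7),
    bb_attach = c(0.55, -0.25, 0.80),  # attachment direction (mirrored for LA)
    ## tube radius keeps the bundle cross-section small enough for the
    ## one-voxel shell to drive it (conduction safety at the junction)
    bb_radius = 0.14,              # cm
    fo_attach = c(0.85, 0.35, -0.15),
    fo_radius = 0.10,              # cm
    includeFo = FALSE
  )
  ov <- list(...)
  cfg[names(ov)] <- ov   # top-level replacement (no recursive merging)
  cfg
}

## vessel/valve ostium axes and angular extents (degrees)
.raOstia <- function() list(
  SCV = list(axis = c(0, 0.35, 0.94), hole = 18, ring = 30),
  ICV = list(axis = c(0, 0.55, -0.84), hole = 20, ring = 32),
  TV  = list(axis = c(0, -0.71, -0.71), hole = 30, ring = 40)
)
.laOstia <- function() list(
  RPV = list(axis = c(-0.45, 0.85, 0.30), hole = 16, ring = 28),
  LPV = list(axis = c(0.45, 0.85, 0.30), hole = 16, ring = 28),
  MV  = list(axis = c(0, -0.71, -0.71), hole = 30, ring = 40)
)

## surrogate principal direction per region (free vectors, normalized by
## the fibre rule); circumferential regions use their ostium axis.
.principalVectors <- function() {
  ra <- .raOstia(); la <- .laOstia()
  list(
    SAN = c(0, 1, 0), CT = c(0, 1, 0), PM = c(0, 0, 1),
    SCV = ra$SCV$axis, ICV = ra$ICV$axis, TV = ra$TV$axis,
    IST = ra$TV$axis,
    RAS = c(0, 1, 0), IB = c(1, 0, 0),
    RAA = c(0.2, 0.87, 0.45), RLW = c(0.2, 0.87, 0.45),
    BBR = c(0, 1, 0), BBL = c(0, 1, 0),
    LAS = c(0, 1, 0), LSW = c(0, 1, 0), LAA = c(0, 0, 1),
    LPW = c(0.3, 1, 0),
    MV = la$MV$axis, RPV = la$RPV$axis, LPV = la$LPV$axis,
    CS = c(0, 1, 0),
    FO = c(0, 1, 0), LFO = c(0, 1, 0)
  )
}

## paint RA shell labels from unit normals (rows of n); first match wins
.paintRA <- function(n) {
  o <- .raOstia()
  aS <- .angleTo(n, o$SCV$axis)
  aI <- .angleTo(n, o$ICV$axis)
  aT <- .angleTo(n, o$TV$axis)
  nx <- n[, 1]; ny <- n[, 2]; nz <- n[, 3]
  lab <- rep(NA_character_, nrow(n))
  ct <- nx < 0 & abs(ny) < 0.20
  pm <- ny < -0.2 & nx < 0.3 &
    (abs(nz - 0.40) < 0.08 | abs(nz - 0.10) < 0.08)
  pick <- function(cond, name) lab[is.na(lab) & cond] <<- name
  pick(ct & nz > 0.55, "SAN")
  pick(ct, "CT")
  pick(aS < o$SCV$ring, "SCV")
  pick(aI < o$ICV$ring, "ICV")
  pick(aT < o$TV$ring, "TV")
  pick(nz < -0.75, "IST")
  pick(pm, "PM")
  pick(nx > 0.45, "RAS")
  pick(nz > 0.30 & ny > 0.25, "IB")
  pick(ny < -0.25 & nz > -0.2, "RAA")
  lab[is.na(lab)] <- "RLW"
  lab
}

## paint LA shell labels
.paintLA <- function(n) {
  o <- .laOstia()
  aR <- .angleTo(n, o$RPV$axis)
  aL <- .angleTo(n, o$LPV$axis)
  aM <- .angleTo(n, o$MV$axis)
  nx <- n[, 1]; ny <- n[, 2]; nz <- n[, 3]
  lab <- rep(NA_character_, nrow(n))
  pick <- function(cond, name) lab[is.na(lab) & cond] <<- name
  pick(aR < o$RPV$ring, "RPV")
  pick(aL < o$LPV$ring, "LPV")
  pick(ny > 0.25 & nz < -0.45, "CS")
  pick(aM < o$MV$ring, "MV")
  pick(nx < -0.50, "LAS")
  pick(nz > 0.45, "LSW")
  pick(ny < -0.30, "LAA")
  lab[is.na(lab)] <- "LPW"
  lab
}

## voxel centres within a tube of given radius around segment p0-p1
.inTube <- function(x, p0, p1, radius, extend = 0) {
  ax <- p1 - p0
  L <- sqrt(sum(ax^2))
  u <- ax / L
  d <- sweep(x, 2L, p0)
  tpar <- d %*% u
  perp2 <- rowSums(d^2) - tpar^2
  as.vector(tpar > -extend & tpar < L + extend & perp2 < radius^2)
}

#' Build the idealized bi-atrial surrogate
#'
#' Voxelizes two ellipsoidal shells (right and left atrium) of one-element
#' wall thickness at the requested spacing, opens vein and valve ostia,
#' paints the 21 anatomical region labels by angular sectors, adds the
#' Bachmann bundle as a roof tube connecting the chambers (right limb BBR,
#' left limb BBL) with the sinoatrial node patch at the top of the crista
#' terminalis strip, and assigns fibres with the cross-product rule from
#' per-region surrogate principal directions.
#'
#' With \code{includeFo = TRUE} a second, thinner interatrial tract (LFO)
#' and a fossa ovalis patch (FO) are added, extending the label set to 23.
#'
#' @param ... configuration overrides (see source: spacing, wall_thickness
#'   in um, shell centres/radii in cm, bundle attachment and radius,
#'   includeFo).
#' @return list with components \code{mesh} ([HexMesh-class]),
#'   \code{labels} (per element), \code{fibres}, \code{normals} (E x 3),
#'   \code{principal} (the direction map), \code{ijk} (voxel indices) and
#'   \code{config}.
#' @export
buildIdealizedAtria <- function(...) {
  cfg <- idealizedAtriaConfig(...)
  h <- cfg$spacing * 1e-4
  th <- cfg$wall_thickness * 1e-4
  if (th < h) stop("wall thickness (", cfg$wall_thickness,
                   " um) must be >= spacing (", cfg$spacing, " um)")

  lo <- pmin(cfg$ra_center - cfg$ra_radii, cfg$la_center - cfg$la_radii) - 2 * h
  hi <- pmax(cfg$ra_center + cfg$ra_radii, cfg$la_center + cfg$la_radii) + 2 * h
  nijk <- ceiling((hi - lo) / h)
  g <- expand.grid(i = 0:(nijk[1] - 1L), j = 0:(nijk[2] - 1L),
                   k = 0:(nijk[3] - 1L))
  ctr <- cbind(lo[1] + (g$i + 0.5) * h, lo[2] + (g$j + 0.5) * h,
               lo[3] + (g$k + 0.5) * h)

  dRA <- .ellipsoidRadialDist(ctr, cfg$ra_center, cfg$ra_radii)
  dLA <- .ellipsoidRadialDist(ctr, cfg$la_center, cfg$la_radii)
  inRA <- abs(dRA) <= th / 2
  inLA <- abs(dLA) <= th / 2 & !inRA

  nRA <- .ellipsoidNormal(ctr[inRA, , drop = FALSE], cfg$ra_center, cfg$ra_radii)
  nLA <- .ellipsoidNormal(ctr[inLA, , drop = FALSE], cfg$la_center, cfg$la_radii)

  ## open the ostia
  holeRA <- rep(FALSE, nrow(nRA))
  for (o in .raOstia()) holeRA <- holeRA | .angleTo(nRA, o$axis) < o$hole
  holeLA <- rep(FALSE, nrow(nLA))
  for (o in .laOstia()) holeLA <- holeLA | .angleTo(nLA, o$axis) < o$hole

  keepRA <- which(inRA)[!holeRA]
  keepLA <- which(inLA)[!holeLA]
  nRA <- nRA[!holeRA, , drop = FALSE]
  nLA <- nLA[!holeLA, , drop = FALSE]

  labRA <- .paintRA(nRA)
  labLA <- .paintLA(nLA)

  ## Bachmann bundle tube across the roof
  pR <- cfg$ra_center + cfg$ra_radii * .unit(cfg$bb_attach)
  pL <- cfg$la_center + cfg$la_radii * .unit(cfg$bb_attach * c(-1, 1, 1))
  inBB <- .inTube(ctr, pR, pL, cfg$bb_radius, extend = 2.5 * h)
  bbOnly <- which(inBB & !(seq_len(nrow(ctr)) %in% c(keepRA, keepLA)) &
                    abs(dRA) > th / 2 & abs(dLA) > th / 2)
  ## shell voxels under the bundle footprint are relabelled to the bundle
  mid <- (cfg$ra_center[1] + cfg$la_center[1]) / 2
  bbShellRA <- .inTube(ctr[keepRA, , drop = FALSE], pR, pL, cfg$bb_radius,
                       extend = 2.5 * h)
  bbShellLA <- .inTube(ctr[keepLA, , drop = FALSE], pR, pL, cfg$bb_radius,
                       extend = 2.5 * h)
  labRA[bbShellRA] <- "BBR"
  labLA[bbShellLA] <- "BBL"

  idx <- c(keepRA, keepLA, bbOnly)
  labels <- c(labRA, labLA,
              ifelse(ctr[bbOnly, 1] < mid, "BBR", "BBL"))
  normals <- rbind(nRA, nLA,
                   matrix(rep(c(0, 0, 1), length(bbOnly)), ncol = 3L,
                          byrow = TRUE))

  ## optional fossa ovalis tract
  if (isTRUE(cfg$includeFo)) {
    pRf <- cfg$ra_center + cfg$ra_radii * .unit(cfg$fo_attach)
    pLf <- cfg$la_center + cfg$la_radii * .unit(cfg$fo_attach * c(-1, 1, 1))
    inFo <- .inTube(ctr, pRf, pLf, cfg$fo_radius, extend = 2.5 * h)
    foOnly <- setdiff(which(inFo), idx)
    foOnly <- foOnly[abs(dRA[foOnly]) > th / 2 & abs(dLA[foOnly]) > th / 2]
    raSide <- seq_along(keepRA)
    nearFo <- .inTube(ctr[idx, , drop = FALSE], pRf, pLf,
                      cfg$fo_radius + 0.5 * h, extend = 2.5 * h)
    labels[nearFo & seq_along(idx) %in% raSide] <- "FO"
    idx <- c(idx, foOnly)
    labels <- c(labels, rep("LFO", length(foOnly)))
    normals <- rbind(normals,
                     matrix(rep(c(0, 0, 1), length(foOnly)), ncol = 3L,
                            byrow = TRUE))
  }

  ijk <- cbind(g$i[idx], g$j[idx], g$k[idx])
  mesh <- voxelMesh(ijk, cfg$spacing, origin = lo)
  fib <- assignFibres(mesh, labels, .principalVectors(), normals)

  list(mesh = mesh, labels = labels, fibres = fib, normals = normals,
       principal = .principalVectors(), ijk = ijk, config = cfg)
}

#' Face-adjacency test between two labelled voxel sets
#'
#' @param ijk voxel index matrix of the mesh (as returned by
#'   [buildIdealizedAtria()]).
#' @param labels element labels.
#' @param a,b two labels.
#' @return TRUE if some element of a shares a face with some element of b.
#' @export
regionsShareFace <- function(ijk, labels, a, b) {
  ia <- ijk[labels == a, , drop = FALSE]
  ib <- ijk[labels == b, , drop = FALSE]
  if (!nrow(ia) || !nrow(ib)) return(FALSE)
  key <- function(m) m[, 1] + 4096 * (m[, 2] + 4096 * m[, 3])
  kb <- key(ib)
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    if (any(key(sweep(ia, 2L, d, "+")) %in% kb)) return(TRUE)
  }
  FALSE
}
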