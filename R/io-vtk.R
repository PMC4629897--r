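## Minimal legacy-ASCII VTK unstructured-grid I/O for hexahedral and
## tetrahedral meshes with named CELL_DATA / POINT_DATA arrays. Covers the
## subset of the format this package writes; no installed R package
## provides VTK unstructured grids, so this is implemented here.

#' Write a mesh with named fields as a legacy VTK file
#'
#' @param mesh a [HexMesh-class] or [TorsoMesh-class].
#' @param file output path.
#' @param cellData named list of per-element fields: numeric/integer/
#'   character vectors (scalars) or E x 3 matrices (vectors).
#' @param pointData named list of per-node fields, same conventions.
#' @return the file path, invisibly.
#' @export
writeFieldVTK <- function(mesh, file, cellData = list(), pointData = list()) {
  isHex <- is(mesh, "HexMesh")
  elems <- if (isHex) mesh@elems else mesh@tets
  nodes <- meshNodes(mesh)
  npe <- ncol(elems)
  vtkType <- if (isHex) 12L else 10L

  checkFields <- function(fields, nEntity, what) {
    for (nm in names(fields)) {
      if (!nzchar(nm)) stop("empty field name in ", what)
      f <- fields[[nm]]
      len <- if (is.matrix(f)) nrow(f) else length(f)
      if (len != nEntity)
        stop("field '", nm, "' has length ", len, " but ", what,
             " expects ", nEntity)
    }
  }
  if (length(cellData) && is.null(names(cellData)))
    stop("cellData fields must be named")
  if (length(pointData) && is.null(names(pointData)))
    stop("pointData fields must be named")
  checkFields(cellData, nrow(elems), "CELL_DATA")
  checkFields(pointData, nrow(nodes), "POINT_DATA")

  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("AtriaSim field export")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS ", nrow(nodes), " double")
  writeLines(apply(format(nodes, digits = 17, trim = TRUE, scientific = FALSE),
                   1L, paste, collapse = " "), con)
  w("CELLS ", nrow(elems), " ", nrow(elems) * (npe + 1L))
  writeLines(paste(npe, apply(elems - 1L, 1L, paste, collapse = " ")), con)
  w("CELL_TYPES ", nrow(elems))
  writeLines(as.character(rep(vtkType, nrow(elems))), con)

  writeFields <- function(fields, header, nEntity) {
    if (!length(fields)) return(invisible())
    w(header, " ", nEntity)
    for (nm in names(fields)) {
      f <- fields[[nm]]
      if (is.matrix(f)) {
        w("VECTORS ", nm, " double")
        writeLines(apply(format(f, digits = 17, trim = TRUE,
                                scientific = FALSE), 1L, paste,
                         collapse = " "), con)
      } else if (is.character(f) || is.factor(f)) {
        lev <- sort(unique(as.character(f)))
        w("SCALARS ", nm, " int 1")
        w("LOOKUP_TABLE default")
        writeLines(as.character(match(as.character(f), lev) - 1L), con)
        w("METADATA levels ", nm, " ", paste(lev, collapse = " "))
      } else if (is.integer(f)) {
        w("SCALARS ", nm, " int 1")
        w("LOOKUP_TABLE default")
        writeLines(as.character(f), con)
      } else {
        w("SCALARS ", nm, " double 1")
        w("LOOKUP_TABLE default")
        writeLines(format(f, digits = 17, trim = TRUE, scientific = FALSE),
                   con)
      }
    }
  }
  writeFields(cellData, "CELL_DATA", nrow(elems))
  writeFields(pointData, "POINT_DATA", nrow(nodes))
  invisible(file)
}

#' Read a legacy VTK unstructured grid written by [writeFieldVTK()]
#'
#' @param file path to a VTK file.
#' @return list with \code{nodes}, \code{elems}, \code{cellType} (12 hex /
#'   10 tet), \code{cellData}, \code{pointData}.
#' @export
readFieldVTK <- function(file) {
  ln <- readLines(file)
  i <- grep("^POINTS ", ln)[1L]
  np <- as.integer(strsplit(ln[i], " ")[[1L]][2L])
  nodes <- matrix(scan(text = ln[(i + 1L):(i + np)], quiet = TRUE),
                  np, 3L, byrow = TRUE)
  i <- grep("^CELLS ", ln)[1L]
  ne <- as.integer(strsplit(ln[i], " ")[[1L]][2L])
  cellRows <- strsplit(ln[(i + 1L):(i + ne)], " ")
  npe <- as.integer(cellRows[[1L]][1L])
  elems <- matrix(as.integer(unlist(lapply(cellRows, `[`, -1L))) + 1L,
                  ne, npe, byrow = TRUE)
  i <- grep("^CELL_TYPES ", ln)[1L]
  cellType <- as.integer(ln[i + 1L])

  parseFields <- function(start, stop, nEntity) {
    out <- list()
    j <- start
    while (j <= stop) {
      if (grepl("^SCALARS ", ln[j])) {
        parts <- strsplit(ln[j], " ")[[1L]]
        nm <- parts[2L]; typ <- parts[3L]
        vals <- scan(text = ln[(j + 2L):(j + 1L + nEntity)], quiet = TRUE)
        j <- j + 2L + nEntity
        if (j <= stop && grepl("^METADATA levels ", ln[j])) {
          lev <- strsplit(ln[j], " ")[[1L]][-(1:3)]
          vals <- lev[vals + 1L]
          j <- j + 1L
        } else if (typ == "int") vals <- as.integer(vals)
        out[[nm]] <- vals
      } else if (grepl("^VECTORS ", ln[j])) {
        nm <- strsplit(ln[j], " ")[[1L]][2L]
        out[[nm]] <- matrix(scan(text = ln[(j + 1L):(j + nEntity)],
                                 quiet = TRUE), nEntity, 3L, byrow = TRUE)
        j <- j + 1L + nEntity
      } else j <- j + 1L
    }
    out
  }
  ic <- grep("^CELL_DATA ", ln)
  ip <- grep("^POINT_DATA ", ln)
  endc <- if (length(ip)) ip - 1L else length(ln)
  cellData <- if (length(ic)) parseFields(ic + 1L, endc, ne) else list()
  pointData <- if (length(ip)) parseFields(ip + 1L, length(ln), np) else list()
  list(nodes = nodes, elems = elems, cellType = cellType,
       cellData = cellData, pointData = pointData)
}
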