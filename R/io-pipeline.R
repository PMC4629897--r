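## Trace CSV round-trip, run configuration, end-to-end pipeline.

#' Write lead traces as CSV
#'
#' Header row of lead names (first column \code{time_ms}), one row per
#' sample; values round-trip within 1e-9 mV.
#'
#' @param traces a [LeadTraces-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeTracesCSV <- function(traces, file) {
  stopifnot(is(traces, "LeadTraces"))
  validObject(traces)
  df <- data.frame(time_ms = traces@time, traces@traces,
                   check.names = FALSE)
  colnames(df) <- c("time_ms", traces@leads)
  write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
            file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read lead traces from CSV
#'
#' @param file path written by [writeTracesCSV()].
#' @return a [LeadTraces-class].
#' @export
readTracesCSV <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  new("LeadTraces", traces = as.matrix(df[, -1L, drop = FALSE]),
      time = df$time_ms, leads = colnames(df)[-1L])
}

#' Write a single-cell trace as CSV
#'
#' Columns: time_ms, Vm_mV, Na_mM, K_mM, Ca_mM.
#'
#' @param trace an [ActionPotentialTrace-class].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeTraceCSV <- function(trace, file) {
  df <- data.frame(time_ms = trace@time, Vm_mV = trace@Vm)
  if (nrow(trace@conc)) {
    df$Na_mM <- trace@conc[, "Na_i"]
    df$K_mM <- trace@conc[, "K_i"]
    df$Ca_mM <- trace@conc[, "Ca_i"]
  }
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

## ---------------------------------------------------------------------
## Run configuration

#' Read and validate a run configuration
#'
#' YAML file (or list) with sections \code{geometry} (kind "slab" or
#' "atria" plus parameters), \code{protocol} (stimulus settings),
#' \code{forward} (mode "pseudo" or "torso", lead set), \code{analysis}
#' (subset of lat, apd, brms, pwave, contrib) and \code{out} (output
#' directory). Unknown or missing mandatory fields raise errors naming the
#' field.
#'
#' @param config path to a YAML file, or a list.
#' @return validated configuration list (with defaults filled in).
#' @export
readRunConfig <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$geometry))
    stop("config is missing the 'geometry' section")
  if (is.null(cfg$geometry$kind) ||
      !cfg$geometry$kind %in% c("slab", "atria"))
    stop("config field 'geometry.kind' must be \"slab\" or \"atria\"")
  defaults <- list(
    protocol = list(amplitude = NA, duration = 2, nBeats = 1, bcl = 1000),
    simulation = list(time = 160, dt = 0.02, outputDt = 1,
                      stabilize = TRUE),
    forward = list(mode = "pseudo"),
    analysis = c("lat"),
    seed = 1L,
    out = tempfile("atriasim-run-")
  )
  cfg <- modifyList(defaults, cfg)
  if (!cfg$forward$mode %in% c("pseudo", "torso", "none"))
    stop("config field 'forward.mode' must be pseudo, torso or none")
  bad <- setdiff(cfg$analysis, c("lat", "apd", "brms", "pwave", "contrib"))
  if (length(bad))
    stop("unknown analysis step(s): ", paste(bad, collapse = ", "))
  cfg
}

#' Run the end-to-end pipeline
#'
#' Executes geometry generation, the monodomain simulation, the forward
#' model and the requested analyses, writing all artifacts plus a JSON
#' manifest (package version, configuration hash, stage timings, outputs)
#' to the output directory. Deterministic given an identical
#' configuration.
#'
#' @param config path to a YAML configuration or a configuration list
#'   (see [readRunConfig()]).
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- readRunConfig(config)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  manifest <- list(
    package = as.character(packageVersion("AtriaSim")),
    r_version = R.version.string,
    config_hash = .configHash(cfg),
    stages = list(), outputs = character()
  )
  tic <- function() Sys.time()
  stageTime <- function(t0) round(as.numeric(Sys.time() - t0, units = "secs"), 3)

  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## geometry ----------------------------------------------------------
  t0 <- tic()
  geo <- wrap("geometry", {
    if (cfg$geometry$kind == "slab") {
      p <- modifyList(list(nx = 50, ny = 50, nz = 3, spacing = 300,
                           region = "RA/PM"), cfg$geometry[-1])
      mesh <- buildSlab(p$nx, p$ny, p$nz, p$spacing)
      fib <- matrix(rep(c(1, 0, 0), each = nElements(mesh)), ncol = 3L)
      list(mesh = mesh, labels = rep(p$region, nElements(mesh)),
           fibres = fib, kind = "slab", params = p)
    } else {
      at <- do.call(buildIdealizedAtria, cfg$geometry[-1])
      at$kind <- "atria"
      at
    }
  })
  manifest$stages$geometry <- stageTime(t0)

  ## conductivity and cell models --------------------------------------
  regions <- sort(unique(geo$labels))
  map <- defaultRegionCellMap()
  cellOf <- function(r) if (r %in% map$region)
    map$cellRegion[match(r, map$region)] else r
  cells <- setNames(lapply(regions, function(r) makeRegionalCell(cellOf(r))),
                    regions)
  cond <- if (geo$kind == "slab") {
    cls <- conductivityTable()
    conductivityField(cls$sigmaL[cls$class == "atrial"],
                      cls$sigmaL[cls$class == "atrial"] * 0.35, geo$fibres)
  } else {
    regionConductivity(geo$labels, geo$fibres,
                       isotropic = isTRUE(cfg$simulation$isotropic))
  }

  ## monodomain ---------------------------------------------------------
  t0 <- tic()
  vm <- wrap("monodomain", {
    stimNodes <- if (geo$kind == "atria") {
      sanElems <- which(geo$labels == "SAN")
      unique(as.vector(geo$mesh@elems[sanElems, ]))
    } else {
      ## a four-node-deep face volume; a single sheet fails to capture
      h <- geo$mesh@spacing * 1e-4
      which(geo$mesh@nodes[, 1] < 3.5 * h)
    }
    amp <- cfg$protocol$amplitude
    if (is.na(amp)) amp <- if (geo$kind == "atria") 30 else 52
    stim <- stimulusSet(stimNodes, start = 0,
                        duration = cfg$protocol$duration,
                        amplitude = amp,
                        period = if (cfg$protocol$nBeats > 1)
                          cfg$protocol$bcl else NA_real_,
                        count = cfg$protocol$nBeats)
    init <- if (isTRUE(cfg$simulation$stabilize))
      setNames(lapply(regions, function(r)
        stabilizedState(cells[[r]])), regions) else NULL
    runMonodomain(geo$mesh, geo$labels, cond, cells, stim,
                  duration = cfg$simulation$time, dt = cfg$simulation$dt,
                  outputDt = cfg$simulation$outputDt, initStates = init)
  })
  manifest$stages$monodomain <- stageTime(t0)

  ## forward ------------------------------------------------------------
  t0 <- tic()
  leads <- NULL
  if (cfg$forward$mode == "pseudo") {
    leads <- wrap("forward", {
      pts <- .defaultPseudoLeads(geo$mesh)
      computePseudoEcg(vm, pts)
    })
  } else if (cfg$forward$mode == "torso") {
    leads <- wrap("forward", {
      tor <- buildSimplifiedTorso()
      fw <- forwardTorso(vm, tor$torso, tor$conductivities)
      std <- standardTorsoLeads(tor$torso)
      extractLeads(fw$fields, tor$torso, std$points, time = vm@time,
                   bipolar = std$bipolar)
    })
  }
  manifest$stages$forward <- stageTime(t0)

  ## analyses and outputs ------------------------------------------------
  t0 <- tic()
  outs <- character()
  cellData <- list(region_label = geo$labels)
  if (!is.null(geo$fibres)) cellData$fibre <- geo$fibres
  pointData <- list()
  if ("lat" %in% cfg$analysis)
    pointData$LAT_ms <- {
      l <- computeLATMap(vm, useSolverLat = TRUE); l[is.na(l)] <- -1; l
    }
  if ("apd" %in% cfg$analysis) {
    am <- computeAPDMap(vm, labels = geo$labels)
    pointData$APD90_ms <- { a <- am$apd; a[is.na(a)] <- -1; a }
    f <- file.path(cfg$out, "apd-regional.csv")
    write.csv(am$regional, f, row.names = FALSE)
    outs <- c(outs, f)
  }
  f <- file.path(cfg$out, "fields.vtk")
  writeFieldVTK(geo$mesh, f, cellData = cellData, pointData = pointData)
  outs <- c(outs, f)
  if (!is.null(leads)) {
    f <- file.path(cfg$out, "leads.csv")
    writeTracesCSV(leads, f)
    outs <- c(outs, f)
    if ("brms" %in% cfg$analysis) {
      f <- file.path(cfg$out, "brms.csv")
      b <- computeBRMSMap(leads)
      write.csv(data.frame(lead = names(b), brms_mV = as.numeric(b)), f,
                row.names = FALSE)
      outs <- c(outs, f)
    }
    if ("pwave" %in% cfg$analysis) {
      f <- file.path(cfg$out, "pwave-features.csv")
      feats <- do.call(rbind, lapply(seq_along(leads@leads), function(i) {
        ft <- extractPWaveFeatures(leads@traces[, i], leads@time)
        data.frame(lead = leads@leads[i], duration_ms = ft$duration,
                   amplitude_mVpp = ft$amplitude, morphology = ft$morphology)
      }))
      write.csv(feats, f, row.names = FALSE)
      outs <- c(outs, f)
    }
    if ("contrib" %in% cfg$analysis && geo$kind == "atria") {
      dec <- decomposeRegionContributions(vm, geo$labels,
                                          .defaultPseudoLeads(geo$mesh))
      f <- file.path(cfg$out, "region-shares.csv")
      write.csv(data.frame(region = names(dec$shares),
                           share_pct = as.numeric(dec$shares)), f,
                row.names = FALSE)
      outs <- c(outs, f)
    }
  }
  if (geo$kind == "slab" && !is.null(vm@meta$lat)) {
    ## convenience: achieved CV along x on the mid line
    manifest$achieved_cv_cm_s <- tryCatch({
      h <- geo$mesh@spacing * 1e-4
      d <- geo$params
      mid <- c(0, d$ny / 2 * h, d$nz / 2 * h)
      pa <- mid; pa[1] <- round(0.3 * d$nx) * h
      pb <- mid; pb[1] <- round(0.7 * d$nx) * h
      measureCV(vm, pa, pb, useSolverLat = TRUE)
    }, error = function(e) NA_real_)
  }
  manifest$stages$analysis <- stageTime(t0)
  manifest$outputs <- outs
  jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

## stable hash of a configuration (md5 of its canonical YAML)
.configHash <- function(cfg) {
  cfg$out <- NULL
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

## small ring of observation points around a source mesh (pseudo mode)
.defaultPseudoLeads <- function(mesh) {
  bb <- apply(mesh@nodes, 2L, range)
  c0 <- colMeans(bb)
  rad <- max(bb[2, ] - bb[1, ]) * 1.5 + 2
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  observationPoints(paste0("P", seq_along(ang)),
                    x = c0[1] + rad * cos(ang),
                    y = c0[2] + rad * sin(ang),
                    z = c0[3])
}
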