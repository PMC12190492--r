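#' @include AllClasses.R synthetic-scene.R io.R
NULL

# Allowed configuration schema: nested named lists of permitted keys.
.configSchema <- list(
  seed = NULL,
  grid_spacing = NULL,
  displacement_smoothing = NULL,
  drift_correction = NULL,
  energy_unit = NULL,
  substrate = c("young_modulus", "poisson_ratio", "pixel_size"),
  detection = c("sigma_small", "sigma_large", "quality_level",
                "min_distance"),
  tracking = c("window", "pyramid_levels", "max_residual",
               "max_displacement"),
  regularization = c("lambda"),
  simulate = c("n_per_group", "magnitudes", "cv", "groups", "image_dim",
               "bead_density", "psf_sigma", "background", "noise_gaussian",
               "noise_poisson", "pattern_kind", "pattern_radius"),
  cells = NULL
)

#' Default pipeline configuration
#'
#' Returns the full configuration with the package defaults: a 12 kPa
#' incompressible substrate imaged at 0.16 um/px, DoG detection sigmas
#' 1.5/2.0 px, a 61 px tracking window, an 8 px analysis grid and
#' regularization constant 2.47e-5 (pixel-normalized units).
#'
#' @return A nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    grid_spacing = 8,
    displacement_smoothing = 0.75,
    drift_correction = TRUE,
    energy_unit = "J",
    substrate = list(young_modulus = 12000, poisson_ratio = 0.5,
                     pixel_size = 0.16),
    detection = list(sigma_small = 1.5, sigma_large = 2.0,
                     quality_level = 0.05, min_distance = 5),
    tracking = list(window = 61, pyramid_levels = 3, max_residual = 0.1,
                    max_displacement = 30),
    regularization = list(lambda = 2.47e-5)
  )
}

# Merge user values over defaults, rejecting unknown keys.
.mergeConfig <- function(user) {
  cfg <- defaultPipelineConfig()
  unknown <- setdiff(names(user), names(.configSchema))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (key in names(user)) {
    sub <- .configSchema[[key]]
    if (is.null(sub) || key == "cells") {
      cfg[[key]] <- user[[key]]
    } else {
      bad <- setdiff(names(user[[key]]), sub)
      if (length(bad))
        stop("unknown configuration key(s) under '", key, "': ",
             paste(bad, collapse = ", "))
      for (k2 in names(user[[key]])) cfg[[key]][[k2]] <- user[[key]][[k2]]
    }
  }
  if (!is.null(cfg$cells)) {
    for (cell in cfg$cells) {
      need <- setdiff(c("id", "group", "loaded", "relaxed", "mask"),
                      names(cell))
      if (length(need))
        stop("cell entry missing field(s): ", paste(need, collapse = ", "))
    }
  }
  cfg
}

#' Read and validate a pipeline configuration file
#'
#' The configuration is a YAML file; values override the package
#' defaults (see [defaultPipelineConfig()]). Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  .mergeConfig(yaml::read_yaml(path))
}

.substrateFromConfig <- function(cfg) {
  SubstrateModel(cfg$substrate$young_modulus, cfg$substrate$poisson_ratio,
                 cfg$substrate$pixel_size)
}

#' Analyze one traction-loaded/traction-free image pair
#'
#' Runs the per-cell chain: bead detection in the relaxed image,
#' optical-flow tracking into the loaded image, optional drift
#' correction against beads outside the cell mask, interpolation onto a
#' regular grid, mild Gaussian smoothing of the gridded field
#' (`displacement_smoothing`, in grid-node units), FTTC traction
#' reconstruction, and the per-cell readouts.
#'
#' @param relaxed,loaded Grayscale image matrices (same shape).
#' @param mask Logical cell mask aligned to the images.
#' @param substrate A [SubstrateModel-class].
#' @param config Pipeline configuration list (defaults:
#'   [defaultPipelineConfig()]).
#' @return A list: `beads` ([BeadDisplacements-class]), `disp`
#'   ([DisplacementGrid-class]), `traction` ([TractionGrid-class]),
#'   `metrics` (named numeric: max/mean traction in Pa, strain energy in
#'   J, n_grid_nodes, n_beads, n_tracked).
#' @export
analyzeScene <- function(relaxed, loaded, mask,
                         substrate = SubstrateModel(),
                         config = defaultPipelineConfig()) {
  det <- config$detection
  trk <- config$tracking
  anchors <- detectBeads(relaxed, det$sigma_small, det$sigma_large,
                         det$quality_level, det$min_distance)
  if (nrow(anchors) < 4) stop("too few beads detected (", nrow(anchors), ")")
  beads <- trackDisplacements(relaxed, loaded, anchors,
                              window = trk$window,
                              pyramidLevels = trk$pyramid_levels,
                              maxResidual = trk$max_residual,
                              maxDisplacement = trk$max_displacement)
  if (isTRUE(config$drift_correction))
    beads <- driftCorrect(beads, mask)
  disp <- gridDisplacements(beads, spacing = config$grid_spacing,
                            imageDim = dim(relaxed))
  # damp sub-grid interpolation/tracking jitter, which the weakly
  # regularized inversion would otherwise amplify at the node scale
  sm <- config$displacement_smoothing %||% 0
  if (sm > 0) {
    disp <- DisplacementGrid(
      EBImage::gblur(disp@vx, sigma = sm, boundary = "replicate"),
      EBImage::gblur(disp@vy, sigma = sm, boundary = "replicate"),
      origin = disp@origin, spacing = disp@spacing, unit = disp@unit)
  }
  traction <- reconstructTraction(disp, substrate,
                                  lambda = config$regularization$lambda)
  # energy needs physical displacement units
  dispUm <- DisplacementGrid(disp@vx * substrate@pixelSize,
                             disp@vy * substrate@pixelSize,
                             origin = disp@origin, spacing = disp@spacing,
                             unit = "um")
  s <- tractionInRegion(traction, mask)
  xy <- nodeCoords(traction)
  ix <- round(xy[, "x"]); iy <- round(xy[, "y"])
  inside <- ix >= 1 & ix <= ncol(mask) & iy >= 1 & iy <= nrow(mask)
  inside[inside] <- mask[cbind(iy[inside], ix[inside])] > 0
  list(beads = beads, disp = dispUm, traction = traction,
       metrics = c(max_traction_pa = unname(s["max"]),
                   mean_traction_pa = unname(s["mean"]),
                   strain_energy_j = strainEnergy(traction, dispUm, substrate),
                   n_grid_nodes = sum(inside),
                   n_beads = length(beads),
                   n_tracked = sum(beads@tracked)))
}

#' Compare two groups of per-cell measurements
#'
#' Two-tailed Mann-Whitney U test on one measurement column of a
#' per-cell table, plus per-group mean, SEM and n.
#'
#' @param measurements `data.frame` with a `group` column.
#' @param valueCol Column to compare. Default `"max_traction_pa"`.
#' @param groupCol Grouping column. Default `"group"`.
#' @return A one-row `data.frame`: value column, group labels, per-group
#'   mean/sem/n, U statistic, p-value, method and significance stars.
#' @export
compareGroups <- function(measurements, valueCol = "max_traction_pa",
                          groupCol = "group") {
  if (!nrow(measurements)) stop("empty measurement table")
  groups <- sort(unique(measurements[[groupCol]]))
  if (length(groups) != 2)
    stop("exactly two groups required, found ", length(groups))
  va <- measurements[[valueCol]][measurements[[groupCol]] == groups[1]]
  vb <- measurements[[valueCol]][measurements[[groupCol]] == groups[2]]
  mw <- mannWhitneyU(va, vb)
  sa <- groupSummary(va); sb <- groupSummary(vb)
  data.frame(value = valueCol,
             group_a = groups[1], group_b = groups[2],
             mean_a = sa["mean"], sem_a = sa["sem"], n_a = sa["n"],
             mean_b = sb["mean"], sem_b = sb["sem"], n_b = sb["n"],
             u_statistic = mw$statistic, p_value = mw$p_value,
             method = mw$method,
             stars = significanceStars(mw$p_value),
             row.names = NULL)
}

#' Render a plain-text comparison report
#'
#' Per-group mean +/- SEM and n for each measurement column, and, when
#' two groups are present, the Mann-Whitney U statistic, p-value and
#' significance stars (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `n.s.` otherwise).
#'
#' @param measurements Per-cell `data.frame` with a `group` column.
#' @param valueCols Measurement columns to report. Default max traction,
#'   mean traction and strain energy.
#' @param energyUnit Display unit for strain energy: `"J"`, `"uJ"` or
#'   `"pJ"`. Default `"J"`.
#' @return Character vector of report lines (invisibly printable via
#'   `cat`). The comparison table is attached as attribute
#'   `"comparison"`.
#' @export
renderReport <- function(measurements,
                         valueCols = c("max_traction_pa",
                                       "mean_traction_pa",
                                       "strain_energy_j"),
                         energyUnit = "J") {
  if (!nrow(measurements)) stop("empty measurement table")
  escale <- switch(energyUnit, J = 1, uJ = 1e6, pJ = 1e12,
                   stop("unknown energy unit: ", energyUnit))
  meas <- measurements
  if ("strain_energy_j" %in% names(meas) && escale != 1) {
    meas$strain_energy_j <- meas$strain_energy_j * escale
  }
  groups <- sort(unique(meas$group))
  lines <- character(0)
  comps <- NULL
  for (vc in intersect(valueCols, names(meas))) {
    label <- if (vc == "strain_energy_j") {
      sub("_j$", paste0("_", tolower(energyUnit)), vc)
    } else vc
    lines <- c(lines, paste0("== ", label, " =="))
    for (g in groups) {
      s <- groupSummary(meas[[vc]][meas$group == g])
      lines <- c(lines, sprintf("  %s: %.4g +/- %.3g (n = %d)",
                                g, s["mean"], s["sem"], as.integer(s["n"])))
    }
    if (length(groups) == 2) {
      cmp <- compareGroups(meas, valueCol = vc)
      comps <- rbind(comps, cmp)
      lines <- c(lines,
                 sprintf("  Mann-Whitney U = %g, p = %.4g (%s) %s",
                         cmp$u_statistic, cmp$p_value, cmp$method, cmp$stars))
    }
    lines <- c(lines, "")
  }
  attr(lines, "comparison") <- comps
  lines
}

#' Run the full TFM pipeline
#'
#' Executes every stage end-to-end and writes the standard outputs to
#' `outDir`: `measurements.csv` (one row per cell), `comparison.csv` and
#' `report.txt` (two-group statistics), per-cell traction maps
#' (`<id>_traction.tif`, 32-bit float), per-cell vector fields
#' (`<id>_field.csv`), bead tables (`<id>_beads.csv`), `manifest.csv`
#' and `run.log`. Inputs come either from `config$simulate` (a synthetic
#' cohort, fully seeded) or from `config$cells` (a list of per-cell
#' image/mask paths with group labels). Reruns with an identical
#' configuration produce identical CSV and TIFF outputs.
#'
#' @param config Configuration list (see [readPipelineConfig()] /
#'   [defaultPipelineConfig()]) or a YAML file path.
#' @param outDir Output directory, created if needed.
#' @return Invisibly, a list with `measurements`, `comparison` and
#'   `manifest` data frames.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L) {
    configPath <- config
    config <- readPipelineConfig(config)
  } else {
    config <- .mergeConfig(config)
    configPath <- NULL
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  # normalized copy of the effective config; its digest identifies the run
  cfgOut <- file.path(outDir, "config_used.yaml")
  yaml::write_yaml(config, cfgOut)
  cfgHash <- unname(tools::md5sum(cfgOut))
  substrate <- .substrateFromConfig(config)
  logLines <- c(sprintf("TFMtools %s", utils::packageVersion("TFMtools")),
                sprintf("started %s", format(Sys.time())),
                sprintf("config hash %s", cfgHash))

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    baseCfg <- sceneConfig(
      imageDim = sim$image_dim %||% c(256, 256),
      beadDensity = sim$bead_density %||% 60,
      psfSigma = sim$psf_sigma %||% 1.3,
      background = sim$background %||% 0.02,
      noiseGaussian = sim$noise_gaussian %||% 0.02,
      noisePoisson = sim$noise_poisson %||% 800,
      substrate = substrate,
      pattern = list(kind = sim$pattern_kind %||% "inward_dipole",
                     magnitude = 300,
                     radius = sim$pattern_radius %||% 30),
      seed = config$seed)
    cohort <- generateCohort(
      nPerGroup = sim$n_per_group,
      magnitudes = unlist(sim$magnitudes %||% c(1000, 700)),
      cv = sim$cv %||% 0.2,
      groups = unlist(sim$groups %||% c("DMD", "WT")),
      config = baseCfg, seed = config$seed)
    inputs <- lapply(seq_along(cohort$scenes), function(i) {
      sc <- cohort$scenes[[i]]
      list(id = cohort$manifest$cell_id[i],
           group = cohort$manifest$group[i],
           relaxed = sc@relaxed, loaded = sc@loaded, mask = sc@mask)
    })
  } else if (!is.null(config$cells)) {
    # fail fast on any missing input before running a single stage
    for (cell in config$cells) {
      for (f in c(cell$loaded, cell$relaxed, cell$mask))
        if (!file.exists(f)) stop("input file not found: ", f)
    }
    inputs <- lapply(config$cells, function(cell) {
      list(id = cell$id, group = cell$group,
           relaxed = readBeadImage(cell$relaxed),
           loaded = readBeadImage(cell$loaded),
           mask = readCellMask(cell$mask))
    })
  } else {
    stop("config must contain either 'simulate' or 'cells'")
  }

  rows <- list()
  manifest <- list()
  for (inp in inputs) {
    status <- "ok"
    res <- tryCatch(
      analyzeScene(inp$relaxed, inp$loaded, inp$mask, substrate, config),
      error = function(e) {
        status <<- paste("failed:", conditionMessage(e))
        NULL
      })
    files <- character(0)
    if (!is.null(res)) {
      tifPath <- file.path(outDir, paste0(inp$id, "_traction.tif"))
      csvPath <- file.path(outDir, paste0(inp$id, "_field.csv"))
      beadPath <- file.path(outDir, paste0(inp$id, "_beads.csv"))
      writeTractionTIFF(res$traction, tifPath, disp = res$disp)
      writeFieldCSV(res$disp, csvPath, traction = res$traction,
                    substrate = substrate)
      writeBeadCSV(res$beads, beadPath)
      files <- basename(c(tifPath, csvPath, beadPath))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = inp$id, group = inp$group, t(res$metrics))
      logLines <- c(logLines, sprintf(
        "%s: %d beads, %d tracked, max |T| = %.4g Pa", inp$id,
        res$metrics["n_beads"], res$metrics["n_tracked"],
        res$metrics["max_traction_pa"]))
    } else {
      logLines <- c(logLines, sprintf("%s: %s", inp$id, status))
    }
    manifest[[length(manifest) + 1L]] <- data.frame(
      cell_id = inp$id, group = inp$group, status = status,
      outputs = paste(files, collapse = ";"),
      config_hash = cfgHash,
      version = as.character(utils::packageVersion("TFMtools")))
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(0), group = character(0))
  manifest <- do.call(rbind, manifest)
  utils::write.csv(measurements, file.path(outDir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  comparison <- NULL
  if (nrow(measurements) &&
      length(unique(measurements$group)) == 2) {
    report <- renderReport(measurements,
                           energyUnit = config$energy_unit %||% "J")
    comparison <- attr(report, "comparison")
    writeLines(report, file.path(outDir, "report.txt"))
    utils::write.csv(comparison, file.path(outDir, "comparison.csv"),
                     row.names = FALSE)
  }
  logLines <- c(logLines, sprintf("finished %s", format(Sys.time())))
  writeLines(logLines, file.path(outDir, "run.log"))
  anyFailed <- any(manifest$status != "ok")
  if (anyFailed)
    warning("some cells failed; see manifest.csv")
  invisible(list(measurements = measurements, comparison = comparison,
                 manifest = manifest))
}
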