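#' @include AllClasses.R substrate-mechanics.R
NULL

# Evaluate expr with a temporary RNG state seeded from `seed`, restoring
# the caller's state afterwards.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scene configuration
#'
#' Bundles all knobs of the synthetic TFM experiment generator. Defaults
#' emulate the imaging conditions the pipeline targets: 100 nm beads
#' rendered as diffraction-limited Gaussian spots (sigma 1.3 px at
#' 0.16 um/px), a seeding density that matches an 8 px analysis grid, a
#' soft 12 kPa incompressible substrate, and shot plus read noise.
#'
#' @param imageDim Image shape `c(nrow, ncol)` in pixels. Default
#'   `c(256, 256)`.
#' @param beadDensity Beads per 100 x 100 px patch. Default 60.
#' @param psfSigma Rendered spot sigma, px. Default 1.3.
#' @param beadIntensity Peak spot intensity (arbitrary units). Default 1.
#' @param background Constant background level. Default 0.02.
#' @param noiseGaussian Read-noise standard deviation as absolute
#'   intensity (same units as `beadIntensity`). Default 0.02.
#' @param noisePoisson Photons per intensity unit for shot noise; 0
#'   disables. Default 800.
#' @param substrate A [SubstrateModel-class]. Default `SubstrateModel()`.
#' @param pattern Traction pattern description: a list with `kind`
#'   (`"circular_patch"`, `"inward_dipole"` or `"multi_adhesion_ring"`),
#'   `magnitude` (Pa), `radius` (px) and optional `centers`,
#'   `orientation`, `nPatches`, `ringRadius`; see [makeTractionPattern()].
#' @param truthSpacing Node spacing of the ground-truth grids, px.
#'   Default 2.
#' @param seed Integer seed; fixes every random draw in the scene.
#' @return A validated list of class `"sceneConfig"`.
#' @export
sceneConfig <- function(imageDim = c(256, 256), beadDensity = 60,
                        psfSigma = 1.3, beadIntensity = 1,
                        background = 0.02, noiseGaussian = 0.02,
                        noisePoisson = 800,
                        substrate = SubstrateModel(),
                        pattern = list(kind = "inward_dipole",
                                       magnitude = 300, radius = 30),
                        truthSpacing = 2, seed = 1L) {
  stopifnot(length(imageDim) == 2, all(imageDim >= 32),
            beadDensity > 0, psfSigma > 0, beadIntensity > 0,
            background >= 0, noiseGaussian >= 0, noisePoisson >= 0,
            is(substrate, "SubstrateModel"), truthSpacing >= 1)
  structure(list(imageDim = as.integer(imageDim),
                 beadDensity = beadDensity, psfSigma = psfSigma,
                 beadIntensity = beadIntensity, background = background,
                 noiseGaussian = noiseGaussian, noisePoisson = noisePoisson,
                 substrate = substrate, pattern = pattern,
                 truthSpacing = truthSpacing, seed = as.integer(seed)),
            class = "sceneConfig")
}

#' Build a ground-truth traction pattern on a regular grid
#'
#' Deterministic adhesion-like traction patterns:
#' * `circular_patch` — one disc of uniform traction of the given
#'   magnitude along `orientation`;
#' * `inward_dipole` — two discs of equal size pulling toward each other
#'   (zero net force by construction: both discs share the same node
#'   stencil with opposite signs);
#' * `multi_adhesion_ring` — `nPatches` discs equally spaced on a ring,
#'   each pulling toward the ring centre (net force cancels by the
#'   symmetry of the exact patch directions).
#'
#' @param kind Pattern kind.
#' @param magnitude Traction magnitude per patch, Pa (>= 0).
#' @param radius Patch radius, px.
#' @param imageDim Image shape `c(nrow, ncol)` the grid spans.
#' @param spacing Grid node spacing, px. Default 2.
#' @param center Pattern centre `(x, y)` in px; image centre by default.
#' @param orientation Direction (radians) of the patch traction /
#'   dipole axis. Default 0.
#' @param separation Centre-to-centre dipole distance, px. Default
#'   `3 * radius`.
#' @param nPatches Number of ring patches. Default 6.
#' @param ringRadius Ring radius, px. Default `3 * radius`.
#' @return A [TractionGrid-class].
#' @export
makeTractionPattern <- function(kind = c("circular_patch", "inward_dipole",
                                         "multi_adhesion_ring"),
                                magnitude, radius, imageDim, spacing = 2,
                                center = NULL, orientation = 0,
                                separation = 3 * radius, nPatches = 6,
                                ringRadius = 3 * radius) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("'magnitude' must be >= 0")
  if (radius <= 0) stop("'radius' must be positive")
  nr <- floor((imageDim[1] - 1) / spacing) + 1
  nc <- floor((imageDim[2] - 1) / spacing) + 1
  tx <- matrix(0, nr, nc); ty <- matrix(0, nr, nc)
  if (is.null(center)) center <- c(imageDim[2], imageDim[1]) / 2
  # shared disc stencil in node offsets, so paired patches cancel exactly
  ro <- ceiling(radius / spacing)
  offs <- expand.grid(di = -ro:ro, dj = -ro:ro)
  offs <- offs[(offs$di^2 + offs$dj^2) * spacing^2 <= radius^2, ]
  placePatch <- function(cx, cy, ux, uy) {
    jc <- round((cx - 1) / spacing) + 1
    ic <- round((cy - 1) / spacing) + 1
    ii <- ic + offs$di; jj <- jc + offs$dj
    if (any(ii < 1 | ii > nr | jj < 1 | jj > nc))
      stop("traction pattern exceeds the grid bounds")
    tx[cbind(ii, jj)] <<- tx[cbind(ii, jj)] + magnitude * ux
    ty[cbind(ii, jj)] <<- ty[cbind(ii, jj)] + magnitude * uy
  }
  if (kind == "circular_patch") {
    placePatch(center[1], center[2], cos(orientation), sin(orientation))
  } else if (kind == "inward_dipole") {
    ax <- cos(orientation); ay <- sin(orientation)
    placePatch(center[1] - ax * separation / 2, center[2] - ay * separation / 2,
               ax, ay)
    placePatch(center[1] + ax * separation / 2, center[2] + ay * separation / 2,
               -ax, -ay)
  } else {
    ang <- orientation + 2 * pi * (seq_len(nPatches) - 1) / nPatches
    for (t in seq_len(nPatches))
      placePatch(center[1] + ringRadius * cos(ang[t]),
                 center[2] + ringRadius * sin(ang[t]),
                 -cos(ang[t]), -sin(ang[t]))
  }
  TractionGrid(tx, ty, origin = c(1, 1), spacing = spacing)
}

#' Render a fluorescent bead image
#'
#' Sums isotropic Gaussian spots at subpixel positions on a constant
#' background, then applies Poisson shot noise (scaled by
#' `noisePoisson` photons per intensity unit) and additive Gaussian read
#' noise. With both noise terms zero the render is deterministic.
#'
#' @param positions Two-column matrix (x, y) of bead positions, px.
#' @param imageDim Image shape `c(nrow, ncol)`.
#' @param psfSigma Spot sigma, px. Default 1.3.
#' @param intensity Peak spot intensity. Default 1.
#' @param background Background level. Default 0.02.
#' @param noiseGaussian Read-noise sd (intensity units). Default 0.
#' @param noisePoisson Photons per intensity unit; 0 disables. Default 0.
#' @param seed Optional seed applied to the noise draws only.
#' @return A numeric matrix (rows = y).
#' @export
renderBeads <- function(positions, imageDim, psfSigma = 1.3, intensity = 1,
                        background = 0.02, noiseGaussian = 0,
                        noisePoisson = 0, seed = NULL) {
  nr <- imageDim[1]; nc <- imageDim[2]
  img <- matrix(background, nr, nc)
  positions <- as.matrix(positions)
  ext <- ceiling(4 * psfSigma)
  for (k in seq_len(nrow(positions))) {
    xb <- positions[k, 1]; yb <- positions[k, 2]
    j0 <- max(1, floor(xb) - ext); j1 <- min(nc, ceiling(xb) + ext)
    i0 <- max(1, floor(yb) - ext); i1 <- min(nr, ceiling(yb) + ext)
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((j0:j1) - xb)^2 / (2 * psfSigma^2))
    gy <- exp(-((i0:i1) - yb)^2 / (2 * psfSigma^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + intensity * outer(gy, gx)
  }
  addNoise <- function(im) {
    if (noisePoisson > 0)
      im <- matrix(stats::rpois(length(im), pmax(im, 0) * noisePoisson),
                   nr, nc) / noisePoisson
    if (noiseGaussian > 0)
      im <- im + matrix(stats::rnorm(length(im), sd = noiseGaussian), nr, nc)
    im
  }
  if (!is.null(seed)) .withSeed(seed, addNoise(img)) else addNoise(img)
}

# Bilinear sample of a gridded field (node lattice) at pixel coords.
.sampleGrid <- function(grid, x, y) {
  xi <- (x - grid@origin[1]) / grid@spacing + 1
  yi <- (y - grid@origin[2]) / grid@spacing + 1
  cbind(.bilinear(grid@vx, xi, yi), .bilinear(grid@vy, xi, yi))
}

#' Generate one synthetic TFM scene
#'
#' Builds a full simulated experiment from a [sceneConfig()]: the
#' ground-truth traction pattern, its forward-modelled displacement
#' field, uniformly seeded bead positions, the loaded positions obtained
#' by displacing each bead by the interpolated truth field, the rendered
#' image pair, a circular cell mask covering the traction pattern, and
#' the truth per-cell metrics. Identical configs (including seed) yield
#' identical scenes.
#'
#' @param config A [sceneConfig()] list.
#' @return A [SyntheticScene-class].
#' @export
generateScene <- function(config) {
  stopifnot(inherits(config, "sceneConfig"))
  dimz <- config$imageDim
  pat <- config$pattern
  truth <- makeTractionPattern(
    kind = pat$kind, magnitude = pat$magnitude, radius = pat$radius,
    imageDim = dimz, spacing = config$truthSpacing,
    center = pat$centers %||% NULL,
    orientation = pat$orientation %||% 0,
    separation = pat$separation %||% (3 * pat$radius),
    nPatches = pat$nPatches %||% 6,
    ringRadius = pat$ringRadius %||% (3 * pat$radius))
  disp <- forwardDisplacement(truth, config$substrate, pad = TRUE)
  .withSeed(config$seed, {
    nBeads <- round(config$beadDensity * prod(dimz) / 1e4)
    bx <- stats::runif(nBeads, 3, dimz[2] - 2)
    by <- stats::runif(nBeads, 3, dimz[1] - 2)
    relaxedPos <- cbind(x = bx, y = by)
    uPx <- .sampleGrid(disp, bx, by) / pixelSize(config$substrate)
    loadedPos <- relaxedPos + uPx
    relaxedImg <- renderBeads(relaxedPos, dimz, config$psfSigma,
                              config$beadIntensity, config$background,
                              config$noiseGaussian, config$noisePoisson)
    loadedImg <- renderBeads(loadedPos, dimz, config$psfSigma,
                             config$beadIntensity, config$background,
                             config$noiseGaussian, config$noisePoisson)
    # mask: disc covering every traction-carrying node plus a margin
    mag <- magnitude(truth)
    ctr <- pat$centers %||% (c(dimz[2], dimz[1]) / 2)
    xy <- nodeCoords(truth)
    act <- mag > 0
    maskR <- if (any(act)) {
      max(sqrt((xy[act, "x"] - ctr[1])^2 + (xy[act, "y"] - ctr[2])^2)) + 12
    } else min(dimz) / 4
    X <- matrix(seq_len(dimz[2]), dimz[1], dimz[2], byrow = TRUE)
    Y <- matrix(seq_len(dimz[1]), dimz[1], dimz[2])
    mask <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= maskR^2
    tm <- tryCatch(tractionInRegion(truth, mask),
                   error = function(e) c(max = 0, mean = 0))
    truthMetrics <- data.frame(
      max_traction_pa = unname(tm["max"]),
      mean_traction_pa = unname(tm["mean"]),
      strain_energy_j = strainEnergy(truth, disp, config$substrate))
    new("SyntheticScene",
        truthTraction = truth, truthDisplacement = disp,
        beadsRelaxed = relaxedPos, beadsLoaded = loadedPos,
        relaxed = relaxedImg, loaded = loadedImg, mask = mask,
        substrate = config$substrate, truthMetrics = truthMetrics,
        seed = config$seed)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a two-group cohort of synthetic scenes
#'
#' Emulates a two-group TFM study (disease-like vs control-like): each
#' cell receives a traction magnitude drawn from its group's
#' distribution (normal with the stated mean and coefficient of
#' variation, truncated at 20 % of the mean), and an independently
#' seeded scene is generated per cell from the master seed.
#'
#' @param nPerGroup Cells per group.
#' @param magnitudes Length-2 numeric: mean pattern magnitude (Pa) for
#'   the two groups. Default `c(1000, 700)`.
#' @param cv Coefficient of variation of per-cell magnitudes. Default 0.2.
#' @param groups Group labels. Default `c("DMD", "WT")`.
#' @param config Base [sceneConfig()]; per-cell seed and magnitude are
#'   overridden.
#' @param seed Master seed.
#' @return A list with `scenes` (list of [SyntheticScene-class]), and
#'   `manifest` (`data.frame`: cell_id, group, magnitude and truth
#'   metrics).
#' @export
generateCohort <- function(nPerGroup, magnitudes = c(1000, 700), cv = 0.2,
                           groups = c("DMD", "WT"),
                           config = sceneConfig(), seed = 1L) {
  stopifnot(nPerGroup >= 1, length(magnitudes) == 2, length(groups) == 2)
  nTot <- 2L * nPerGroup
  mags <- .withSeed(seed, {
    m <- rep(magnitudes, each = nPerGroup)
    pmax(stats::rnorm(nTot, m, cv * m), 0.2 * m)
  })
  grp <- rep(groups, each = nPerGroup)
  scenes <- vector("list", nTot)
  rows <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    sSeed <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
    cfg <- config
    cfg$pattern$magnitude <- mags[i]
    cfg$seed <- sSeed
    scenes[[i]] <- generateScene(cfg)
    rows[[i]] <- data.frame(cell_id = sprintf("cell%03d", i),
                            group = grp[i], magnitude_pa = mags[i],
                            scenes[[i]]@truthMetrics)
  }
  list(scenes = scenes, manifest = do.call(rbind, rows))
}
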