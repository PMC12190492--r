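#' @import methods
NULL

#' Elastic substrate and optics parameters
#'
#' Describes the linear-elastic half-space the cells deform — a thick,
#' flat hydrogel or silicone layer — together with the imaging scale.
#' The substrate is assumed semi-infinite and laterally homogeneous, so
#' two elastic constants and the pixel size fully determine the
#' force-displacement relation used throughout the package.
#'
#' @slot youngModulus Young's modulus of the substrate, in Pa.
#' @slot poissonRatio Poisson ratio, dimensionless in \[0, 0.5\];
#'   0.5 denotes an incompressible gel.
#' @slot pixelSize Physical size of one image pixel, in micrometres.
#'
#' @seealso [SubstrateModel()] for the user-facing constructor.
#' @exportClass SubstrateModel
setClass("SubstrateModel",
  representation(
    youngModulus = "numeric",
    poissonRatio = "numeric",
    pixelSize    = "numeric"
  ),
  prototype(
    youngModulus = 12000,
    poissonRatio = 0.5,
    pixelSize    = 0.16
  )
)

setValidity("SubstrateModel", function(object) {
  msg <- character()
  if (length(object@youngModulus) != 1L || !is.finite(object@youngModulus) ||
      object@youngModulus <= 0)
    msg <- c(msg, "'youngModulus' must be a single positive finite number (Pa)")
  if (length(object@poissonRatio) != 1L || !is.finite(object@poissonRatio) ||
      object@poissonRatio < 0 || object@poissonRatio > 0.5)
    msg <- c(msg, "'poissonRatio' must lie in [0, 0.5]")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "'pixelSize' must be a single positive number (um/px)")
  if (length(msg)) msg else TRUE
})

#' Construct a substrate model
#'
#' @param youngModulus Young's modulus in Pa. Default 12000 Pa, a soft
#'   silicone of stiffness comparable to muscle tissue.
#' @param poissonRatio Poisson ratio in \[0, 0.5\]. Default 0.5
#'   (incompressible).
#' @param pixelSize Image pixel size in micrometres per pixel. Default
#'   0.16 um/px, typical of a 40x objective.
#' @return A [SubstrateModel-class] object.
#' @examples
#' sub <- SubstrateModel()
#' youngModulus(sub)
#' @export
SubstrateModel <- function(youngModulus = 12000, poissonRatio = 0.5,
                           pixelSize = 0.16) {
  new("SubstrateModel", youngModulus = as.numeric(youngModulus),
      poissonRatio = as.numeric(poissonRatio),
      pixelSize = as.numeric(pixelSize))
}

#' Regular-grid 2D vector field (virtual base class)
#'
#' Common representation for displacement and traction fields sampled on
#' a regular grid of nodes laid over the image. Node `[i, j]` sits at
#' pixel coordinates `x = origin[1] + (j-1) * spacing`,
#' `y = origin[2] + (i-1) * spacing` (x = column, y = row, origin
#' top-left, 1-based).
#'
#' @slot vx,vy Numeric matrices holding the x and y vector components per
#'   grid node; identical dimensions.
#' @slot origin Length-2 numeric, pixel coordinates (x, y) of node `[1, 1]`.
#' @slot spacing Grid spacing in pixels per node (>= 1).
#' @slot unit Unit tag of the components.
#' @exportClass VectorGrid
setClass("VectorGrid",
  representation("VIRTUAL",
    vx      = "matrix",
    vy      = "matrix",
    origin  = "numeric",
    spacing = "numeric",
    unit    = "character"
  )
)

setValidity("VectorGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@vx), dim(object@vy)))
    msg <- c(msg, "'vx' and 'vy' must have identical dimensions")
  if (length(object@origin) != 2L || !all(is.finite(object@origin)))
    msg <- c(msg, "'origin' must be two finite pixel coordinates (x, y)")
  if (length(object@spacing) != 1L || !is.finite(object@spacing) ||
      object@spacing < 1)
    msg <- c(msg, "'spacing' must be a single number >= 1 (pixels)")
  if (length(object@unit) != 1L)
    msg <- c(msg, "'unit' must be a single character tag")
  if (length(msg)) msg else TRUE
})

#' Gridded substrate displacement field
#'
#' Displacements of the substrate surface under cellular traction,
#' interpolated from tracked beads onto a regular grid (see
#' [gridDisplacements()]), or produced by the forward elastic model
#' ([forwardDisplacement()]). The unit tag is `"px"` or `"um"`.
#'
#' @exportClass DisplacementGrid
setClass("DisplacementGrid", contains = "VectorGrid",
         prototype = prototype(unit = "um"))

setValidity("DisplacementGrid", function(object) {
  if (!object@unit %in% c("px", "um"))
    return("displacement unit must be 'px' or 'um'")
  TRUE
})

#' Gridded traction stress field
#'
#' In-plane traction stresses (Pa) the cell exerts on the substrate
#' surface, on the same grid convention as [DisplacementGrid-class].
#' The magnitude at each node is `sqrt(tx^2 + ty^2)`; see [magnitude()].
#'
#' @exportClass TractionGrid
setClass("TractionGrid", contains = "VectorGrid",
         prototype = prototype(unit = "Pa"))

setValidity("TractionGrid", function(object) {
  if (!identical(object@unit, "Pa"))
    return("traction unit must be 'Pa'")
  TRUE
})

#' Construct a gridded displacement field
#'
#' @param ux,uy Numeric matrices of displacement components per node.
#' @param origin Pixel coordinates (x, y) of node `[1, 1]`. Default `c(1, 1)`.
#' @param spacing Grid spacing in pixels. Default 1.
#' @param unit `"px"` or `"um"`.
#' @return A [DisplacementGrid-class].
#' @export
DisplacementGrid <- function(ux, uy, origin = c(1, 1), spacing = 1,
                             unit = c("um", "px")) {
  unit <- match.arg(unit)
  new("DisplacementGrid", vx = as.matrix(ux), vy = as.matrix(uy),
      origin = as.numeric(origin), spacing = as.numeric(spacing), unit = unit)
}

#' Construct a gridded traction field
#'
#' @param tx,ty Numeric matrices of traction components per node, in Pa.
#' @param origin Pixel coordinates (x, y) of node `[1, 1]`. Default `c(1, 1)`.
#' @param spacing Grid spacing in pixels. Default 1.
#' @return A [TractionGrid-class].
#' @export
TractionGrid <- function(tx, ty, origin = c(1, 1), spacing = 1) {
  new("TractionGrid", vx = as.matrix(tx), vy = as.matrix(ty),
      origin = as.numeric(origin), spacing = as.numeric(spacing), unit = "Pa")
}

#' Scattered bead displacement field
#'
#' Per-bead displacement vectors measured by optical-flow tracking.
#' Anchors are the subpixel bead positions detected in the relaxed
#' (traction-free) image; vectors point to the bead positions in the
#' loaded image. Beads whose track failed the residual, displacement or
#' forward-backward consistency checks are flagged not tracked and carry
#' `NA` vectors.
#'
#' @slot x,y Anchor positions in the relaxed image (pixels, subpixel;
#'   x = column, y = row, 1-based).
#' @slot dx,dy Displacement components in pixels (`NA` where lost).
#' @slot tracked Logical flag per bead.
#' @exportClass BeadDisplacements
setClass("BeadDisplacements",
  representation(
    x = "numeric", y = "numeric",
    dx = "numeric", dy = "numeric",
    tracked = "logical"
  )
)

setValidity("BeadDisplacements", function(object) {
  n <- length(object@x)
  msg <- character()
  if (length(object@y) != n || length(object@dx) != n ||
      length(object@dy) != n || length(object@tracked) != n)
    msg <- c(msg, "all per-bead slots must have equal length")
  if (any(object@tracked & (is.na(object@dx) | is.na(object@dy))))
    msg <- c(msg, "tracked beads must carry finite vectors")
  if (length(msg)) msg else TRUE
})

#' Construct a scattered bead displacement field
#'
#' @param x,y Anchor positions (px).
#' @param dx,dy Displacement components (px); `NA` allowed for lost beads.
#' @param tracked Logical per-bead flag; defaults to beads with finite
#'   vectors.
#' @return A [BeadDisplacements-class].
#' @export
BeadDisplacements <- function(x, y, dx, dy,
                              tracked = is.finite(dx) & is.finite(dy)) {
  dx[!tracked] <- NA_real_
  dy[!tracked] <- NA_real_
  new("BeadDisplacements", x = as.numeric(x), y = as.numeric(y),
      dx = as.numeric(dx), dy = as.numeric(dy), tracked = as.logical(tracked))
}

#' Synthetic TFM scene with ground truth
#'
#' A complete simulated experiment: a ground-truth traction pattern, the
#' forward-modelled substrate displacement, bead positions before and
#' after loading, the rendered image pair, a cell mask, and the truth
#' per-cell metrics. Used to validate every stage of the pipeline.
#'
#' @slot truthTraction Ground-truth [TractionGrid-class].
#' @slot truthDisplacement Forward-modelled [DisplacementGrid-class] (um).
#' @slot beadsRelaxed,beadsLoaded Two-column matrices (x, y) of bead
#'   positions in px; loaded = relaxed + truth displacement at the bead.
#' @slot relaxed,loaded Rendered grayscale images (matrices, rows = y).
#' @slot mask Logical matrix, `TRUE` inside the cell region.
#' @slot substrate The [SubstrateModel-class] used.
#' @slot truthMetrics One-row `data.frame` of ground-truth per-cell
#'   readouts (max/mean traction in Pa, strain energy in J).
#' @slot seed Integer seed the scene was generated from.
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(
    truthTraction     = "TractionGrid",
    truthDisplacement = "DisplacementGrid",
    beadsRelaxed      = "matrix",
    beadsLoaded       = "matrix",
    relaxed           = "matrix",
    loaded            = "matrix",
    mask              = "matrix",
    substrate         = "SubstrateModel",
    truthMetrics      = "data.frame",
    seed              = "integer"
  )
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (!identical(dim(object@relaxed), dim(object@loaded)))
    msg <- c(msg, "'relaxed' and 'loaded' images must have identical shape")
  if (!identical(dim(object@relaxed), dim(object@mask)))
    msg <- c(msg, "'mask' must match the image shape")
  if (nrow(object@beadsRelaxed) != nrow(object@beadsLoaded))
    msg <- c(msg, "bead position matrices must have equal row counts")
  if (length(msg)) msg else TRUE
})
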