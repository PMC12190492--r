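#' @include AllClasses.R
NULL

#' Strain energy stored in the substrate
#'
#' Total elastic energy the cell has invested in deforming the gel,
#' \deqn{U = \tfrac{1}{2} \sum_{\mathrm{nodes}} (T \cdot u)\, \Delta A,}
#' evaluated over the full field of view, with \eqn{\Delta A} the
#' physical area per grid node. Traction in Pa and displacement in
#' micrometres give \eqn{Pa\,\mu m^3 = 10^{-18}} J per term; the result
#' is returned in joules.
#'
#' @param traction A [TractionGrid-class] (Pa).
#' @param disp A [DisplacementGrid-class] on the same grid; converted to
#'   micrometres internally if tagged `"px"`.
#' @param substrate A [SubstrateModel-class] (supplies the pixel size).
#' @return Strain energy in joules (scalar).
#' @export
strainEnergy <- function(traction, disp, substrate) {
  stopifnot(is(traction, "TractionGrid"), is(disp, "DisplacementGrid"),
            is(substrate, "SubstrateModel"))
  if (!identical(dim(traction@vx), dim(disp@vx)) ||
      !isTRUE(all.equal(traction@spacing, disp@spacing)))
    stop("traction and displacement must share the same grid")
  ux <- disp@vx; uy <- disp@vy
  if (disp@unit == "px") {
    ux <- ux * substrate@pixelSize
    uy <- uy * substrate@pixelSize
  }
  dA <- (traction@spacing * substrate@pixelSize)^2  # um^2 per node
  0.5 * sum(traction@vx * ux + traction@vy * uy) * dA * 1e-18
}

#' Traction statistics within a cell region
#'
#' Maximum and mean traction magnitude over the grid nodes that fall
#' inside a binary cell mask; nodes are assigned to mask pixels by
#' nearest-pixel lookup.
#'
#' @param traction A [TractionGrid-class].
#' @param mask Logical or 0/1 matrix aligned to the bead images
#'   (`TRUE`/nonzero inside the cell).
#' @return Named numeric vector `c(max = , mean = )` in Pa.
#' @export
tractionInRegion <- function(traction, mask) {
  stopifnot(is(traction, "TractionGrid"))
  mask <- as.matrix(mask)
  if (!any(mask > 0)) stop("cell mask is empty")
  xy <- nodeCoords(traction)
  ix <- round(xy[, "x"]); iy <- round(xy[, "y"])
  inside <- ix >= 1 & ix <= ncol(mask) & iy >= 1 & iy <= nrow(mask)
  inside[inside] <- mask[cbind(iy[inside], ix[inside])] > 0
  if (!any(inside))
    stop("no traction grid node falls inside the cell mask")
  m <- as.vector(magnitude(traction))[inside]
  c(max = max(m), mean = mean(m))
}

#' Per-cell contractility readouts
#'
#' Tabulates, for each cell region, the maximum and mean traction
#' magnitude inside the mask and the strain energy over the cell's full
#' field of view. A failure for one cell (e.g. a mask that overlaps no
#' grid node) is caught, reported via a warning, and does not abort the
#' remaining cells.
#'
#' @param traction A [TractionGrid-class].
#' @param disp The matching [DisplacementGrid-class].
#' @param regions A list of cell regions; each element a list with
#'   components `mask` (binary matrix), `cellId` and `group`.
#' @param substrate A [SubstrateModel-class].
#' @return A `data.frame` with columns `cell_id`, `group`,
#'   `max_traction_pa`, `mean_traction_pa`, `strain_energy_j`,
#'   `n_grid_nodes`; one row per successfully measured cell.
#' @export
measureCells <- function(traction, disp, regions, substrate) {
  rows <- vector("list", length(regions))
  for (r in seq_along(regions)) {
    reg <- regions[[r]]
    rows[[r]] <- tryCatch({
      s <- tractionInRegion(traction, reg$mask)
      xy <- nodeCoords(traction)
      ix <- round(xy[, "x"]); iy <- round(xy[, "y"])
      inside <- ix >= 1 & ix <= ncol(reg$mask) & iy >= 1 & iy <= nrow(reg$mask)
      inside[inside] <- as.matrix(reg$mask)[cbind(iy[inside], ix[inside])] > 0
      data.frame(
        cell_id = as.character(reg$cellId),
        group = as.character(reg$group),
        max_traction_pa = unname(s["max"]),
        mean_traction_pa = unname(s["mean"]),
        strain_energy_j = strainEnergy(traction, disp, substrate),
        n_grid_nodes = sum(inside)
      )
    }, error = function(e) {
      warning("cell '", reg$cellId, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(cell_id = character(0), group = character(0),
                      max_traction_pa = numeric(0),
                      mean_traction_pa = numeric(0),
                      strain_energy_j = numeric(0),
                      n_grid_nodes = integer(0)))
  do.call(rbind, rows)
}
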