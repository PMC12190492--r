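#' @include AllClasses.R
NULL

#' Read a grayscale microscopy image
#'
#' Reads a single-plane TIFF or PNG into a numeric matrix (rows = y).
#' Multi-channel images are averaged to one channel. Intensities are
#' returned on the scale the reader yields (0-1 for integer TIFF/PNG);
#' all detection and tracking steps are invariant to a global intensity
#' scale.
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @return A numeric matrix.
#' @export
readBeadImage <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (is.list(img)) img <- img[[1]]
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  as.matrix(img)
}

#' Read a binary cell mask
#'
#' Nonzero pixels mark the inside of the cell region.
#'
#' @param path TIFF or PNG file path.
#' @return A logical matrix.
#' @export
readCellMask <- function(path) {
  readBeadImage(path) > 0
}

#' Write a grayscale image to TIFF
#'
#' @param image Numeric matrix; values are clipped to \[0, 1\] for
#'   integer output.
#' @param path Output path.
#' @param bits Bits per sample: 8, 16, or 32 (float, unclipped). Default
#'   16.
#' @export
writeImageTIFF <- function(image, path, bits = 16) {
  img <- as.matrix(image)
  if (bits != 32) img <- pmin(pmax(img, 0), 1)
  tiff::writeTIFF(img, path, bits.per.sample = bits)
  invisible(path)
}

#' Write traction/displacement maps as multi-channel 32-bit float TIFF
#'
#' Channels: tx, ty, |T| (Pa), and when a displacement grid is supplied
#' additionally ux, uy (um). Because TIFF sample storage spans \[0, 1\],
#' each channel is min-max normalized (32-bit samples, ~1e-9 relative
#' precision) and the per-channel ranges are written to a sidecar table
#' `<path>_scale.csv`, from which [readTractionTIFF()] restores
#' physical values.
#'
#' @param traction A [TractionGrid-class].
#' @param path Output path.
#' @param disp Optional matching [DisplacementGrid-class].
#' @export
writeTractionTIFF <- function(traction, path, disp = NULL) {
  stopifnot(is(traction, "TractionGrid"))
  ch <- list(tx = traction@vx, ty = traction@vy, tmag = magnitude(traction))
  if (!is.null(disp)) ch <- c(ch, list(ux = disp@vx, uy = disp@vy))
  lo <- vapply(ch, min, numeric(1))
  hi <- vapply(ch, max, numeric(1))
  span <- ifelse(hi > lo, hi - lo, 1)
  norm <- lapply(seq_along(ch), function(i) (ch[[i]] - lo[i]) / span[i])
  tiff::writeTIFF(norm, path, bits.per.sample = 32, reduce = FALSE)
  utils::write.csv(data.frame(channel = names(ch), lo = lo, hi = hi),
                   .scalePath(path), row.names = FALSE)
  invisible(path)
}

.scalePath <- function(path) paste0(sub("\\.tiff?$", "", path), "_scale.csv")

#' Read maps written by [writeTractionTIFF()]
#'
#' @param path TIFF path.
#' @return A named list of numeric matrices in physical units (tx, ty,
#'   tmag in Pa; ux, uy in um when present).
#' @export
readTractionTIFF <- function(path) {
  sp <- .scalePath(path)
  if (!file.exists(sp))
    stop("missing channel scale table for traction TIFF: ", sp)
  scl <- utils::read.csv(sp)
  pages <- tiff::readTIFF(path, all = TRUE)
  span <- ifelse(scl$hi > scl$lo, scl$hi - scl$lo, 1)
  out <- lapply(seq_len(nrow(scl)), function(i)
    pages[[i]] * span[i] + scl$lo[i])
  names(out) <- scl$channel
  out
}

#' Write a gridded field to CSV
#'
#' Long-format table with one row per grid node: `row`, `col`, `x_um`,
#' `y_um`, displacement columns `ux`, `uy` (um) and, when a traction
#' grid is given, `tx`, `ty`, `tmag` (Pa).
#'
#' @param disp A [DisplacementGrid-class].
#' @param path Output CSV path.
#' @param traction Optional matching [TractionGrid-class].
#' @param substrate A [SubstrateModel-class] (pixel size for the um
#'   coordinates and px-to-um conversion).
#' @export
writeFieldCSV <- function(disp, path, traction = NULL,
                          substrate = SubstrateModel()) {
  stopifnot(is(disp, "DisplacementGrid"))
  d <- dim(disp@vx)
  idx <- expand.grid(row = seq_len(d[1]), col = seq_len(d[2]))
  xy <- nodeCoords(disp)
  scale <- if (disp@unit == "px") substrate@pixelSize else 1
  out <- data.frame(idx,
                    x_um = xy[, "x"] * substrate@pixelSize,
                    y_um = xy[, "y"] * substrate@pixelSize,
                    ux = as.vector(disp@vx) * scale,
                    uy = as.vector(disp@vy) * scale)
  if (!is.null(traction)) {
    stopifnot(is(traction, "TractionGrid"),
              identical(dim(traction@vx), d))
    out$tx <- as.vector(traction@vx)
    out$ty <- as.vector(traction@vy)
    out$tmag <- as.vector(magnitude(traction))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a gridded field from CSV written by [writeFieldCSV()]
#'
#' @param path CSV path.
#' @param substrate A [SubstrateModel-class] matching the one used at
#'   write time.
#' @return A list with `disp` ([DisplacementGrid-class], um) and
#'   `traction` ([TractionGrid-class] or `NULL`).
#' @export
readFieldCSV <- function(path, substrate = SubstrateModel()) {
  df <- utils::read.csv(path)
  nr <- max(df$row); nc <- max(df$col)
  toM <- function(v) matrix(v[order(df$col, df$row)], nr, nc)
  xpx <- df$x_um / substrate@pixelSize
  ypx <- df$y_um / substrate@pixelSize
  spacing <- if (nc > 1) (max(xpx) - min(xpx)) / (nc - 1) else 1
  disp <- DisplacementGrid(toM(df$ux), toM(df$uy),
                           origin = c(min(xpx), min(ypx)),
                           spacing = spacing, unit = "um")
  traction <- if ("tx" %in% names(df)) {
    TractionGrid(toM(df$tx), toM(df$ty),
                 origin = c(min(xpx), min(ypx)), spacing = spacing)
  }
  list(disp = disp, traction = traction)
}

#' Write a scattered bead field to CSV
#'
#' Columns: `x`, `y`, `dx`, `dy`, `status`.
#'
#' @param field A [BeadDisplacements-class].
#' @param path Output CSV path.
#' @export
writeBeadCSV <- function(field, path) {
  stopifnot(is(field, "BeadDisplacements"))
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' Export a synthetic scene to a directory
#'
#' Writes `loaded.tif` and `relaxed.tif` (16-bit), `mask.png`, the
#' ground-truth field table `truth_field.csv` and one-row
#' `truth_metrics.csv`.
#'
#' @param scene A [SyntheticScene-class].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeScene <- function(scene, dir) {
  stopifnot(is(scene, "SyntheticScene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hi <- max(scene@loaded, scene@relaxed, 1e-12)
  writeImageTIFF(scene@relaxed / hi, file.path(dir, "relaxed.tif"))
  writeImageTIFF(scene@loaded / hi, file.path(dir, "loaded.tif"))
  png::writePNG(scene@mask * 1, file.path(dir, "mask.png"))
  writeFieldCSV(scene@truthDisplacement, file.path(dir, "truth_field.csv"),
                traction = scene@truthTraction, substrate = scene@substrate)
  utils::write.csv(scene@truthMetrics, file.path(dir, "truth_metrics.csv"),
                   row.names = FALSE)
  invisible(dir)
}
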