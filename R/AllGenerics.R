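#' @include AllClasses.R
NULL

#' Accessors for substrate parameters
#'
#' @param object A [SubstrateModel-class].
#' @return The corresponding scalar parameter.
#' @name substrate-accessors
#' @aliases youngModulus poissonRatio pixelSize
#' @examples
#' s <- SubstrateModel(12000, 0.5, 0.16)
#' c(youngModulus(s), poissonRatio(s), pixelSize(s))
NULL

#' @rdname substrate-accessors
#' @export
setGeneric("youngModulus", function(object) standardGeneric("youngModulus"))

#' @rdname substrate-accessors
#' @export
setGeneric("poissonRatio", function(object) standardGeneric("poissonRatio"))

#' @rdname substrate-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' Accessors for gridded vector fields
#'
#' `vectorX()`/`vectorY()` return the component matrices, `gridOrigin()`
#' and `gridSpacing()` the grid geometry, `fieldUnit()` the unit tag,
#' `magnitude()` the per-node Euclidean magnitude, and `nodeCoords()` a
#' two-column matrix of (x, y) pixel coordinates of all nodes in
#' column-major node order.
#'
#' @param object A [VectorGrid-class] derivative.
#' @name grid-accessors
#' @aliases vectorX vectorY gridOrigin gridSpacing fieldUnit magnitude
#'   nodeCoords
NULL

#' @rdname grid-accessors
#' @export
setGeneric("vectorX", function(object) standardGeneric("vectorX"))

#' @rdname grid-accessors
#' @export
setGeneric("vectorY", function(object) standardGeneric("vectorY"))

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(object) standardGeneric("gridOrigin"))

#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(object) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("fieldUnit", function(object) standardGeneric("fieldUnit"))

#' @rdname grid-accessors
#' @export
setGeneric("magnitude", function(object) standardGeneric("magnitude"))

#' @rdname grid-accessors
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))
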