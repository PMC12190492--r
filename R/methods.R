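#' @include AllGenerics.R
NULL

#' @rdname substrate-accessors
setMethod("youngModulus", "SubstrateModel", function(object) object@youngModulus)

#' @rdname substrate-accessors
setMethod("poissonRatio", "SubstrateModel", function(object) object@poissonRatio)

#' @rdname substrate-accessors
setMethod("pixelSize", "SubstrateModel", function(object) object@pixelSize)

#' @rdname grid-accessors
setMethod("vectorX", "VectorGrid", function(object) object@vx)

#' @rdname grid-accessors
setMethod("vectorY", "VectorGrid", function(object) object@vy)

#' @rdname grid-accessors
setMethod("gridOrigin", "VectorGrid", function(object) object@origin)

#' @rdname grid-accessors
setMethod("gridSpacing", "VectorGrid", function(object) object@spacing)

#' @rdname grid-accessors
setMethod("fieldUnit", "VectorGrid", function(object) object@unit)

#' @rdname grid-accessors
setMethod("magnitude", "VectorGrid", function(object)
  sqrt(object@vx^2 + object@vy^2))

#' @rdname grid-accessors
setMethod("nodeCoords", "VectorGrid", function(object) {
  d <- dim(object@vx)
  xs <- object@origin[1] + (seq_len(d[2]) - 1) * object@spacing
  ys <- object@origin[2] + (seq_len(d[1]) - 1) * object@spacing
  cbind(x = rep(xs, each = d[1]), y = rep(ys, times = d[2]))
})

#' @rdname grid-accessors
#' @param x A [VectorGrid-class] derivative.
#' @export
setMethod("dim", "VectorGrid", function(x) dim(x@vx))

setMethod("show", "SubstrateModel", function(object) {
  cat("SubstrateModel: E =", object@youngModulus, "Pa, nu =",
      object@poissonRatio, ", pixel size =", object@pixelSize, "um/px\n")
})

setMethod("show", "VectorGrid", function(object) {
  d <- dim(object@vx)
  m <- sqrt(object@vx^2 + object@vy^2)
  cat(class(object), ": ", d[1], " x ", d[2], " nodes, spacing ",
      object@spacing, " px, origin (", object@origin[1], ", ",
      object@origin[2], ")\n", sep = "")
  cat("  |v| [", object@unit, "]: max ", signif(max(m), 4),
      ", mean ", signif(mean(m), 4), "\n", sep = "")
})

setMethod("show", "BeadDisplacements", function(object) {
  n <- length(object@x)
  nt <- sum(object@tracked)
  cat("BeadDisplacements:", n, "beads,", nt, "tracked\n")
  if (nt) {
    m <- sqrt(object@dx[object@tracked]^2 + object@dy[object@tracked]^2)
    cat("  |u| [px]: median", signif(stats::median(m), 4),
        ", max", signif(max(m), 4), "\n")
  }
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:", nrow(object@relaxed), "x", ncol(object@relaxed),
      "px,", nrow(object@beadsRelaxed), "beads, seed", object@seed, "\n")
  cat("  truth max traction:",
      signif(object@truthMetrics$max_traction_pa, 4), "Pa\n")
})

#' @describeIn BeadDisplacements-class Coerce to a `data.frame` with
#'   columns `x, y, dx, dy, status` (`status` is `"tracked"` or `"lost"`).
#' @param x A [BeadDisplacements-class].
#' @param ... Ignored.
#' @method as.data.frame BeadDisplacements
#' @export
as.data.frame.BeadDisplacements <- function(x, ...) {
  data.frame(x = x@x, y = x@y, dx = x@dx, dy = x@dy,
             status = ifelse(x@tracked, "tracked", "lost"))
}

setMethod("as.data.frame", "BeadDisplacements", as.data.frame.BeadDisplacements)

#' Number of beads in a scattered field
#' @param x A [BeadDisplacements-class].
#' @export
setMethod("length", "BeadDisplacements", function(x) length(x@x))
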