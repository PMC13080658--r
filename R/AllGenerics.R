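#' Accessors for image volumes and related objects
#'
#' `voxelData` returns the raw array (z, y, x); `spacing` and `origin` the
#' voxel geometry in um; `voxelRole` the role tag. `fixedPoints` /
#' `movingPoints` return landmark coordinate matrices.
#'
#' @param x an object.
#' @return The slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("voxelRole", function(x) standardGeneric("voxelRole"))
#' @rdname accessors
#' @export
setGeneric("fixedPoints", function(x) standardGeneric("fixedPoints"))
#' @rdname accessors
#' @export
setGeneric("movingPoints", function(x) standardGeneric("movingPoints"))
#' @rdname accessors
#' @export
setGeneric("landmarkNames", function(x) standardGeneric("landmarkNames"))

#' @rdname accessors
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelRole", "ImageVolume", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("voxelData", "Kymograph", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("fixedPoints", "LandmarkSet", function(x) x@fixed)
#' @rdname accessors
#' @export
setMethod("movingPoints", "LandmarkSet", function(x) x@moving)
#' @rdname accessors
#' @export
setMethod("landmarkNames", "LandmarkSet", function(x) x@names)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("lineInterval", function(x) standardGeneric("lineInterval"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Kymograph", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("lineInterval", "Kymograph", function(x) x@lineInterval)

#' @rdname accessors
#' @export
setGeneric("vesselSegments", function(x) standardGeneric("vesselSegments"))
#' @rdname accessors
#' @export
setMethod("vesselSegments", "PhantomScene", function(x) x@segments)
#' @rdname accessors
#' @export
setGeneric("bifurcationPoints", function(x) standardGeneric("bifurcationPoints"))
#' @rdname accessors
#' @export
setMethod("bifurcationPoints", "PhantomScene", function(x) x@bifurcations)
#' @rdname accessors
#' @export
setGeneric("tumorField", function(x) standardGeneric("tumorField"))
#' @rdname accessors
#' @export
setMethod("tumorField", "PhantomScene", function(x) x@tumorField)

setMethod("show", "ImageVolume", function(object) {
    d <- dim(object@data)
    cat(sprintf("%s of dimension %d x %d x %d (z, y, x)\n",
                class(object), d[1], d[2], d[3]))
    cat(sprintf("  spacing (um): %s | origin (um): %s | role: %s\n",
                paste(signif(object@spacing, 6), collapse = " x "),
                paste(signif(object@origin, 6), collapse = ", "),
                object@role))
    rng <- suppressWarnings(range(object@data, na.rm = TRUE))
    cat(sprintf("  value range: [%.6g, %.6g]\n", rng[1], rng[2]))
})

setMethod("show", "LandmarkSet", function(object) {
    cat(sprintf("LandmarkSet with %d paired points (world um, z/y/x)\n",
                nrow(object@fixed)))
    cat(sprintf("  RMSE fixed vs moving: %.4g um\n",
                landmarkRMSE(object@fixed, object@moving)))
})

setMethod("show", "SpatialTransform", function(object) {
    cat(sprintf("SpatialTransform: %s (%dD)\n", object@kind,
                object@dimension))
    if (object@kind == "composite") {
        cat(sprintf("  chain of %d transforms: %s\n", length(object@chain),
                    paste(vapply(object@chain, slot, "", "kind"),
                          collapse = " -> ")))
    } else if (object@kind == "tps") {
        cat(sprintf("  %d control points\n", nrow(object@ctrl)))
    } else {
        cat(sprintf("  translation (um): %s\n",
                    paste(signif(object@t, 6), collapse = ", ")))
    }
})

setMethod("show", "Kymograph", function(object) {
    cat(sprintf(
        "Kymograph: %d lines x %d px | pixel %.4g um | interval %.4g ms\n",
        nrow(object@data), ncol(object@data), object@pixelSize,
        object@lineInterval))
})

setMethod("show", "PhantomScene", function(object) {
    cat(sprintf("PhantomScene: %d vessel segments, %d bifurcations\n",
                length(object@segments), nrow(object@bifurcations)))
    cat(sprintf("  extent (um): %s | tumor field: %s | deformation: %s\n",
                paste(signif(object@extent, 6), collapse = " x "),
                if (is.null(object@tumorField)) "none" else "present",
                if (is.null(object@deformation)) "none"
                else object@deformation@kind))
})
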