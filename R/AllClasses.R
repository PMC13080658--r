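#' @title Core S4 classes
#' @name micromri-classes
#' @aliases ImageVolume-class BinaryMask-class LabelMask-class
#'   LandmarkSet-class SpatialTransform-class Kymograph-class
#'   PhantomScene-class
#' @description
#' `ImageVolume` is the unit of exchange between all pipeline stages: a 3D
#' scalar array in (z, y, x) axis order plus per-axis voxel spacing (um),
#' the world position (um) of the center of voxel (0,0,0), and a role tag
#' (`"intensity"`, `"density"` or `"probability"`). `BinaryMask` and
#' `LabelMask` specialize it for logical and non-negative integer grids.
NULL

setClass("ImageVolume",
    representation(
        data = "array",
        spacing = "numeric",
        origin = "numeric",
        role = "character"
    ),
    prototype(
        spacing = c(1, 1, 1),
        origin = c(0, 0, 0),
        role = "intensity"
    )
)

setValidity("ImageVolume", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
        msg <- c(msg, "data must be a 3D array (z, y, x)")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        msg <- c(msg, "spacing must be 3 strictly positive values (z, y, x)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        msg <- c(msg, "origin must be 3 finite values (z, y, x)")
    if (!object@role %in% c("intensity", "density", "probability"))
        msg <- c(msg, "role must be intensity, density or probability")
    if (object@role %in% c("density", "probability")) {
        rng <- range(object@data, na.rm = TRUE)
        if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9))
            msg <- c(msg, sprintf(
                "%s values must lie in [0,1] (observed %.4g..%.4g)",
                object@role, rng[1], rng[2]))
    }
    if (length(msg)) msg else TRUE
})

setClass("BinaryMask", contains = "ImageVolume")

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@data))
        "BinaryMask data must be a logical array" else TRUE
})

setClass("LabelMask", contains = "ImageVolume")

setValidity("LabelMask", function(object) {
    d <- object@data
    if (!(is.integer(d) || (is.numeric(d) && all(d == round(d), na.rm = TRUE))))
        return("LabelMask data must be integer-valued")
    if (any(d < 0, na.rm = TRUE))
        return("LabelMask labels must be non-negative (0 = background)")
    TRUE
})

#' Construct an image volume
#'
#' @param data 3D array, axis order (z, y, x).
#' @param spacing voxel spacing in um per axis (z, y, x); strictly positive.
#' @param origin world um of the center of voxel (0, 0, 0).
#' @param role one of `"intensity"`, `"density"`, `"probability"`. Density
#'   and probability volumes are clamped to \[0, 1\].
#' @return An `ImageVolume`.
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 4)), spacing = c(100, 100, 100))
#' spacing(v)
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        role = "intensity") {
    if (is.null(dim(data))) dim(data) <- c(length(data), 1L, 1L)
    storage.mode(data) <- "double"
    if (role %in% c("density", "probability"))
        data <- pmin(pmax(data, 0), 1)
    new("ImageVolume", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), role = role)
}

#' @rdname ImageVolume
#' @export
BinaryMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    if (!is.logical(data)) {
        d <- array(as.logical(data != 0), dim(data))
        data <- d
    }
    new("BinaryMask", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), role = "intensity")
}

#' @rdname ImageVolume
#' @export
LabelMask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(data) <- "integer"
    new("LabelMask", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), role = "intensity")
}

setClass("LandmarkSet",
    representation(
        fixed = "matrix",
        moving = "matrix",
        names = "character"
    )
)

setValidity("LandmarkSet", function(object) {
    msg <- character()
    if (ncol(object@fixed) != 3L || ncol(object@moving) != 3L)
        msg <- c(msg, "landmark points must be N x 3 (z, y, x world um)")
    if (nrow(object@fixed) != nrow(object@moving))
        msg <- c(msg, "fixed and moving landmark counts differ")
    if (nrow(object@fixed) < 1L)
        msg <- c(msg, "at least one landmark pair is required")
    if (length(object@names) != nrow(object@fixed))
        msg <- c(msg, "one name per landmark pair is required")
    if (nrow(object@fixed) > 1L) {
        d <- as.matrix(stats::dist(object@fixed))
        diag(d) <- Inf
        if (min(d) < 1e-6)
            msg <- c(msg, "duplicate fixed points (within 1e-6 um)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a landmark set
#'
#' Paired fixed/moving 3D points in world um, axis order (z, y, x).
#'
#' @param fixed,moving N x 3 matrices of world coordinates (um).
#' @param names optional landmark labels.
#' @return A `LandmarkSet`.
#' @export
LandmarkSet <- function(fixed, moving, names = NULL) {
    fixed <- as.matrix(fixed); moving <- as.matrix(moving)
    storage.mode(fixed) <- storage.mode(moving) <- "double"
    if (is.null(names)) names <- sprintf("L%03d", seq_len(nrow(fixed)))
    new("LandmarkSet", fixed = fixed, moving = moving,
        names = as.character(names))
}

setClass("SpatialTransform",
    representation(
        kind = "character",       # rigid | similarity | affine | tps | composite
        dimension = "integer",
        A = "matrix",             # linear part (affine part for TPS)
        t = "numeric",            # translation
        ctrl = "matrix",          # TPS control (fixed) points
        W = "matrix",             # TPS kernel weights (n_ctrl x dim)
        chain = "list"            # composite: transforms applied in order
    )
)

setValidity("SpatialTransform", function(object) {
    k <- object@kind
    if (!k %in% c("rigid", "similarity", "affine", "tps", "composite"))
        return("unknown transform kind")
    d <- object@dimension
    if (!d %in% c(2L, 3L)) return("dimensionality must be 2 or 3")
    if (k %in% c("rigid", "similarity", "affine", "tps")) {
        if (!all(dim(object@A) == c(d, d)))
            return("linear part must be dim x dim")
        if (length(object@t) != d)
            return("translation length must equal dimension")
    }
    if (k == "rigid") {
        R <- object@A
        if (max(abs(crossprod(R) - diag(d))) > 1e-6 || det(R) < 0)
            return("rigid rotation part must be orthonormal with det +1")
    }
    if (k == "similarity") {
        s <- det(object@A)^(1 / d)
        if (!is.finite(s) || s <= 0)
            return("similarity scale must be positive")
        R <- object@A / s
        if (max(abs(crossprod(R) - diag(d))) > 1e-6)
            return("similarity must be rotation times positive scale")
    }
    if (k == "composite" && length(object@chain) == 0L)
        return("composite transform needs a non-empty chain")
    TRUE
})

setClass("Kymograph",
    representation(
        data = "matrix",          # time lines x position px
        pixelSize = "numeric",    # um per position pixel
        lineInterval = "numeric"  # ms per line
    )
)

setValidity("Kymograph", function(object) {
    msg <- character()
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive value (um)")
    if (length(object@lineInterval) != 1L || object@lineInterval <= 0)
        msg <- c(msg, "lineInterval must be a single positive value (ms)")
    if (length(msg)) msg else TRUE
})

#' Construct a kymograph
#'
#' @param data matrix, rows = scan lines (time), columns = position pixels.
#' @param pixelSize um per position pixel.
#' @param lineInterval ms per scan line.
#' @return A `Kymograph`.
#' @export
Kymograph <- function(data, pixelSize, lineInterval) {
    new("Kymograph", data = as.matrix(data), pixelSize = pixelSize,
        lineInterval = lineInterval)
}

setClass("PhantomScene",
    representation(
        segments = "list",        # VesselSegment records
        bifurcations = "matrix",  # branch points, world um (z,y,x)
        tumorField = "ANY",       # ImageVolume or NULL
        deformation = "ANY",      # SpatialTransform or NULL
        extent = "numeric",       # scene extent um (z,y,x)
        seed = "integer"
    )
)

setValidity("PhantomScene", function(object) {
    msg <- character()
    if (length(object@extent) != 3L || any(object@extent <= 0))
        msg <- c(msg, "extent must be 3 positive values (z, y, x um)")
    for (s in object@segments) {
        if (nrow(s$points) < 2L)
            msg <- c(msg, "every vessel segment needs >= 2 centerline points")
        if (any(s$radius <= 0))
            msg <- c(msg, "vessel radii must be positive")
    }
    if (length(msg)) unique(msg) else TRUE
})
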