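#' Voxel / world coordinate conversion
#'
#' Converts between 0-based voxel indices and world coordinates (um) under
#' the voxel-center convention `world = origin + index * spacing`. Both
#' functions accept an N x 3 matrix (columns z, y, x) or a length-3 vector.
#'
#' @param volume an [ImageVolume] (or mask) providing the grid geometry.
#' @param index 0-based voxel indices (may be fractional).
#' @param world world coordinates in um.
#' @return An N x 3 matrix.
#' @examples
#' v <- ImageVolume(array(0, c(4, 4, 4)), spacing = c(100, 50, 50),
#'                  origin = c(10, 0, 0))
#' indexToWorld(v, c(1, 1, 1))
#' worldToIndex(v, indexToWorld(v, c(1, 1, 1)))
#' @export
indexToWorld <- function(volume, index) {
    idx <- asPointMatrix(index)
    sweep(sweep(idx, 2, spacing(volume), "*"), 2, origin(volume), "+")
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(volume, world) {
    w <- asPointMatrix(world)
    sweep(sweep(w, 2, origin(volume), "-"), 2, spacing(volume), "/")
}

asPointMatrix <- function(p) {
    if (is.null(dim(p))) p <- matrix(p, nrow = 1)
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    p
}

#' Grid geometry helpers
#'
#' `sameGrid` tests that two volumes share shape, spacing and origin (to
#' `tol` um); `gridCenters` returns the world coordinates of all voxel
#' centers in array order.
#'
#' @param a,b volumes to compare.
#' @param tol tolerance in um.
#' @return `sameGrid`: logical. `gridCenters`: (n voxels) x 3 matrix.
#' @export
sameGrid <- function(a, b, tol = 1e-6) {
    all(dim(voxelData(a)) == dim(voxelData(b))) &&
        max(abs(spacing(a) - spacing(b))) <= tol &&
        max(abs(origin(a) - origin(b))) <= tol
}

#' @rdname sameGrid
#' @param volume volume whose voxel centers are wanted.
#' @export
gridCenters <- function(volume) {
    d <- dim(voxelData(volume))
    idx <- cbind(
        z = rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
        y = rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        x = rep(seq_len(d[3]) - 1, each = d[1] * d[2])
    )
    indexToWorld(volume, idx)
}

#' Clamp a density/probability volume into [0, 1]
#'
#' @param volume an [ImageVolume].
#' @return The volume with values clamped to \[0, 1\].
#' @export
clampUnit <- function(volume) {
    ImageVolume(pmin(pmax(voxelData(volume), 0), 1), spacing(volume),
                origin(volume), role = voxelRole(volume))
}
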