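#' Sample a volume at arbitrary world points
#'
#' Trilinear or nearest-neighbor interpolation at world coordinates (um);
#' points outside the voxel-center hull (linear) or the grid (nearest)
#' receive `fill`.
#'
#' @param volume an [ImageVolume] or mask.
#' @param points N x 3 matrix of world um (z, y, x).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill out-of-field value.
#' @return numeric vector of sampled values.
#' @export
sampleVolumeAt <- function(volume, points,
                           interpolation = c("linear", "nearest"),
                           fill = 0) {
    interpolation <- match.arg(interpolation)
    arr <- voxelData(volume)
    storage.mode(arr) <- "double"
    d <- dim(arr)
    idx <- worldToIndex(volume, points)
    n <- nrow(idx)
    if (interpolation == "nearest") {
        r <- round(idx)
        ok <- r[, 1] >= 0 & r[, 1] <= d[1] - 1 &
              r[, 2] >= 0 & r[, 2] <= d[2] - 1 &
              r[, 3] >= 0 & r[, 3] <= d[3] - 1
        out <- rep(fill, n)
        if (any(ok)) {
            lin <- r[ok, 1] + d[1] * (r[ok, 2] + d[2] * r[ok, 3]) + 1
            out[ok] <- arr[lin]
        }
        return(out)
    }
    f0 <- floor(idx)
    w <- idx - f0
    ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
          idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
          idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
    out <- rep(fill, n)
    if (!any(ok)) return(out)
    f0 <- f0[ok, , drop = FALSE]
    w <- w[ok, , drop = FALSE]
    acc <- numeric(nrow(f0))
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
        wt <- (if (dz) w[, 1] else 1 - w[, 1]) *
              (if (dy) w[, 2] else 1 - w[, 2]) *
              (if (dx) w[, 3] else 1 - w[, 3])
        nz <- wt > 0
        if (!any(nz)) next
        i <- pmin(f0[nz, 1] + dz, d[1] - 1)
        j <- pmin(f0[nz, 2] + dy, d[2] - 1)
        k <- pmin(f0[nz, 3] + dx, d[3] - 1)
        acc[nz] <- acc[nz] + wt[nz] * arr[i + d[1] * (j + d[2] * k) + 1]
    }
    out[ok] <- acc
    out
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: `transform` maps target world coordinates into
#' moving world coordinates; each target voxel center is mapped and the
#' moving volume interpolated there. Masks should use
#' `interpolation = "nearest"` (the default for `BinaryMask`/`LabelMask`
#' inputs).
#'
#' @param moving volume to resample.
#' @param transform a `SpatialTransform` (target -> moving world), or
#'   `NULL` for identity.
#' @param targetGrid an [ImageVolume] (or mask) supplying the output
#'   geometry.
#' @param interpolation `"linear"`, `"nearest"`, or `NULL` to choose by
#'   input class.
#' @param fill out-of-field fill value.
#' @return A volume of the same class as `moving` on the target grid.
#' @export
resampleVolume <- function(moving, transform, targetGrid,
                           interpolation = NULL, fill = 0) {
    if (is.null(interpolation))
        interpolation <- if (is(moving, "BinaryMask") ||
                             is(moving, "LabelMask")) "nearest" else "linear"
    if (!interpolation %in% c("linear", "nearest"))
        stop("unknown interpolation: ", interpolation)
    pts <- gridCenters(targetGrid)
    if (!is.null(transform)) pts <- transformPoints(transform, pts)
    vals <- sampleVolumeAt(moving, pts, interpolation, fill)
    d <- dim(voxelData(targetGrid))
    out <- array(vals, d)
    if (is(moving, "BinaryMask"))
        BinaryMask(out != 0, spacing(targetGrid), origin(targetGrid))
    else if (is(moving, "LabelMask"))
        LabelMask(out, spacing(targetGrid), origin(targetGrid))
    else
        ImageVolume(out, spacing(targetGrid), origin(targetGrid),
                    role = voxelRole(moving))
}

#' Reslice a volume to a plane
#'
#' Rotates the sampling frame so that the output z-axis is parallel to the
#' given plane normal (e.g. the cranial window glass used as a common
#' reslicing frame across modalities), then resamples linearly. The
#' returned rigid transform maps new-frame world coordinates to old-frame
#' world coordinates.
#'
#' @param volume input [ImageVolume].
#' @param point a point on the plane, world um (defaults to the volume
#'   center).
#' @param normal plane normal in world (z, y, x) components; need not be
#'   unit length.
#' @param outSpacing output voxel spacing (defaults to input spacing).
#' @param fill out-of-field fill.
#' @return list with `volume` (resliced) and `transform` (new -> old).
#' @export
resliceToPlane <- function(volume, point = NULL, normal = c(1, 0, 0),
                           outSpacing = NULL, fill = 0) {
    if (vnorm(normal) == 0) stop("plane normal must be non-zero")
    d <- dim(voxelData(volume))
    sp <- if (is.null(outSpacing)) spacing(volume)
          else rep(outSpacing, length.out = 3)
    if (is.null(point))
        point <- as.numeric(indexToWorld(volume, (d - 1) / 2))
    ez <- normal / vnorm(normal)
    # pick the world axis least aligned with the normal to seed the frame
    seed <- diag(3)[which.min(abs(ez)), ]
    ey <- seed - sum(seed * ez) * ez
    ey <- ey / vnorm(ey)
    ex <- c(ez[2] * ey[3] - ez[3] * ey[2],
            ez[3] * ey[1] - ez[1] * ey[3],
            ez[1] * ey[2] - ez[2] * ey[1])
    R <- cbind(ez, ey, ex)   # columns: new axes in old coordinates
    # output extent: project input corner offsets onto the new axes
    corners <- as.matrix(expand.grid(z = c(0, d[1] - 1), y = c(0, d[2] - 1),
                                     x = c(0, d[3] - 1)))
    cw <- sweep(indexToWorld(volume, corners), 2, point)
    proj <- cw %*% R
    lo <- apply(proj, 2, min); hi <- apply(proj, 2, max)
    nOut <- pmax(1L, floor((hi - lo) / sp) + 1L)
    originNew <- lo
    # new-frame world p -> old world: point + R p
    tr <- newLinearOrTps("rigid", 3L, R, as.numeric(point))
    target <- ImageVolume(array(0, nOut), spacing = sp, origin = originNew)
    out <- resampleVolume(volume, tr, target, interpolation = "linear",
                          fill = fill)
    list(volume = out, transform = tr)
}

#' Upscale the in-plane (x, y) grid of an MRI volume
#'
#' Linear interpolation in x and y only (z untouched), used to bring the
#' MRI grid to the microscopy in-plane resolution before landmark
#' registration. The world extent of the volume is preserved to within one
#' target voxel.
#'
#' @param mri input [ImageVolume].
#' @param targetXY target in-plane spacing, um (scalar or (y, x)).
#' @return An [ImageVolume] with spacing (z, targetXY).
#' @export
matchGridXY <- function(mri, targetXY) {
    targetXY <- rep(targetXY, length.out = 2)
    sp <- spacing(mri)
    if (any(targetXY > sp[2:3] + 1e-9))
        stop("target spacing must not be coarser than the MRI grid")
    d <- dim(voxelData(mri))
    newN <- c(d[1], round(d[2] * sp[2] / targetXY[1]),
              round(d[3] * sp[3] / targetXY[2]))
    newSp <- c(sp[1], targetXY)
    edge <- origin(mri) - sp / 2
    newOrigin <- c(origin(mri)[1], edge[2:3] + newSp[2:3] / 2)
    target <- ImageVolume(array(0, newN), spacing = newSp,
                          origin = newOrigin)
    resampleVolume(clampEdgesXY(mri), NULL, target,
                   interpolation = "linear")
}

# extend sampling beyond the first/last voxel centers in x/y by clamping:
# avoids a half-voxel fill border when upsampling in place
clampEdgesXY <- function(vol) {
    arr <- voxelData(vol)
    d <- dim(arr)
    pad <- array(0, d + c(0, 2, 2))
    pad[, 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
    pad[, 1, ] <- pad[, 2, ]; pad[, d[2] + 2, ] <- pad[, d[2] + 1, ]
    pad[, , 1] <- pad[, , 2]; pad[, , d[3] + 2] <- pad[, , d[3] + 1]
    ImageVolume(pad, spacing(vol),
                origin(vol) - c(0, spacing(vol)[2], spacing(vol)[3]),
                role = voxelRole(vol))
}
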