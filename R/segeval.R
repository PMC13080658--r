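#' Binarize a probability or intensity volume
#'
#' Voxel is foreground iff `value >= threshold` (raw units; 10000
#' corresponds to the conventional cutoff on 16-bit probability maps).
#'
#' @param prob [ImageVolume].
#' @param threshold cutoff in the volume's raw units.
#' @return [BinaryMask].
#' @export
binarize <- function(prob, threshold) {
    BinaryMask(voxelData(prob) >= threshold, spacing(prob), origin(prob))
}

#' Tolerance-aware Dice overlap (Dilated Dice)
#'
#' `DD = (|A intersect D(B)| + |D(A) intersect B|) / (|A| + |B|)`, where
#' `D(X)` dilates `X` by a world-metric ball of radius `toleranceUm` (a
#' voxel belongs to the dilation iff its center lies within the
#' tolerance of some foreground voxel center). Credits matches within
#' the registration tolerance; at tolerance 0 it reduces to the plain
#' Dice coefficient, and `DD(A, A) = 1`. With 100 um slice spacing a
#' 50 um ball adds no out-of-plane neighbors; raise the tolerance if
#' cross-slice credit is wanted.
#'
#' @param A ground-truth [BinaryMask].
#' @param B prediction [BinaryMask] on the same grid.
#' @param toleranceUm dilation radius, um (default 50).
#' @return value in \[0, 1\].
#' @export
dilatedDice <- function(A, B, toleranceUm = 50) {
    if (!sameGrid(A, B)) stop("masks are on different grids")
    if (toleranceUm < 0) stop("tolerance must be >= 0")
    a <- voxelData(A); b <- voxelData(B)
    nA <- sum(a); nB <- sum(b)
    if (nA + nB == 0) stop("both masks are empty; overlap undefined")
    tol <- toleranceUm + 1e-9
    dA <- if (nA) distanceToMask(A) <= tol else array(FALSE, dim(a))
    dB <- if (nB) distanceToMask(B) <= tol else array(FALSE, dim(b))
    (sum(a & dB) + sum(dA & b)) / (nA + nB)
}

#' Mean absolute surface distance (MASD)
#'
#' `( sum_{a in A} d(a, B) + sum_{b in B} d(b, A) ) / (|A| + |B|)` with
#' Euclidean world distances (um) between voxel centers, computed over
#' all foreground voxels (set `surfaceOnly = TRUE` for the conventional
#' ASSD over boundary voxels). Symmetric; 0 iff the masks are equal as
#' voxel sets.
#'
#' @param A,B nonempty [BinaryMask]s on one grid.
#' @param surfaceOnly restrict both sets to their boundary voxels.
#' @return distance in um.
#' @export
masd <- function(A, B, surfaceOnly = FALSE) {
    if (!sameGrid(A, B)) stop("masks are on different grids")
    a <- voxelData(A); b <- voxelData(B)
    if (!any(a) || !any(b)) stop("MASD needs two nonempty masks")
    if (surfaceOnly) {
        A <- BinaryMask(surfaceVoxels(a), spacing(A), origin(A))
        B <- BinaryMask(surfaceVoxels(b), spacing(B), origin(B))
        a <- voxelData(A); b <- voxelData(B)
    }
    dToB <- distanceToMask(B)
    dToA <- distanceToMask(A)
    (sum(dToB[a]) + sum(dToA[b])) / (sum(a) + sum(b))
}

# 6-neighborhood boundary: foreground voxels with a background face
# neighbor (volume faces count as boundary)
surfaceVoxels <- function(arr) {
    d <- dim(arr)
    pad <- array(FALSE, d + 2L)
    pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- arr
    core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
    allN <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
            pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
            pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
    core & !allN
}

#' Subject-grouped k-fold cross-validation split
#'
#' Partitions dataset ids into k folds, grouping by subject so the same
#' animal never appears in both train and validation; fold sizes (in
#' groups) differ by at most one. Deterministic under `seed`.
#'
#' @param ids dataset identifiers.
#' @param k number of folds (default 5).
#' @param groupBy subject id per dataset (default: ids themselves).
#' @param seed integer seed.
#' @return list of class `FoldAssignment`: `fold` (0-based fold per id),
#'   `k`, `seed`.
#' @export
crossvalSplit <- function(ids, k = 5, groupBy = NULL, seed = 1) {
    if (is.null(groupBy)) groupBy <- ids
    if (length(groupBy) != length(ids))
        stop("groupBy must have one entry per id")
    groups <- unique(groupBy)
    if (length(groups) < k)
        stop("fewer groups (", length(groups), ") than folds (", k, ")")
    perm <- withSeed(seed, sample(groups))
    gf <- setNames(rep(seq_len(k) - 1L, length.out = length(perm)), perm)
    fold <- unname(gf[as.character(groupBy)])
    structure(list(fold = setNames(as.integer(fold), ids), k = as.integer(k),
                   seed = as.integer(seed)),
              class = "FoldAssignment")
}

#' @export
print.FoldAssignment <- function(x, ...) {
    cat(sprintf("%d-fold split of %d datasets (seed %d)\n", x$k,
                length(x$fold), x$seed))
    print(table(fold = x$fold))
    invisible(x)
}

#' Prepare image/label training pairs for an external segmentation network
#'
#' Resamples a registered image/ground-truth pair to the training grid
#' (in-plane 25 um, slice depth 100 um by default), removes label
#' structures below the minimum diameter, binarizes, optionally crops,
#' and applies random in-plane flips and 90-degree rotations identically
#' to image and label. Deterministic under `seed`. The network itself is
#' external; [exportTrainingPairs] writes the folder layout it consumes.
#'
#' @param image registered intensity [ImageVolume] (microscopy on the MRI
#'   frame).
#' @param label vessel ground truth ([BinaryMask] or probability
#'   [ImageVolume] with `labelThreshold`).
#' @param targetSpacing training grid spacing um (z, y, x); default
#'   c(100, 25, 25).
#' @param minDiameter vessel diameter filter, um.
#' @param labelThreshold binarization threshold for probability labels.
#' @param nAugment augmented copies per source pair (flips/rotations).
#' @param seed integer seed.
#' @return list of pairs, each `list(image =, label =, case =)`.
#' @export
prepTrainingPairs <- function(image, label, targetSpacing = c(100, 25, 25),
                              minDiameter = 30, labelThreshold = 0.5,
                              nAugment = 3, seed = 1) {
    if (!sameGrid(image, label))
        stop("image and label are not registered on a common grid")
    ext <- dim(voxelData(image)) * spacing(image)
    n <- pmax(1L, floor(ext / targetSpacing))
    target <- ImageVolume(array(0, n), spacing = targetSpacing,
                          origin = origin(image) - spacing(image) / 2 +
                              targetSpacing / 2)
    img <- resampleVolume(image, NULL, target, interpolation = "linear")
    labMask <- if (is(label, "BinaryMask")) label
               else binarize(label, labelThreshold)
    lab <- resampleVolume(labMask, NULL, target, interpolation = "nearest")
    lab <- filterByDiameter(lab, minDiameter)
    augments <- withSeed(seed, lapply(seq_len(nAugment), function(i)
        list(flipY = runif(1) < 0.5, flipX = runif(1) < 0.5,
             rot = sample(0:3, 1))))
    pairs <- vector("list", nAugment + 1L)
    pairs[[1]] <- list(image = img, label = lab, case = "CASE_0000")
    for (i in seq_len(nAugment)) {
        a <- augments[[i]]
        pairs[[i + 1L]] <- list(
            image = augmentVolume(img, a),
            label = augmentVolume(lab, a),
            case = sprintf("CASE_%04d", i))
    }
    pairs
}

# identical geometric augmentation for image and label: in-plane flips and
# k*90 degree rotations (rotations other than 180 require square xy)
augmentVolume <- function(vol, a) {
    arr <- voxelData(vol)
    if (a$flipY) arr <- arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]
    if (a$flipX) arr <- arr[, , rev(seq_len(dim(arr)[3])), drop = FALSE]
    rot <- a$rot %% 4
    if (rot > 0 && dim(arr)[2] != dim(arr)[3]) rot <- 2 * (rot %/% 2)
    for (r in seq_len(rot)) {
        arr <- aperm(arr, c(1, 3, 2))
        arr <- arr[, rev(seq_len(dim(arr)[2])), , drop = FALSE]
    }
    if (is(vol, "BinaryMask"))
        BinaryMask(arr, spacing(vol), origin(vol))
    else ImageVolume(arr, spacing(vol), origin(vol), role = voxelRole(vol))
}

#' @rdname prepTrainingPairs
#' @param pairs output of `prepTrainingPairs`.
#' @param dir output directory; `imagesTr/CASE_xxxx_0000.nii.gz` and
#'   `labelsTr/CASE_xxxx.nii.gz` are created.
#' @export
exportTrainingPairs <- function(pairs, dir) {
    dir.create(file.path(dir, "imagesTr"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(dir, "labelsTr"), recursive = TRUE,
               showWarnings = FALSE)
    for (p in pairs) {
        writeVolume(p$image, file.path(dir, "imagesTr",
                                       paste0(p$case, "_0000.nii.gz")))
        lab <- ImageVolume(voxelData(p$label) * 1.0, spacing(p$label),
                           origin(p$label))
        writeVolume(lab, file.path(dir, "labelsTr",
                                   paste0(p$case, ".nii.gz")))
    }
    invisible(dir)
}

#' Vessel visibility transition matrix
#'
#' Counts vessels moving between visibility categories (e.g. from the
#' raw MR image to a network prediction); entry (i, j) is the number of
#' vessels rated category i before and j after. Row/column totals
#' conserve the vessel count.
#'
#' @param before,after character vectors of per-vessel categories.
#' @param levels the category set, in display order.
#' @return a `table` (before x after).
#' @export
visibilityTransitions <- function(before, after,
                                  levels = c("strongly visible",
                                             "barely visible",
                                             "not visible")) {
    if (length(before) != length(after))
        stop("before/after must rate the same vessels")
    bad <- setdiff(unique(c(before, after)), levels)
    if (length(bad))
        stop("unknown visibility label(s): ", paste(bad, collapse = ", "))
    table(before = factor(before, levels),
          after = factor(after, levels))
}

#' Local vessel diameter at a probe point
#'
#' Reads the maximal-inscribed-sphere diameter at a probed world
#' position, enabling per-vessel diameter comparisons between a
#' prediction, a thresholded MR image and the microscopy ground truth.
#'
#' @param mask [BinaryMask] (e.g. thresholded MRI or prediction).
#' @param probe world um (z, y, x) inside a foreground component.
#' @param diameters optional precomputed diameter volume.
#' @return diameter in um.
#' @export
vesselDiameterFromMask <- function(mask, probe, diameters = NULL) {
    idx <- round(worldToIndex(mask, probe))
    d <- dim(voxelData(mask))
    if (any(idx < 0) || any(idx >= matrix(d, nrow(idx), 3, byrow = TRUE)))
        stop("probe point is outside the volume")
    lin <- idx[, 1] + d[1] * (idx[, 2] + d[2] * idx[, 3]) + 1
    if (!all(voxelData(mask)[lin]))
        stop("probe point is in the background")
    if (is.null(diameters)) diameters <- estimateLocalDiameter(mask)
    as.numeric(voxelData(diameters)[lin])
}
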