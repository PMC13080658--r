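#' Group microscopy z-slices to the MRI voxel depth
#'
#' Averages consecutive z-slices so one output slice spans one MRI voxel
#' depth. For a binary input the output voxel value is the foreground
#' volume fraction in \[0, 1\]. The MRI depth must be an integer multiple
#' of the stack slice spacing (within `tol` relative tolerance); a
#' trailing partial group is dropped with a warning.
#'
#' @param stack microscopy [ImageVolume] (or [BinaryMask]).
#' @param mriZSpacing target slice depth, um.
#' @param tol relative tolerance on the spacing ratio.
#' @return An [ImageVolume] with z spacing `mriZSpacing`; density role when
#'   the input was binary or a density.
#' @export
groupZByAverage <- function(stack, mriZSpacing, tol = 0.01) {
    sp <- spacing(stack)
    ratio <- mriZSpacing / sp[1]
    f <- round(ratio)
    if (f < 1 || abs(ratio - f) > tol * ratio)
        stop("MRI z spacing (", mriZSpacing, " um) is not an integer ",
             "multiple of the stack z spacing (", sp[1], " um); resample ",
             "the stack first")
    arr <- voxelData(stack) * 1.0
    d <- dim(arr)
    nOut <- d[1] %/% f
    if (nOut * f < d[1])
        warning("dropping trailing partial group of ", d[1] - nOut * f,
                " slice(s)")
    out <- blockMeanAxis(arr, as.integer(f), 1L)
    role <- if (is(stack, "BinaryMask") ||
                voxelRole(stack) %in% c("density", "probability"))
        "density" else "intensity"
    ImageVolume(out, spacing = c(mriZSpacing, sp[2], sp[3]),
                origin = c(origin(stack)[1] + (f - 1) / 2 * sp[1],
                           origin(stack)[2:3]),
                role = role)
}

#' Downscale a density map in x/y onto the MRI grid
#'
#' Brings a z-grouped, registered microscopy density map to the MRI
#' in-plane resolution so each output value is the density within that
#' MRI voxel (in \[0, 1\]). For integer scale factors >= 2 the
#' implementation is area-weighted block averaging, which preserves the
#' volume-fraction interpretation; for factors < 2 plain bilinear
#' sampling is used.
#'
#' @param micro density [ImageVolume], already z-grouped to the MRI depth.
#' @param mriGrid [ImageVolume] (or mask) defining the target geometry.
#' @return A density [ImageVolume] on `mriGrid`'s geometry.
#' @export
downsampleXYDensity <- function(micro, mriGrid) {
    spM <- spacing(micro); spG <- spacing(mriGrid)
    if (abs(spM[1] - spG[1]) > 0.01 * spG[1] ||
        dim(voxelData(micro))[1] != dim(voxelData(mriGrid))[1])
        stop("z grids differ; group the stack to the MRI depth first")
    fy <- spG[2] / spM[2]; fx <- spG[3] / spM[3]
    if (fy >= 2 && fx >= 2 &&
        abs(fy - round(fy)) < 0.01 && abs(fx - round(fx)) < 0.01) {
        arr <- voxelData(micro) * 1.0
        arr <- blockMeanAxis(arr, as.integer(round(fy)), 2L)
        arr <- blockMeanAxis(arr, as.integer(round(fx)), 3L)
        darr <- dim(arr); dg <- dim(voxelData(mriGrid))
        if (!all(darr == dg))
            stop("block-averaged grid ", paste(darr, collapse = "x"),
                 " does not match the MRI grid ",
                 paste(dg, collapse = "x"))
        out <- arr
    } else {
        out <- voxelData(resampleVolume(clampEdgesXY(micro), NULL, mriGrid,
                                        interpolation = "linear"))
    }
    ImageVolume(pmin(pmax(out, 0), 1), spacing(mriGrid), origin(mriGrid),
                role = "density")
}

#' Z-normalize MRI intensities to normal-appearing gray matter
#'
#' Standardizes a sequence by the mean and standard deviation of the
#' voxels inside the normal-appearing-gray-matter (NAGM) mask, so
#' intensities are comparable across sessions and sequences; only gray
#' matter is analyzed downstream. The whole volume is transformed; the
#' in-mask voxels have mean 0 and sd 1 afterwards.
#'
#' @param mri [ImageVolume].
#' @param nagmMask [BinaryMask] of normal-appearing gray matter on the
#'   same grid.
#' @param minVoxels minimum mask size for stable statistics.
#' @return list: `volume` (normalized) and `stats`
#'   (mean/sd/n, class `NormalizationStats`).
#' @export
znormalizeNagm <- function(mri, nagmMask, minVoxels = 30) {
    if (!sameGrid(mri, nagmMask))
        stop("MRI and NAGM mask are on different grids")
    vals <- voxelData(mri)[voxelData(nagmMask)]
    if (length(vals) == 0) stop("NAGM mask is empty")
    if (length(vals) < minVoxels)
        stop("NAGM mask has ", length(vals), " voxels; at least ",
             minVoxels, " required for stable statistics")
    m <- mean(vals); s <- sd(vals)
    if (!is.finite(s) || s == 0)
        stop("NAGM intensities have zero variance; normalization undefined")
    stats <- structure(list(mean = m, sd = s, n = length(vals)),
                       class = "NormalizationStats")
    list(volume = ImageVolume((voxelData(mri) - m) / s, spacing(mri),
                              origin(mri)),
         stats = stats)
}

#' @export
print.NormalizationStats <- function(x, ...) {
    cat(sprintf("NAGM normalization: mean %.6g, sd %.6g (n = %d voxels)\n",
                x$mean, x$sd, x$n))
    invisible(x)
}

#' Fit a mono-exponential T2* map from multi-echo data
#'
#' Per-voxel weighted log-linear regression of
#' `S(TE) = S0 * exp(-TE / T2*)`: `log S` is regressed on TE with weights
#' `S^2` (the standard variance-stabilizing choice for log-transformed
#' Rician-ish magnitude data). Non-physical fits (T2* <= 0 or above
#' `cap`) are masked invalid (NA).
#'
#' @param echoes list of [ImageVolume]s, one per echo, same grid.
#' @param echoTimes echo times, ms (>= 3).
#' @param cap physiological upper bound for T2*, ms.
#' @param floor intensity floor applied before the log.
#' @return list: `t2star` (ms, NA where invalid), `s0`, both
#'   [ImageVolume]s.
#' @export
fitT2starMap <- function(echoes, echoTimes, cap = 1000, floor = 1e-6) {
    if (length(echoes) < 3 || length(echoTimes) != length(echoes))
        stop("need >= 3 echoes with matching echo times")
    g <- echoes[[1]]
    for (e in echoes[-1]) if (!sameGrid(g, e))
        stop("echo volumes are on different grids")
    d <- dim(voxelData(g))
    nV <- prod(d); nE <- length(echoes)
    S <- matrix(0, nV, nE)
    for (j in seq_len(nE)) S[, j] <- pmax(as.numeric(voxelData(echoes[[j]])),
                                          floor)
    L <- log(S)
    W <- S^2
    te <- as.numeric(echoTimes)
    # closed-form weighted simple regression per voxel (vectorized)
    sw <- rowSums(W)
    mx <- rowSums(W * matrix(te, nV, nE, byrow = TRUE)) / sw
    my <- rowSums(W * L) / sw
    dx <- matrix(te, nV, nE, byrow = TRUE) - mx
    beta <- rowSums(W * dx * (L - my)) / rowSums(W * dx^2)
    t2 <- -1 / beta
    s0 <- exp(my - beta * mx)
    bad <- !is.finite(t2) | t2 <= 0 | t2 > cap
    t2[bad] <- NA_real_
    list(t2star = ImageVolume(array(t2, d), spacing(g), origin(g)),
         s0 = ImageVolume(array(s0, d), spacing(g), origin(g)))
}

#' Extract a paired voxel table
#'
#' One row per voxel with a positive category label, carrying the values
#' of every named layer (densities, normalized sequence intensities), the
#' voxel index and world position, and the supplied metadata.
#'
#' @param layers named list of [ImageVolume]s on one common grid.
#' @param categoryMask [LabelMask]; 0 = excluded, positive labels become
#'   the `category` column (named via `categoryLabels`).
#' @param categoryLabels optional character vector mapping label i to a
#'   name.
#' @param metadata named list of scalar columns (e.g. `timepoint_days`,
#'   `dataset_id`, `subject_id`).
#' @return data.frame (voxel table).
#' @export
extractVoxelTable <- function(layers, categoryMask, categoryLabels = NULL,
                              metadata = list()) {
    stopifnot(length(layers) >= 1, !is.null(names(layers)))
    for (nm in names(layers))
        if (!sameGrid(layers[[nm]], categoryMask))
            stop("layer '", nm, "' is not on the category mask grid")
    lab <- voxelData(categoryMask)
    sel <- which(lab > 0)
    d <- dim(lab)
    if (length(sel) == 0) {
        tab <- data.frame(iz = integer(), iy = integer(), ix = integer(),
                          wz = numeric(), wy = numeric(), wx = numeric(),
                          category = character())
        for (nm in names(layers)) tab[[nm]] <- numeric()
        return(tab)
    }
    sel0 <- sel - 1L
    iz <- sel0 %% d[1]
    iy <- (sel0 %/% d[1]) %% d[2]
    ix <- sel0 %/% (d[1] * d[2])
    w <- indexToWorld(categoryMask, cbind(iz, iy, ix))
    cat_ <- lab[sel]
    category <- if (is.null(categoryLabels)) as.character(cat_)
                else categoryLabels[cat_]
    tab <- data.frame(iz = iz, iy = iy, ix = ix,
                      wz = w[, 1], wy = w[, 2], wx = w[, 3],
                      category = category, stringsAsFactors = FALSE)
    for (nm in names(layers))
        tab[[nm]] <- as.numeric(voxelData(layers[[nm]])[sel])
    for (nm in names(metadata)) tab[[nm]] <- metadata[[nm]]
    tab
}

#' Bin voxels by density
#'
#' Groups voxel-table rows into the density classes used for
#' density-vs-intensity comparisons: `w/o glioma` (rows whose category is
#' `normalCategory`, density forced to 0), then half-open bins
#' `[0, 5) [5, 25) [25, 50) [50, 75)` percent and a closed top bin
#' `[75, 100]`.
#'
#' @param table voxel table with a density column.
#' @param densityColumn name of the density column (values in \[0, 1\]).
#' @param normalCategory category value marking normal tissue.
#' @param edges internal bin edges, percent.
#' @return the table with a `density_bin` factor column (levels ordered).
#' @export
binByDensity <- function(table, densityColumn = "glioma_density",
                         normalCategory = "w/o glioma",
                         edges = c(0, 5, 25, 50, 75, 100)) {
    dens <- table[[densityColumn]]
    if (is.null(dens)) stop("no column '", densityColumn, "' in table")
    if (any(dens < -1e-9 | dens > 1 + 1e-9, na.rm = TRUE))
        stop("densities outside [0, 1]")
    pct <- pmin(pmax(dens * 100, 0), 100)
    labs <- paste0(edges[-length(edges)], "-", edges[-1], "%")
    # half-open [lo, hi), top bin closed at 100
    bin <- cut(pct, breaks = edges, labels = labs, right = FALSE,
               include.lowest = FALSE)
    bin[pct >= edges[length(edges)]] <- labs[length(labs)]
    lev <- c(normalCategory, labs)
    out <- as.character(bin)
    normal <- !is.na(table$category) & table$category == normalCategory
    out[normal] <- normalCategory
    if (anyNA(out)) stop("unbinned densities remain")
    table$density_bin <- factor(out, levels = lev)
    table
}

#' Per-voxel growth rate from a registered longitudinal series
#'
#' Growth rate in percent density per day,
#' `100 * (density(t_last) - density(t_first)) / (t_last - t_first)`,
#' computed only inside the intersection of all timepoint masks (the
#' overlap mask built by intersecting every session's analysis mask).
#'
#' @param densities list of density [ImageVolume]s co-registered to the
#'   first timepoint, one per day.
#' @param days numeric vector of acquisition days.
#' @param masks optional list of [BinaryMask]s (one per timepoint); the
#'   overlap is their intersection. Default: everywhere.
#' @param perInterval if `TRUE`, also return per-interval rates.
#' @return data.frame: voxel index, density per timepoint, `growth_rate`
#'   (%/day), `overlap` flag.
#' @export
computeGrowthRate <- function(densities, days, masks = NULL,
                              perInterval = FALSE) {
    if (length(densities) < 2) stop("need >= 2 timepoints")
    if (length(days) != length(densities))
        stop("days and densities lengths differ")
    span <- days[length(days)] - days[1]
    if (span == 0) stop("zero day span between first and last timepoint")
    g <- densities[[1]]
    for (v in densities[-1]) if (!sameGrid(g, v))
        stop("density volumes are on different grids")
    d <- dim(voxelData(g))
    overlap <- array(TRUE, d)
    if (!is.null(masks))
        for (m in masks) overlap <- overlap & voxelData(m)
    sel <- which(overlap)
    sel0 <- sel - 1L
    tab <- data.frame(iz = sel0 %% d[1],
                      iy = (sel0 %/% d[1]) %% d[2],
                      ix = sel0 %/% (d[1] * d[2]))
    for (i in seq_along(densities))
        tab[[sprintf("density_d%g", days[i])]] <-
            as.numeric(voxelData(densities[[i]])[sel])
    first <- as.numeric(voxelData(densities[[1]])[sel])
    last <- as.numeric(voxelData(densities[[length(densities)]])[sel])
    tab$growth_rate <- 100 * (last - first) / span
    tab$overlap <- TRUE
    if (perInterval) {
        for (i in seq_len(length(days) - 1)) {
            a <- as.numeric(voxelData(densities[[i]])[sel])
            b <- as.numeric(voxelData(densities[[i + 1]])[sel])
            tab[[sprintf("rate_d%g_d%g", days[i], days[i + 1])]] <-
                100 * (b - a) / (days[i + 1] - days[i])
        }
    }
    tab
}
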