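#' Local vessel diameter (maximal inscribed sphere)
#'
#' Local thickness in world units: each foreground voxel is assigned the
#' diameter of the largest sphere that both fits inside the mask and
#' contains the voxel (distance-transform ridge propagation). Computed in
#' world um, so anisotropic spacing (e.g. 25/25/100 um) is handled
#' correctly. Off-axis voxels of a tube get the full tube diameter, which
#' is what a diameter threshold filter requires.
#'
#' @param mask [BinaryMask]; must contain at least one foreground voxel.
#' @return [ImageVolume] of diameters (um); 0 in the background.
#' @export
estimateLocalDiameter <- function(mask) {
    arr <- voxelData(mask)
    if (!any(arr)) stop("mask is empty")
    d <- dim(arr)
    sp <- spacing(mask)
    # inscribed radius: distance to the nearest background voxel center
    bg <- distanceToMask(BinaryMask(!arr, sp, origin(mask)))
    r <- array(0, d)
    r[arr] <- bg[arr]
    th <- cpp_local_thickness(as.numeric(r), as.integer(d), as.numeric(sp))
    ImageVolume(array(th, d), sp, origin(mask))
}

#' Filter a vessel mask by minimum diameter
#'
#' Removes voxels whose local diameter is below `minDiameter` um (the
#' visibility threshold for vessels in T2w is about 30 um, the default).
#' Never adds voxels and is idempotent.
#'
#' @param mask [BinaryMask].
#' @param minDiameter threshold, um.
#' @return filtered [BinaryMask].
#' @export
filterByDiameter <- function(mask, minDiameter = 30) {
    if (minDiameter <= 0) return(mask)
    if (!any(voxelData(mask)))
        return(mask)
    dia <- voxelData(estimateLocalDiameter(mask))
    keep <- voxelData(mask) & dia >= minDiameter
    BinaryMask(keep, spacing(mask), origin(mask))
}

#' Vessel diameter distribution
#'
#' Proportion of foreground voxels per diameter bin; proportions sum
#' to 1.
#'
#' @param mask [BinaryMask].
#' @param binEdges diameter bin edges, um, covering the observed range.
#' @param diameters optional precomputed diameter volume (from
#'   [estimateLocalDiameter]).
#' @return named numeric vector of proportions.
#' @export
diameterDistribution <- function(mask, binEdges = c(0, 30, 60, 120, Inf),
                                 diameters = NULL) {
    if (!any(voxelData(mask))) stop("mask is empty")
    if (is.null(diameters)) diameters <- estimateLocalDiameter(mask)
    dia <- voxelData(diameters)[voxelData(mask)]
    if (min(dia) < binEdges[1] || max(dia) > binEdges[length(binEdges)])
        stop("bin edges do not cover the observed diameter range (",
             signif(min(dia), 4), "-", signif(max(dia), 4), " um)")
    idx <- findInterval(dia, binEdges)            # bins [lo, hi)
    idx <- pmin(idx, length(binEdges) - 1L)       # top edge closed
    p <- tabulate(idx, nbins = length(binEdges) - 1L) / length(dia)
    names(p) <- paste0(binEdges[-length(binEdges)], "-",
                       binEdges[-1], "um")
    p
}

#' Equivalence-margin stability of category proportions
#'
#' For each category, the maximum absolute deviation of its proportion
#' from the reference timepoint across all timepoints; a category is
#' stable if that deviation stays within the a priori equivalence margin
#' (default +/-5%, i.e. 0.05 in proportion units).
#'
#' @param proportions matrix (timepoints x categories); each row must sum
#'   to 1 within 1e-6.
#' @param referenceIndex row index of the reference timepoint.
#' @param margin equivalence margin (proportion units).
#' @return list of class `EquivalenceReport`: `maxDeviation` and `stable`
#'   per category, `margin`, `referenceIndex`, `proportions`.
#' @export
equivalenceStability <- function(proportions, referenceIndex = 1,
                                 margin = 0.05) {
    p <- as.matrix(proportions)
    if (nrow(p) < 2) stop("need proportions for >= 2 timepoints")
    sums <- rowSums(p)
    if (any(abs(sums - 1) > 1e-6))
        stop("proportions must sum to 1 per timepoint (worst deviation ",
             signif(max(abs(sums - 1)), 3), ")")
    ref <- p[referenceIndex, ]
    dev <- sweep(p, 2, ref)
    maxDev <- apply(abs(dev), 2, max)
    if (is.null(names(maxDev)))
        names(maxDev) <- paste0("category", seq_along(maxDev))
    structure(list(maxDeviation = maxDev,
                   stable = maxDev <= margin + 1e-12,
                   margin = margin, referenceIndex = referenceIndex,
                   proportions = p),
              class = "EquivalenceReport")
}

#' @export
print.EquivalenceReport <- function(x, ...) {
    cat(sprintf(
        "Equivalence report (margin +/-%.3g, reference timepoint %d)\n",
        x$margin, x$referenceIndex))
    df <- data.frame(category = names(x$maxDeviation),
                     max_abs_deviation = x$maxDeviation,
                     stable = x$stable, row.names = NULL)
    print(df, digits = 3)
    invisible(x)
}

#' Percent signal enhancement and cohort coefficient of variation
#'
#' `PSE = (SI_post - SI_pre) / SI_pre * 100` (percent), the
#' contrast-uptake QC statistic; `cohortCV` summarizes a cohort of PSE
#' values as mean, sample standard deviation (n - 1) and
#' `CV = sd / mean * 100` percent.
#'
#' @param siPre,siPost pre-/post-contrast signal intensities (vectors
#'   allowed); `siPre` must be positive.
#' @return `percentSignalEnhancement`: PSE in percent.
#' @examples
#' percentSignalEnhancement(100, 300)   # 200
#' @export
percentSignalEnhancement <- function(siPre, siPost) {
    if (any(siPre <= 0)) stop("siPre must be positive")
    (siPost - siPre) / siPre * 100
}

#' @rdname percentSignalEnhancement
#' @param values cohort of per-dataset values (e.g. PSE percentages).
#' @return `cohortCV`: list with `mean`, `sd`, `cv` (percent), `n`.
#' @export
cohortCV <- function(values) {
    if (length(values) < 2) stop("cohort CV needs >= 2 values")
    m <- mean(values); s <- sd(values)
    list(mean = m, sd = s, cv = s / m * 100, n = length(values))
}

#' Kymograph line-scan velocimetry
#'
#' Velocity from manually drawn streak-parallel lines: for a segment
#' spanning `dpx` position pixels and `dlines` scan lines,
#' `v = |dpx| * pixelSize / (|dlines| * lineInterval)` in mm/s (um/ms and
#' mm/s coincide). Speed only; the sign of the slope is discarded.
#'
#' @param kymo a [Kymograph-class].
#' @param lines data.frame (or matrix) with columns `px0, line0, px1,
#'   line1`, one row per drawn line.
#' @return list: `mean` (mm/s), `sd` (sample sd), `velocities` per line.
#' @examples
#' k <- Kymograph(matrix(0, 20, 128), 1.1838, 0.15)
#' kymographVelocity(k, data.frame(px0 = 0, line0 = 0, px1 = 10,
#'                                 line1 = 10))
#' @export
kymographVelocity <- function(kymo, lines) {
    ln <- as.data.frame(lines)
    need <- c("px0", "line0", "px1", "line1")
    if (!all(need %in% names(ln)))
        stop("lines must have columns px0, line0, px1, line1")
    dl <- abs(ln$line1 - ln$line0)
    if (any(dl < 1))
        stop("each line must span >= 1 scan-line interval ",
             "(zero time span gives an infinite velocity)")
    dp <- abs(ln$px1 - ln$px0)
    v <- dp * pixelSize(kymo) / (dl * lineInterval(kymo))
    list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
         velocities = v)
}

#' Automatic dominant streak velocity
#'
#' Automates the manual line drawing: sweeps candidate streak slopes,
#' integrates the image along each candidate direction (with wraparound
#' in the position axis) and scores the variance of the integrated
#' profile; the slope maximizing the response is refined on a finer grid
#' and converted to a velocity. A flat angular response (no dominant
#' orientation) is reported as indeterminate.
#'
#' @param kymo a [Kymograph-class].
#' @param maxVelocity largest velocity considered, mm/s.
#' @param nCoarse coarse sweep size.
#' @param flatTol response flatness threshold (ratio of best response to
#'   median response below which the result is indeterminate).
#' @return list: `velocity` (mm/s, `NA` if indeterminate), `slope`
#'   (px/line), `indeterminate`, `response` (the sweep table).
#' @export
autoStreakAngle <- function(kymo, maxVelocity = 20, nCoarse = 121,
                            flatTol = 5) {
    img <- voxelData(kymo)
    img <- sweep(img, 1, rowMeans(img))    # remove per-line offsets
    nL <- nrow(img); nPx <- ncol(img)
    maxSlope <- maxVelocity * lineInterval(kymo) / pixelSize(kymo)
    score <- function(s) {
        # mean intensity along trajectories x = b + s*t (wraparound)
        prof <- numeric(nPx)
        for (t in seq_len(nL)) {
            sh <- (s * (t - 1)) %% nPx
            i0 <- floor(sh); w <- sh - i0
            cols <- ((seq_len(nPx) - 1 + i0) %% nPx) + 1
            cols2 <- ((seq_len(nPx) + i0) %% nPx) + 1
            prof <- prof + (1 - w) * img[t, cols] + w * img[t, cols2]
        }
        var(prof / nL)
    }
    slopes <- seq(-maxSlope, maxSlope, length.out = nCoarse)
    resp <- vapply(slopes, score, 0)
    best <- which.max(resp)
    flat <- max(resp) < flatTol * median(resp) || max(resp) <= 0
    if (flat)
        return(list(velocity = NA_real_, slope = NA_real_,
                    indeterminate = TRUE,
                    response = data.frame(slope = slopes, score = resp)))
    lo <- slopes[max(1, best - 1)]; hi <- slopes[min(nCoarse, best + 1)]
    fineS <- seq(lo, hi, length.out = 41)
    fineR <- vapply(fineS, score, 0)
    sBest <- fineS[which.max(fineR)]
    v <- abs(sBest) * pixelSize(kymo) / lineInterval(kymo)
    list(velocity = v, slope = sBest, indeterminate = FALSE,
         response = data.frame(slope = slopes, score = resp))
}
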