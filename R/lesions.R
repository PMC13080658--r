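#' Quantify clusters per ROI
#'
#' Per region of interest: threshold the image, label connected
#' components (default 26-connectivity in 3D, which degenerates to
#' 8-connectivity on single-slice data), drop components below
#' `minSizeVoxels`, and report counts and world volumes - the
#' particle-analysis step used for metastatic cell clusters and
#' erythrocyte clusters.
#'
#' @param image probability/intensity [ImageVolume] or a [BinaryMask].
#' @param rois [LabelMask] of regions of interest on the same grid.
#' @param threshold foreground cutoff (ignored for mask input).
#' @param minSizeVoxels smallest component kept, voxels.
#' @param connectivity 6, 18 or 26.
#' @return data.frame of class `ClusterStats`: one row per ROI with
#'   `roi`, `n_clusters`, `total_volume_um3`; per-cluster volumes in the
#'   `clusters` attribute (named list).
#' @export
quantifyClusters <- function(image, rois, threshold = 0.5,
                             minSizeVoxels = 1, connectivity = 26) {
    if (!sameGrid(image, rois)) stop("image and ROI grids differ")
    if (!connectivity %in% c(6, 18, 26))
        stop("connectivity must be 6, 18 or 26")
    fg <- if (is(image, "BinaryMask")) voxelData(image)
          else voxelData(image) >= threshold
    labArr <- voxelData(rois)
    voxVol <- prod(spacing(rois))
    roiIds <- sort(setdiff(unique(as.integer(labArr)), 0L))
    d <- dim(fg)
    perRoi <- vector("list", length(roiIds))
    names(perRoi) <- as.character(roiIds)
    rows <- lapply(seq_along(roiIds), function(i) {
        id <- roiIds[i]
        m <- fg & labArr == id
        if (!any(m)) {
            perRoi[[i]] <<- numeric(0)
            return(data.frame(roi = id, n_clusters = 0L,
                              total_volume_um3 = 0))
        }
        comp <- cpp_label_components(as.logical(m), as.integer(d),
                                     as.integer(connectivity))
        sizes <- tabulate(comp)
        sizes <- sizes[sizes >= minSizeVoxels]
        perRoi[[i]] <<- sizes * voxVol
        data.frame(roi = id, n_clusters = length(sizes),
                   total_volume_um3 = sum(sizes) * voxVol)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(roi = integer(), n_clusters = integer(),
                          total_volume_um3 = numeric())
    attr(out, "clusters") <- perRoi
    class(out) <- c("ClusterStats", class(out))
    out
}

#' Compare lesion groups
#'
#' Two-sided Mann-Whitney U comparison of a cluster statistic (count or
#' total volume) between two lesion classes (e.g. T2*-negative vs
#' T2*-positive metastases), with group medians and IQRs.
#'
#' @param stats data.frame with the metric column and a `group` column,
#'   or a `ClusterStats` with `group` added.
#' @param metric column to compare (`"n_clusters"` or
#'   `"total_volume_um3"`, or any numeric column).
#' @param groupColumn grouping column name.
#' @return list: `U`, `p`, `medians`, `iqrs`, `n`.
#' @export
compareLesionGroups <- function(stats, metric = "n_clusters",
                                groupColumn = "group") {
    df <- as.data.frame(stats)
    g <- factor(df[[groupColumn]])
    if (nlevels(g) != 2) stop("exactly two lesion groups are required")
    x <- df[[metric]][g == levels(g)[1]]
    y <- df[[metric]][g == levels(g)[2]]
    if (!length(x) || !length(y)) stop("a lesion group is empty")
    wt <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
    list(U = unname(wt$statistic), p = wt$p.value,
         medians = setNames(c(median(x), median(y)), levels(g)),
         iqrs = setNames(c(stats::IQR(x), stats::IQR(y)), levels(g)),
         n = setNames(c(length(x), length(y)), levels(g)))
}

#' Marker co-positivity fraction
#'
#' Fraction of marker-A-positive nuclei that are also marker-B-positive,
#' `|A+ intersect B+| / |A+|` (e.g. the fraction of Nestin-positive
#' nuclei with intrinsic GFP signal). Supply the nuclei label mask to
#' validate that the id sets refer to existing nuclei.
#'
#' @param aPositive,bPositive vectors of positive nucleus ids.
#' @param nuclei optional [LabelMask] of segmented nuclei.
#' @return fraction in \[0, 1\].
#' @examples
#' copositivityFraction(1:50, c(1:47, 200, 201, 202))  # 0.94
#' @export
copositivityFraction <- function(aPositive, bPositive, nuclei = NULL) {
    aPositive <- unique(aPositive); bPositive <- unique(bPositive)
    if (length(aPositive) == 0)
        stop("no marker-A-positive nuclei; fraction undefined")
    if (!is.null(nuclei)) {
        present <- setdiff(unique(as.integer(voxelData(nuclei))), 0L)
        bad <- setdiff(c(aPositive, bPositive), present)
        if (length(bad))
            stop("ids not present in the nuclei mask: ",
                 paste(utils::head(bad, 5), collapse = ", "))
    }
    length(intersect(aPositive, bPositive)) / length(aPositive)
}

#' Classify lesions by perilesional signal
#'
#' Computes a statistic of the normalized signal in a perilesional shell
#' (voxels within `shellWidth` um outside the ROI, excluding all ROIs)
#' and classifies each ROI as signal-positive (statistic at or below
#' `threshold`; hypointense shell) or negative. The threshold is a
#' configurable z-score cutoff and is logged with the result; the rule
#' is invariant to ROI label renumbering.
#'
#' @param rois [LabelMask] of lesion ROIs.
#' @param signal normalized signal [ImageVolume] on the same grid.
#' @param shellWidth shell width, um.
#' @param threshold classification cutoff (z-units).
#' @param statistic `"mean"` or `"median"`.
#' @return data.frame: `roi`, `shell_stat`, `n_shell`, `class`
#'   (`"positive"`/`"negative"`); threshold and shell width as
#'   attributes.
#' @export
classifyLesionsBySignal <- function(rois, signal, shellWidth = 100,
                                    threshold = -1,
                                    statistic = c("mean", "median")) {
    statistic <- match.arg(statistic)
    if (!sameGrid(rois, signal)) stop("ROI and signal grids differ")
    labArr <- voxelData(rois)
    sig <- voxelData(signal)
    anyRoi <- labArr > 0
    ids <- sort(setdiff(unique(as.integer(labArr)), 0L))
    rows <- lapply(ids, function(id) {
        m <- BinaryMask(labArr == id, spacing(rois), origin(rois))
        shell <- distanceToMask(m) <= shellWidth & !anyRoi
        if (!any(shell))
            stop("empty perilesional shell for ROI ", id,
                 "; widen shellWidth")
        v <- sig[shell]
        s <- if (statistic == "mean") mean(v) else median(v)
        data.frame(roi = id, shell_stat = s, n_shell = sum(shell),
                   class = if (s <= threshold) "positive" else "negative")
    })
    out <- do.call(rbind, rows)
    attr(out, "threshold") <- threshold
    attr(out, "shellWidth") <- shellWidth
    out
}
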