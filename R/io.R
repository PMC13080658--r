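#' Read a 3D volume from NIfTI or multi-page TIFF
#'
#' NIfTI voxel dimensions are taken from the header (converted from mm to
#' um); TIFF stacks carry no reliable 3D spacing, so `spacingOverride` is
#' required unless an x/y resolution tag is embedded (then only z must be
#' supplied). On disk NIfTI stores (x, y, z); arrays are reordered to the
#' internal (z, y, x) convention at the boundary.
#'
#' @param path file path.
#' @param format `"nifti"` or `"tiff"`; guessed from the extension when
#'   omitted.
#' @param spacingOverride voxel spacing um (z, y, x); overrides any header.
#' @param origin world um of voxel (0,0,0) center.
#' @param role volume role tag, see [ImageVolume].
#' @return An [ImageVolume].
#' @export
readVolume <- function(path, format = c("auto", "nifti", "tiff"),
                       spacingOverride = NULL, origin = c(0, 0, 0),
                       role = "intensity") {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file does not exist: ", path)
    if (format == "auto") {
        format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
            "nifti" else "tiff"
    }
    if (format == "nifti") {
        img <- RNifti::readNifti(path)
        arr <- as.array(img)
        if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
            arr <- arr[, , , 1, drop = TRUE]
        if (length(dim(arr)) != 3L)
            stop("expected 3D NIfTI data, got ", length(dim(arr)), "D")
        sp_xyz <- RNifti::pixdim(img)[1:3] * 1000  # header mm -> um
        arr <- aperm(arr, c(3, 2, 1))              # (x,y,z) -> (z,y,x)
        sp <- rev(sp_xyz)
        if (!is.null(spacingOverride)) sp <- as.numeric(spacingOverride)
        return(ImageVolume(arr, spacing = sp, origin = origin, role = role))
    }
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3L) p[, , 1, drop = TRUE] else p
    })
    if (length(pages) < 2L && is.null(spacingOverride))
        stop("2D TIFF without spacingOverride: supply (z, y, x) spacing in um")
    if (is.null(spacingOverride))
        stop("TIFF stacks require spacingOverride (z, y, x um); ",
             "embedded resolution tags do not define slice depth")
    arr <- array(0, c(length(pages), dim(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    ImageVolume(arr, spacing = as.numeric(spacingOverride), origin = origin,
                role = role)
}

#' Write a volume to NIfTI or TIFF
#'
#' @param volume an [ImageVolume] or mask.
#' @param path output path (`.nii`/`.nii.gz` or `.tif`).
#' @param format as in [readVolume].
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, format = c("auto", "nifti", "tiff")) {
    format <- match.arg(format)
    if (format == "auto") {
        format <- if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
            "nifti" else "tiff"
    }
    arr <- voxelData(volume)
    storage.mode(arr) <- "double"
    if (format == "nifti") {
        img <- RNifti::asNifti(aperm(arr, c(3, 2, 1)))
        RNifti::pixdim(img) <- rev(spacing(volume)) / 1000  # um -> header mm
        RNifti::writeNifti(img, path)
    } else {
        rng <- range(arr)
        scaled <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1])
                  else arr * 0
        slices <- lapply(seq_len(dim(arr)[1]), function(i) scaled[i, , ])
        tiff::writeTIFF(slices, path, bits.per.sample = 16L)
    }
    invisible(path)
}

#' Read paired landmarks
#'
#' The CSV dialect holds one pair per row with columns
#' `name, fixed_z, fixed_y, fixed_x, moving_z, moving_y, moving_x`
#' (world um). The FCSV dialect (3D Slicer markups) stores one point set
#' per file in RAS millimeters; supply `path` as
#' `c(fixed = ..., moving = ...)`. RAS (x, y, z) mm is mapped to the
#' internal (z, y, x) um frame by coordinate reversal and a x1000 unit
#' change; no sign flips are applied (windows are registered in a common
#' scanner frame).
#'
#' @param path file path (CSV) or length-2 vector of paths (FCSV).
#' @param dialect `"csv"` or `"fcsv"`.
#' @return A [LandmarkSet].
#' @export
readLandmarks <- function(path, dialect = c("csv", "fcsv")) {
    dialect <- match.arg(dialect)
    if (dialect == "csv") {
        df <- read.csv(path, stringsAsFactors = FALSE)
        need <- c("fixed_z", "fixed_y", "fixed_x",
                  "moving_z", "moving_y", "moving_x")
        if (!all(need %in% names(df)))
            stop("landmark CSV must have columns: name, ",
                 paste(need, collapse = ", "))
        return(LandmarkSet(
            fixed = as.matrix(df[, c("fixed_z", "fixed_y", "fixed_x")]),
            moving = as.matrix(df[, c("moving_z", "moving_y", "moving_x")]),
            names = if ("name" %in% names(df)) df$name else NULL))
    }
    if (length(path) != 2L)
        stop("fcsv dialect needs two files: c(fixed = ..., moving = ...)")
    readOne <- function(p) {
        lines <- readLines(p)
        lines <- lines[!startsWith(lines, "#")]
        df <- read.csv(text = lines, header = FALSE,
                       stringsAsFactors = FALSE)
        # Slicer markups: id, x, y, z, ... (RAS mm)
        ras_mm <- as.matrix(df[, 2:4])
        cbind(ras_mm[, 3], ras_mm[, 2], ras_mm[, 1]) * 1000
    }
    f <- readOne(path[[1]])
    m <- readOne(path[[2]])
    if (nrow(f) != nrow(m))
        stop("fixed (", nrow(f), ") and moving (", nrow(m),
             ") landmark counts differ")
    LandmarkSet(fixed = f, moving = m)
}

#' @rdname readLandmarks
#' @param landmarks a [LandmarkSet] to write (CSV dialect).
#' @export
writeLandmarks <- function(landmarks, path) {
    f <- fixedPoints(landmarks); m <- movingPoints(landmarks)
    df <- data.frame(name = landmarkNames(landmarks),
                     fixed_z = f[, 1], fixed_y = f[, 2], fixed_x = f[, 3],
                     moving_z = m[, 1], moving_y = m[, 2], moving_x = m[, 3])
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write / read a voxel table
#'
#' A voxel table is a plain data.frame with one row per in-mask MRI voxel
#' (voxel index, world position, densities, per-sequence normalized
#' intensities, category, timepoint and dataset identifiers). CSV is the
#' canonical on-disk format (comma delimiter, point decimal, UTF-8);
#' numeric columns round-trip to full double precision.
#'
#' @param table data.frame as produced by [extractVoxelTable].
#' @param path output CSV path.
#' @return `writeVoxelTable`: `path` invisibly. `readVoxelTable`: the
#'   data.frame.
#' @export
writeVoxelTable <- function(table, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    fmt <- table
    for (j in seq_along(fmt)) {
        if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
    }
    write.csv(fmt, con, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' @rdname writeVoxelTable
#' @export
readVoxelTable <- function(path) {
    read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}

#' Serialize a spatial transform to JSON
#'
#' The file records the kind, dimensionality, parameters and the direction
#' convention (`"maps fixed/target world coordinates to moving world
#' coordinates (pull-back)"`) so a reader needs no external context.
#'
#' @param transform a `SpatialTransform`.
#' @param path output JSON path.
#' @return `path` (write) / `SpatialTransform` (read).
#' @export
writeTransform <- function(transform, path) {
    ser <- function(tr) {
        if (tr@kind == "composite")
            return(list(kind = "composite", chain = lapply(tr@chain, ser)))
        list(kind = tr@kind, dimension = tr@dimension,
             A = tr@A, t = tr@t,
             ctrl = if (tr@kind == "tps") tr@ctrl else NULL,
             W = if (tr@kind == "tps") tr@W else NULL)
    }
    obj <- ser(transform)
    obj$direction <- paste("maps fixed/target world coordinates to moving",
                           "world coordinates (pull-back)")
    obj$units <- "um"
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
    invisible(path)
}

#' @rdname writeTransform
#' @export
readTransform <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    de <- function(o) {
        if (o$kind == "composite") {
            chain <- lapply(seq_len(if (is.data.frame(o$chain))
                nrow(o$chain) else length(o$chain)), function(i)
                de(if (is.data.frame(o$chain)) lapply(o$chain, `[[`, i)
                   else o$chain[[i]]))
            return(newComposite(chain))
        }
        d <- as.integer(o$dimension)
        newLinearOrTps(o$kind, d, asPointMatrix(o$A),
                       as.numeric(o$t),
                       ctrl = if (!is.null(o$ctrl)) asPointMatrix(o$ctrl),
                       W = if (!is.null(o$W)) asPointMatrix(o$W))
    }
    de(obj)
}

#' Read a YAML configuration file
#'
#' Thin wrapper around [yaml::read_yaml()] used by the command-line
#' interface; returns a named list.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
readConfig <- function(path) yaml::read_yaml(path)
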