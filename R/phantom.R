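#' Generate a synthetic vessel tree
#'
#' Builds a branching vascular phantom by recursive random binary
#' branching: each root seeds a segment; at each bifurcation the child
#' radii follow a Murray-type decay `r^m = r1^m + r2^m` (exponent
#' `murrayExponent`, default 3) with a random split fraction, and
#' directions deviate by a random branching angle. Blood flow velocity is
#' assigned monotonically in radius so that flow-sensitive contrast has a
#' known sign. All randomness derives from `seed`; identical inputs give
#' identical scenes.
#'
#' @param extent scene extent um (z, y, x), all positive.
#' @param nRoots number of independent root vessels (connected components).
#' @param radiusRange c(min, max) vessel radius um; must lie in
#'   (0, extent/4\].
#' @param maxDepth maximum bifurcation depth per root.
#' @param branchAngle mean branching half-angle, radians.
#' @param murrayExponent radius decay exponent at bifurcations.
#' @param velocityRange c(min, max) centerline flow velocity, mm/s,
#'   assigned linearly in radius.
#' @param stepLength centerline sampling step, um.
#' @param seed integer seed.
#' @return A [PhantomScene-class] (no tumor field; add one with
#'   [addTumorField]).
#' @export
generateVesselTree <- function(extent, nRoots = 3, radiusRange = c(10, 60),
                               maxDepth = 3, branchAngle = 0.6,
                               murrayExponent = 3,
                               velocityRange = c(0.5, 8),
                               stepLength = 25, seed = 1) {
    extent <- rep(extent, length.out = 3)
    if (any(extent <= 0)) stop("scene extent must be positive")
    if (radiusRange[1] <= 0 || radiusRange[2] > min(extent) / 4)
        stop("radius range must lie within (0, extent/4]")
    withSeed(seed, {
        segments <- list()
        bifs <- matrix(0, 0, 3)
        velOf <- function(r)
            velocityRange[1] + (velocityRange[2] - velocityRange[1]) *
                (r - radiusRange[1]) / max(radiusRange[2] - radiusRange[1],
                                           1e-9)
        clampR <- function(r) pmin(pmax(r, radiusRange[1]), radiusRange[2])
        grow <- function(pos, dir, r, depth, rootId) {
            len <- runif(1, 0.25, 0.45) * min(extent)
            nStep <- max(2L, ceiling(len / stepLength))
            pts <- matrix(0, nStep, 3)
            pts[1, ] <- pos
            for (i in 2:nStep) {
                dir <- dir + rnorm(3, sd = 0.12)
                dir <- dir / vnorm(dir)
                cand <- pts[i - 1, ] + dir * stepLength
                # reflect at the box walls (margin one radius)
                for (ax in 1:3) {
                    if (cand[ax] < r) { cand[ax] <- 2 * r - cand[ax]
                        dir[ax] <- abs(dir[ax]) }
                    if (cand[ax] > extent[ax] - r) {
                        cand[ax] <- 2 * (extent[ax] - r) - cand[ax]
                        dir[ax] <- -abs(dir[ax]) }
                }
                pts[i, ] <- cand
            }
            rEnd <- clampR(r * runif(1, 0.85, 1))
            segments[[length(segments) + 1L]] <<- list(
                points = pts,
                radius = seq(r, rEnd, length.out = nStep),
                velocity = velOf((r + rEnd) / 2),
                root = rootId)
            if (depth < maxDepth && rEnd > radiusRange[1] * 1.15) {
                bifs <<- rbind(bifs, pts[nStep, ])
                f <- runif(1, 0.35, 0.65)
                r1 <- clampR(rEnd * f^(1 / murrayExponent))
                r2 <- clampR(rEnd * (1 - f)^(1 / murrayExponent))
                for (rc in c(r1, r2)) {
                    ax <- rnorm(3); ax <- ax / vnorm(ax)
                    perp <- ax - sum(ax * dir) * dir
                    if (vnorm(perp) < 1e-6) perp <- c(dir[2], -dir[1], 0)
                    perp <- perp / vnorm(perp)
                    th <- branchAngle * runif(1, 0.6, 1.4) *
                        sample(c(-1, 1), 1)
                    nd <- cos(th) * dir + sin(th) * perp
                    grow(pts[nStep, ], nd / vnorm(nd), rc, depth + 1L,
                         rootId)
                }
            }
        }
        for (rootId in seq_len(nRoots)) {
            pos <- c(runif(1, 0.15, 0.85) * extent[1],
                     runif(1, 0.15, 0.85) * extent[2],
                     radiusRange[2])
            dir <- c(rnorm(2, sd = 0.3), 1)
            r0 <- runif(1, 0.75, 1) * radiusRange[2]
            grow(pos, dir / vnorm(dir), r0, 0L, rootId)
        }
        new("PhantomScene", segments = segments, bifurcations = bifs,
            tumorField = NULL, deformation = NULL, extent = extent,
            seed = as.integer(seed))
    })
}

#' Add a smooth tumor density field to a scene
#'
#' The field is a clamped sum of random Gaussian blobs sampled on a grid
#' at `fieldSpacing`, values in \[0, 1\] (volume density of tumor cells per
#' voxel).
#'
#' @param scene a [PhantomScene-class].
#' @param nBlobs number of Gaussian density blobs.
#' @param blobSigma blob half-width um (range sampled uniformly).
#' @param peak peak density per blob.
#' @param fieldSpacing grid spacing um of the stored field.
#' @param cutoff density subtracted from the blob sum before clamping, so
#'   tissue outside the infiltration margin has exactly zero density.
#' @param seed integer seed.
#' @return The scene with `tumorField` set.
#' @export
addTumorField <- function(scene, nBlobs = 4, blobSigma = c(100, 250),
                          peak = 0.9, fieldSpacing = 10, cutoff = 0.05,
                          seed = 1) {
    ext <- scene@extent
    n <- pmax(2L, round(ext / fieldSpacing))
    sp <- ext / n
    vol <- ImageVolume(array(0, n), spacing = sp, origin = sp / 2,
                       role = "intensity")
    ctr <- gridCenters(vol)
    acc <- numeric(nrow(ctr))
    withSeed(seed, {
        for (b in seq_len(nBlobs)) {
            mu <- runif(3, 0.25, 0.75) * ext
            sg <- runif(1, blobSigma[1], blobSigma[2])
            a <- runif(1, 0.6, 1) * peak
            acc <- acc + a * exp(-rowSums(sweep(ctr, 2, mu)^2) / (2 * sg^2))
        }
    })
    # soft-shrink the Gaussian tails so normal tissue has exactly zero
    # density (a sharp infiltration margin)
    acc <- pmax(acc - cutoff, 0) / (1 - cutoff)
    field <- ImageVolume(array(pmin(acc, 1), n), spacing = sp,
                         origin = sp / 2, role = "density")
    initialize(scene, tumorField = field)
}

# rasterize vessel tubes on a grid: returns list(indicator, velocity) arrays
rasterizeTubes <- function(scene, grid) {
    d <- dim(voxelData(grid))
    sp <- spacing(grid); org <- origin(grid)
    ind <- array(FALSE, d)
    vel <- array(0, d)
    for (seg in scene@segments) {
        pts <- seg$points; rad <- seg$radius
        for (i in seq_len(nrow(pts) - 1L)) {
            p1 <- pts[i, ]; p2 <- pts[i + 1L, ]
            r1 <- rad[i]; r2 <- rad[i + 1L]
            rmax <- max(r1, r2)
            lo <- pmax(ceiling((pmin(p1, p2) - rmax - org) / sp), 0)
            hi <- pmin(floor((pmax(p1, p2) + rmax - org) / sp), d - 1)
            if (any(hi < lo)) next
            ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
            kk <- seq.int(lo[3], hi[3])
            idx <- as.matrix(expand.grid(z = ii, y = jj, x = kk))
            w <- sweep(sweep(idx, 2, sp, "*"), 2, org, "+")
            v <- p2 - p1
            L2 <- sum(v^2)
            t <- if (L2 > 0)
                pmin(pmax((sweep(w, 2, p1) %*% v) / L2, 0), 1) else
                rep(0, nrow(w))
            proj <- matrix(p1, nrow(w), 3, byrow = TRUE) + t %*% t(v)
            dist2 <- rowSums((w - proj)^2)
            rt <- r1 + as.numeric(t) * (r2 - r1)
            inside <- dist2 <= rt^2
            if (!any(inside)) next
            sub <- idx[inside, , drop = FALSE]
            lin <- sub[, 1] + d[1] * (sub[, 2] + d[2] * sub[, 3]) + 1
            ind[lin] <- TRUE
            vel[lin] <- pmax(vel[lin], seg$velocity)
        }
    }
    list(indicator = ind, velocity = vel)
}

sceneGrid <- function(scene, spacingUm) {
    spacingUm <- rep(spacingUm, length.out = 3)
    n <- pmax(1L, round(scene@extent / spacingUm))
    ImageVolume(array(0, n), spacing = spacingUm, origin = spacingUm / 2)
}

#' Rasterize microscopy channels from a phantom scene
#'
#' The vessel channel is the tube indicator (optionally PSF-blurred with a
#' Gaussian of `psfSigma` um and degraded with additive Gaussian noise);
#' the tumor channel is the scene's density field resampled to the
#' requested grid. Noise-free binary ground-truth masks are always emitted
#' alongside.
#'
#' @param scene a [PhantomScene-class].
#' @param spacingUm voxel spacing um (z, y, x or scalar). A warning is
#'   given when it exceeds half the smallest vessel radius.
#' @param channels subset of `c("vessel", "tumor")`.
#' @param noiseSd additive Gaussian noise sd (intensity units).
#' @param psfSigma Gaussian PSF sigma, um.
#' @param seed integer seed for the noise realization.
#' @return list with entries `vessel`, `vesselMask`, `tumor`, `tumorTruth`
#'   (subset by `channels`), all on the same grid.
#' @export
rasterizeMicroscopy <- function(scene, spacingUm,
                                channels = c("vessel", "tumor"),
                                noiseSd = 0, psfSigma = 0, seed = 1) {
    grid <- sceneGrid(scene, spacingUm)
    minR <- min(unlist(lapply(scene@segments, `[[`, "radius")))
    if (length(minR) && max(spacing(grid)) > minR / 2)
        warning("spacing exceeds half the smallest vessel radius (",
                signif(minR, 3), " um); rasterization will be coarse")
    out <- list()
    if ("vessel" %in% channels) {
        ras <- rasterizeTubes(scene, grid)
        img <- ras$indicator * 1.0
        if (psfSigma > 0)
            img <- gaussianSmooth3(img, psfSigma, spacing(grid))
        if (noiseSd > 0)
            img <- img + withSeed(seed,
                array(rnorm(length(img), sd = noiseSd), dim(img)))
        out$vessel <- ImageVolume(img, spacing(grid), origin(grid))
        out$vesselMask <- BinaryMask(ras$indicator, spacing(grid),
                                     origin(grid))
    }
    if ("tumor" %in% channels) {
        if (is.null(scene@tumorField))
            stop("scene has no tumor field; call addTumorField() first")
        truth <- resampleVolume(scene@tumorField, NULL, grid,
                                interpolation = "linear")
        truth <- ImageVolume(voxelData(truth), spacing(grid), origin(grid),
                             role = "density")
        img <- voxelData(truth)
        if (noiseSd > 0)
            img <- img + withSeed(seed + 1L,
                array(rnorm(length(img), sd = noiseSd), dim(img)))
        out$tumor <- ImageVolume(img, spacing(grid), origin(grid))
        out$tumorTruth <- truth
    }
    out
}

# ground-truth per-MRI-voxel fractions by fine rasterization + block mean
blockMeanAxis <- function(arr, f, axis) {
    if (f == 1L) return(arr)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    da <- dim(a)
    n <- da[1] %/% f
    a <- a[seq_len(n * f), , , drop = FALSE]
    dim(a) <- c(f, n, da[2], da[3])
    m <- colMeans(a)                       # n x d2 x d3
    aperm(m, order(perm))
}

#' Ground-truth per-voxel fractions on an MRI grid
#'
#' Rasterizes the scene at `oversample` times the target resolution and
#' block-averages, giving the vessel volume fraction, the flow-weighted
#' vessel fraction (velocity-weighted occupancy, mm/s units) and the tumor
#' density per target voxel.
#'
#' @param scene a [PhantomScene-class].
#' @param spacingUm target (MRI) voxel spacing um.
#' @param oversample sub-voxel sampling factor per axis.
#' @return list of [ImageVolume]s: `vesselFraction`, `flowFraction`,
#'   `tumorDensity` (the latter `NULL` without a tumor field).
#' @export
sceneFractions <- function(scene, spacingUm, oversample = 4L) {
    spacingUm <- rep(spacingUm, length.out = 3)
    coarse <- sceneGrid(scene, spacingUm)
    fineSp <- spacingUm / oversample
    fine <- ImageVolume(array(0, dim(voxelData(coarse)) * oversample),
                        spacing = fineSp, origin = fineSp / 2)
    ras <- rasterizeTubes(scene, fine)
    bm <- function(a) {
        for (ax in 1:3) a <- blockMeanAxis(a, oversample, ax)
        a
    }
    frac <- bm(ras$indicator * 1.0)
    flow <- bm(ras$velocity)
    mk <- function(a, role) ImageVolume(a, spacing(coarse), origin(coarse),
                                        role = role)
    tum <- NULL
    if (!is.null(scene@tumorField)) {
        t_ <- resampleVolume(scene@tumorField, NULL, fine,
                             interpolation = "linear")
        tum <- mk(pmin(pmax(bm(voxelData(t_)), 0), 1), "density")
    }
    list(vesselFraction = mk(frac, "density"), flowFraction = mk(flow,
         "intensity"), tumorDensity = tum)
}

#' Simulate sequence-specific MRI contrast from a phantom scene
#'
#' Linear contrast model with configurable coefficients:
#' T2w/T2*w voxel intensity
#' `baseline - kVessel * vesselFraction + kTumor * tumorDensity + noise`;
#' TOF intensity `baseline + kFlow * flowFraction + noise`. The model makes
#' no claim of MR physics; it fixes the signs of the vessel, tumor and
#' flow dependencies so downstream statistics have known directions.
#'
#' @param scene a [PhantomScene-class].
#' @param spacingUm MRI voxel spacing um (must be at least the microscopy
#'   spacing in use).
#' @param sequence `"t2w"`, `"t2star"` or `"tof"`.
#' @param baseline,kVessel,kTumor,kFlow contrast coefficients (intensity
#'   units; `kFlow` per mm/s).
#' @param noiseSd additive Gaussian noise sd.
#' @param oversample sub-voxel factor for the ground-truth fractions.
#' @param seed integer seed for the noise realization.
#' @return list: `volume` (simulated MRI) plus the ground-truth fraction
#'   volumes from [sceneFractions].
#' @export
simulateMri <- function(scene, spacingUm, sequence = c("t2w", "t2star",
                        "tof"), baseline = 100, kVessel = 40, kTumor = 30,
                        kFlow = 10, noiseSd = 0, oversample = 4L,
                        seed = 1) {
    sequence <- match.arg(sequence)
    fr <- sceneFractions(scene, spacingUm, oversample)
    tum <- if (is.null(fr$tumorDensity)) 0 else voxelData(fr$tumorDensity)
    sig <- if (sequence %in% c("t2w", "t2star")) {
        baseline - kVessel * voxelData(fr$vesselFraction) + kTumor * tum
    } else {
        baseline + kFlow * voxelData(fr$flowFraction)
    }
    if (noiseSd > 0)
        sig <- sig + withSeed(seed,
            array(rnorm(length(sig), sd = noiseSd), dim(sig)))
    vol <- ImageVolume(array(sig, dim(voxelData(fr$vesselFraction))),
                       spacing(fr$vesselFraction),
                       origin(fr$vesselFraction))
    c(list(volume = vol), fr)
}

#' Apply a known synthetic deformation to a volume
#'
#' The returned transform `T` maps deformed-frame world coordinates to
#' original-frame coordinates (pull-back: the deformed volume is
#' `V'(x) = V(T(x))`). Smooth random warps are thin-plate interpolants of
#' random displacements on a coarse control grid, rescaled so the maximum
#' displacement equals `amplitude`; amplitudes below half the control
#' spacing keep the warp invertible. Landmark pairs are generated at the
#' supplied probe points (vessel bifurcations in the phantom pipeline):
#' `moving` are the original-frame positions, `fixed` their exact
#' deformed-frame preimages.
#'
#' @param volume an [ImageVolume].
#' @param spec list with `kind` in `"identity"`, `"rigid"`, `"affine"`,
#'   `"smooth"`; for rigid: `angles` (rad) and `translation` (um); for
#'   affine: `A` and `translation`; for smooth: `amplitude` (um) and
#'   optional `nControl` (per-axis control grid size, default 4).
#' @param points probe points (world um) for the ground-truth landmarks;
#'   default: a regular interior grid.
#' @param seed integer seed (smooth warps).
#' @return list: `deformed` volume, `landmarks` ([LandmarkSet]),
#'   `transform`.
#' @export
applySyntheticDeformation <- function(volume, spec, points = NULL,
                                      seed = 1) {
    d <- dim(voxelData(volume))
    ext <- d * spacing(volume)
    tr <- switch(spec$kind,
        identity = identityTransform(3L),
        rigid = rigidTransform(spec$angles %||% c(0, 0, 0),
                               spec$translation %||% c(0, 0, 0)),
        affine = newLinearOrTps("affine", 3L, spec$A,
                                as.numeric(spec$translation %||% rep(0, 3))),
        smooth = {
            A <- spec$amplitude
            if (is.null(A)) stop("smooth spec needs an amplitude (um)")
            if (A > min(ext) / 2)
                stop("amplitude exceeds half the volume extent")
            nC <- spec$nControl %||% 4L
            ctrlSpacing <- min(ext) / (nC - 1)
            if (A >= ctrlSpacing / 2)
                warning("amplitude >= half control spacing; ",
                        "warp may not be invertible")
            ax <- lapply(1:3, function(i)
                seq(origin(volume)[i] - spacing(volume)[i],
                    origin(volume)[i] + ext[i], length.out = nC))
            ctrl <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]],
                                          x = ax[[3]]))
            disp <- withSeed(seed,
                matrix(runif(length(ctrl), -1, 1), nrow(ctrl), 3))
            t0 <- fitLandmarkTransform(list(fixed = ctrl,
                                            moving = ctrl + disp), "tps")
            # the warp is linear in the control displacements: rescale so
            # the max displacement over a dense probe grid equals A
            probe <- gridCenters(volume)
            if (nrow(probe) > 8000)
                probe <- probe[seq(1, nrow(probe),
                                   length.out = 8000), , drop = FALSE]
            delta <- transformPoints(t0, probe) - probe
            sc <- A / max(sqrt(rowSums(delta^2)))
            fitLandmarkTransform(list(fixed = ctrl,
                                      moving = ctrl + sc * disp), "tps")
        },
        stop("unknown deformation kind: ", spec$kind))
    deformed <- resampleVolume(volume, tr, volume, interpolation = "linear")
    if (is.null(points)) {
        s <- spacing(volume)
        ax <- lapply(1:3, function(i)
            seq(0.2 * ext[i], 0.8 * ext[i], length.out = 3))
        points <- as.matrix(expand.grid(z = ax[[1]], y = ax[[2]],
                                        x = ax[[3]]))
    }
    points <- asPointMatrix(points)
    fixed <- invertPointwise(tr, points)
    lm <- LandmarkSet(fixed = fixed, moving = points)
    list(deformed = deformed, landmarks = lm, transform = tr)
}

# solve T(q) = p per point by damped fixed-point iteration (T close to
# identity for the deformations generated here)
invertPointwise <- function(transform, p, iters = 60L) {
    q <- p
    for (i in seq_len(iters)) {
        r <- transformPoints(transform, q) - p
        if (max(abs(r)) < 1e-9) break
        q <- q - r
    }
    q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a streaked line-scan kymograph
#'
#' Repeated line scans across a vessel produce a space-time image in which
#' moving erythrocytes appear as dark streaks; the streak slope encodes
#' velocity: a particle advances `velocity * lineInterval / pixelSize`
#' pixels per line (mm/s equals um/ms). Streaks wrap around the position
#' axis so the streak density is stationary.
#'
#' @param velocity ground-truth velocity, mm/s (> 0).
#' @param pixelSize um per position pixel.
#' @param lineInterval ms per line.
#' @param nLines number of scan lines (rows).
#' @param nPx line length, pixels.
#' @param streakWidth Gaussian streak half-width, px.
#' @param nStreaks number of streaks.
#' @param noiseSd additive Gaussian noise sd (image in \[0,1\]).
#' @param seed integer seed.
#' @return A [Kymograph-class].
#' @export
generateKymograph <- function(velocity, pixelSize = 1.1838,
                              lineInterval = 0.15, nLines = 200,
                              nPx = 128, streakWidth = 1.5, nStreaks = 10,
                              noiseSd = 0, seed = 1) {
    if (velocity <= 0) stop("velocity must be positive")
    if (nLines < 2) stop("a kymograph needs at least 2 lines")
    slope <- velocity * lineInterval / pixelSize   # px per line
    img <- matrix(1, nLines, nPx)
    px <- seq_len(nPx) - 1
    withSeed(seed, {
        x0 <- runif(nStreaks, 0, nPx)
        for (t in seq_len(nLines)) {
            prof <- numeric(nPx)
            for (s in seq_len(nStreaks)) {
                c0 <- (x0[s] + slope * (t - 1)) %% nPx
                dd <- abs(px - c0)
                dd <- pmin(dd, nPx - dd)            # wraparound distance
                prof <- prof + exp(-0.5 * (dd / streakWidth)^2)
            }
            img[t, ] <- 1 - 0.8 * pmin(prof, 1)
        }
        if (noiseSd > 0)
            img <- img + matrix(rnorm(length(img), sd = noiseSd),
                                nLines, nPx)
    })
    Kymograph(img, pixelSize, lineInterval)
}

#' Generate a longitudinal phantom series with known growth
#'
#' Per-voxel tumor density evolves as
#' `density(t) = clamp(density(0) + rate/100 * t, 0, 1)` (rate in percent
#' per day, i.e. absolute density percentage points per day); vessel
#' geometry is shared across timepoints.
#'
#' @param scene a [PhantomScene-class] with a tumor field.
#' @param growthRate growth rate, %/day.
#' @param days numeric vector of timepoints (days); must be non-empty.
#' @return list of scenes, one per timepoint, with attribute `days`.
#' @export
generateLongitudinalSeries <- function(scene, growthRate, days) {
    if (length(days) == 0) stop("days must be a non-empty vector")
    if (is.null(scene@tumorField))
        stop("scene has no tumor field; call addTumorField() first")
    d0 <- voxelData(scene@tumorField)
    out <- lapply(days, function(t) {
        dt <- d0 + growthRate / 100 * t
        if (any(dt > 1 + 1e-12) || any(dt < -1e-12))
            warning("densities clamped to [0, 1] at day ", t)
        fld <- ImageVolume(pmin(pmax(dt, 0), 1),
                           spacing(scene@tumorField),
                           origin(scene@tumorField), role = "density")
        initialize(scene, tumorField = fld)
    })
    attr(out, "days") <- days
    out
}
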