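test_that("vessel trees honor radius bounds, roots and determinism", {
    sc <- generateVesselTree(c(600, 600, 600), nRoots = 3,
                             radiusRange = c(10, 60), seed = 5)
    radii <- unlist(lapply(vesselSegments(sc), `[[`, "radius"))
    expect_gte(min(radii), 10)
    expect_lte(max(radii), 60)
    roots <- vapply(vesselSegments(sc), `[[`, 0L, "root")
    expect_setequal(unique(roots), 1:3)
    sc2 <- generateVesselTree(c(600, 600, 600), nRoots = 3,
                              radiusRange = c(10, 60), seed = 5)
    expect_identical(vesselSegments(sc)[[1]]$points,
                     vesselSegments(sc2)[[1]]$points)
    expect_identical(bifurcationPoints(sc), bifurcationPoints(sc2))
    expect_error(generateVesselTree(c(0, 100, 100)), "positive")
    expect_error(generateVesselTree(c(100, 100, 100),
                                    radiusRange = c(10, 60)),
                 "radius range")
})

test_that("rasterization matches cylinder geometry and analytic volume", {
    # single straight cylinder radius 25 um at 5 um spacing
    seg <- list(points = rbind(c(50, 60, 0), c(50, 60, 120)),
                radius = c(25, 25), velocity = 2, root = 1L)
    sc <- new("PhantomScene", segments = list(seg),
              bifurcations = matrix(0, 0, 3), tumorField = NULL,
              deformation = NULL, extent = c(100, 120, 120), seed = 1L)
    ras <- suppressWarnings(rasterizeMicroscopy(sc, 5,
                                                channels = "vessel"))
    ind <- voxelData(ras$vesselMask)
    # central-slice width: 10 +/- 1 voxels across the tube
    width <- sum(ind[10, , 12])
    expect_gte(width, 9); expect_lte(width, 11)
    # sigma=0 noise and PSF: intensity equals the indicator exactly
    expect_equal(voxelData(ras$vessel), ind * 1.0)
    # same seed gives identical noise realization
    r1 <- suppressWarnings(rasterizeMicroscopy(sc, 5,
        channels = "vessel", noiseSd = 0.1, seed = 7))
    r2 <- suppressWarnings(rasterizeMicroscopy(sc, 5,
        channels = "vessel", noiseSd = 0.1, seed = 7))
    expect_identical(voxelData(r1$vessel), voxelData(r2$vessel))
    # voxel volume within 10% of analytic pi r^2 L at spacing <= r/4
    vol <- sum(ind) * 125
    expect_lt(abs(vol - pi * 25^2 * 120) / (pi * 25^2 * 120), 0.1)
})

test_that("simulated MRI follows the linear contrast model exactly", {
    sc <- generateVesselTree(c(400, 400, 400), nRoots = 1, maxDepth = 2,
                             radiusRange = c(20, 50), seed = 8)
    sc <- addTumorField(sc, fieldSpacing = 20, seed = 8)
    sim <- simulateMri(sc, 50, "t2w", baseline = 100, kVessel = 40,
                       kTumor = 30, oversample = 2)
    pred <- 100 - 40 * voxelData(sim$vesselFraction) +
        30 * voxelData(sim$tumorDensity)
    expect_equal(voxelData(sim$volume), pred, tolerance = 1e-12)
    # a voxel fully inside a vessel, no tumor: baseline - kVessel
    full <- which(voxelData(sim$vesselFraction) == 1 &
                  voxelData(sim$tumorDensity) == 0)
    if (length(full))
        expect_equal(unname(voxelData(sim$volume)[full[1]]), 60)
    # TOF is strictly monotone in flow-weighted occupancy
    tof <- simulateMri(sc, 50, "tof", baseline = 100, kFlow = 10,
                       oversample = 2)
    ff <- voxelData(tof$flowFraction)
    lo <- which(ff > 0 & ff < median(ff[ff > 0]))
    hi <- which(ff > 2 * median(ff[ff > 0]))
    if (length(lo) && length(hi))
        expect_lt(max(voxelData(tof$volume)[lo]),
                  min(voxelData(tof$volume)[hi]) + 1e-9)
    expect_error(simulateMri(sc, 50, "flair"), "arg")
})

test_that("synthetic deformations produce exact landmark ground truth", {
    v <- toyVolume(c(16, 16, 16), c(40, 40, 40))
    pts <- as.matrix(expand.grid(c(100, 300), c(100, 300), c(100, 300)))
    # identity: volume unchanged, RMSE 0
    did <- applySyntheticDeformation(v, list(kind = "identity"),
                                     points = pts)
    expect_equal(voxelData(did$deformed), voxelData(v), tolerance = 1e-9)
    expect_equal(landmarkRMSE(did$landmarks), 0)
    # pure translation: every pair differs by exactly the shift
    dtr <- applySyntheticDeformation(v,
        list(kind = "rigid", translation = c(50, 0, 0)), points = pts)
    diff <- movingPoints(dtr$landmarks) - fixedPoints(dtr$landmarks)
    expect_equal(diff, matrix(c(50, 0, 0), nrow(pts), 3, byrow = TRUE),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # smooth warp: displacement bounded by the requested amplitude
    dsw <- applySyntheticDeformation(v,
        list(kind = "smooth", amplitude = 80), points = pts, seed = 3)
    disp <- sqrt(rowSums((movingPoints(dsw$landmarks) -
                          fixedPoints(dsw$landmarks))^2))
    expect_lte(max(disp), 80 + 1e-6)
    # the landmark preimages are exact under the generating transform
    expect_lt(max(abs(transformPoints(dsw$transform,
        fixedPoints(dsw$landmarks)) - movingPoints(dsw$landmarks))),
        1e-6)
    expect_error(applySyntheticDeformation(v,
        list(kind = "smooth", amplitude = 1e5)), "amplitude")
})

test_that("kymograph streaks advance at the configured slope", {
    k <- generateKymograph(2, pixelSize = 1.1838, lineInterval = 0.15,
                           nLines = 100, nStreaks = 1, seed = 2)
    expect_equal(pixelSize(k), 1.1838)
    # slope px/line = v * dt / dx = 2 * 0.15 / 1.1838
    slope <- 2 * 0.15 / 1.1838
    expect_equal(slope, 0.2534, tolerance = 1e-3)
    # locate the darkest pixel of one streak on two distant lines
    img <- voxelData(k)
    p1 <- which.min(img[1, ]); p50 <- which.min(img[50, ])
    adv <- (p50 - p1) %% 128
    expect_equal(adv, round(slope * 49), tolerance = 1)
    # near-infinite velocity: streaks nearly vertical in time
    kf <- generateKymograph(1000, nLines = 100, seed = 2)
    expect_lt(1 / (1000 * 0.15 / 1.1838), 0.01)  # lines per px
    expect_identical(voxelData(generateKymograph(3, seed = 9)),
                     voxelData(generateKymograph(3, seed = 9)))
    expect_error(generateKymograph(0), "positive")
})

test_that("longitudinal series grow linearly with clamping", {
    sc <- generateVesselTree(c(300, 300, 300), nRoots = 1, maxDepth = 1,
                             radiusRange = c(15, 40), seed = 4)
    sc <- addTumorField(sc, nBlobs = 2, peak = 0.5, fieldSpacing = 30,
                        cutoff = 0, seed = 4)
    base <- voxelData(tumorField(sc))
    ser <- generateLongitudinalSeries(sc, growthRate = 2,
                                      days = c(0, 5, 10))
    expect_length(ser, 3)
    expect_equal(voxelData(tumorField(ser[[3]])),
                 pmin(base + 0.2, 1), tolerance = 1e-12)
    # rate 0: identical fields
    ser0 <- generateLongitudinalSeries(sc, 0, c(0, 7))
    expect_identical(voxelData(tumorField(ser0[[1]])),
                     voxelData(tumorField(ser0[[2]])))
    # clamping warns
    scHigh <- addTumorField(sc, nBlobs = 3, peak = 0.95,
                            fieldSpacing = 30, cutoff = 0, seed = 5)
    expect_warning(generateLongitudinalSeries(scHigh, 2, c(0, 10)),
                   "clamped")
    expect_error(generateLongitudinalSeries(sc, 2, numeric()),
                 "non-empty")
})
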