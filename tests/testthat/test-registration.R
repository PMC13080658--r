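test_that("rigid and similarity fits recover generating parameters", {
    ang <- c(pi / 6, 0, 0); tr_t <- c(10, 20, 0)
    lm <- rigidPair(8, ang, tr_t)
    fit <- fitLandmarkTransform(lm, "rigid")
    R <- micromri:::rotationMatrix3(ang)
    expect_equal(fit@A, R, tolerance = 1e-9)
    expect_equal(fit@t, tr_t, tolerance = 1e-6)
    # recovered rotation angle about z
    expect_equal(atan2(fit@A[3, 2], fit@A[2, 2]), pi / 6,
                 tolerance = 1e-9)
    set.seed(3)
    X <- matrix(rnorm(24, sd = 150), 8, 3)
    s <- 1.37
    Y <- s * X %*% t(R) + matrix(c(5, -3, 2), 8, 3, byrow = TRUE)
    fs <- fitLandmarkTransform(list(fixed = X, moving = Y), "similarity")
    expect_equal(det(fs@A)^(1 / 3), s, tolerance = 1e-9)
    expect_equal(transformPoints(fs, X), Y, tolerance = 1e-6,
                 ignore_attr = TRUE)
})

test_that("affine fit is exact on affine-consistent landmarks", {
    set.seed(4)
    A <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
    X <- matrix(rnorm(30, sd = 100), 10, 3)
    Y <- X %*% t(A) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
    fit <- fitLandmarkTransform(list(fixed = X, moving = Y), "affine")
    expect_equal(fit@A, A, tolerance = 1e-9)
    expect_equal(fit@t, c(1, 2, 3), tolerance = 1e-9)
})

test_that("TPS interpolates its landmarks exactly and degenerates to
           affine on affine-consistent data", {
    lm <- rigidPair(10, c(0.3, 0.1, -0.2), c(5, 5, 5), seed = 9)
    tps <- fitLandmarkTransform(lm, "tps")
    expect_lt(max(abs(transformPoints(tps, fixedPoints(lm)) -
                      movingPoints(lm))), 1e-6)
    # identity pairs: zero kernel weights, identity affine part
    X <- fixedPoints(lm)
    tid <- fitLandmarkTransform(list(fixed = X, moving = X), "tps")
    expect_lt(max(abs(tid@W)), 1e-9)
    expect_equal(tid@A, diag(3), tolerance = 1e-9)
    # affine-consistent pairs: non-affine warp energy vanishes
    expect_lt(max(abs(tps@W)), 1e-9)
    bendingEnergy <- sum(tps@W * micromri:::tpsKernelMatrix(
        fixedPoints(lm), fixedPoints(lm), 3L) %*% tps@W)
    expect_lt(abs(bendingEnergy), 1e-9)
})

test_that("degenerate configurations are rejected with a named cause", {
    line <- cbind(1:5, 0, 0) * 10
    expect_error(fitLandmarkTransform(list(fixed = line,
                                           moving = line), "rigid"),
                 "collinear")
    plane <- cbind(expand.grid(1:3, 1:3), 0) * 10
    expect_error(fitLandmarkTransform(list(fixed = as.matrix(plane),
                                           moving = as.matrix(plane)),
                                      "affine"), "coplanar")
    expect_error(fitLandmarkTransform(list(fixed = line[1:2, ],
                                           moving = line[1:2, ]),
                                      "rigid"), "at least")
})

test_that("transform composition and inversion behave algebraically", {
    t1 <- rigidTransform(c(0.2, 0, 0), c(1, 2, 3))
    t2 <- rigidTransform(c(0, -0.1, 0.3), c(-4, 0, 7))
    pts <- matrix(rnorm(30, sd = 50), 10, 3)
    # composite equals sequential application, matrix-product closed form
    comp <- composeTransforms(list(t1, t2))
    expect_equal(comp@kind, "rigid")
    expect_equal(transformPoints(comp, pts),
                 transformPoints(t2, transformPoints(t1, pts)),
                 tolerance = 1e-9)
    expect_equal(comp@A, t2@A %*% t1@A, tolerance = 1e-12)
    # T composed with its inverse is the identity
    inv <- invertTransform(t1)
    round <- composeTransforms(list(t1, inv))
    expect_equal(transformPoints(round, pts), pts, tolerance = 1e-9)
    # translation then its negation
    tp <- composeTransforms(list(rigidTransform(translation = c(1, 2, 3)),
                                 rigidTransform(translation = -c(1, 2, 3))))
    expect_equal(transformPoints(tp, pts), pts, tolerance = 1e-12)
    expect_error(composeTransforms(list()), "empty")
    expect_error(transformPoints(t1, matrix(0, 2, 2)), "dimensionality")
    # chains through a mid-space reproduce the direct mapping
    lmAB <- rigidPair(8, c(0.1, 0, 0), c(5, 0, 0), seed = 11)
    trAB <- fitLandmarkTransform(lmAB, "rigid")
    trBC <- rigidTransform(c(0, 0.15, 0), c(0, -8, 2))
    direct <- transformPoints(trBC,
                              transformPoints(trAB, fixedPoints(lmAB)))
    chain <- composeTransforms(list(trAB, trBC))
    expect_equal(transformPoints(chain, fixedPoints(lmAB)), direct,
                 tolerance = 1e-9)
})

test_that("landmark RMSE matches hand arithmetic", {
    expect_equal(landmarkRMSE(matrix(0, 1, 3), matrix(c(3, 4, 0), 1)), 5)
    a <- rbind(c(0, 0, 0), c(0, 0, 0))
    b <- rbind(c(5, 0, 0), c(0, 0, 0))
    expect_equal(landmarkRMSE(a, b), sqrt(12.5))
    expect_equal(landmarkRMSE(a, a), 0)
    expect_error(landmarkRMSE(a[0, , drop = FALSE], b[0, , drop = FALSE]),
                 "empty")
})

test_that("inter-rater grid RMSE reflects chain differences", {
    v <- ImageVolume(array(0, c(3, 60, 60)), spacing = c(100, 10, 10))
    id <- identityTransform()
    expect_equal(interraterRMSE(v, id, id, sampleN = 400)$rmse, 0)
    shift <- rigidTransform(translation = c(0, 30, 40))
    expect_equal(interraterRMSE(v, id, shift, sampleN = 400)$rmse, 50,
                 tolerance = 1e-9)
    # subsampled RMSE approximates the full-grid value on smooth chains
    warpCtrl <- matrix(rnorm(24, sd = 20), 8, 3)
    base <- as.matrix(expand.grid(c(0, 300), c(0, 300), c(0, 300)))
    warp <- fitLandmarkTransform(list(fixed = base,
                                      moving = base + warpCtrl), "tps")
    full <- interraterRMSE(v, id, warp, sampleN = 1e7)$rmse
    sub <- interraterRMSE(v, id, warp, sampleN = 600, seed = 4)$rmse
    expect_lt(abs(sub - full) / full, 0.05)
})

test_that("longitudinal rigid registration recovers a known pose", {
    scene <- generateVesselTree(extent = c(600, 600, 600), nRoots = 2,
                                maxDepth = 3, radiusRange = c(30, 60),
                                seed = 3)
    ref <- rasterizeMicroscopy(scene, 15, channels = "vessel",
                               psfSigma = 15)$vessel
    truth <- rigidTransform(c(5 * pi / 180, 0, 0), c(30, 0, 0))
    mov <- resampleVolume(ref, invertTransform(truth), ref)
    # self-registration: identity
    self <- registerLongitudinal(ref, ref, maxAngle = 0.05, maxShift = 20)
    expect_lt(sqrt(sum(self$diagnostics$par^2)), 1e-3)
    # landmark mode: closed form within 0.1 deg / 2 um
    pts <- as.matrix(expand.grid(c(100, 300, 500), c(100, 500),
                                 c(100, 500)))
    lm <- LandmarkSet(pts, transformPoints(truth, pts))
    fitL <- registerLongitudinal(mov, ref, landmarks = lm)
    expect_equal(fitL$transform@A, truth@A, tolerance = 1e-6)
    expect_lt(max(abs(fitL$transform@t - truth@t)), 2)
    expect_equal(fitL$transform@kind, "rigid")
    # intensity mode: within 0.5 deg and half a voxel (7.5 um)
    fitI <- registerLongitudinal(mov, ref, maxAngle = 0.15,
                                 maxShift = 60)
    angErr <- acos(pmin(1, (sum(diag(t(fitI$transform@A) %*% truth@A)) -
                            1) / 2))
    expect_lt(angErr, 0.5 * pi / 180)
    expect_lt(max(abs(fitI$transform@t - truth@t)), 7.5)
})
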