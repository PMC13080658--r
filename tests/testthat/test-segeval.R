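test_that("binarization follows the >= threshold rule", {
    v <- ImageVolume(array(c(9999, 10000, 60000, 0, 1, 2), c(1, 2, 3)),
                     c(25, 25, 25))
    b <- binarize(v, 10000)
    expect_equal(as.vector(voxelData(b)),
                 c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
    expect_false(any(voxelData(binarize(v, 60001))))
    expect_true(all(voxelData(binarize(v, 0))))
})

test_that("dilated Dice matches the hand-enumerated shift example", {
    a <- array(FALSE, c(1, 1, 10)); a[1, 1, 1:4] <- TRUE
    b <- array(FALSE, c(1, 1, 10)); b[1, 1, 4:7] <- TRUE
    A <- BinaryMask(a, c(25, 25, 25)); B <- BinaryMask(b, c(25, 25, 25))
    expect_equal(dilatedDice(A, B, 50), 0.75)
    expect_equal(dilatedDice(A, B, 0), 0.25)   # plain Dice
    expect_equal(dilatedDice(A, A, 50), 1)
    # far-separated masks score 0
    far <- array(FALSE, c(1, 1, 10)); far[1, 1, 10] <- TRUE
    a1 <- array(FALSE, c(1, 1, 10)); a1[1, 1, 1] <- TRUE
    expect_equal(dilatedDice(BinaryMask(a1, c(25, 25, 25)),
                             BinaryMask(far, c(25, 25, 25)), 50), 0)
    expect_error(dilatedDice(BinaryMask(array(FALSE, c(1, 1, 10)),
                                        c(25, 25, 25)),
                             BinaryMask(array(FALSE, c(1, 1, 10)),
                                        c(25, 25, 25))), "empty")
})

test_that("MASD matches hand arithmetic and is symmetric", {
    a <- array(FALSE, c(1, 1, 5)); a[1, 1, 1] <- TRUE
    b <- array(FALSE, c(1, 1, 5)); b[1, 1, 3] <- TRUE
    A <- BinaryMask(a, c(25, 25, 25)); B <- BinaryMask(b, c(25, 25, 25))
    expect_equal(masd(A, B), 50)              # (50 + 50) / 2
    expect_equal(masd(A, B), masd(B, A))
    expect_equal(masd(A, A), 0)
    expect_error(masd(A, BinaryMask(array(FALSE, c(1, 1, 5)),
                                    c(25, 25, 25))), "nonempty")
})

test_that("metrics agree exactly with brute-force all-pairs oracles", {
    for (seed in 1:20) {
        A <- randomMask(c(10, 10, 3), p = 0.12, seed = seed)
        B <- randomMask(c(10, 10, 3), p = 0.12, seed = seed + 1000)
        for (tol in c(0, 25, 50)) {
            expect_equal(dilatedDice(A, B, tol),
                         bruteDilatedDice(A, B, tol), tolerance = 1e-12)
        }
        expect_equal(masd(A, B), bruteMasd(A, B), tolerance = 1e-9)
        # monotone in tolerance
        dd <- vapply(c(0, 25, 50, 100), function(t)
            dilatedDice(A, B, t), 0)
        expect_true(all(diff(dd) >= -1e-12))
    }
})

test_that("dilated Dice reaches 1 when Hausdorff is within tolerance", {
    A <- randomMask(c(6, 6, 2), p = 0.3, seed = 42)
    B <- randomMask(c(6, 6, 2), p = 0.3, seed = 43)
    pa <- maskCenters(A); pb <- maskCenters(B)
    h <- max(
        max(apply(pa, 1, function(p)
            sqrt(min(colSums((t(pb) - p)^2))))),
        max(apply(pb, 1, function(p)
            sqrt(min(colSums((t(pa) - p)^2))))))
    expect_equal(dilatedDice(A, B, h + 1), 1)
})

test_that("anisotropic spacing: a 50 um ball adds no z neighbors at
           100 um slices", {
    a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
    b <- array(FALSE, c(5, 5, 5)); b[2, 3, 3] <- TRUE  # 100 um away in z
    A <- BinaryMask(a, c(100, 25, 25)); B <- BinaryMask(b, c(100, 25, 25))
    expect_equal(dilatedDice(A, B, 50), 0)
    bx <- array(FALSE, c(5, 5, 5)); bx[3, 3, 4] <- TRUE  # 25 um in x
    expect_equal(dilatedDice(A, BinaryMask(bx, c(100, 25, 25)), 50), 1)
})

test_that("subject-grouped folds partition datasets deterministically", {
    ids <- sprintf("ds%02d", 1:20)
    subj <- rep(sprintf("m%d", 1:10), each = 2)
    fa <- crossvalSplit(ids, k = 5, groupBy = subj, seed = 3)
    expect_equal(sort(unique(fa$fold)), 0:4)
    # subjects are never split across folds
    bySubj <- tapply(fa$fold, subj, function(x) length(unique(x)))
    expect_true(all(bySubj == 1))
    # sizes differ by <= 1 (in subjects)
    sizes <- table(tapply(fa$fold, subj, unique))
    expect_lte(diff(range(sizes)), 1)
    # union = all ids, disjoint by construction
    expect_setequal(names(fa$fold), ids)
    expect_identical(crossvalSplit(ids, 5, subj, seed = 3)$fold, fa$fold)
    expect_error(crossvalSplit(ids[1:4], k = 5), "fewer groups")
})

test_that("training pairs share geometry, honor the diameter filter and
           augment deterministically", {
    scene <- generateVesselTree(c(600, 600, 600), nRoots = 2,
                                maxDepth = 2, radiusRange = c(10, 60),
                                seed = 6)
    micro <- suppressWarnings(rasterizeMicroscopy(scene, 12.5,
                                                  channels = "vessel"))
    pairs <- prepTrainingPairs(micro$vessel, micro$vesselMask,
                               targetSpacing = c(100, 25, 25),
                               minDiameter = 30, nAugment = 2, seed = 4)
    expect_length(pairs, 3)
    for (p in pairs) {
        expect_equal(spacing(p$image), c(100, 25, 25))
        expect_true(sameGrid(p$image, p$label))
    }
    # no surviving label voxel has local diameter < 30 um
    lab <- pairs[[1]]$label
    if (any(voxelData(lab))) {
        dia <- voxelData(estimateLocalDiameter(lab))[voxelData(lab)]
        expect_true(all(dia >= 30 - 1e-9))
    }
    pairs2 <- prepTrainingPairs(micro$vessel, micro$vesselMask,
                                targetSpacing = c(100, 25, 25),
                                minDiameter = 30, nAugment = 2, seed = 4)
    expect_identical(voxelData(pairs[[3]]$image),
                     voxelData(pairs2[[3]]$image))
    expect_identical(voxelData(pairs[[3]]$label),
                     voxelData(pairs2[[3]]$label))
    # exported folder layout
    d <- withr::local_tempdir()
    exportTrainingPairs(pairs, d)
    expect_true(file.exists(file.path(d, "imagesTr",
                                      "CASE_0000_0000.nii.gz")))
    expect_true(file.exists(file.path(d, "labelsTr", "CASE_0000.nii.gz")))
})

test_that("visibility transitions conserve the vessel count", {
    lv <- c("strongly visible", "barely visible", "not visible")
    before <- rep(lv, c(20, 20, 11))
    after <- before
    m <- visibilityTransitions(before, after)
    expect_equal(sum(m), 51)
    expect_true(all(m[upper.tri(m)] == 0) && all(m[lower.tri(m)] == 0))
    after[1] <- "not visible"
    m2 <- visibilityTransitions(before, after)
    expect_equal(m2["strongly visible", "not visible"], 1,
                 ignore_attr = TRUE)
    expect_equal(sum(m2), 51)
    expect_error(visibilityTransitions(c("shiny"), c("not visible")),
                 "unknown")
})

test_that("probe diameters read the thickness map consistently", {
    cyl <- cylinderMask(30, 5, nz = 12, ny = 31, nx = 31)
    ctr <- dim(voxelData(cyl)) * 5 / 2
    d1 <- vesselDiameterFromMask(cyl, c(20, ctr[2], ctr[3]))
    d2 <- vesselDiameterFromMask(cyl, c(40, ctr[2], ctr[3]))
    expect_lt(abs(d1 - 60), 5.1)
    expect_lt(abs(d1 - d2), 5.1)          # same straight segment
    expect_error(vesselDiameterFromMask(cyl, c(20, 2.5, 2.5)),
                 "background")
})

test_that("flipped ground truth scores poorly (negative control)", {
    scene <- generateVesselTree(c(1000, 1000, 1000), nRoots = 2,
                                maxDepth = 2, radiusRange = c(15, 35),
                                seed = 9)
    mask <- suppressWarnings(rasterizeMicroscopy(scene, 12.5,
        channels = "vessel"))$vesselMask
    arr <- voxelData(mask)
    flipped <- BinaryMask(arr[, rev(seq_len(dim(arr)[2])), ],
                          spacing(mask), origin(mask))
    expect_equal(dilatedDice(mask, mask, 50), 1)
    expect_lt(dilatedDice(mask, flipped, 50), 0.2)
})
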