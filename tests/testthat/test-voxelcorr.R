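test_that("z-grouping averages slices and preserves foreground volume", {
    arr <- array(0, c(20, 4, 4))
    arr[1:10, , ] <- 1                      # half the slices foreground
    stack <- BinaryMask(arr == 1, c(5, 10, 10))
    g <- groupZByAverage(stack, 100)
    expect_equal(dim(voxelData(g)), c(1L, 4L, 4L))
    expect_true(all(voxelData(g) == 0.5))
    expect_equal(spacing(g)[1], 100)
    # arbitrary stack: each output slice is the mean of its group
    v <- toyVolume(c(20, 3, 3), c(5, 10, 10))
    g2 <- groupZByAverage(v, 100)
    expect_equal(voxelData(g2)[1, 2, 2],
                 mean(voxelData(v)[1:20, 2, 2]), tolerance = 1e-12)
    # conservation of total foreground volume
    tot_in <- sum(voxelData(stack)) * prod(spacing(stack))
    tot_out <- sum(voxelData(g)) * prod(spacing(g))
    expect_equal(tot_out, tot_in, tolerance = 1e-9)
    # partial trailing group dropped with warning
    v23 <- toyVolume(c(23, 3, 3), c(5, 10, 10))
    expect_warning(g3 <- groupZByAverage(v23, 100), "partial")
    expect_equal(dim(voxelData(g3))[1], 1L)
    expect_error(groupZByAverage(v, 72), "integer")
})

test_that("xy density downsampling preserves constants and ramps", {
    ones <- ImageVolume(array(1, c(2, 16, 16)), c(100, 10, 10),
                        origin = c(50, 5, 5), role = "density")
    grid <- ImageVolume(array(0, c(2, 4, 4)), c(100, 40, 40),
                        origin = c(50, 20, 20))
    expect_true(all(voxelData(downsampleXYDensity(ones, grid)) == 1))
    zeros <- ImageVolume(array(0, c(2, 16, 16)), c(100, 10, 10),
                         origin = c(50, 5, 5), role = "density")
    expect_true(all(voxelData(downsampleXYDensity(zeros, grid)) == 0))
    # linear ramp in x: block means equal the ramp at output centers
    rampv <- array(rep(seq_len(16), each = 2 * 16) / 16, c(2, 16, 16))
    ramp <- ImageVolume(rampv, c(100, 10, 10), origin = c(50, 5, 5),
                        role = "density")
    out <- downsampleXYDensity(ramp, grid)
    ctrX <- gridCenters(out)[, 3]
    oracle <- (ctrX + 5) / 160          # mean of the 4 merged columns
    expect_lt(max(abs(as.vector(voxelData(out)) - oracle)), 1e-9)
    expect_error(downsampleXYDensity(
        ImageVolume(array(0, c(3, 16, 16)), c(100, 10, 10)), grid), "z")
})

test_that("NAGM z-normalization standardizes in-mask statistics", {
    set.seed(6)
    arr <- array(rnorm(8 * 8 * 8, mean = 100, sd = 10), c(8, 8, 8))
    v <- ImageVolume(arr, c(40, 40, 40))
    maskArr <- array(FALSE, c(8, 8, 8)); maskArr[, 1:4, ] <- TRUE
    m <- BinaryMask(maskArr, c(40, 40, 40))
    zn <- znormalizeNagm(v, m)
    inm <- voxelData(zn$volume)[maskArr]
    expect_lt(abs(mean(inm)), 1e-9)
    expect_equal(sd(inm), 1, tolerance = 1e-9)
    # formula check: voxel 2 sd above the mean maps to z = 2
    expect_equal((120 - zn$stats$mean) / zn$stats$sd,
                 (120 - mean(arr[maskArr])) / sd(arr[maskArr]))
    # idempotent up to stats
    zn2 <- znormalizeNagm(zn$volume, m)
    expect_lt(abs(zn2$stats$mean), 1e-9)
    expect_equal(zn2$stats$sd, 1, tolerance = 1e-9)
    flat <- ImageVolume(array(5, c(8, 8, 8)), c(40, 40, 40))
    expect_error(znormalizeNagm(flat, m), "variance")
    empty <- BinaryMask(array(FALSE, c(8, 8, 8)), c(40, 40, 40))
    expect_error(znormalizeNagm(v, empty), "empty")
})

test_that("T2* mapping recovers mono-exponential decay", {
    te <- c(3, 6, 9, 12)
    d <- c(4, 4, 4)
    mk <- function(s0, t2) lapply(te, function(t)
        ImageVolume(array(s0 * exp(-t / t2), d), c(40, 40, 40)))
    fit <- fitT2starMap(mk(1000, 20), te)
    expect_equal(voxelData(fit$t2star)[1, 1, 1], 20, tolerance = 1e-6)
    expect_equal(voxelData(fit$s0)[1, 1, 1], 1000, tolerance = 1e-3)
    # constant signal: infinite T2* masked invalid
    flat <- lapply(te, function(t) ImageVolume(array(500, d),
                                               c(40, 40, 40)))
    expect_true(all(is.na(voxelData(fitT2starMap(flat, te)$t2star))))
    expect_error(fitT2starMap(mk(1000, 20)[1:2], te[1:2]), "3 echoes")
    # noisy recovery: median over 1000 voxels within 5% at SNR 50
    set.seed(11)
    dd <- c(10, 10, 10)
    noisy <- lapply(te, function(t) ImageVolume(
        array(1000 * exp(-t / 20) + rnorm(1000, sd = 20), dd),
        c(40, 40, 40)))
    t2 <- voxelData(fitT2starMap(noisy, te)$t2star)
    expect_lt(abs(median(t2, na.rm = TRUE) - 20) / 20, 0.05)
})

test_that("voxel-table extraction copies layer values inside the mask", {
    v1 <- toyVolume(c(4, 5, 6), c(40, 40, 40), seed = 3)
    v2 <- toyVolume(c(4, 5, 6), c(40, 40, 40), seed = 4)
    lab <- array(0L, c(4, 5, 6))
    keep <- sample(prod(c(4, 5, 6)), 7)
    lab[keep] <- 1:7 %% 2 + 1L
    cm <- LabelMask(lab, c(40, 40, 40), origin = c(20, 20, 20))
    tab <- extractVoxelTable(list(a = v1, b = v2), cm,
                             categoryLabels = c("w/o glioma", "glioma"),
                             metadata = list(subject_id = "m1"))
    expect_equal(nrow(tab), 7L)
    expect_true(all(tab$subject_id == "m1"))
    # values equal direct indexing for every row
    lin <- tab$iz + 4 * (tab$iy + 5 * tab$ix) + 1
    expect_equal(tab$a, voxelData(v1)[lin])
    expect_equal(tab$b, voxelData(v2)[lin])
    # empty mask -> empty table
    expect_equal(nrow(extractVoxelTable(list(a = v1),
        LabelMask(array(0L, c(4, 5, 6)), c(40, 40, 40),
                  origin = c(20, 20, 20)))), 0L)
    # mismatched geometry is rejected naming the layer
    bad <- toyVolume(c(4, 5, 6), c(50, 40, 40))
    expect_error(extractVoxelTable(list(a = v1, oops = bad), cm), "oops")
})

test_that("density bins follow the half-open convention and partition", {
    tab <- data.frame(glioma_density = c(0, 0.049, 0.05, 0.25, 0.75, 1),
                      category = "glioma")
    b <- binByDensity(tab)
    expect_equal(as.character(b$density_bin),
                 c("0-5%", "0-5%", "5-25%", "25-50%", "75-100%",
                   "75-100%"))
    # normal-category rows land in the w/o bin
    tab2 <- data.frame(glioma_density = c(0, 0.6),
                       category = c("w/o glioma", "glioma"))
    expect_equal(as.character(binByDensity(tab2)$density_bin)[1],
                 "w/o glioma")
    # bins partition any table
    set.seed(2)
    tab3 <- data.frame(glioma_density = runif(1000), category = "glioma")
    b3 <- binByDensity(tab3)
    expect_equal(sum(table(b3$density_bin)), 1000)
    expect_false(anyNA(b3$density_bin))
    expect_error(binByDensity(data.frame(glioma_density = 1.2,
                                         category = "glioma")), "0, 1")
})

test_that("growth rates recover the generating rate inside the overlap", {
    d <- c(4, 4, 4)
    mk <- function(x) ImageVolume(array(x, d), c(40, 40, 40),
                                  role = "density")
    dens <- list(mk(0.1), mk(0.2), mk(0.3))
    gr <- computeGrowthRate(dens, c(0, 5, 10))
    expect_true(all(abs(gr$growth_rate - 2) < 1e-9))
    # constant density: zero rate
    gr0 <- computeGrowthRate(list(mk(0.4), mk(0.4)), c(0, 7))
    expect_true(all(gr0$growth_rate == 0))
    # voxels outside one timepoint's mask are excluded
    m1 <- BinaryMask(array(TRUE, d), c(40, 40, 40))
    m2arr <- array(TRUE, d); m2arr[1, 1, 1] <- FALSE
    m2 <- BinaryMask(m2arr, c(40, 40, 40))
    grM <- computeGrowthRate(dens, c(0, 5, 10),
                             masks = list(m1, m2, m1))
    expect_equal(nrow(grM), prod(d) - 1L)
    expect_false(any(grM$iz == 0 & grM$iy == 0 & grM$ix == 0))
    expect_error(computeGrowthRate(dens, c(3, 4, 3)), "zero day span")
})

test_that("group statistics run the named tests with correct adjustment", {
    set.seed(8)
    # huge effect: Welch p astronomically small
    x <- c(rnorm(50), rnorm(50, mean = 3))
    g <- rep(c("a", "b"), each = 50)
    w <- groupStats(x, g, "welch")
    expect_lt(w$omnibus$p, 1e-10)
    expect_equal(w$pairwise$direction, "increase")
    # identical groups: Mann-Whitney p is 1 (ties handled, no exact)
    same <- rep(c(1, 2, 3, 4, 5), 2)
    gs <- rep(c("a", "b"), each = 5)
    mw <- groupStats(same, gs, "mannwhitney")
    expect_gt(mw$omnibus$p, 0.99)
    # three groups: Dunn-Bonferroni gives 3 pairwise rows, p_adj = 3*raw
    y <- c(rnorm(20), rnorm(20, 1), rnorm(20, 2))
    gg <- rep(c("g1", "g2", "g3"), each = 20)
    kd <- groupStats(y, gg, "kruskal_dunn_bonf")
    expect_equal(nrow(kd$pairwise), 3L)
    expect_equal(kd$pairwise$p_adj,
                 pmin(1, kd$pairwise$p_raw * 3), tolerance = 1e-12)
    # ANOVA/Tukey agrees with stats::aov on group count
    at <- groupStats(y, gg, "anova_tukey")
    expect_equal(nrow(at$pairwise), 3L)
    expect_lt(at$omnibus$p, 1e-6)
    expect_error(groupStats(y, rep("one", 60)), "2 groups")
    # report serializes
    p <- withr::local_tempfile(fileext = ".csv")
    writeStatsReport(at, p)
    expect_gt(nrow(read.csv(p)), 3)
})

test_that("Dunn z-tests match a hand-computed small example", {
    # hand oracle: ranks of c(1,2,3,4,5,6) in groups (a,a,b,b,c,c)
    vals <- c(1, 2, 3, 4, 5, 6)
    g <- c("a", "a", "b", "b", "c", "c")
    d <- micromri:::dunnTest(vals, factor(g))
    # mean ranks: a=1.5, b=3.5, c=5.5; se = sqrt((6*7/12)*(1/2+1/2))
    se <- sqrt(6 * 7 / 12)
    expect_equal(d$z[d$comparison == "b - a"], 2 / se, tolerance = 1e-12)
    expect_equal(d$z[d$comparison == "c - a"], 4 / se, tolerance = 1e-12)
    expect_equal(d$p_adj, pmin(1, d$p_raw * 3), tolerance = 1e-15)
})
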