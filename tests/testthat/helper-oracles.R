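# Fixture builders and independent brute-force oracles used across tests.

# axis-aligned cylinder mask along z; center (cy, cx) and radius in um
cylinderMask <- function(radius, spacingUm = 5, nz = 12, ny = 25, nx = 25,
                         cy = NULL, cx = NULL) {
    sp <- rep(spacingUm, length.out = 3)
    if (is.null(cy)) cy <- ny * sp[2] / 2
    if (is.null(cx)) cx <- nx * sp[3] / 2
    yc <- (seq_len(ny) - 0.5) * sp[2]
    xc <- (seq_len(nx) - 0.5) * sp[3]
    disk <- outer(yc, xc, function(y, x) (y - cy)^2 + (x - cx)^2 <=
                                          radius^2)
    arr <- array(rep(disk, each = nz), c(nz, ny, nx))
    BinaryMask(arr, sp, origin = sp / 2)
}

sphereMask <- function(radius, spacingUm = 5, n = 25) {
    sp <- rep(spacingUm, length.out = 3)
    ctr <- n * sp / 2
    ax <- lapply(1:3, function(i) (seq_len(n) - 0.5) * sp[i] - ctr[i])
    arr <- array(FALSE, rep(n, 3))
    for (k in seq_len(n)) {
        d2 <- outer(ax[[1]]^2, ax[[2]]^2, "+") + ax[[3]][k]^2
        arr[, , k] <- d2 <= radius^2
    }
    BinaryMask(arr, sp, origin = sp / 2)
}

randomMask <- function(dims, p = 0.15, spacingUm = c(25, 25, 25),
                       seed = 1) {
    set.seed(seed)
    arr <- array(runif(prod(dims)) < p, dims)
    if (!any(arr)) arr[1] <- TRUE
    BinaryMask(arr, spacingUm)
}

# world coordinates of all foreground voxel centers
maskCenters <- function(mask) {
    gridCenters(mask)[as.vector(voxelData(mask)), , drop = FALSE]
}

# brute-force all-pairs metrics (quadratic; tiny masks only)
bruteDilatedDice <- function(A, B, tol) {
    pa <- maskCenters(A); pb <- maskCenters(B)
    ca <- gridCenters(A); cb <- gridCenters(B)
    a <- as.vector(voxelData(A)); b <- as.vector(voxelData(B))
    minDist <- function(pts, feat)
        apply(pts, 1, function(p) sqrt(min(colSums((t(feat) - p)^2))))
    inDB <- rep(FALSE, length(a))
    if (nrow(pb)) inDB <- minDist(ca, pb) <= tol + 1e-9
    inDA <- rep(FALSE, length(b))
    if (nrow(pa)) inDA <- minDist(cb, pa) <= tol + 1e-9
    (sum(a & inDB) + sum(inDA & b)) / (sum(a) + sum(b))
}

bruteMasd <- function(A, B) {
    pa <- maskCenters(A); pb <- maskCenters(B)
    dAB <- apply(pa, 1, function(p) sqrt(min(colSums((t(pb) - p)^2))))
    dBA <- apply(pb, 1, function(p) sqrt(min(colSums((t(pa) - p)^2))))
    (sum(dAB) + sum(dBA)) / (nrow(pa) + nrow(pb))
}

# brute-force flood-fill component count/sizes (26- or 6-connectivity)
bruteComponents <- function(arr, connectivity = 26) {
    d <- dim(arr)
    lab <- array(0L, d)
    nxt <- 0L
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[rowSums(offs != 0) > 0, ]
    if (connectivity == 6) offs <- offs[rowSums(offs != 0) == 1, ]
    idxAll <- which(arr)
    for (s in idxAll) {
        if (lab[s] != 0L) next
        nxt <- nxt + 1L
        queue <- s
        lab[s] <- nxt
        while (length(queue)) {
            p <- queue[[1]]; queue <- queue[-1]
            p0 <- p - 1L
            pi <- p0 %% d[1]; pj <- (p0 %/% d[1]) %% d[2]
            pk <- p0 %/% (d[1] * d[2])
            for (r in seq_len(nrow(offs))) {
                i <- pi + offs[r, 1]; j <- pj + offs[r, 2]
                k <- pk + offs[r, 3]
                if (i < 0 || i >= d[1] || j < 0 || j >= d[2] ||
                    k < 0 || k >= d[3]) next
                q <- i + d[1] * (j + d[2] * k) + 1L
                if (arr[q] && lab[q] == 0L) {
                    lab[q] <- nxt
                    queue <- c(queue, q)
                }
            }
        }
    }
    tabulate(lab[lab > 0])
}

# small intensity volume with reproducible content
toyVolume <- function(dims = c(6, 7, 8), spacingUm = c(10, 10, 10),
                      seed = 1) {
    set.seed(seed)
    ImageVolume(array(rnorm(prod(dims)), dims), spacingUm,
                origin = spacingUm / 2)
}

# landmark set related by a known rigid motion
rigidPair <- function(n = 8, angles = c(pi / 6, 0, 0),
                      translation = c(10, 20, 0), seed = 2) {
    set.seed(seed)
    X <- matrix(rnorm(3 * n, sd = 200), n, 3)
    R <- micromri:::rotationMatrix3(angles)
    LandmarkSet(X, X %*% t(R) +
                matrix(translation, n, 3, byrow = TRUE))
}
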