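#' Landmark-based transform fitting
#'
#' Fits a spatial transform mapping the fixed landmarks onto the moving
#' landmarks (the pull-back direction used for resampling: target/fixed
#' world coordinates in, moving world coordinates out).
#'
#' Rigid and similarity modes use the closed-form least-squares orthogonal
#' (Procrustes/Umeyama) fit; affine uses linear least squares; the
#' thin-plate spline interpolates the pairs exactly at `lambda = 0`
#' (kernel `U(r) = r` in 3D, `U(r) = r^2 log r` in 2D).
#'
#' @param landmarks a [LandmarkSet] (or a list with `fixed`/`moving`
#'   matrices).
#' @param kind `"rigid"`, `"similarity"`, `"affine"` or `"tps"`.
#' @param lambda thin-plate regularization; 0 (default) interpolates
#'   exactly, positive values smooth noisy landmarks.
#' @param dimension 2 or 3; default taken from the point columns.
#' @return A `SpatialTransform`.
#' @examples
#' th <- pi / 6
#' R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
#' fx <- matrix(rnorm(15, sd = 100), 5, 3)
#' lm <- LandmarkSet(fx, fx %*% t(R) + rep(c(10, 20, 0), each = 5))
#' fitLandmarkTransform(lm, "rigid")
#' @export
fitLandmarkTransform <- function(landmarks, kind = c("tps", "rigid",
                                 "similarity", "affine"), lambda = 0,
                                 dimension = NULL) {
    kind <- match.arg(kind)
    X <- if (is(landmarks, "LandmarkSet")) fixedPoints(landmarks)
         else asPointMatrix(landmarks$fixed)
    Y <- if (is(landmarks, "LandmarkSet")) movingPoints(landmarks)
         else asPointMatrix(landmarks$moving)
    d <- if (is.null(dimension)) ncol(X) else as.integer(dimension)
    X <- X[, seq_len(d), drop = FALSE]
    Y <- Y[, seq_len(d), drop = FALSE]
    n <- nrow(X)
    minN <- switch(kind, rigid = d, similarity = d,
                   affine = d + 1L, tps = d + 2L)
    if (n < minN)
        stop(kind, " fit needs at least ", minN, " landmark pairs in ",
             d, "D, got ", n)
    checkDegeneracy(X, kind, d)
    if (kind %in% c("rigid", "similarity")) {
        fit <- umeyama(X, Y, with_scale = kind == "similarity")
        return(newLinearOrTps(kind, d, fit$A, fit$t))
    }
    if (kind == "affine") {
        Xh <- cbind(X, 1)
        beta <- qr.solve(Xh, Y)            # (d+1) x d
        A <- t(beta[seq_len(d), , drop = FALSE])
        return(newLinearOrTps("affine", d, A, as.numeric(beta[d + 1L, ])))
    }
    # thin-plate spline
    K <- tpsKernelMatrix(X, X, d)
    if (lambda > 0) K <- K + lambda * diag(n)
    P <- cbind(1, X)
    L <- rbind(cbind(K, P), cbind(t(P), matrix(0, d + 1L, d + 1L)))
    rhs <- rbind(Y, matrix(0, d + 1L, d))
    sol <- tryCatch(solve(L, rhs), error = function(e)
        stop("degenerate landmark configuration for TPS (",
             conditionMessage(e), ")"))
    W <- sol[seq_len(n), , drop = FALSE]
    aff <- sol[n + seq_len(d + 1L), , drop = FALSE]
    newLinearOrTps("tps", d, t(aff[-1L, , drop = FALSE]),
                   as.numeric(aff[1L, ]), ctrl = X, W = W)
}

checkDegeneracy <- function(X, kind, d) {
    Xc <- sweep(X, 2, colMeans(X))
    r <- qr(Xc, tol = 1e-10)$rank
    if (kind %in% c("affine", "tps") && r < d)
        stop("degenerate landmarks: points are ",
             if (d == 3L && r <= 1L) "collinear" else
             if (d == 3L) "coplanar" else "collinear",
             "; ", kind, " fit in ", d, "D needs full spatial rank")
    if (kind %in% c("rigid", "similarity") && r < d - 1L)
        stop("degenerate landmarks: points are collinear; ", kind,
             " rotation is not determined")
    invisible(TRUE)
}

umeyama <- function(X, Y, with_scale = FALSE) {
    mx <- colMeans(X); my <- colMeans(Y)
    Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
    S <- crossprod(Yc, Xc) / nrow(X)
    sv <- svd(S)
    d <- ncol(X)
    Dfix <- diag(d)
    if (det(sv$u) * det(sv$v) < 0) Dfix[d, d] <- -1
    R <- sv$u %*% Dfix %*% t(sv$v)
    s <- 1
    if (with_scale) {
        varX <- mean(rowSums(Xc^2))
        s <- sum(sv$d * diag(Dfix)) / varX
    }
    A <- s * R
    list(A = A, t = as.numeric(my - A %*% mx))
}

tpsKernel <- function(r, d) {
    if (d == 3L) return(r)
    u <- r^2 * log(r)
    u[r == 0] <- 0
    u
}

tpsKernelMatrix <- function(P, C, d) {
    r2 <- outer(rowSums(P^2), rep(1, nrow(C))) +
          outer(rep(1, nrow(P)), rowSums(C^2)) - 2 * P %*% t(C)
    tpsKernel(sqrt(pmax(r2, 0)), d)
}

newLinearOrTps <- function(kind, d, A, t, ctrl = NULL, W = NULL) {
    new("SpatialTransform", kind = kind, dimension = as.integer(d),
        A = A, t = t,
        ctrl = if (is.null(ctrl)) matrix(0, 0, d) else ctrl,
        W = if (is.null(W)) matrix(0, 0, d) else W,
        chain = list())
}

newComposite <- function(chain) {
    new("SpatialTransform", kind = "composite",
        dimension = chain[[1]]@dimension,
        A = matrix(0, 0, 0), t = numeric(), ctrl = matrix(0, 0, 0),
        W = matrix(0, 0, 0), chain = chain)
}

#' Identity / explicit transforms
#'
#' `identityTransform` builds the identity; `rigidTransform` builds a rigid
#' (or, with `scale != 1`, similarity) transform from Euler angles
#' (radians, applied about the z, y, x axes in that order) and a
#' translation in um.
#'
#' @param dimension 2 or 3.
#' @param angles rotation angles in radians; length 1 (2D) or 3 (3D).
#' @param translation translation vector, um (z, y, x order).
#' @param scale isotropic scale factor.
#' @return A `SpatialTransform`.
#' @export
identityTransform <- function(dimension = 3L) {
    d <- as.integer(dimension)
    newLinearOrTps("rigid", d, diag(d), rep(0, d))
}

#' @rdname identityTransform
#' @export
rigidTransform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                           scale = 1, dimension = 3L) {
    d <- as.integer(dimension)
    if (d == 2L) {
        th <- angles[1]
        R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
        translation <- translation[seq_len(2)]
    } else {
        R <- rotationMatrix3(angles)
    }
    newLinearOrTps(if (scale == 1) "rigid" else "similarity", d, scale * R,
                   as.numeric(translation))
}

# rotation about axes: coordinates ordered (z, y, x); angles[1] rotates the
# (y, x) plane about z, angles[2] the (z, x) plane, angles[3] the (z, y)
# plane
rotationMatrix3 <- function(angles) {
    rot <- function(i, j, th) {
        R <- diag(3)
        R[i, i] <- cos(th); R[j, j] <- cos(th)
        R[i, j] <- -sin(th); R[j, i] <- sin(th)
        R
    }
    rot(2, 3, angles[1]) %*% rot(1, 3, angles[2]) %*% rot(1, 2, angles[3])
}

#' Apply a transform to points
#'
#' Forward mapping of an N x d matrix of world coordinates (um).
#'
#' @param transform a `SpatialTransform`.
#' @param points N x d matrix (or length-d vector), world um.
#' @return N x d matrix of mapped coordinates.
#' @export
transformPoints <- function(transform, points) {
    p <- asPointMatrix(points)
    if (transform@kind == "composite") {
        for (tr in transform@chain) p <- transformPoints(tr, p)
        return(p)
    }
    d <- transform@dimension
    if (ncol(p) != d)
        stop("point dimensionality ", ncol(p),
             " does not match transform dimensionality ", d)
    out <- p %*% t(transform@A) +
        matrix(transform@t, nrow(p), d, byrow = TRUE)
    if (transform@kind == "tps" && nrow(transform@ctrl) > 0) {
        U <- tpsKernelMatrix(p, transform@ctrl, d)
        out <- out + U %*% transform@W
    }
    out
}

#' Compose transforms
#'
#' Returns a transform equivalent to applying the list elements in order
#' (first element first). Chains of rigid/similarity/affine transforms
#' collapse to a single closed-form transform of the weakest class in the
#' chain; chains containing a thin-plate spline are returned as a
#' composite point-mapper.
#'
#' @param transforms list of `SpatialTransform`s.
#' @return A `SpatialTransform`.
#' @export
composeTransforms <- function(transforms) {
    if (length(transforms) == 0L) stop("cannot compose an empty list")
    if (length(transforms) == 1L) return(transforms[[1]])
    flat <- list()
    for (tr in transforms)
        flat <- c(flat, if (tr@kind == "composite") tr@chain else list(tr))
    kinds <- vapply(flat, slot, "", "kind")
    if (any(kinds == "tps")) return(newComposite(flat))
    d <- flat[[1]]@dimension
    A <- diag(d); t <- rep(0, d)
    for (tr in flat) {            # x -> A_tr (A x + t) + t_tr
        A <- tr@A %*% A
        t <- as.numeric(tr@A %*% t) + tr@t
    }
    kind <- if (all(kinds == "rigid")) "rigid"
            else if (all(kinds %in% c("rigid", "similarity"))) "similarity"
            else "affine"
    newLinearOrTps(kind, d, A, t)
}

#' Invert a transform
#'
#' Rigid/similarity/affine transforms are inverted in closed form. A
#' thin-plate spline has no closed-form inverse; it is re-fit with the
#' landmark roles swapped (exact at the defining landmarks, approximate
#' elsewhere), which is the standard pull-back trick for resampling.
#'
#' @param transform a `SpatialTransform`.
#' @param lambda regularization for the swapped-role TPS refit.
#' @return A `SpatialTransform` mapping in the opposite direction.
#' @export
invertTransform <- function(transform, lambda = 0) {
    if (transform@kind == "composite")
        return(newComposite(rev(lapply(transform@chain, invertTransform))))
    d <- transform@dimension
    if (transform@kind != "tps") {
        Ai <- solve(transform@A)
        return(newLinearOrTps(transform@kind, d, Ai,
                              as.numeric(-Ai %*% transform@t)))
    }
    fwd <- transformPoints(transform, transform@ctrl)
    fitLandmarkTransform(list(fixed = fwd, moving = transform@ctrl),
                         kind = "tps", lambda = lambda, dimension = d)
}

#' Root-mean-square landmark error
#'
#' `sqrt(mean(||a_i - b_i||^2))` over paired points, in um.
#'
#' @param pointsA,pointsB N x 3 matrices of corresponding world points, or
#'   `pointsA` a [LandmarkSet] (then `pointsB` is ignored and fixed vs
#'   moving points are compared).
#' @return RMSE in um.
#' @examples
#' landmarkRMSE(matrix(c(0, 0, 0), 1), matrix(c(3, 4, 0), 1)) # 5
#' @export
landmarkRMSE <- function(pointsA, pointsB = NULL) {
    if (is(pointsA, "LandmarkSet")) {
        pointsB <- movingPoints(pointsA)
        pointsA <- fixedPoints(pointsA)
    }
    a <- asPointMatrix(pointsA); b <- asPointMatrix(pointsB)
    if (nrow(a) != nrow(b)) stop("point counts differ")
    if (nrow(a) == 0L) stop("RMSE of an empty point set is undefined")
    sqrt(mean(rowSums((a - b)^2)))
}

#' Inter-rater registration reproducibility
#'
#' Pushes a regular grid of coordinates (rows x columns per slice, in the
#' un-resliced frame) through two raters' transform chains and reports the
#' RMSE between the mapped positions over a random subsample, emulating an
#' inter-rater evaluation on a 50 x 50 per-slice coordinate grid.
#'
#' @param gridVolume [ImageVolume] defining the grid domain (its slices are
#'   sampled `rows` x `cols`).
#' @param chain1,chain2 `SpatialTransform`s (possibly composite).
#' @param rows,cols grid resolution per slice.
#' @param sampleN number of coordinates to sample (all, if larger than the
#'   grid).
#' @param seed RNG seed for the subsample.
#' @return list with `rmse` (um), `n`, and the sampled displacements.
#' @export
interraterRMSE <- function(gridVolume, chain1, chain2, rows = 50, cols = 50,
                           sampleN = 2500, seed = 1) {
    d <- dim(voxelData(gridVolume))
    zi <- seq_len(d[1]) - 1
    yi <- seq(0, d[2] - 1, length.out = rows)
    xi <- seq(0, d[3] - 1, length.out = cols)
    idx <- as.matrix(expand.grid(z = zi, y = yi, x = xi))
    pts <- indexToWorld(gridVolume, idx)
    take <- if (sampleN >= nrow(pts)) seq_len(nrow(pts))
            else sort(withSeed(seed, sample.int(nrow(pts), sampleN)))
    p1 <- transformPoints(chain1, pts[take, , drop = FALSE])
    p2 <- transformPoints(chain2, pts[take, , drop = FALSE])
    list(rmse = landmarkRMSE(p1, p2), n = length(take),
         displacement = sqrt(rowSums((p1 - p2)^2)))
}
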