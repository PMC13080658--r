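#' Longitudinal rigid registration (rotation + translation)
#'
#' Registers a follow-up volume to the reference timepoint with a rigid
#' model (no scaling), as used when chaining each session back to the
#' first. With landmarks the fit is the closed-form orthogonal
#' least-squares solution; without, a multi-start local search maximizes
#' the Pearson correlation between the reference and the resampled moving
#' volume. The returned transform maps reference world coordinates to
#' moving world coordinates (pull-back), so
#' `resampleVolume(moving, transform, reference)` aligns the follow-up
#' onto the reference grid.
#'
#' @param moving follow-up [ImageVolume].
#' @param reference reference [ImageVolume].
#' @param landmarks optional [LandmarkSet] (fixed = reference frame,
#'   moving = follow-up frame).
#' @param maxAngle,maxShift search bounds (radians / um) for the intensity
#'   mode.
#' @param nStarts number of rotation starts per axis in the intensity
#'   mode.
#' @return list with `transform`, `correlation` (intensity mode),
#'   `converged`, and `diagnostics`.
#' @export
registerLongitudinal <- function(moving, reference, landmarks = NULL,
                                 maxAngle = 0.2, maxShift = 100,
                                 nStarts = 3) {
    if (!is.null(landmarks)) {
        tr <- fitLandmarkTransform(landmarks, kind = "rigid")
        res <- transformPoints(tr, fixedPoints(landmarks)) -
            movingPoints(landmarks)
        return(list(transform = tr, correlation = NA_real_,
                    converged = TRUE,
                    diagnostics = list(mode = "landmark",
                                       rmse = sqrt(mean(rowSums(res^2))))))
    }
    refArr <- voxelData(reference)
    refMean <- mean(refArr); refSd <- sd(as.numeric(refArr))
    if (refSd == 0) stop("reference volume is constant; ",
                         "intensity registration is undefined")
    objective <- function(par) {
        tr <- rigidTransform(par[1:3], par[4:6])
        res <- resampleVolume(moving, tr, reference,
                              interpolation = "linear", fill = NA)
        v <- voxelData(res)
        ok <- !is.na(v)
        if (mean(ok) < 0.5) return(1e6)  # < 50% overlap: reject
        -suppressWarnings(stats::cor(v[ok], refArr[ok]))
    }
    starts <- as.matrix(expand.grid(
        a1 = seq(-maxAngle, maxAngle, length.out = nStarts), a2 = 0,
        a3 = 0, t1 = 0, t2 = 0, t3 = 0))
    pscale <- c(rep(max(maxAngle / 2, 0.02), 3),
                rep(max(maxShift / 2, 10), 3))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
        fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                            control = list(maxit = 600, reltol = 1e-10,
                                           parscale = pscale))
        if (is.null(best) || fit$value < best$value - 1e-12 ||
            (abs(fit$value - best$value) <= 1e-12 &&
             sum(fit$par^2) < sum(best$par^2)))  # deterministic tie-break
            best <- fit
    }
    if (best$value >= 1e6)
        stop("intensity registration failed: no pose with >= 50% overlap ",
             "found within the search bounds")
    tr <- rigidTransform(best$par[1:3], best$par[4:6])
    list(transform = tr, correlation = -best$value,
         converged = best$convergence == 0,
         diagnostics = list(mode = "intensity", par = best$par,
                            optim = best$convergence))
}
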