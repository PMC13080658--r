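# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards: generators are pure functions of
# (params, seed) and never touch global RNG state.
withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

# separable Gaussian smoothing of a (z,y,x) array; sigma in world um per
# axis (recycled), kernel truncated at 3 sigma; zero-padded borders
gaussianSmooth3 <- function(arr, sigma_um, spacing) {
    sigma_um <- rep(sigma_um, length.out = 3)
    d <- dim(arr)
    for (ax in 1:3) {
        s_vox <- sigma_um[ax] / spacing[ax]
        if (s_vox <= 0) next
        half <- max(1L, ceiling(3 * s_vox))
        k <- exp(-0.5 * ((-half:half) / s_vox)^2)
        k <- k / sum(k)
        out <- array(0, d)
        for (o in -half:half) {
            w <- k[o + half + 1L]
            src <- pmin(pmax(seq_len(d[ax]) + o, 1L), d[ax])
            # clamped (replicate) borders keep tube interiors at full value
            out <- out + w * switch(ax,
                arr[src, , , drop = FALSE],
                arr[, src, , drop = FALSE],
                arr[, , src, drop = FALSE])
        }
        arr <- out
    }
    arr
}

stopIfNot3D <- function(volume) {
    if (length(dim(voxelData(volume))) != 3L)
        stop("expected a 3D volume")
    invisible(volume)
}

# shared world-metric distance map: per-voxel Euclidean distance (um) from
# every voxel center to the nearest TRUE voxel center; Inf if none
distanceToMask <- function(mask) {
    arr <- voxelData(mask)
    d <- dim(arr)
    sqrt(array(cpp_edt2(as.logical(arr), as.integer(d),
                        as.numeric(spacing(mask))), d))
}
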