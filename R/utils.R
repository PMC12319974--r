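# Internal numerical helpers shared across modules.

# Separable Gaussian smoothing of a 3D array (sigma in voxels, per axis).
# Kernel truncated at 4 sigma; edges renormalized (kernel mass restricted
# to the grid), so constants are preserved exactly.
gaussianSmooth3d <- function(arr, sigma) {
    stopifnot(length(dim(arr)) == 3L)
    if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
    out <- arr
    for (ax in 1:3) {
        s <- sigma[ax]
        if (s <= 0) next
        n <- dim(out)[ax]
        half <- max(1L, ceiling(4 * s))
        k <- stats::dnorm(seq(-half, half), sd = s)
        K <- matrix(0, n, n)
        for (i in seq_len(n)) {
            j <- (i - half):(i + half)
            ok <- j >= 1L & j <= n
            K[i, j[ok]] <- k[ok] / sum(k[ok])
        }
        perm <- c(ax, setdiff(1:3, ax))
        x <- aperm(out, perm)
        d <- dim(x)
        x <- K %*% matrix(x, nrow = d[1])
        dim(x) <- d
        out <- aperm(x, order(perm))
    }
    out
}

# Per-frame 3D Gaussian smoothing of a 4D array.
gaussianSmooth4d <- function(arr, sigma) {
    stopifnot(length(dim(arr)) == 4L)
    for (t in seq_len(dim(arr)[4]))
        arr[, , , t] <- gaussianSmooth3d(arr[, , , t, drop = TRUE], sigma)
    arr
}

# Draw n rows from MVN(0, C) via Cholesky (with a PSD jitter fallback).
rmvn <- function(n, C) {
    K <- nrow(C)
    L <- tryCatch(chol(C), error = function(e) chol(C + diag(1e-10, K)))
    matrix(stats::rnorm(n * K), n, K) %*% L
}

# Zero-phase second-order Butterworth band-pass/stop of the columns of a
# matrix (frames x series). Wrapper around signal::butter + filtfilt.
filterColumns <- function(x, w, type) {
    bf <- signal::butter(2, w, type = type)
    apply(x, 2L, function(col) signal::filtfilt(bf, col))
}

# Flatten a 4D array to voxels x time for a logical 3D mask.
maskMatrix <- function(arr4d, mask) {
    d <- dim(arr4d)
    m <- matrix(arr4d, prod(d[1:3]), d[4])
    m[as.vector(mask), , drop = FALSE]
}

# Pearson correlation matrix of the rows of a nodes x time matrix,
# returning NA rows/cols for constant nodes instead of propagating errors.
rowCorrelation <- function(x) {
    sds <- apply(x, 1L, stats::sd)
    ok <- is.finite(sds) & sds > 0
    R <- matrix(NA_real_, nrow(x), nrow(x))
    if (any(ok))
        R[ok, ok] <- stats::cor(t(x[ok, , drop = FALSE]))
    diag(R)[ok] <- 1
    attr(R, "flagged") <- which(!ok)
    R
}
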