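toyMasks <- function(grid = c(6L, 6L, 6L)) {
    g <- array(TRUE, grid)
    wm <- array(FALSE, grid); wm[1:2, , ] <- TRUE
    csf <- array(FALSE, grid); csf[5:6, , ] <- TRUE
    list(global = g, wm = wm, csf = csf)
}

test_that("the confound matrix has exactly 36 columns with the documented structure", {
    grid <- c(6L, 6L, 6L); nT <- 12L
    dat <- array(rnorm(prod(grid) * nT, 100), c(grid, nT))
    p <- matrix(0, nT, 6)
    p[, 1] <- seq_len(nT)  # x(t) = t
    cf <- buildConfounds(dat, toyMasks(grid), motionTrace(p, tr = 2))
    expect_equal(ncol(cf), 36L)
    expect_equal(unname(cf[, "d_trans_x"]), c(0, rep(1, nT - 1)))
    expect_equal(unname(cf[, "trans_x_sq"]), (seq_len(nT))^2)
    expect_equal(unname(cf[, "d_trans_x_sq"]), c(0, rep(1, nT - 1))^2)
    # constant data + zero motion: all derivative columns vanish
    datC <- array(7, c(grid, nT))
    cf0 <- buildConfounds(datC, toyMasks(grid),
                          motionTrace(matrix(0, nT, 6), tr = 2))
    expect_true(all(cf0[, grepl("^d_", colnames(cf0))] == 0))
    expect_true(all(cf0[, "global_signal"] == 7))
    badMasks <- toyMasks(grid); badMasks$csf[] <- FALSE
    expect_error(buildConfounds(dat, badMasks,
                                motionTrace(matrix(0, nT, 6), tr = 2)),
                 "empty tissue mask")
})

test_that("band-pass keeps the BOLD band and strongly attenuates out-of-band signal", {
    tr <- 1.761; n <- 500
    t <- (seq_len(n) - 1) * tr
    hiF <- sin(2 * pi * 0.2 * t)    # above the 0.08 Hz upper edge
    inB <- sin(2 * pi * 0.03 * t)   # inside the pass band
    X <- rbind(hiF, inB)
    out <- cleanTimeseries(X, confounds = NULL, tr = tr)
    mid <- 60:(n - 60)
    attn <- sd(out[1, mid] - mean(out[1, mid])) / sd(hiF[mid])
    expect_lt(attn, 0.10)   # > 90% attenuation
    keep <- sd(out[2, mid] - mean(out[2, mid])) / sd(inB[mid])
    expect_gt(keep, 0.85)
    expect_error(cleanTimeseries(X, NULL, band = c(0.009, 0.4), tr = tr),
                 "Nyquist")
})

test_that("residuals are orthogonal to the filtered confounds", {
    set.seed(8)
    tr <- 1.761; n <- 300; V <- 30
    conf <- matrix(rnorm(n * 4), n, 4)
    X <- matrix(rnorm(V * n), V, n)
    X[1, ] <- X[1, ] + 3 * conf[, 2]  # inject a confound into one voxel
    cleaned <- cleanTimeseries(X, conf, tr = tr)
    w <- c(0.009, 0.08) / (1 / (2 * tr))
    bf <- signal::butter(2, w, type = "pass")
    confF <- apply(conf, 2, function(col) signal::filtfilt(bf, col))
    cen <- cleaned - rowMeans(cleaned)
    dots <- abs(cen %*% confF)
    norms <- outer(sqrt(rowSums(cen^2)),
                   sqrt(colSums(confF^2)))
    expect_lt(max(dots / norms), 1e-8)
    expect_lt(abs(cor(cleaned[1, ], confF[, 2])), 0.01)
})

test_that("censored frames are interpolated for filtering and re-excluded for correlation", {
    set.seed(3)
    n <- 200; tr <- 1.761
    fd <- rep(0, n); fd[c(50, 51, 120)] <- 1
    mk <- censorFrames(fd, 0.3)
    X <- matrix(rnorm(5 * n), 5, n)
    cleaned <- cleanTimeseries(X, NULL, censorHi = mk, tr = tr)
    # corrupting the censored frames must not change the final connectivity
    X2 <- X
    X2[, !retainedFrames(mk)] <- 100
    cleaned2 <- cleanTimeseries(X2, NULL, censorHi = mk, tr = tr)
    cm1 <- connectivity(cleaned, censorLo = mk)
    cm2 <- connectivity(cleaned2, censorLo = mk)
    expect_equal(connValues(cm1), connValues(cm2), tolerance = 1e-12)
    expect_error(cleanTimeseries(X, NULL,
                                 censorHi = censorFrames(rep(1, n), 0.3),
                                 tr = tr))
})

test_that("connectivity contracts: duplicates, symmetry, affine invariance, flagged constants", {
    set.seed(5)
    ts <- matrix(rnorm(6 * 80), 6, 80)
    ts[2, ] <- ts[1, ]
    ts[5, ] <- 4            # constant node
    cm <- connectivity(ts)
    V <- connValues(cm)
    expect_equal(V[1, 2], 1)
    expect_true(all(is.na(V[5, -5])))
    expect_equal(attr(cm, "flagged"), 5L)
    expect_equal(V, t(V))
    expect_equal(diag(V)[-5], rep(1, 5))
    # affine rescaling of a node leaves correlations unchanged
    ts2 <- ts
    ts2[3, ] <- -2.5 * ts[3, ] + 7
    V2 <- connValues(connectivity(ts2))
    expect_equal(abs(V2[3, 1]), abs(V[3, 1]), tolerance = 1e-12)
    expect_error(connectivity(ts[, 1, drop = FALSE]), "retained frames")
})

test_that("parcel connectivity recovers the generator's network structure at scale", {
    grid <- c(10L, 10L, 10L)
    nm <- networkModel(grid, nNetworks = 4, parcelEdge = 3,
                       deltaR2sAmplitude = 0.3, idioFraction = 0)
    acq <- acquisitionParams(30, tr = 1.761, nFrames = 20000,
                             gridShape = grid)
    run <- simulateRun(acq, tissuePreset("adult"), network = nm,
                       noise = quietNoise(), seed = 19, arTimescale = 0.01)
    nts <- nodeTimeseries(
        magnitudeData(run$series, 1), run$truth$parcels)
    expect_equal(nts$kind, "parcel")
    cm <- connectivity(nts$series)
    # with no idiosyncratic component, parcel series carry exactly their
    # network's correlation structure (up to the small-signal linearization)
    netOfParcel <- run$truth$parcelNetwork
    truthPar <- run$truth$trueConnectivity[netOfParcel, netOfParcel]
    diag(truthPar) <- 1
    expect_lt(max(abs(connValues(cm) - truthPar)), 0.02)
})

test_that("confound regression moves connectivity toward the ground truth", {
    # enough networks and voxel-level variance that the global-signal
    # regressor does not soak up the neural structure itself
    grid <- c(12L, 12L, 12L)
    nm <- networkModel(grid, nNetworks = 6, parcelEdge = 3,
                       deltaR2sAmplitude = 0.4, idioFraction = 0.5)
    acq <- acquisitionParams(30, tr = 1.761, nFrames = 600,
                             gridShape = grid)
    run <- simulateRun(acq, tissuePreset("adult"), network = nm,
                       noise = noiseModel(thermalSigma = 0,
                                          respAmplitude = 0.15,
                                          driftAmplitude = 0.3,
                                          motionSpikeProb = 0), seed = 23)
    mask <- run$truth$mask
    dat <- magnitudeData(run$series, 1)
    cf <- buildConfounds(dat, syntheticTissueMasks(mask), run$motion)
    cleaned <- cleanTimeseries(dat, cf, tr = 1.761)
    netOfParcel <- run$truth$parcelNetwork
    truthPar <- run$truth$trueConnectivity[netOfParcel, netOfParcel]
    diag(truthPar) <- 1
    off <- upper.tri(truthPar)
    simTo <- function(d) {
        V <- connValues(connectivity(nodeTimeseries(d,
                                                    run$truth$parcels)$series))
        cor(V[off], truthPar[off])
    }
    expect_gt(simTo(cleaned), simTo(dat))
})
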