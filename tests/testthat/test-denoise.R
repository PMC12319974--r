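test_that("noise sigma is recovered from noise frames within 2%", {
    grid <- c(12L, 12L, 12L)
    acq <- acquisitionParams(c(20, 50), tr = 2, nFrames = 5,
                             nNoiseFrames = 3, gridShape = grid)
    run <- simulateRun(acq, tissuePreset("adult"),
                       noise = noiseModel(thermalSigma = 3), seed = 8)
    est <- estimateNoiseSigma(run$series)
    expect_equal(noiseSource(est), "noise_frames")
    expect_lt(abs(noiseSigma(est) - 3) / 3, 0.02)
})

test_that("theoretical fallback records the 1/sqrt(2) factor", {
    run <- noisyRun()
    est <- estimateNoiseSigma(run$series, method = "theoretical")
    expect_equal(noiseSource(est), "theoretical")
    expect_equal(est@theoreticalFactor, 1 / sqrt(2))
    expect_gt(noiseSigma(est), 0)
})

test_that("degenerate noise frames raise an error", {
    grid <- c(8L, 8L, 8L)
    acq <- acquisitionParams(c(20, 50), tr = 2, nFrames = 4,
                             nNoiseFrames = 2, gridShape = grid)
    run <- simulateRun(acq, tissuePreset("adult"),
                       noise = quietNoise(0), seed = 1)
    expect_error(estimateNoiseSigma(run$series), "degenerate")
    noNoise <- multiEchoSeries(magnitudeData(run$series, 1),
                               echoTimes = 20, tr = 2)
    expect_error(estimateNoiseSigma(noNoise), "no noise frames")
})

test_that("singular value edge matches the asymptotic Marchenko-Pastur edge", {
    cases <- list(c(100, 100), c(125, 50), c(343, 60))
    for (mn in cases) {
        tau <- noiseSingularValueEdge(mn[1], mn[2], sigma = 1,
                                      mcDraws = 5, seed = 4)
        edge <- sqrt(2) * (sqrt(mn[1]) + sqrt(mn[2]))
        expect_lt(abs(tau - edge) / edge, 0.05)
    }
    expect_equal(noiseSingularValueEdge(50, 50, sigma = 0), 0)
    t1 <- noiseSingularValueEdge(60, 40, sigma = 1.5, mcDraws = 3, seed = 2)
    t2 <- noiseSingularValueEdge(60, 40, sigma = 3.0, mcDraws = 3, seed = 2)
    expect_equal(t2, 2 * t1, tolerance = 1e-12)
    expect_error(noiseSingularValueEdge(50, 50, 1, mcDraws = 0), "mcDraws")
})

test_that("hard thresholding preserves strong low-rank structure and is identity at tau=0", {
    set.seed(6)
    u <- rnorm(80); v <- rnorm(30)
    X <- 50 * u %o% v
    D <- denoisePatch(X, tau = 1)
    expect_lt(norm(D - X, "F") / norm(X, "F"), 1e-10)
    expect_equal(attr(D, "nRetained"), 1L)
    expect_identical(denoisePatch(X, 0)[, ], X)
    # complex input round-trips too
    Z <- (u + 1i * rev(u)) %o% (v - 1i * v) * 10
    expect_lt(frob(denoisePatch(Z, tau = 1) - Z) / frob(Z), 1e-10)
})

test_that("pure-noise patches lose nearly all Frobenius norm at the edge threshold", {
    m <- 125; n <- 50; sigma <- 1
    tau <- sqrt(2) * sigma * (sqrt(m) + sqrt(n))  # asymptotic noise edge
    set.seed(21)
    ratios <- replicate(20, {
        X <- matrix(complex(real = rnorm(m * n, 0, sigma),
                            imaginary = rnorm(m * n, 0, sigma)), m, n)
        frob(denoisePatch(X, tau)) / frob(X)
    })
    expect_lt(mean(ratios), 0.15)
})

test_that("denoising a noiseless run is (numerically) the identity", {
    run <- noiselessTwin()
    tiny <- new("NoiseEstimate", sigma = 1e-9, source = "noise_frames",
                theoreticalFactor = NA_real_)
    den <- nordicDenoiseRun(run$series, noise = tiny, patchEdge = 7,
                            mcDraws = 2, seed = 5)
    for (e in c(1L, 3L, 5L)) {
        a <- magnitudeData(run$series, e)
        b <- magnitudeData(den, e)
        expect_lt(max(abs(a - b)) / max(a), 1e-8)
    }
})

test_that("denoising raises tSNR substantially on thermal-noise-limited data", {
    run <- noisyRun()
    den <- denoisedRun()
    mask <- run$truth$mask
    for (e in c(2L)) {
        raw <- tsnrMap(magnitudeData(run$series, e)[, , , 1:40], mask = mask)
        dn <- tsnrMap(magnitudeData(den, e)[, , , 1:40], mask = mask)
        mRaw <- mean(tsnrValues(raw)[validVoxels(raw)])
        mDen <- mean(tsnrValues(dn)[validVoxels(dn)])
        expect_gt(mDen, mRaw)
        expect_gt((mDen - mRaw) / mRaw, 0.10)
    }
})

test_that("denoising removes variance where there is only noise and preserves means", {
    run <- noisyRun()
    den <- denoisedRun()
    bg <- !run$truth$mask
    e <- 1L
    raw <- magnitudeData(run$series, e)[, , , 1:40]
    dn <- magnitudeData(den, e)[, , , 1:40]
    varRatio <- mean(apply(matrix(dn, 14^3, 40)[as.vector(bg), ], 1, var)) /
        mean(apply(matrix(raw, 14^3, 40)[as.vector(bg), ], 1, var))
    expect_lt(varRatio, 0.25)
    # in-mask temporal means move by < 1% of S0
    s0 <- run$truth$s0[run$truth$mask]
    dMean <- abs(rowMeans(echoMatrix(den, e, run$truth$mask)) -
                 rowMeans(echoMatrix(run$series, e, run$truth$mask)))
    expect_lt(mean(dMean / s0), 0.01)
})

test_that("denoising adds less than half a voxel of smoothing beyond the signal's own", {
    run <- noisyRun()
    den <- denoisedRun()
    clean <- noiselessTwin()
    mask <- run$truth$mask
    dn <- estimateFwhm(magnitudeData(den, 2)[, , , 1:40],
                       mask = mask, voxelSize = 2)
    truthF <- estimateFwhm(magnitudeData(clean$series, 2)[, , , 1:40],
                           mask = mask, voxelSize = 2)
    # against the noiseless signal: whatever smoothness the denoised data
    # shows beyond this is smoothing introduced by the algorithm
    expect_lt(dn$fwhm - truthF$fwhm, 0.5 * 2)  # < 0.5 voxels of 2 mm
})

test_that("the smoothness guard holds at moderate noise too", {
    run <- simulateRun(smallAcq(), tissuePreset("adult"),
                       noise = noiseModel(thermalSigma = 1.5,
                                          respAmplitude = 0,
                                          driftAmplitude = 0,
                                          motionSpikeProb = 0),
                       seed = 57)
    clean <- simulateRun(smallAcq(), tissuePreset("adult"),
                         noise = quietNoise(), seed = 57)
    den <- nordicDenoiseRun(run$series, patchEdge = 7, mcDraws = 3, seed = 8)
    mask <- run$truth$mask
    dn <- estimateFwhm(magnitudeData(den, 2)[, , , 1:40],
                       mask = mask, voxelSize = 2)
    truthF <- estimateFwhm(magnitudeData(clean$series, 2)[, , , 1:40],
                           mask = mask, voxelSize = 2)
    expect_lt(dn$fwhm - truthF$fwhm, 0.5 * 2)
})

test_that("non-overlapping stride tiles every voxel exactly once", {
    s <- mebold:::patchStarts(12L, 4L, 4L)
    expect_equal(s, c(1L, 5L, 9L))
    cover <- integer(12)
    for (st in s) cover[st:(st + 3L)] <- cover[st:(st + 3L)] + 1L
    expect_true(all(cover == 1L))
    # trailing patch is pulled flush when stride does not divide evenly
    s2 <- mebold:::patchStarts(13L, 4L, 4L)
    expect_equal(s2[length(s2)], 10L)
    cover2 <- integer(13)
    for (st in s2) cover2[st:(st + 3L)] <- cover2[st:(st + 3L)] + 1L
    expect_true(all(cover2 >= 1L))
})

test_that("magnitude-only input falls back with a warning and QC flag", {
    run <- noisyRun()
    magOnly <- multiEchoSeries(run$series@magnitude[1],
                               echoTimes = fiveTE[1], tr = 1.761,
                               nNoiseFrames = 3L)
    expect_warning(den <- nordicDenoiseRun(magOnly, patchEdge = 7,
                                           mcDraws = 2, seed = 1),
                   "magnitude-only")
    expect_true(attr(den, "qc")$magnitudeOnly)
    expect_false(hasPhase(den))
})

test_that("denoise-then-combine tracks noiseless truth better than combining raw", {
    noisy <- noisyRun(); clean <- noiselessTwin(); den <- denoisedRun()
    mask <- noisy$truth$mask
    sigma <- noiseSigma(estimateNoiseSigma(noisy$series))
    combRef <- optimalCombine(clean$series,
                              fitT2Star(clean$series, mask = mask))
    combRaw <- optimalCombine(noisy$series,
                              fitT2Star(noisy$series, mask = mask,
                                        sigma = sigma))
    combDen <- optimalCombine(den, fitT2Star(den, mask = mask))
    ref <- echoMatrix(combRef, 1, mask)
    errRaw <- norm(echoMatrix(combRaw, 1, mask) - ref, "F")
    errDen <- norm(echoMatrix(combDen, 1, mask) - ref, "F")
    expect_lt(errDen, errRaw)
})
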