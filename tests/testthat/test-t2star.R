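# Build a series directly from per-echo constant volumes (no simulation).
constantSeries <- function(means, te, grid = c(4L, 4L, 4L), nT = 3L) {
    mags <- lapply(means, function(m) array(m, c(grid, nT)))
    multiEchoSeries(mags, echoTimes = te, tr = 2)
}

test_that("two-echo fit matches the closed form", {
    s <- constantSeries(c(100, 50), c(14.2, 38.93))
    t2 <- fitT2Star(s)
    expected <- (38.93 - 14.2) / log(2)
    expect_equal(unique(as.vector(t2starValues(t2))), expected,
                 tolerance = 1e-9)
    expect_equal(unique(as.vector(s0Values(t2))),
                 100 * exp(14.2 / expected), tolerance = 1e-9)
    expect_equal(unique(as.vector(r2starValues(t2))), 1000 / expected,
                 tolerance = 1e-9)
})

test_that("noiseless simulated data is recovered exactly; 4 vs 5 echoes agree", {
    # static monoexponential decay: no BOLD fluctuation, no noise
    run <- simulateRun(smallAcq(),
                       tissuePreset("adult"),
                       network = staticNetwork(c(14L, 14L, 14L)),
                       noise = quietNoise(), seed = 42)
    mask <- run$truth$mask
    t2 <- fitT2Star(run$series, mask = mask)
    relErr <- abs(t2starValues(t2)[mask] - run$truth$t2star[mask]) /
        run$truth$t2star[mask]
    expect_lt(max(relErr), 1e-6)
    # drop the fifth echo: the log-linear fit must not move
    four <- multiEchoSeries(run$series@magnitude[1:4],
                            echoTimes = fiveTE[1:4], tr = 1.761,
                            nNoiseFrames = 3L)
    t2four <- fitT2Star(four, mask = mask)
    expect_lt(max(abs(t2starValues(t2four)[mask] -
                      t2starValues(t2)[mask])), 1e-9)
})

test_that("echoes with no signal are dropped from the tail; degenerate voxels flagged", {
    grid <- c(3L, 3L, 3L); nT <- 3L
    mags <- list(array(100, c(grid, nT)), array(50, c(grid, nT)),
                 array(0, c(grid, nT)))
    s <- multiEchoSeries(mags, echoTimes = c(10, 30, 60), tr = 2)
    t2 <- fitT2Star(s)
    expect_true(all(t2@nEchoesUsed == 2))
    expect_true(all(validVoxels(t2)))
    expect_equal(unique(as.vector(t2starValues(t2))), 20 / log(2),
                 tolerance = 1e-9)
    # only one usable echo -> invalid, not an error
    s1 <- multiEchoSeries(list(array(100, c(grid, nT)),
                               array(0, c(grid, nT)),
                               array(0, c(grid, nT))),
                          echoTimes = c(10, 30, 60), tr = 2)
    t21 <- fitT2Star(s1)
    expect_false(any(validVoxels(t21)))
    # zero decay hits the upper bound
    sFlat <- constantSeries(c(80, 80, 80), c(10, 30, 60))
    t2f <- fitT2Star(sFlat, bounds = c(2, 500))
    expect_true(all(t2starValues(t2f) == 500))
})

test_that("echo weights reproduce the published per-subject medians", {
    te <- c(14.2, 38.93, 63.66, 88.39, 113.12)
    # adult, median cortical T2* 50.71 ms
    expect_equal(round(weightsAtT2Star(te, 50.71), 3)[c(1, 2, 5)],
                 c(0.144, 0.242, 0.163))
    # newborn PB004, 98.58 ms: weight shifts to the late echoes
    expect_equal(round(weightsAtT2Star(te, 98.58), 3)[c(1, 4)],
                 c(0.085, 0.251))
    expect_equal(round(weightsAtT2Star(te, 98.58), 2)[5], 0.25)
    # newborn PB005, 79.73 ms
    expect_equal(round(weightsAtT2Star(te, 79.73), 3)[c(1, 5)],
                 c(0.098, 0.226))
})

test_that("weights normalize, respect the T2*->inf limit, and are monotone in T2*", {
    te <- fiveTE
    t2grid <- seq(20, 140, by = 5)
    W <- weightsAtT2Star(te, t2grid)
    expect_equal(rowSums(W), rep(1, nrow(W)), tolerance = 1e-9)
    # infinite-T2* limit: weights proportional to TE
    wInf <- weightsAtT2Star(te, 1e12)
    expect_equal(wInf, te / sum(te), tolerance = 1e-6)
    expect_equal(wInf[1], 14.2 / 318.3, tolerance = 1e-3)
    # first echo's weight strictly decreasing, last strictly increasing
    expect_true(all(diff(W[, 1]) < 0))
    expect_true(all(diff(W[, 5]) > 0))
    expect_error(weightsAtT2Star(te, -5), "positive")
})

test_that("optimal combination is the identity for one echo and for duplicate echoes", {
    run <- noiselessTwin()
    mask <- run$truth$mask
    t2 <- fitT2Star(run$series, mask = mask)
    e2 <- extractEcho(run$series, 2)
    combOne <- optimalCombine(e2, t2)
    expect_equal(magnitudeData(combOne, 1), magnitudeData(e2, 1),
                 tolerance = 1e-12)
    # duplicated data across echoes: convexity makes the result echo-invariant
    dup <- multiEchoSeries(rep(run$series@magnitude[2], 5),
                           echoTimes = fiveTE, tr = 1.761,
                           nNoiseFrames = 3L)
    combDup <- optimalCombine(dup, t2)
    expect_equal(magnitudeData(combDup, 1), magnitudeData(e2, 1),
                 tolerance = 1e-9)
})

test_that("combination beats every single echo on tSNR under thermal noise", {
    run <- noisyRun()
    mask <- run$truth$mask
    sigma <- noiseSigma(estimateNoiseSigma(run$series))
    t2 <- fitT2Star(run$series, mask = mask, sigma = sigma)
    comb <- optimalCombine(run$series, t2)
    tComb <- tsnrMap(comb, mask = mask)
    mComb <- mean(tsnrValues(tComb)[validVoxels(tComb)])
    for (e in 1:5) {
        tE <- tsnrMap(magnitudeData(run$series, e)[, , , 1:40], mask = mask)
        expect_gt(mComb, mean(tsnrValues(tE)[validVoxels(tE)]))
    }
})

test_that("T2* recovery stays unbiased under thermal noise with the noise-floor correction", {
    # SNR 10 at baseline: S0 = 100, per-channel sigma = 10
    grid <- c(12L, 12L, 12L)
    acq <- acquisitionParams(fiveTE, tr = 1.761, nFrames = 200,
                             nNoiseFrames = 3, gridShape = grid)
    run <- simulateRun(acq, tissuePreset("adult"),
                       network = staticNetwork(grid),
                       noise = noiseModel(thermalSigma = 10,
                                          respAmplitude = 0,
                                          driftAmplitude = 0,
                                          motionSpikeProb = 0), seed = 12)
    mask <- run$truth$mask
    sigma <- noiseSigma(estimateNoiseSigma(run$series))
    t2 <- fitT2Star(run$series, mask = mask, sigma = sigma)
    bias <- (t2starValues(t2)[mask] - run$truth$t2star[mask]) /
        run$truth$t2star[mask]
    expect_lt(abs(median(bias)), 0.03)
})

test_that("denoising the echoes barely moves the median T2*", {
    noisy <- noisyRun(); den <- denoisedRun()
    mask <- noisy$truth$mask
    sigma <- noiseSigma(estimateNoiseSigma(noisy$series))
    mRaw <- median(t2starValues(fitT2Star(noisy$series, mask = mask,
                                          sigma = sigma))[mask])
    mDen <- median(t2starValues(fitT2Star(den, mask = mask))[mask])
    expect_lt(abs(mDen - mRaw) / mRaw, 0.02)
})

test_that("weight summaries match the analytic weights and age ordering", {
    te <- fiveTE
    # constant map: every row equals the analytic weights
    grid <- c(6L, 6L, 6L)
    t2c <- fitT2Star(constantSeries(100 * exp(-te / 50.71), te, grid = grid))
    ws <- weightSummary(t2c, te)
    wAna <- weightsAtT2Star(te, 50.71)
    for (rw in c("mean", "median", "p05", "p95"))
        expect_equal(unlist(ws[rw, -1]), wAna, tolerance = 1e-6,
                     ignore_attr = TRUE)
    expect_equal(unlist(ws["sd", -1]), rep(0, 5), tolerance = 1e-9,
                 ignore_attr = TRUE)

    # sampled maps: median row commutes with the monotone echoes (1, 2, 5)
    for (label in c("adult", "infant")) {
        maps <- makeTissueMaps(tissuePreset(label), c(16, 16, 16), seed = 3)
        s <- multiEchoSeries(lapply(te, function(T) {
            array(rep(maps$s0 * exp(-T / maps$t2star), 2), c(16, 16, 16, 2))
        }), echoTimes = te, tr = 1.761)
        t2m <- fitT2Star(s)
        ws <- weightSummary(t2m, te)
        wMed <- weightsAtT2Star(te, median(t2starValues(t2m)))
        expect_lt(max(abs(unlist(ws["median", c(2, 3, 6)]) -
                          wMed[c(1, 2, 5)])), 0.005)
        heaviest <- order(unlist(ws["mean", -1]), decreasing = TRUE)[1:3]
        if (label == "infant") {
            expect_setequal(heaviest, 3:5)  # late echoes dominate
        } else {
            expect_true(all(c(2, 3) %in% heaviest))  # mid echoes dominate
        }
    }
    expect_error(weightSummary(t2c, te, mask = array(FALSE, grid)), "empty")
})
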