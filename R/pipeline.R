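#' Synthetic tissue masks for confound regression
#'
#' Splits a brain mask into the three tissue compartments the 36-parameter
#' confound model expects: the whole mask as the global compartment, an
#' outer shell standing in for white matter and a central core standing in
#' for CSF. These are geometric stand-ins for segmentation output,
#' sufficient for exercising the regression.
#'
#' @param mask logical 3D array.
#' @return list with logical arrays \code{global}, \code{wm}, \code{csf}.
#' @export
syntheticTissueMasks <- function(mask) {
    stopifnot(is.logical(mask), any(mask))
    grid <- dim(mask)
    ctr <- (grid + 1) / 2
    ax <- lapply(1:3, function(k) seq_len(grid[k]) - ctr[k])
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
    d <- sqrt(d2)
    rMax <- max(d[mask])
    list(global = mask,
         wm = mask & d > 0.75 * rMax,
         csf = mask & d <= 0.3 * rMax)
}

#' Simulate a multi-run subject
#'
#' One subject: tissue maps and network model are drawn once and shared
#' across runs; neural series, physiological noise, motion and thermal
#' noise are redrawn per run.
#'
#' @param acq an [AcquisitionParams-class].
#' @param preset a [TissuePreset-class].
#' @param network a [NetworkModel-class] or NULL for the default.
#' @param noise a [NoiseModel-class] or NULL for the default.
#' @param nRuns integer(1).
#' @param seed integer(1).
#' @return list of per-run lists (\code{series}, \code{motion},
#'   \code{truth}), plus attribute \code{network}.
#' @export
simulateSubject <- function(acq, preset, network = NULL, noise = NULL,
                            nRuns = 4L, seed = 1L) {
    if (is.null(network)) network <- networkModel(acq@gridShape)
    tissue <- makeTissueMaps(preset, acq@gridShape, seed = seed)
    runs <- lapply(seq_len(nRuns), function(r)
        simulateRun(acq, tissue, network = network, noise = noise,
                    seed = seed + 1000L * r))
    attr(runs, "network") <- network
    runs
}

# Derive a condition's single-echo (combined or extracted) series plus its
# T2* map, from a simulated multi-echo run.
conditionSeries <- function(run, condition, seEcho = 2L, patchEdge = NULL,
                            stride = NULL, mcDraws = 5L, seed = 1L) {
    series <- run$series
    denoised <- grepl("denoised", condition)
    if (startsWith(condition, "SE")) {
        se <- extractEcho(series, seEcho)
        if (denoised)
            se <- nordicDenoiseRun(se, patchEdge = patchEdge, stride = stride,
                                   mcDraws = mcDraws, seed = seed)
        return(list(series = se, t2map = NULL))
    }
    if (denoised)
        series <- nordicDenoiseRun(series, patchEdge = patchEdge,
                                   stride = stride, mcDraws = mcDraws,
                                   seed = seed)
    # the noise-floor correction applies to the raw data only: after
    # denoising the residual thermal level is far below the estimate
    sigma <- if (denoised) NULL
             else noiseSigma(estimateNoiseSigma(run$series))
    t2map <- fitT2Star(series, mask = run$truth$mask, sigma = sigma)
    list(series = optimalCombine(series, t2map), t2map = t2map)
}

#' Run the end-to-end conditions-grid experiment
#'
#' Simulates a multi-run subject and carries each run through the full
#' processing chain under the four acquisition-by-processing conditions
#' (multi-echo vs single-echo, raw vs thermally denoised): per-echo
#' denoising, T2* fitting and optimal combination (multi-echo), motion QC
#' with respiratory band-stop filtering and FD censoring, 36-parameter
#' confound regression with band-pass filtering, parcel connectivity,
#' per-run and run-averaged tSNR, and permuted split-half reliability per
#' condition. Deterministic given the seed. When \code{outDir} is given,
#' per-condition tSNR and reliability tables (TSV) and a JSON provenance
#' record of every parameter are written there.
#'
#' @param acq an [AcquisitionParams-class].
#' @param preset a [TissuePreset-class].
#' @param nRuns integer(1), number of runs (>= 2 for reliability).
#' @param conditions character, subset of \code{"ME-raw"},
#'   \code{"ME-denoised"}, \code{"SE-raw"}, \code{"SE-denoised"}.
#' @param network,noise optional model overrides.
#' @param seed integer(1).
#' @param outDir optional output directory.
#' @param config list of processing parameters; defaults:
#'   \code{fdInterp = 0.3} and \code{fdConn = 0.2} (mm),
#'   \code{band = c(0.009, 0.08)} Hz, \code{bandstopBpm = c(12, 18)},
#'   \code{nPermutations = 25}, \code{minutesGrid = NULL} (auto),
#'   \code{seEcho = 2}, \code{patchEdge = NULL} (auto), \code{stride =
#'   NULL}, \code{mcDraws = 5}.
#' @return list with per-condition results (\code{tsnrSummary},
#'   \code{tsnrMaps}, \code{reliability}, \code{t2starSummary}), the QC
#'   block (\code{fd}, censor masks, kept runs) and the provenance list.
#' @export
runPipeline <- function(acq, preset, nRuns = 4L,
                        conditions = c("ME-raw", "ME-denoised",
                                       "SE-raw", "SE-denoised"),
                        network = NULL, noise = NULL, seed = 1L,
                        outDir = NULL, config = list()) {
    cfg <- utils::modifyList(list(
        fdInterp = 0.3, fdConn = 0.2, band = c(0.009, 0.08),
        bandstopBpm = c(12, 18), nPermutations = 25L, minutesGrid = NULL,
        seEcho = 2L, patchEdge = NULL, stride = NULL, mcDraws = 5L,
        reliabilityNodes = "dense", maxDenseNodes = 600L), config)
    conditions <- match.arg(conditions, several.ok = TRUE)
    if (is.null(network)) network <- networkModel(acq@gridShape)
    runs <- simulateSubject(acq, preset, network = network, noise = noise,
                            nRuns = nRuns, seed = seed)
    mask <- runs[[1L]]$truth$mask
    parcels <- runs[[1L]]$truth$parcels
    tissueMasks <- syntheticTissueMasks(mask)
    # reliability nodes: parcel means, or a regular dense voxel subsample
    # (parcel averaging already cancels voxelwise thermal noise, so the
    # dense nodes are the ones that show what denoising buys)
    vIdx <- which(mask)
    denseIdx <- vIdx[seq(1L, length(vIdx),
                         by = max(1L, ceiling(length(vIdx) /
                                              cfg$maxDenseNodes)))]

    # shared motion QC (motion is acquisition-level, not condition-level)
    qc <- lapply(runs, function(run) {
        mt <- bandstopMotion(run$motion, cfg$bandstopBpm)
        fd <- framewiseDisplacement(mt)
        list(motion = mt, fd = fd,
             maskHi = censorFrames(fd, cfg$fdInterp),
             maskLo = censorFrames(fd, cfg$fdConn))
    })
    keptTsnr <- selectRuns(lapply(qc, `[[`, "maskHi"), "tsnr_averaging")

    results <- list()
    for (cond in conditions) {
        condRes <- list(tsnrMaps = list(), nodeSeries = list())
        t2sum <- NULL
        for (r in seq_len(nRuns)) {
            cs <- conditionSeries(runs[[r]], cond, seEcho = cfg$seEcho,
                                  patchEdge = cfg$patchEdge,
                                  stride = cfg$stride,
                                  mcDraws = cfg$mcDraws,
                                  seed = seed + 17L * r)
            condRes$tsnrMaps[[r]] <- tsnrMap(cs$series, mask = mask,
                                             conditionLabel = cond)
            if (!is.null(cs$t2map) && r == 1L)
                t2sum <- weightSummary(cs$t2map, echoTimes(acq), mask)
            dat <- cs$series@magnitude[[1L]]
            dat <- dat[, , , seq_len(nFrames(cs$series)), drop = FALSE]
            confounds <- buildConfounds(dat, tissueMasks, qc[[r]]$motion)
            cleaned <- cleanTimeseries(dat, confounds,
                                       censorHi = qc[[r]]$maskHi,
                                       band = cfg$band, tr = acq@tr)
            ns <- if (cfg$reliabilityNodes == "parcel") {
                nodeTimeseries(cleaned, parcels)$series
            } else {
                matrix(cleaned, prod(dim(cleaned)[1:3]),
                       dim(cleaned)[4])[denseIdx, , drop = FALSE]
            }
            condRes$nodeSeries[[r]] <- list(
                series = ns, retained = retainedFrames(qc[[r]]$maskLo))
        }
        avg <- averageTsnr(condRes$tsnrMaps, keep = keptTsnr,
                           conditionLabel = cond)
        rel <- splitHalfReliability(condRes$nodeSeries,
                                    minutesGrid = cfg$minutesGrid,
                                    tr = acq@tr,
                                    nPermutations = cfg$nPermutations,
                                    seed = seed + 7L,
                                    nodeKind = cfg$reliabilityNodes)
        results[[cond]] <- list(
            tsnrMaps = condRes$tsnrMaps, tsnrAverage = avg,
            tsnrSummary = attr(avg, "summary"),
            reliability = rel, t2starSummary = t2sum)
    }

    provenance <- list(seed = seed, nRuns = nRuns, conditions = conditions,
                       gridShape = acq@gridShape, nFrames = acq@nFrames,
                       echoTimes = acq@echoTimes, tr = acq@tr,
                       config = cfg[c("fdInterp", "fdConn", "band",
                                      "bandstopBpm", "nPermutations",
                                      "seEcho", "mcDraws")],
                       keptTsnrRuns = keptTsnr,
                       pctRetained03 = vapply(qc, function(q)
                           pctRetained(q$maskHi), numeric(1)))
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        tsnrTab <- data.frame(
            condition = names(results),
            mean = vapply(results, function(x) x$tsnrSummary["mean"],
                          numeric(1)),
            sd = vapply(results, function(x) x$tsnrSummary["sd"],
                        numeric(1)))
        utils::write.table(tsnrTab, file.path(outDir, "tsnr_summary.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        for (cond in names(results)) {
            rel <- results[[cond]]$reliability
            utils::write.table(
                data.frame(minutes = rel@minutesGrid, mean_r = rel@meanR,
                           sd_r = rel@sdR),
                file.path(outDir, sprintf("reliability_%s.tsv", cond)),
                sep = "\t", row.names = FALSE, quote = FALSE)
        }
        jsonlite::write_json(provenance,
                             file.path(outDir, "provenance.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(results = results, qc = qc, provenance = provenance)
}
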