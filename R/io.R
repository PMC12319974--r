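#' Write a simulated run to disk
#'
#' Writes per-echo magnitude (and phase) volumes as NIfTI with the naming
#' pattern \code{sub-<X>_run-<Y>_echo-<N>_part-<mag|phase>_bold.nii.gz},
#' the motion parameters as a 6-column TSV (translations in mm, rotations
#' in radians), a JSON sidecar with the acquisition metadata, and -- when
#' ground truth is supplied -- a \code{truth/} subdirectory with the T2*
#' and S0 maps (NIfTI), the true network connectivity (TSV) and the true
#' FD trace (TSV).
#'
#' @param series a [MultiEchoSeries-class].
#' @param motion a [MotionTrace-class] or NULL.
#' @param dir output directory (created if needed).
#' @param subject,run labels used in file names.
#' @param truth optional ground-truth list from [simulateRun()].
#' @param voxelSize numeric(1), mm, written into the NIfTI header.
#' @return invisibly, the paths written.
#' @seealso [readRun()]
#' @export
writeRun <- function(series, motion = NULL, dir, subject = "01", run = 1L,
                     truth = NULL, voxelSize = 2) {
    stopifnot(is(series, "MultiEchoSeries"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    stem <- sprintf("sub-%s_run-%02d", subject, as.integer(run))
    paths <- character()
    writeVol <- function(arr, path) {
        img <- RNifti::asNifti(arr)
        RNifti::pixdim(img) <- c(rep(voxelSize, 3),
                                 repetitionTime(series))[seq_along(dim(arr))]
        RNifti::writeNifti(img, path)
        path
    }
    for (e in seq_len(nEchoes(series))) {
        p <- file.path(dir, sprintf("%s_echo-%d_part-mag_bold.nii.gz",
                                    stem, e))
        paths <- c(paths, writeVol(series@magnitude[[e]], p))
        if (hasPhase(series)) {
            p <- file.path(dir, sprintf("%s_echo-%d_part-phase_bold.nii.gz",
                                        stem, e))
            paths <- c(paths, writeVol(series@phase[[e]], p))
        }
    }
    meta <- list(EchoTimes = echoTimes(series),
                 RepetitionTime = repetitionTime(series),
                 NumNoiseFrames = nNoiseFrames(series),
                 NumFrames = nFrames(series))
    metaPath <- file.path(dir, paste0(stem, "_bold.json"))
    jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, metaPath)
    if (!is.null(motion)) {
        mp <- file.path(dir, paste0(stem, "_motion.tsv"))
        utils::write.table(motionParams(motion), mp, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        paths <- c(paths, mp)
    }
    if (!is.null(truth)) {
        tdir <- file.path(dir, "truth")
        dir.create(tdir, showWarnings = FALSE)
        paths <- c(paths,
            writeVol(truth$t2star, file.path(tdir, paste0(stem, "_t2star.nii.gz"))),
            writeVol(truth$s0, file.path(tdir, paste0(stem, "_s0.nii.gz"))))
        cp <- file.path(tdir, paste0(stem, "_true-connectivity.tsv"))
        utils::write.table(truth$trueConnectivity, cp, sep = "\t",
                           row.names = FALSE, col.names = FALSE)
        fp <- file.path(tdir, paste0(stem, "_fd-true.tsv"))
        utils::write.table(data.frame(fd = truth$fdTrue), fp, sep = "\t",
                           row.names = FALSE, quote = FALSE)
        paths <- c(paths, cp, fp)
    }
    invisible(paths)
}

#' Read a run written by [writeRun()]
#'
#' @param dir directory containing the files.
#' @param subject,run labels matching those given at write time.
#' @return list with \code{series} ([MultiEchoSeries-class]) and
#'   \code{motion} ([MotionTrace-class] or NULL).
#' @export
readRun <- function(dir, subject = "01", run = 1L) {
    stem <- sprintf("sub-%s_run-%02d", subject, as.integer(run))
    meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_bold.json")),
                                simplifyVector = TRUE)
    E <- length(meta$EchoTimes)
    readVol <- function(path) {
        arr <- RNifti::readNifti(path)
        array(as.numeric(arr), dim(arr))
    }
    magnitude <- lapply(seq_len(E), function(e)
        readVol(file.path(dir, sprintf("%s_echo-%d_part-mag_bold.nii.gz",
                                       stem, e))))
    phasePath <- file.path(dir, sprintf("%s_echo-1_part-phase_bold.nii.gz",
                                        stem))
    phase <- if (file.exists(phasePath)) {
        lapply(seq_len(E), function(e)
            readVol(file.path(dir,
                sprintf("%s_echo-%d_part-phase_bold.nii.gz", stem, e))))
    } else list()
    series <- multiEchoSeries(magnitude, echoTimes = meta$EchoTimes,
                              tr = meta$RepetitionTime, phase = phase,
                              nNoiseFrames = meta$NumNoiseFrames)
    mp <- file.path(dir, paste0(stem, "_motion.tsv"))
    motion <- if (file.exists(mp)) {
        motionTrace(as.matrix(utils::read.delim(mp)),
                    tr = meta$RepetitionTime)
    } else NULL
    list(series = series, motion = motion)
}
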