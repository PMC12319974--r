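#' Framewise displacement
#'
#' Per-frame head-motion summary: sum of absolute backward differences of
#' the three translations (mm) plus \code{headRadius} times the sum of
#' absolute backward differences of the three rotations (radians), i.e.
#' rotations are converted to arc length on a sphere approximating the
#' head. The first frame has no predecessor and is defined as FD = 0.
#'
#' @param motion a [MotionTrace-class].
#' @param headRadius numeric(1), head radius in mm (default 50, the
#'   conventional value).
#' @return numeric, FD in mm per frame.
#' @examples
#' m <- motionTrace(matrix(0, 5, 6), tr = 2)
#' framewiseDisplacement(m)  # all zeros
#' @export
framewiseDisplacement <- function(motion, headRadius = 50) {
    stopifnot(is(motion, "MotionTrace"))
    validObject(motion)
    p <- motionParams(motion)
    d <- abs(apply(p, 2L, function(col) c(0, diff(col))))
    if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
    rowSums(d[, 1:3, drop = FALSE]) +
        headRadius * rowSums(d[, 4:6, drop = FALSE])
}

#' Band-stop (notch) filtering of motion parameters
#'
#' Removes the respiratory band from the six motion parameter traces with
#' a zero-phase second-order Butterworth band-stop filter, applied to each
#' column. The band is given in breaths per minute and converted to Hz as
#' bpm/60. When the lower band edge is at or above the Nyquist frequency
#' (as for neonatal respiration rates at typical TRs), the filter cannot
#' target the band and the trace is returned unchanged with a message and
#' attribute \code{skipped = TRUE} recording the reason.
#'
#' @param motion a [MotionTrace-class].
#' @param bandBpm numeric(2), stop-band in breaths/min.
#' @return a filtered [MotionTrace-class]; attribute \code{skipped} is
#'   TRUE with a \code{reason} when filtering was not applicable.
#' @examples
#' m <- motionTrace(matrix(rnorm(600), 100, 6), tr = 1.761)
#' mf <- bandstopMotion(m, c(12, 18))
#' @export
bandstopMotion <- function(motion, bandBpm) {
    stopifnot(is(motion, "MotionTrace"))
    validObject(motion)
    stopifnot(length(bandBpm) == 2L, bandBpm[1] < bandBpm[2],
              bandBpm[1] > 0)
    nyq <- 1 / (2 * repetitionTime(motion))
    bandHz <- bandBpm / 60
    if (bandHz[1] >= nyq) {
        message(sprintf(
            "band-stop skipped: band %.3g-%.3g Hz is at/above Nyquist %.3g Hz",
            bandHz[1], bandHz[2], nyq))
        attr(motion, "skipped") <- TRUE
        attr(motion, "reason") <- "band at or above Nyquist"
        return(motion)
    }
    w <- pmin(bandHz / nyq, 0.999)
    filtered <- filterColumns(motionParams(motion), w, type = "stop")
    out <- motionTrace(filtered, tr = repetitionTime(motion))
    attr(out, "skipped") <- FALSE
    out
}

#' Censor frames by framewise displacement
#'
#' Frames with FD strictly above the threshold are censored; the rest are
#' retained (the first frame, FD 0, is always retained).
#'
#' @param fd numeric, FD in mm per frame, or a [MotionTrace-class] from
#'   which FD is computed.
#' @param threshold numeric(1), mm; 0.2 mm is the conventional threshold
#'   for connectivity, 0.3 mm for interpolation/run-level rules.
#' @return a [CensorMask-class].
#' @examples
#' m <- censorFrames(c(0, 0.1, 0.25, 0.4, 0.15), threshold = 0.3)
#' retainedFrames(m)
#' pctRetained(m)
#' @export
censorFrames <- function(fd, threshold) {
    if (is(fd, "MotionTrace")) fd <- framewiseDisplacement(fd)
    stopifnot(is.numeric(fd), all(is.finite(fd)), threshold > 0)
    retained <- fd <= threshold
    new("CensorMask", fd = as.numeric(fd), threshold = as.numeric(threshold),
        retained = retained, pctRetained = 100 * mean(retained))
}

#' Run-level selection rules
#'
#' Applies one of the two run-level inclusion rules to a set of censoring
#' masks (one per run, computed at the FD threshold the rule expects,
#' conventionally 0.3 mm):
#' \describe{
#'   \item{tsnr_averaging}{keep runs with \emph{more than} 90\% of frames
#'     retained -- the low-motion runs averaged for tSNR maps.}
#'   \item{infant_inclusion}{drop runs with \emph{less than} 30\% of
#'     frames retained -- the exclusion rule for infant runs.}
#' }
#' Both boundaries are strict, exactly as stated.
#'
#' @param masks list of [CensorMask-class].
#' @param rule character(1), "tsnr_averaging" or "infant_inclusion".
#' @return integer vector of kept run indices (possibly empty, with a
#'   warning).
#' @examples
#' fd <- list(rep(0, 10), c(rep(0, 8), 1, 1))
#' masks <- lapply(fd, censorFrames, threshold = 0.3)
#' selectRuns(masks, "tsnr_averaging")
#' @export
selectRuns <- function(masks, rule = c("tsnr_averaging", "infant_inclusion")) {
    rule <- match.arg(rule)
    stopifnot(length(masks) >= 1L,
              all(vapply(masks, is, TRUE, "CensorMask")))
    pct <- vapply(masks, pctRetained, numeric(1))
    keep <- switch(rule,
        tsnr_averaging = which(pct > 90),
        infant_inclusion = which(!(pct < 30)))
    if (length(keep) == 0L)
        warning("no runs qualify under rule '", rule, "'")
    keep
}
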