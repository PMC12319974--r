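# Mean over nodes of the correlation between matching rows of two
# connectivity matrices, diagonal excluded; NA rows skipped.
matrixRowReliability <- function(A, B, fisherZ = FALSE) {
    stopifnot(identical(dim(A), dim(B)))
    n <- nrow(A)
    vals <- vapply(seq_len(n), function(i) {
        a <- A[i, -i]; b <- B[i, -i]
        if (fisherZ) { a <- atanh(pmin(pmax(a, -0.999999), 0.999999))
                       b <- atanh(pmin(pmax(b, -0.999999), 0.999999)) }
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) < 3L || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
            return(NA_real_)
        stats::cor(a[ok], b[ok])
    }, numeric(1))
    vals
}

#' Permuted split-half reliability curve
#'
#' Quantifies how quickly connectivity estimates stabilize with the amount
#' of data. Per permutation the run order is shuffled and the runs split
#' into two halves (the extra run of an odd count goes to the held-out
#' half). The held-out matrix uses all retained frames of its half; for
#' each grid point m the test matrix uses the first m minutes of retained
#' frames taken consecutively from the concatenated first half.
#' Reliability at m is the mean over nodes of the Pearson correlation
#' between each node's connectivity row in the two matrices (diagonal
#' excluded). The curve reports mean and SD across permutations, plus the
#' per-node reliability map at the largest data amount. Note the absolute
#' values also depend on the held-out half's own size.
#'
#' @param runs list of runs; each a nodes x time matrix of cleaned data,
#'   or a list with elements \code{series} (nodes x time) and
#'   \code{retained} (logical per frame). Frames failing the censoring
#'   mask are never used.
#' @param minutesGrid numeric, data amounts in minutes (strictly
#'   increasing). Default: 5-minute increments up to half the retained
#'   data.
#' @param tr numeric(1), repetition time in seconds (minutes-to-frames
#'   conversion uses retained frames: floor(m * 60 / tr)).
#' @param nPermutations integer(1), run-order permutations (default 100).
#' @param seed integer(1).
#' @param fisherZ logical(1); correlate Fisher-z rows instead of raw r.
#' @param nodeKind character(1), "dense" or "parcel" (provenance).
#' @return a [ReliabilityCurve-class]. Grid points exceeding the
#'   available retained data are dropped with a warning.
#' @export
splitHalfReliability <- function(runs, minutesGrid = NULL, tr,
                                 nPermutations = 100L, seed = 1L,
                                 fisherZ = FALSE, nodeKind = "dense") {
    stopifnot(length(runs) >= 2L)
    runs <- lapply(runs, function(r) {
        if (is.matrix(r)) list(series = r, retained = rep(TRUE, ncol(r)))
        else {
            stopifnot(is.matrix(r$series))
            if (is.null(r$retained)) r$retained <- rep(TRUE, ncol(r$series))
            list(series = r$series, retained = as.logical(r$retained))
        }
    })
    nRuns <- length(runs)
    retPerRun <- vapply(runs, function(r) sum(r$retained), integer(1))
    nHalfA <- floor(nRuns / 2)
    # worst-case frames available in the smaller half
    minHalfFrames <- sum(sort(retPerRun)[seq_len(nHalfA)])
    if (is.null(minutesGrid)) {
        maxMin <- floor(minHalfFrames * tr / 60)
        minutesGrid <- seq(5, max(5, maxMin), by = 5)
    }
    stopifnot(all(diff(minutesGrid) > 0))
    framesNeeded <- floor(minutesGrid * 60 / tr)
    usable <- framesNeeded <= minHalfFrames & framesNeeded >= 2L
    if (!all(usable)) {
        warning("dropping grid points beyond the available retained data: ",
                paste(minutesGrid[!usable], collapse = ", "), " min")
        minutesGrid <- minutesGrid[usable]
        framesNeeded <- framesNeeded[usable]
    }
    if (length(minutesGrid) == 0L)
        stop("no usable grid points")
    nG <- length(minutesGrid)
    nNodes <- nrow(runs[[1L]]$series)

    rel <- matrix(NA_real_, nPermutations, nG)
    nodeAcc <- numeric(nNodes); nodeCnt <- 0L
    withSeed(seed, {
        for (p in seq_len(nPermutations)) {
            ord <- sample.int(nRuns)
            aIdx <- ord[seq_len(nHalfA)]
            bIdx <- ord[(nHalfA + 1L):nRuns]
            catRet <- function(idx) do.call(cbind, lapply(idx, function(i)
                runs[[i]]$series[, runs[[i]]$retained, drop = FALSE]))
            A <- catRet(aIdx)
            B <- catRet(bIdx)
            RB <- rowCorrelation(B)
            for (g in seq_len(nG)) {
                RA <- rowCorrelation(A[, seq_len(framesNeeded[g]),
                                       drop = FALSE])
                r <- matrixRowReliability(RA, RB, fisherZ = fisherZ)
                rel[p, g] <- mean(r, na.rm = TRUE)
                if (g == nG) {
                    nodeAcc <- nodeAcc + ifelse(is.na(r), 0, r)
                    nodeCnt <- nodeCnt + 1L
                }
            }
        }
    })
    new("ReliabilityCurve",
        minutesGrid = as.numeric(minutesGrid),
        meanR = colMeans(rel),
        sdR = if (nPermutations == 1L) rep(0, nG)
              else apply(rel, 2L, stats::sd),
        nPermutations = as.integer(nPermutations),
        nodeKind = nodeKind,
        nodeReliability = nodeAcc / max(nodeCnt, 1L))
}

#' Minutes needed to reach a target reliability
#'
#' Finds where a reliability curve first reaches a target value (typically
#' another condition's reliability at some reference data amount), by
#' linear interpolation between grid points.
#'
#' @param curve a [ReliabilityCurve-class].
#' @param target numeric(1), the reliability value to reach.
#' @return list with \code{reached} (logical), \code{minutes} (numeric,
#'   NA when not reached) and \code{interval}: the bracketing grid points.
#' @examples
#' curve <- new("ReliabilityCurve", minutesGrid = c(5, 10, 15),
#'              meanR = c(0.1, 0.2, 0.3), sdR = rep(0, 3),
#'              nPermutations = 1L, nodeKind = "dense",
#'              nodeReliability = numeric())
#' reliabilityEquivalentMinutes(curve, 0.24)  # 12 minutes
#' @export
reliabilityEquivalentMinutes <- function(curve, target) {
    stopifnot(is(curve, "ReliabilityCurve"), length(target) == 1L)
    g <- curve@minutesGrid
    r <- curve@meanR
    hit <- which(r >= target)
    if (length(hit) == 0L)
        return(list(reached = FALSE, minutes = NA_real_,
                    interval = c(NA_real_, NA_real_)))
    i <- hit[1L]
    if (i == 1L)
        return(list(reached = TRUE, minutes = g[1L],
                    interval = c(NA_real_, g[1L])))
    m <- g[i - 1L] + (target - r[i - 1L]) / (r[i] - r[i - 1L]) *
        (g[i] - g[i - 1L])
    list(reached = TRUE, minutes = m, interval = c(g[i - 1L], g[i]))
}
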