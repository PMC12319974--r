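# Coerce 4D data or a voxels x time matrix to matrix form.
asVoxelMatrix <- function(data, mask = NULL) {
    if (is.matrix(data)) return(data)
    stopifnot(length(dim(data)) == 4L)
    if (is.null(mask)) {
        d <- dim(data)
        matrix(data, prod(d[1:3]), d[4])
    } else maskMatrix(data, mask)
}

#' Build the 36-parameter confound matrix
#'
#' The standard 36-regressor nuisance model: six rigid-body motion
#' parameters and three tissue mean signals (global/whole-mask, white
#' matter, CSF), their temporal derivatives (backward differences, first
#' frame 0 by convention), and the elementwise squares of all 18, in a
#' fixed documented column order.
#'
#' @param data 4D array (x, y, z, t), noise frames already removed.
#' @param tissueMasks named list of logical 3D arrays with elements
#'   \code{global}, \code{wm}, \code{csf}.
#' @param motion a [MotionTrace-class] with matching frame count.
#' @return numeric matrix, frames x 36, with descriptive column names:
#'   the 9 base columns, then \code{d_*} derivatives, then \code{*_sq}
#'   quadratics.
#' @examples
#' dat <- array(rnorm(4^3 * 10, 100), c(4, 4, 4, 10))
#' masks <- list(global = array(TRUE, c(4, 4, 4)),
#'               wm = array(c(TRUE, FALSE), c(4, 4, 4)),
#'               csf = array(c(FALSE, TRUE), c(4, 4, 4)))
#' cf <- buildConfounds(dat, masks, motionTrace(matrix(0, 10, 6), tr = 2))
#' ncol(cf)  # 36
#' @export
buildConfounds <- function(data, tissueMasks, motion) {
    stopifnot(is(motion, "MotionTrace"),
              all(c("global", "wm", "csf") %in% names(tissueMasks)))
    nT <- dim(data)[4]
    stopifnot(nFrames(motion) == nT)
    tissue <- vapply(c("global", "wm", "csf"), function(nm) {
        m <- tissueMasks[[nm]]
        if (is.null(m) || !any(m))
            stop("missing or empty tissue mask: ", nm)
        colMeans(asVoxelMatrix(data, m))
    }, numeric(nT))
    base <- cbind(motionParams(motion), tissue)
    colnames(base) <- c(colnames(motionParams(motion)),
                        "global_signal", "wm_signal", "csf_signal")
    deriv <- apply(base, 2L, function(col) c(0, diff(col)))
    colnames(deriv) <- paste0("d_", colnames(base))
    quad <- cbind(base, deriv)^2
    colnames(quad) <- paste0(c(colnames(base), colnames(deriv)), "_sq")
    out <- cbind(base, deriv, quad)
    stopifnot(ncol(out) == 36L)
    out
}

# Linear interpolation of censored frames from nearest retained neighbors
# (edges held constant), applied to the columns of a frames x k matrix or
# rows of voxels x frames via t().
interpolateCensored <- function(x, retained) {
    if (all(retained)) return(x)
    if (!any(retained)) stop("all frames censored: nothing to interpolate from")
    tIdx <- seq_along(retained)
    keep <- which(retained)
    apply(x, 1L, function(row)
        stats::approx(keep, row[keep], xout = tIdx, rule = 2)$y) |> t()
}

#' Confound regression with censored-frame interpolation and band-pass
#'
#' The connectivity-preprocessing chain, in the order: (1) frames censored
#' at the high FD threshold (conventionally 0.3 mm) are replaced by linear
#' interpolation from the nearest retained neighbors (edges held
#' constant), so the spikes do not leak through the filter; (2) a
#' zero-phase second-order Butterworth band-pass (default 0.009-0.08 Hz)
#' is applied identically to the data and to every confound column;
#' (3) voxelwise OLS residuals against the filtered confounds (plus
#' intercept) are returned with the original temporal mean restored.
#'
#' Downstream correlation should re-exclude the censored frames (the
#' interpolated values are filtering aids, not data); see
#' [connectivity()].
#'
#' @param data 4D array or voxels x time matrix (noise frames removed).
#' @param confounds numeric matrix, frames x k (e.g. [buildConfounds()]);
#'   NULL for filtering-only.
#' @param censorHi a [CensorMask-class] at the interpolation threshold, or
#'   NULL for no censoring.
#' @param band numeric(2), band-pass edges in Hz.
#' @param tr numeric(1), repetition time in seconds.
#' @return cleaned data in the same shape as the input.
#' @export
cleanTimeseries <- function(data, confounds, censorHi = NULL,
                            band = c(0.009, 0.08), tr) {
    was4d <- !is.matrix(data)
    d4 <- if (was4d) dim(data) else NULL
    X <- asVoxelMatrix(data)
    nT <- ncol(X)
    nyq <- 1 / (2 * tr)
    stopifnot(length(band) == 2L, band[1] > 0, band[1] < band[2])
    if (band[2] >= nyq)
        stop(sprintf("band upper edge %.3g Hz is at/above Nyquist %.3g Hz",
                     band[2], nyq))
    retained <- if (is.null(censorHi)) rep(TRUE, nT)
                else retainedFrames(censorHi)
    stopifnot(length(retained) == nT)
    if (!any(retained)) stop("all frames censored")

    X <- interpolateCensored(X, retained)
    means <- rowMeans(X)
    w <- band / nyq
    Xf <- t(filterColumns(t(X), w, type = "pass"))
    if (!is.null(confounds)) {
        stopifnot(nrow(confounds) == nT)
        if (ncol(confounds) + 1L >= nT)
            stop("confound model leaves no residual degrees of freedom: ",
                 ncol(confounds), " columns for ", nT, " frames")
        C <- interpolateCensored(t(confounds), retained) |> t()
        Cf <- filterColumns(C, w, type = "pass")
        qrC <- qr(cbind(1, Cf))
        Xf <- t(qr.resid(qrC, t(Xf)))
    }
    out <- Xf + means
    if (was4d) array(out, d4) else out
}

#' Node time series from volumetric data
#'
#' @param data 4D array or voxels x time matrix.
#' @param nodes logical 3D mask (each in-mask voxel a node, "dense") or
#'   integer 3D parcel label array (mean series per label > 0, "parcel").
#' @return list with \code{series} (nodes x time) and \code{kind}.
#' @export
nodeTimeseries <- function(data, nodes) {
    if (is.matrix(data))
        return(list(series = data, kind = "dense"))
    stopifnot(length(dim(data)) == 4L, identical(dim(nodes), dim(data)[1:3]))
    if (is.logical(nodes))
        return(list(series = maskMatrix(data, nodes), kind = "dense"))
    labs <- sort(unique(nodes[nodes > 0L]))
    V <- asVoxelMatrix(data)
    series <- t(vapply(labs, function(l) colMeans(V[which(nodes == l), ,
                                                    drop = FALSE]),
                       numeric(ncol(V))))
    list(series = series, kind = "parcel")
}

#' Functional connectivity matrix
#'
#' Pearson correlations between node time series over retained frames
#' only (frames interpolated for filtering are re-excluded here). Nodes
#' are dense voxels within a mask, parcel means over an integer label
#' volume, or the rows of a supplied matrix. Constant node series yield
#' flagged NA rows rather than propagating errors.
#'
#' @param data cleaned 4D array or nodes x time matrix
#'   (see [cleanTimeseries()]).
#' @param nodes 3D mask or parcel labels; ignored for matrix input.
#' @param censorLo a [CensorMask-class] at the connectivity threshold
#'   (conventionally 0.2 mm), or NULL to use all frames.
#' @param fisherZ logical(1); transform off-diagonal values to Fisher z
#'   (used when averaging or correlating matrices).
#' @return a [ConnectivityMatrix-class]; attribute \code{flagged} lists
#'   constant nodes.
#' @examples
#' ts <- matrix(rnorm(5 * 50), 5, 50)
#' ts[2, ] <- ts[1, ]  # duplicated node
#' cm <- connectivity(ts)
#' connValues(cm)[1, 2]  # exactly 1
#' @export
connectivity <- function(data, nodes = NULL, censorLo = NULL,
                         fisherZ = FALSE) {
    nt <- if (is.matrix(data)) list(series = data, kind = "dense")
          else nodeTimeseries(data, nodes)
    ts <- nt$series
    nT <- ncol(ts)
    if (!is.null(censorLo)) {
        retained <- retainedFrames(censorLo)
        stopifnot(length(retained) == nT)
        ts <- ts[, retained, drop = FALSE]
    }
    if (ncol(ts) < 2L)
        stop("need at least 2 retained frames for correlation")
    R <- rowCorrelation(ts)
    flagged <- attr(R, "flagged")
    if (fisherZ) {
        Rz <- atanh(pmin(pmax(R, -1 + 1e-15), 1 - 1e-15))
        diag(Rz) <- Inf
        R <- Rz
        diag(R)[is.finite(diag(R))] <- Inf
    }
    out <- new("ConnectivityMatrix", values = unname(R),
               nodeKind = nt$kind, fisherZ = fisherZ,
               nFramesUsed = ncol(ts),
               fdThreshold = if (is.null(censorLo)) NA_real_
                             else censorLo@threshold)
    attr(out, "flagged") <- flagged
    out
}
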