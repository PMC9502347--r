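## Per-image measurements: channel extraction, surface detection, SCT/AF-SC,
## autofluorescence-removal thresholding, AROSA and MPD.

#' Extract the acquisition channel for a surrogate
#'
#' Colour-camera acquisitions store the hydrophilic dye's emission in the
#' green channel and the lipophilic dye's in the red channel; grayscale
#' acquisitions pass through unchanged.
#'
#' @param x numeric matrix (grayscale) or \code{height x width x 3} array
#'   (RGB), or a [SectionImage-class] (passed through).
#' @param surrogate \code{"hydrophilic"} (green), \code{"lipophilic"} (red)
#'   or \code{"gray"}.
#' @param scaleUmPerPx,imageId,earId,condition,cutIndex metadata for the
#'   returned [SectionImage-class] when \code{x} is a raw matrix/array.
#' @return a [SectionImage-class] holding the 2-D pixel grid.
#' @examples
#' arr <- array(0, c(8, 8, 3)); arr[, , 2] <- 7
#' max(pixels(extractChannel(arr, "hydrophilic")))
#' @export
extractChannel <- function(x, surrogate = c("gray", "hydrophilic",
                                            "lipophilic"),
                           scaleUmPerPx = 2.84, imageId = NA_character_,
                           earId = NA_character_, condition = NA_character_,
                           cutIndex = NA_integer_) {
  surrogate <- match.arg(surrogate)
  if (is(x, "SectionImage")) return(x)
  channel <- switch(surrogate, gray = "gray", hydrophilic = "green",
                    lipophilic = "red")
  if (is.matrix(x)) {
    if (channel != "gray")
      stop("channel '", channel, "' absent: input image is grayscale")
    px <- x
  } else if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) {
    px <- switch(channel,
                 gray = stop("grayscale extraction from an RGB image is ",
                             "ambiguous; pick a surrogate channel"),
                 green = x[, , 2L], red = x[, , 1L])
  } else {
    stop("x must be a 2-D grayscale matrix or an RGB array")
  }
  SectionImage(px, scaleUmPerPx = scaleUmPerPx, channel = channel,
               imageId = imageId, earId = earId, condition = condition,
               cutIndex = cutIndex)
}

## centred running mean down each column; edges fall back to the raw values
.colSmooth <- function(px, window) {
  if (window <= 1L) return(px)
  sm <- stats::filter(px, rep(1 / window, window), sides = 2)
  sm <- matrix(as.numeric(sm), nrow(px), ncol(px))
  sm[is.na(sm)] <- px[is.na(sm)]
  sm
}

#' Detect the skin surface in each column
#'
#' Estimates a background level from the top image margin (exterior, above
#' the skin) as \code{quantile + offset}, smooths each column profile with a
#' centred running mean, and takes the first row (top-down) whose smoothed
#' intensity reaches the background threshold. The crossing is then refined
#' to the first raw-intensity crossing within one smoothing window, which
#' removes the half-window bias of the smoothed profile. Columns without a
#' crossing are returned as \code{NA}.
#'
#' @param image a [SectionImage-class].
#' @param smoothingWindowPx running-mean window (rows), default 5.
#' @param backgroundQuantile quantile of the top-margin intensities used as
#'   background estimate (default 0.99).
#' @param backgroundMarginPx number of top rows treated as exterior margin.
#' @param offset grey-level offset added to the background quantile.
#' @return integer vector of 1-based surface rows per column (\code{NA} =
#'   not found), with the detection threshold in
#'   \code{attr(, "threshold")}.
#' @section Errors: if no column yields a crossing the function signals an
#'   error of class \code{"dermaquant_surface_not_found"}.
#' @export
detectSurface <- function(image, smoothingWindowPx = 5L,
                          backgroundQuantile = 0.99,
                          backgroundMarginPx = 12L, offset = 6) {
  stopifnot(is(image, "SectionImage"))
  px <- pixels(image)
  H <- nrow(px); W <- ncol(px)
  if (H < smoothingWindowPx)
    stop("image has fewer rows than the smoothing window")
  margin <- px[seq_len(min(backgroundMarginPx, max(H - 1L, 1L))), ,
               drop = FALSE]
  thr <- stats::quantile(margin, backgroundQuantile, names = FALSE) + offset
  sm <- .colSmooth(px, smoothingWindowPx)
  surface <- rep(NA_integer_, W)
  for (j in seq_len(W)) {
    r <- which(sm[, j] >= thr)
    if (length(r) == 0L) next
    r <- r[1L]
    from <- max(1L, r - smoothingWindowPx)
    raw <- which(px[from:H, j] >= thr)
    surface[j] <- if (length(raw)) from + raw[1L] - 1L else r
  }
  if (all(is.na(surface)))
    stop(errorCondition("surface not found in any column (SURFACE_NOT_FOUND)",
                        class = c("dermaquant_surface_not_found", "error",
                                  "condition")))
  attr(surface, "threshold") <- thr
  surface
}

#' Measure stratum corneum thickness and autofluorescence
#'
#' Samples \code{nLines} evenly spaced columns with a detected surface and
#' measures, along each vertical line, the stratum corneum as the segment
#' from the surface row down to the first row whose smoothed intensity
#' drops below a cut level between the local SC-band level and the local
#' viable-tissue level:
#' \code{cut = tissue + boundaryFraction * (SC - tissue)}. The SC level is
#' estimated from the first rows below the surface and the tissue level
#' from a depth window well below any plausible SC. Per line the thickness
#' (px and um via the pixel scale) and the mean grey value per pixel along
#' the segment (the SC autofluorescence, AF-SC) are recorded; lines without
#' a boundary crossing are dropped.
#'
#' @param image a [SectionImage-class].
#' @param surfaceRows per-column surface rows from [detectSurface()].
#' @param nLines number of lines to sample (default 10).
#' @param boundaryFraction position of the SC lower boundary between the
#'   tissue and SC levels (default 0.5).
#' @param smoothingWindowPx running-mean window for the boundary search.
#' @param tissueDepthPx depth window (px below the surface) used to estimate
#'   the viable-tissue level; pixel units keep every pixel-grid measurement
#'   independent of the physical scale, which then enters only through the
#'   px-to-um conversion.
#' @return a [SctProfile-class].
#' @export
measureSct <- function(image, surfaceRows, nLines = 10L,
                       boundaryFraction = 0.5, smoothingWindowPx = 3L,
                       tissueDepthPx = c(21L, 49L)) {
  stopifnot(is(image, "SectionImage"))
  px <- pixels(image)
  H <- nrow(px)
  scl <- pixelScale(image)
  valid <- which(!is.na(surfaceRows) & surfaceRows < H - 2L)
  if (length(valid) < nLines)
    stop("only ", length(valid), " columns with a detected surface, but ",
         nLines, " lines requested")
  cols <- valid[unique(round(seq(1, length(valid), length.out = nLines)))]
  sm <- .colSmooth(px, smoothingWindowPx)
  d1 <- max(1L, as.integer(tissueDepthPx[1]))
  d2 <- max(d1 + 1L, as.integer(tissueDepthPx[2]))

  surf <- integer(0); bottom <- integer(0); afLine <- numeric(0)
  keptCols <- integer(0)
  for (j in cols) {
    s <- surfaceRows[j]
    levelSc <- mean(px[s:min(s + 2L, H), j])
    tRows <- (s + d1):min(s + d2, H)
    tRows <- tRows[tRows <= H]
    if (length(tRows) < 3L) next
    levelTissue <- stats::median(px[tRows, j])
    cut <- levelTissue + boundaryFraction * (levelSc - levelTissue)
    rows <- (s + 1L):H
    b <- rows[which(sm[rows, j] < cut)[1L]]
    if (is.na(b) || b <= s) next
    keptCols <- c(keptCols, j)
    surf <- c(surf, s)
    bottom <- c(bottom, b)
    afLine <- c(afLine, mean(px[s:(b - 1L), j]))
  }
  if (length(keptCols) == 0L)
    stop("no usable SC boundary found on any sampled line")
  new("SctProfile", lineColumns = as.integer(keptCols),
      surfaceRowPx = as.integer(surf), scBottomRowPx = as.integer(bottom),
      sctPx = as.integer(bottom - surf), afScPerLine = afLine,
      scaleUmPerPx = scl)
}

## ---------------------------------------------------------------------------
## Thresholding
## ---------------------------------------------------------------------------

#' Threshold from a pool of autofluorescence intensities
#'
#' The control-statistics threshold core: \code{mean + k * SD} of a pool of
#' dye-free autofluorescence intensities.
#'
#' @param values numeric vector of pooled grey values.
#' @param k SD multiplier (default 3).
#' @return numeric threshold. A constant pool returns its value (SD = 0).
#' @examples
#' thresholdFromPixels(rep(50, 100))   # 50
#' @export
thresholdFromPixels <- function(values, k = 3) {
  if (length(values) == 0L) stop("empty intensity pool")
  s <- stats::sd(values)
  if (is.na(s)) s <- 0
  mean(values) + k * s
}

## pool the stratum corneum band intensities of one control image
.scBandPool <- function(image, ...) {
  surface <- detectSurface(image, ...)
  prof <- measureSct(image, surface)
  bandPx <- max(1L, round(stats::median(prof@sctPx)))
  px <- pixels(image)
  rel <- matrix(seq_len(nrow(px)), nrow(px), ncol(px)) -
    matrix(surface, nrow(px), ncol(px), byrow = TRUE)
  px[!is.na(rel) & rel >= 0 & rel < bandPx]
}

#' Otsu threshold of an integer-valued image region
#'
#' Exhaustively maximizes the between-class variance of the grey-level
#' histogram over all candidate thresholds; pixels strictly above the
#' returned level form the foreground class. Ties resolve to the lowest
#' level.
#'
#' @param values numeric vector of (integer-valued) grey levels.
#' @return the between-class-variance-maximizing grey level.
#' @export
otsuThreshold <- function(values) {
  v <- as.integer(round(values))
  if (length(unique(v)) < 2L)
    stop("Otsu threshold undefined for a constant image")
  lv <- sort(unique(v))
  counts <- tabulate(match(v, lv))
  n <- length(v)
  w0 <- cumsum(counts) / n
  mu <- cumsum(counts * lv) / n
  muT <- mu[length(mu)]
  sigmaB <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  cand <- seq_len(length(lv) - 1L)       # splitting above the top level is void
  lv[cand[which.max(sigmaB[cand])]]
}

#' Compute the autofluorescence-removal threshold
#'
#' Two automated methods to remove the skin's autofluorescence:
#' \describe{
#'   \item{\code{control_stats} (default)}{\code{mean + k * SD} of the
#'     stratum corneum band intensities pooled over one or more dye-free
#'     control images of the same ear and channel. The SC band is the skin's
#'     brightest autofluorescent compartment, so this statistic clears every
#'     autofluorescence structure and guarantees near-zero signal on blank
#'     images.}
#'   \item{\code{otsu}}{the between-class-variance-maximizing grey level of
#'     the target image's own histogram (whole image, or restricted below a
#'     detected surface via \code{surfaceRows}); fallback when no dye-free
#'     controls exist.}
#' }
#'
#' @param x for \code{control_stats}: a [SectionImage-class] or list of
#'   them (dye-free controls); for \code{otsu}: a single non-constant
#'   [SectionImage-class].
#' @param method \code{"control_stats"} or \code{"otsu"}.
#' @param k SD multiplier for \code{control_stats} (default 3).
#' @param surfaceRows optional per-column surface rows restricting the Otsu
#'   histogram to the skin region.
#' @param ... passed to [detectSurface()] for the control-band pooling.
#' @return numeric threshold with attributes \code{method} and \code{k}.
#' @export
computeThreshold <- function(x, method = c("control_stats", "otsu"), k = 3,
                             surfaceRows = NULL, ...) {
  method <- match.arg(method)
  if (method == "control_stats") {
    if (is(x, "SectionImage")) x <- list(x)
    if (!is.list(x) || length(x) == 0L)
      stop("control_stats requires at least one dye-free control image")
    pool <- unlist(lapply(x, .scBandPool, ...))
    thr <- thresholdFromPixels(pool, k = k)
  } else {
    stopifnot(is(x, "SectionImage"))
    px <- pixels(x)
    if (!is.null(surfaceRows)) {
      rel <- matrix(seq_len(nrow(px)), nrow(px), ncol(px)) -
        matrix(surfaceRows, nrow(px), ncol(px), byrow = TRUE)
      px <- px[!is.na(rel) & rel >= 0]
    }
    thr <- otsuThreshold(px)
  }
  attr(thr, "method") <- method
  attr(thr, "k") <- if (method == "control_stats") k else NA_real_
  thr
}

## ---------------------------------------------------------------------------
## AROSA and MPD
## ---------------------------------------------------------------------------

#' Remove the skin's autofluorescence by thresholding
#'
#' Pixels strictly greater than the threshold are retained unchanged; all
#' others are set to zero. Dimensions and metadata are preserved.
#'
#' @param image a [SectionImage-class].
#' @param threshold finite grey-level threshold.
#' @return the masked [SectionImage-class].
#' @export
removeAutofluorescence <- function(image, threshold) {
  stopifnot(is(image, "SectionImage"), is.finite(threshold))
  px <- pixels(image)
  px[px <= threshold] <- 0
  initialize(image, pixels = px)
}

#' AROSA: mean grey value per pixel after autofluorescence removal
#'
#' Sum of the retained grey values divided by the total pixel count of the
#' image, so both suprathreshold intensity and suprathreshold area
#' contribute — matching its role as a surrogate for the total amount of
#' penetrated active ingredient. Set \code{perRetainedPixel = TRUE} for the
#' sensitivity-analysis variant that averages over retained pixels only.
#'
#' @param masked a [SectionImage-class] produced by
#'   [removeAutofluorescence()].
#' @param perRetainedPixel average over retained pixels instead of all
#'   pixels (default \code{FALSE}).
#' @return AROSA in mean grey value per pixel.
#' @export
computeArosa <- function(masked, perRetainedPixel = FALSE) {
  px <- pixels(masked)
  if (perRetainedPixel) {
    n <- sum(px > 0)
    if (n == 0L) return(0)
    sum(px) / n
  } else {
    sum(px) / length(px)
  }
}

#' Mean penetration depth of the suprathreshold signal
#'
#' Depth of each retained pixel is its row offset below the surface row of
#' its column, converted to micrometres; pixels above the surface (e.g. a
#' formulation film on top of the skin) are excluded. The MPD is the
#' unweighted mean depth over all retained sub-surface pixels.
#'
#' @param masked a masked [SectionImage-class] from
#'   [removeAutofluorescence()].
#' @param surfaceRows per-column surface rows from [detectSurface()];
#'   retained pixels in columns with no surface are skipped and counted in
#'   a flag.
#' @param scaleUmPerPx micrometres per pixel; defaults to the image scale.
#' @return a list with \code{mpdUm}, \code{nSignalPx} (all suprathreshold
#'   pixels), \code{nDepthPx} (those entering the depth average) and
#'   \code{flags}.
#' @export
computeMpd <- function(masked, surfaceRows,
                       scaleUmPerPx = pixelScale(masked)) {
  px <- pixels(masked)
  H <- nrow(px); W <- ncol(px)
  stopifnot(length(surfaceRows) == W)
  sig <- px > 0
  nSignal <- sum(sig)
  flagSet <- character(0)
  if (nSignal == 0L)
    return(list(mpdUm = 0, nSignalPx = 0L, nDepthPx = 0L,
                flags = "NO_SIGNAL"))
  surfMat <- matrix(surfaceRows, H, W, byrow = TRUE)
  rel <- matrix(seq_len(H), H, W) - surfMat
  missing <- sig & is.na(surfMat)
  nMissing <- sum(missing)
  if (nMissing > 0L)
    flagSet <- c(flagSet, sprintf("MISSING_SURFACE_COLUMNS:%d",
                                  length(unique(which(missing,
                                                      arr.ind = TRUE)[, 2]))))
  use <- sig & !is.na(surfMat) & rel >= 0
  nDepth <- sum(use)
  if (nDepth == 0L) {
    flagSet <- c(flagSet, "NO_SUBSURFACE_SIGNAL")
    return(list(mpdUm = 0, nSignalPx = as.integer(nSignal), nDepthPx = 0L,
                flags = flagSet))
  }
  list(mpdUm = mean(rel[use]) * scaleUmPerPx,
       nSignalPx = as.integer(nSignal), nDepthPx = as.integer(nDepth),
       flags = flagSet)
}

#' Measure one image end to end
#'
#' Convenience wrapper running the whole per-image chain: surface detection,
#' SCT/AF-SC measurement, autofluorescence removal at the given threshold,
#' AROSA and MPD.
#'
#' @param image a [SectionImage-class].
#' @param threshold grey-level threshold (e.g. from [computeThreshold()]).
#' @param nLines lines for [measureSct()].
#' @param ... passed to [detectSurface()].
#' @return list with \code{profile} ([SctProfile-class]), \code{metrics}
#'   ([PenetrationMetrics-class]) and \code{row}, a one-row data.frame for
#'   tidy per-image tables.
#' @export
measureImage <- function(image, threshold, nLines = 10L, ...) {
  surface <- detectSurface(image, ...)
  profile <- measureSct(image, surface, nLines = nLines)
  masked <- removeAutofluorescence(image, threshold)
  aro <- computeArosa(masked)
  mp <- computeMpd(masked, surface)
  metrics <- new("PenetrationMetrics",
                 thresholdValue = as.numeric(threshold),
                 method = attr(threshold, "method") %||% "fixed",
                 arosaMgvPerPx = if (mp$nSignalPx == 0L) 0 else aro,
                 mpdUm = mp$mpdUm, nSignalPx = mp$nSignalPx,
                 flags = mp$flags)
  row <- data.frame(
    image_id = image@imageId, ear = image@earId,
    condition = image@condition, cut = image@cutIndex,
    sct_um = sctUm(profile), sct_um_sd = sctUmSd(profile),
    af_sc = afSc(profile), threshold = as.numeric(threshold),
    arosa = arosa(metrics), mpd_um = mpdUm(metrics),
    n_signal_px = metrics@nSignalPx,
    flags = paste(metrics@flags, collapse = ";"),
    stringsAsFactors = FALSE)
  list(profile = profile, metrics = metrics, row = row)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
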