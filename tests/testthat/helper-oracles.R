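## Brute-force, loop-based reference implementations used as independent
## oracles for the vectorized package code, plus small fixture helpers.

## threshold masking, pixel by pixel
bfMask <- function(px, threshold) {
  out <- px
  for (i in seq_len(nrow(px)))
    for (j in seq_len(ncol(px)))
      out[i, j] <- if (px[i, j] > threshold) px[i, j] else 0
  out
}

## mean grey value per pixel by explicit accumulation
bfArosa <- function(px) {
  s <- 0
  for (i in seq_len(nrow(px)))
    for (j in seq_len(ncol(px)))
      s <- s + px[i, j]
  s / (nrow(px) * ncol(px))
}

## unweighted mean depth of retained sub-surface pixels
bfMpd <- function(px, surfaceRows, scale) {
  depths <- numeric(0)
  for (j in seq_len(ncol(px))) {
    s <- surfaceRows[j]
    if (is.na(s)) next
    for (i in seq_len(nrow(px)))
      if (px[i, j] > 0 && i >= s) depths <- c(depths, (i - s) * scale)
  }
  if (length(depths) == 0L) 0 else mean(depths)
}

## exhaustive between-class-variance scan over all candidate grey levels
bfOtsu <- function(values) {
  v <- as.integer(round(values))
  levels <- sort(unique(v))
  best <- -Inf; bestT <- levels[1]
  for (t in levels[-length(levels)]) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    sB <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sB > best + 1e-12) { best <- sB; bestT <- t }
  }
  bestT
}

## small fast generator settings for unit tests
quickParams <- function(...) {
  GeneratorParams(imageHeightPx = 96L, imageWidthPx = 64L,
                  hotspotDensity = 0, ...)
}

## a tiny two-condition manifest (one control + one treated per stratum)
tinyManifest <- function(surrogate = "hydrophilic", timepoint = "after",
                         treatedMods = c(dye_amount = 0.5),
                         ears = c("e1", "e2"), minCuts = 2L,
                         minImages = 4L) {
  StudyManifest(
    ears = ears,
    presets = list(
      ConditionPreset(1, surrogate, timepoint),
      ConditionPreset(3, surrogate, timepoint, modifiers = treatedMods)),
    minCuts = minCuts, minImages = minImages)
}

## control-statistics threshold from blank renders of the given parameters
blankThreshold <- function(params, nBlanks = 4L, seedBase = 9000L, k = 3) {
  blank <- do.call(GeneratorParams, modifyList(
    as.list(paramsToList(params)), list(dyeAmount = 0, hotspotDensity = 0)))
  imgs <- lapply(seq_len(nBlanks),
                 function(s) generateSectionImage(blank, seedBase + s)$image)
  computeThreshold(imgs, method = "control_stats", k = k)
}

## GeneratorParams -> constructor argument list
paramsToList <- function(p) {
  nm <- slotNames("GeneratorParams")
  stats::setNames(lapply(nm, function(s) slot(p, s)), nm)
}
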