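#' @import methods
NULL

## ---------------------------------------------------------------------------
## GeneratorParams
## ---------------------------------------------------------------------------

#' Parameters of the synthetic skin-section renderer
#'
#' Describes one synthetic vertical skin-section fluorescence micrograph:
#' geometry (image size, pixel scale, surface position and roughness), tissue
#' optics (stratum corneum thickness, autofluorescence levels, a hydration
#' index that couples the two), the dye signal (deposited amount, e-folding
#' penetration depth, surface-film factor), sebum/bacteria hotspots and
#' camera noise.
#'
#' Hydration is coupled to the stratum corneum the way dehydrated skin
#' behaves under epifluorescence: drier skin scatters more light (higher
#' SC autofluorescence) and is thinner. The effective values used for
#' rendering are
#' \deqn{SCT_{eff} = sctUm \cdot (0.8 + 0.4\,h), \qquad
#'       AF_{eff} = afScLevel \cdot (1.2 - 0.4\,h)}
#' with hydration index \eqn{h \in [0, 1]}, so a fully hydrated SC is thicker
#' and less autofluorescent than a dry one.
#'
#' @slot imageHeightPx,imageWidthPx image size in pixels.
#' @slot scaleUmPerPx physical pixel size in micrometres per pixel
#'   (default 2.84).
#' @slot surfaceRowMeanPx mean row (1-based, top-down) of the skin surface.
#' @slot surfaceRoughnessPx SD of the per-column surface jitter in pixels.
#' @slot sctUm nominal stratum corneum thickness in micrometres (before the
#'   hydration coupling).
#' @slot hydrationIndex hydration index in \[0, 1\]; 1 = fully hydrated.
#' @slot afScLevel nominal mean SC autofluorescence in grey units.
#' @slot afTissueLevel mean viable-tissue autofluorescence in grey units;
#'   must be below \code{afScLevel}.
#' @slot dyeAmount dye amplitude at the surface in grey units (total
#'   deposited signal scales linearly with it); 0 renders a blank.
#' @slot dyeDecayUm e-folding depth of the dye profile in micrometres.
#' @slot depositFactor brightness of the surface film (rows just above the
#'   surface) as a multiple of \code{dyeAmount}.
#' @slot hotspotDensity expected number of bright sebum/bacteria hotspots
#'   per image (Poisson).
#' @slot noiseSd SD of additive Gaussian camera noise in grey units.
#' @slot bitDepth 8 or 16; grey values are clipped to \code{[0, 2^bitDepth-1]}.
#'
#' @seealso [GeneratorParams()] for the user constructor,
#'   [generateSectionImage()] for the renderer.
#' @export
setClass("GeneratorParams",
  representation(
    imageHeightPx     = "integer",
    imageWidthPx      = "integer",
    scaleUmPerPx      = "numeric",
    surfaceRowMeanPx  = "numeric",
    surfaceRoughnessPx = "numeric",
    sctUm             = "numeric",
    hydrationIndex    = "numeric",
    afScLevel         = "numeric",
    afTissueLevel     = "numeric",
    dyeAmount         = "numeric",
    dyeDecayUm        = "numeric",
    depositFactor     = "numeric",
    hotspotDensity    = "numeric",
    noiseSd           = "numeric",
    bitDepth          = "integer"
  )
)

setValidity("GeneratorParams", function(object) {
  msg <- character()
  scalar <- function(x) length(x) == 1L && is.finite(x)
  if (!scalar(object@imageHeightPx) || object@imageHeightPx < 1L ||
      !scalar(object@imageWidthPx) || object@imageWidthPx < 1L)
    msg <- c(msg, "image dimensions must be positive integers")
  if (!scalar(object@scaleUmPerPx) || object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be > 0")
  if (!scalar(object@surfaceRowMeanPx) || object@surfaceRowMeanPx < 0)
    msg <- c(msg, "surfaceRowMeanPx must be >= 0")
  if (!scalar(object@surfaceRoughnessPx) || object@surfaceRoughnessPx < 0)
    msg <- c(msg, "surfaceRoughnessPx must be >= 0")
  if (!scalar(object@sctUm) || object@sctUm <= 0)
    msg <- c(msg, "sctUm must be > 0")
  if (!scalar(object@hydrationIndex) ||
      object@hydrationIndex < 0 || object@hydrationIndex > 1)
    msg <- c(msg, "hydrationIndex must lie in [0, 1]")
  if (!scalar(object@afScLevel) || object@afScLevel <= 0 ||
      !scalar(object@afTissueLevel) || object@afTissueLevel <= 0)
    msg <- c(msg, "autofluorescence levels must be > 0")
  else if (object@afTissueLevel >= object@afScLevel)
    msg <- c(msg, "afTissueLevel must be < afScLevel (SC band is brighter)")
  if (!scalar(object@dyeAmount) || object@dyeAmount < 0)
    msg <- c(msg, "dyeAmount must be >= 0")
  if (!scalar(object@dyeDecayUm) || object@dyeDecayUm <= 0)
    msg <- c(msg, "dyeDecayUm must be > 0")
  if (!scalar(object@depositFactor) || object@depositFactor < 0)
    msg <- c(msg, "depositFactor must be >= 0")
  if (!scalar(object@hotspotDensity) || object@hotspotDensity < 0)
    msg <- c(msg, "hotspotDensity must be >= 0")
  if (!scalar(object@noiseSd) || object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be >= 0")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg) == 0L) {
    ## the rendered SC band must fit below the mean surface position
    sctEffPx <- round(object@sctUm * (0.8 + 0.4 * object@hydrationIndex) /
                        object@scaleUmPerPx)
    if (object@surfaceRowMeanPx + sctEffPx >= object@imageHeightPx)
      msg <- c(msg, "sctUm exceeds the image depth below the surface")
  }
  if (length(msg)) msg else TRUE
})

#' Create generator parameters for synthetic skin sections
#'
#' Returns a [GeneratorParams-class] object. The defaults define the
#' package's canonical synthetic study conditions: a 160 x 160 px field of
#' view at 2.84 um/px, a 20 um stratum corneum over viable tissue with a
#' 1.5-fold SC/tissue autofluorescence contrast, a surface-anchored
#' exponential dye profile with a 40 um e-folding depth, roughly one
#' sebum/bacteria hotspot per field and mild camera noise on an 8-bit range.
#'
#' @param imageHeightPx,imageWidthPx image size in pixels.
#' @param scaleUmPerPx micrometres per pixel.
#' @param surfaceRowMeanPx mean skin-surface row (1-based, top-down).
#' @param surfaceRoughnessPx SD of per-column surface jitter (px).
#' @param sctUm nominal stratum corneum thickness (um).
#' @param hydrationIndex hydration index in \[0, 1\].
#' @param afScLevel,afTissueLevel mean SC / viable-tissue autofluorescence
#'   (grey units); the SC must be brighter.
#' @param dyeAmount dye amplitude at the surface (grey units).
#' @param dyeDecayUm e-folding depth of the dye profile (um).
#' @param depositFactor surface-film brightness as a multiple of
#'   \code{dyeAmount}.
#' @param hotspotDensity expected hotspots per image.
#' @param noiseSd additive Gaussian noise SD (grey units).
#' @param bitDepth 8 or 16.
#' @return A validated [GeneratorParams-class] object.
#' @examples
#' p <- GeneratorParams(sctUm = 56.8)
#' p
#' @export
GeneratorParams <- function(imageHeightPx = 160L, imageWidthPx = 160L,
                            scaleUmPerPx = 2.84,
                            surfaceRowMeanPx = 20, surfaceRoughnessPx = 1.5,
                            sctUm = 20, hydrationIndex = 0.5,
                            afScLevel = 45, afTissueLevel = 30,
                            dyeAmount = 120, dyeDecayUm = 40,
                            depositFactor = 2,
                            hotspotDensity = 1, noiseSd = 5,
                            bitDepth = 8L) {
  new("GeneratorParams",
      imageHeightPx = as.integer(imageHeightPx),
      imageWidthPx = as.integer(imageWidthPx),
      scaleUmPerPx = as.numeric(scaleUmPerPx),
      surfaceRowMeanPx = as.numeric(surfaceRowMeanPx),
      surfaceRoughnessPx = as.numeric(surfaceRoughnessPx),
      sctUm = as.numeric(sctUm),
      hydrationIndex = as.numeric(hydrationIndex),
      afScLevel = as.numeric(afScLevel),
      afTissueLevel = as.numeric(afTissueLevel),
      dyeAmount = as.numeric(dyeAmount),
      dyeDecayUm = as.numeric(dyeDecayUm),
      depositFactor = as.numeric(depositFactor),
      hotspotDensity = as.numeric(hotspotDensity),
      noiseSd = as.numeric(noiseSd),
      bitDepth = as.integer(bitDepth))
}

## ---------------------------------------------------------------------------
## SectionImage
## ---------------------------------------------------------------------------

#' A single skin-section micrograph
#'
#' One field of view of a vertical skin cryosection under epifluorescence,
#' stored as a numeric matrix of non-negative grey values. Rows are indexed
#' top-down: row 1 is exterior (above the skin surface) and depth increases
#' with the row index. The physical pixel size links pixel measurements to
#' micrometres.
#'
#' @slot pixels numeric matrix of grey values (rows top-down).
#' @slot scaleUmPerPx micrometres per pixel (> 0).
#' @slot channel one of \code{"gray"}, \code{"green"}, \code{"red"}.
#' @slot imageId,earId,condition character identifiers (may be empty).
#' @slot cutIndex integer skin-cut index within the biopsy.
#' @export
setClass("SectionImage",
  representation(
    pixels = "matrix",
    scaleUmPerPx = "numeric",
    channel = "character",
    imageId = "character",
    earId = "character",
    condition = "character",
    cutIndex = "integer"
  ),
  prototype(
    scaleUmPerPx = 2.84, channel = "gray",
    imageId = NA_character_, earId = NA_character_,
    condition = NA_character_, cutIndex = NA_integer_
  )
)

setValidity("SectionImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be a numeric matrix")
  else if (any(object@pixels < 0, na.rm = TRUE))
    msg <- c(msg, "pixel grey values must be non-negative")
  if (length(object@scaleUmPerPx) != 1L || !is.finite(object@scaleUmPerPx) ||
      object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be a single positive number")
  if (length(object@channel) != 1L ||
      !(object@channel %in% c("gray", "green", "red")))
    msg <- c(msg, "channel must be one of 'gray', 'green', 'red'")
  if (length(msg)) msg else TRUE
})

#' Construct a SectionImage
#'
#' @param pixels numeric matrix of non-negative grey values, rows top-down.
#' @param scaleUmPerPx micrometres per pixel.
#' @param channel acquisition channel: \code{"gray"}, \code{"green"} or
#'   \code{"red"}.
#' @param imageId,earId,condition optional identifiers.
#' @param cutIndex optional skin-cut index.
#' @return A [SectionImage-class] object.
#' @examples
#' img <- SectionImage(matrix(0, 32, 32))
#' dim(pixels(img))
#' @export
SectionImage <- function(pixels, scaleUmPerPx = 2.84, channel = "gray",
                         imageId = NA_character_, earId = NA_character_,
                         condition = NA_character_, cutIndex = NA_integer_) {
  new("SectionImage", pixels = pixels,
      scaleUmPerPx = as.numeric(scaleUmPerPx), channel = channel,
      imageId = as.character(imageId), earId = as.character(earId),
      condition = as.character(condition), cutIndex = as.integer(cutIndex))
}

## ---------------------------------------------------------------------------
## GroundTruth
## ---------------------------------------------------------------------------

#' Ground truth of a rendered synthetic section
#'
#' Records the effective generator values actually used to render one
#' synthetic image (after the hydration coupling), the seed, and the true
#' per-column surface rows, so every downstream measurement can be checked
#' against truth.
#'
#' @slot effective named numeric vector of effective parameter values,
#'   including \code{sctEffUm}, \code{sctPx}, \code{afScEff},
#'   \code{afTissueLevel}, \code{dyeAmount}, \code{dyeDecayUm},
#'   \code{noiseSd}, \code{scaleUmPerPx} and friends.
#' @slot seed integer seed the renderer was called with.
#' @slot surfaceRows integer vector of true surface rows (1-based) per column.
#' @export
setClass("GroundTruth",
  representation(
    effective = "numeric",
    seed = "integer",
    surfaceRows = "integer"
  )
)

## ---------------------------------------------------------------------------
## SctProfile
## ---------------------------------------------------------------------------

#' Per-line stratum corneum thickness profile
#'
#' Result of measuring the stratum corneum along vertical lines: per sampled
#' column the surface row, the SC lower-boundary row, the thickness in pixels
#' and the mean grey value along the surface-to-boundary segment (the SC
#' autofluorescence, AF-SC). Thickness in micrometres is derived through the
#' pixel scale.
#'
#' @slot lineColumns integer columns sampled.
#' @slot surfaceRowPx,scBottomRowPx integer rows per line (1-based); the
#'   SC segment is the half-open row range \code{[surface, bottom)}.
#' @slot sctPx integer thickness per line in pixels (> 0).
#' @slot afScPerLine mean grey value per pixel along each SC line.
#' @slot scaleUmPerPx micrometres per pixel.
#' @export
setClass("SctProfile",
  representation(
    lineColumns = "integer",
    surfaceRowPx = "integer",
    scBottomRowPx = "integer",
    sctPx = "integer",
    afScPerLine = "numeric",
    scaleUmPerPx = "numeric"
  )
)

setValidity("SctProfile", function(object) {
  n <- length(object@lineColumns)
  msg <- character()
  if (length(object@surfaceRowPx) != n || length(object@scBottomRowPx) != n ||
      length(object@sctPx) != n || length(object@afScPerLine) != n)
    msg <- c(msg, "per-line slots must have equal length")
  if (n > 0L && any(object@sctPx <= 0L))
    msg <- c(msg, "sctPx must be > 0 for every retained line")
  if (n > 0L &&
      !all(object@sctPx == object@scBottomRowPx - object@surfaceRowPx))
    msg <- c(msg, "sctPx must equal scBottomRowPx - surfaceRowPx")
  if (length(object@scaleUmPerPx) != 1L || object@scaleUmPerPx <= 0)
    msg <- c(msg, "scaleUmPerPx must be a single positive number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PenetrationMetrics
## ---------------------------------------------------------------------------

#' Per-image penetration metrics
#'
#' Holds the autofluorescence-removal threshold, the AROSA value (mean grey
#' value per pixel remaining after thresholding, a surrogate for the total
#' amount of penetrated active ingredient) and the mean penetration depth
#' (MPD, um) of one image, plus bookkeeping flags.
#'
#' @slot thresholdValue grey-level threshold used.
#' @slot method threshold method tag (\code{"control_stats"} or
#'   \code{"otsu"}).
#' @slot arosaMgvPerPx AROSA in mean grey value per pixel (>= 0).
#' @slot mpdUm mean penetration depth in micrometres (>= 0).
#' @slot nSignalPx number of suprathreshold pixels (>= 0).
#' @slot flags character flags, e.g. \code{"NO_SIGNAL"}.
#' @export
setClass("PenetrationMetrics",
  representation(
    thresholdValue = "numeric",
    method = "character",
    arosaMgvPerPx = "numeric",
    mpdUm = "numeric",
    nSignalPx = "integer",
    flags = "character"
  )
)

setValidity("PenetrationMetrics", function(object) {
  msg <- character()
  if (object@arosaMgvPerPx < 0) msg <- c(msg, "arosaMgvPerPx must be >= 0")
  if (object@mpdUm < 0) msg <- c(msg, "mpdUm must be >= 0")
  if (object@nSignalPx < 0L) msg <- c(msg, "nSignalPx must be >= 0")
  noSig <- "NO_SIGNAL" %in% object@flags
  if ((object@nSignalPx == 0L) != noSig)
    msg <- c(msg, "NO_SIGNAL flag must be set iff nSignalPx == 0")
  if (noSig && (object@arosaMgvPerPx != 0 || object@mpdUm != 0))
    msg <- c(msg, "NO_SIGNAL implies arosa == 0 and mpd == 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ConditionPreset / StudyManifest
## ---------------------------------------------------------------------------

#' A study condition preset
#'
#' One cell of the study design: skin section (1 = no treatment / control,
#' 2 = professional treatment without massage, 3 = professional treatment
#' with massage), active-ingredient surrogate (hydrophilic or lipophilic)
#' and application time point (during or after the treatment). The
#' \code{modifiers} map generator parameter names (snake_case, e.g.
#' \code{dye_amount}) to multiplicative factors applied on top of the base
#' generator parameters; control presets carry no modification.
#'
#' @slot label unique condition label.
#' @slot skinSection integer in 1..3.
#' @slot surrogate \code{"hydrophilic"} or \code{"lipophilic"}.
#' @slot timepoint \code{"during"} or \code{"after"}.
#' @slot modifiers named numeric vector of multiplicative factors.
#' @export
setClass("ConditionPreset",
  representation(
    label = "character",
    skinSection = "integer",
    surrogate = "character",
    timepoint = "character",
    modifiers = "numeric"
  )
)

setValidity("ConditionPreset", function(object) {
  msg <- character()
  if (!(object@skinSection %in% 1:3))
    msg <- c(msg, "skinSection must be 1, 2 or 3")
  if (!(object@surrogate %in% c("hydrophilic", "lipophilic")))
    msg <- c(msg, "surrogate must be 'hydrophilic' or 'lipophilic'")
  if (!(object@timepoint %in% c("during", "after")))
    msg <- c(msg, "timepoint must be 'during' or 'after'")
  if (length(object@modifiers) &&
      (is.null(names(object@modifiers)) || any(names(object@modifiers) == "")))
    msg <- c(msg, "modifiers must be a named numeric vector")
  if (object@skinSection == 1L &&
      length(object@modifiers) && any(object@modifiers != 1))
    msg <- c(msg, "control presets (skin section 1) must have all modifiers = 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ConditionPreset
#'
#' @param skinSection 1 (control), 2 (treatment without massage) or
#'   3 (treatment with massage).
#' @param surrogate \code{"hydrophilic"} or \code{"lipophilic"}.
#' @param timepoint \code{"during"} or \code{"after"}.
#' @param modifiers named numeric vector of multiplicative factors on
#'   generator parameters (snake_case names such as \code{dye_amount},
#'   \code{dye_decay_um}, \code{hydration_index}).
#' @param label condition label; defaults to
#'   \code{"s<section>_<surrogate>_<timepoint>"}.
#' @return A [ConditionPreset-class] object.
#' @export
ConditionPreset <- function(skinSection, surrogate, timepoint,
                            modifiers = numeric(0), label = NULL) {
  if (is.null(label))
    label <- sprintf("s%d_%s_%s", as.integer(skinSection), surrogate,
                     timepoint)
  mods <- unlist(modifiers)
  if (is.null(mods)) mods <- numeric(0)
  new("ConditionPreset", label = label,
      skinSection = as.integer(skinSection), surrogate = surrogate,
      timepoint = timepoint, modifiers = mods)
}

#' Study manifest
#'
#' The design of one penetration study: ears (the independent biological
#' unit), the condition presets, and the per-biopsy minimum counts of skin
#' cuts and images. Skin section 1 is the untreated control of each
#' (surrogate, timepoint) stratum.
#'
#' @slot ears character ear identifiers.
#' @slot presets list of [ConditionPreset-class] objects with unique labels.
#' @slot minCuts minimum skin cuts per biopsy (default 12).
#' @slot minImages minimum images per biopsy (default 40).
#' @export
setClass("StudyManifest",
  representation(
    ears = "character",
    presets = "list",
    minCuts = "integer",
    minImages = "integer"
  )
)

setValidity("StudyManifest", function(object) {
  msg <- character()
  if (length(object@ears) < 1L) msg <- c(msg, "at least one ear required")
  if (length(object@presets) < 1L)
    msg <- c(msg, "at least one condition preset required")
  if (!all(vapply(object@presets, is, logical(1), "ConditionPreset")))
    msg <- c(msg, "presets must all be ConditionPreset objects")
  else {
    labs <- vapply(object@presets, function(p) p@label, character(1))
    if (anyDuplicated(labs))
      msg <- c(msg, "condition labels must be unique")
    strata <- unique(vapply(object@presets,
                            function(p) paste(p@surrogate, p@timepoint),
                            character(1)))
    for (s in strata) {
      nCtrl <- sum(vapply(object@presets, function(p)
        paste(p@surrogate, p@timepoint) == s && p@skinSection == 1L,
        logical(1)))
      if (nCtrl != 1L)
        msg <- c(msg, sprintf(
          "stratum '%s' must contain exactly one control (section 1) preset, found %d",
          s, nCtrl))
    }
  }
  if (object@minCuts < 1L || object@minImages < 1L)
    msg <- c(msg, "per-biopsy minimums must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StudyManifest
#'
#' @param ears ear identifiers (default three independent ears).
#' @param presets list of [ConditionPreset-class] objects; defaults to the
#'   full 3-section x 2-surrogate x 2-timepoint design from
#'   [defaultPresets()].
#' @param minCuts minimum skin cuts per biopsy (default 12).
#' @param minImages minimum images per biopsy (default 40).
#' @return A [StudyManifest-class] object.
#' @export
StudyManifest <- function(ears = c("ear1", "ear2", "ear3"),
                          presets = defaultPresets(),
                          minCuts = 12L, minImages = 40L) {
  new("StudyManifest", ears = as.character(ears), presets = presets,
      minCuts = as.integer(minCuts), minImages = as.integer(minImages))
}

## ---------------------------------------------------------------------------
## PenetrationStudy
## ---------------------------------------------------------------------------

#' A rendered synthetic study
#'
#' Container for a full synthetic dataset: the rendered images, the truth
#' table (one row per image, recording the effective generator values) and
#' the manifest that produced them.
#'
#' @slot images list of [SectionImage-class] objects.
#' @slot truth data.frame keyed by \code{image_id}.
#' @slot manifest the [StudyManifest-class] used.
#' @export
setClass("PenetrationStudy",
  representation(
    images = "list",
    truth = "data.frame",
    manifest = "StudyManifest"
  )
)

## ---------------------------------------------------------------------------
## GroupComparison
## ---------------------------------------------------------------------------

#' Result of an assumption-driven group comparison
#'
#' Captures the full decision path of the statistical workflow: per-group
#' Shapiro-Wilk normality checks, Levene's variance-homogeneity test, the
#' selected omnibus test (ANOVA, Welch ANOVA or Kruskal-Wallis), the paired
#' post hoc procedure (Tukey, Games-Howell or Dunn) with significance stars,
#' and an ordered trace of every rule that fired.
#'
#' @slot metric name of the compared metric.
#' @slot omnibus \code{"ANOVA"}, \code{"Welch-ANOVA"} or
#'   \code{"Kruskal-Wallis"}.
#' @slot statistic,p omnibus test statistic and p value.
#' @slot assumptions list with elements \code{shapiro} (data.frame) and
#'   \code{levene} (list or NULL).
#' @slot postHoc \code{"Tukey"}, \code{"Games-Howell"} or \code{"Dunn"}.
#' @slot pairwise data.frame: group1, group2, estimate, statistic, p_adj,
#'   stars.
#' @slot trace character vector of decision-rule firings, in order.
#' @slot alpha significance level used.
#' @export
setClass("GroupComparison",
  representation(
    metric = "character",
    omnibus = "character",
    statistic = "numeric",
    p = "numeric",
    assumptions = "list",
    postHoc = "character",
    pairwise = "data.frame",
    trace = "character",
    alpha = "numeric"
  )
)

setValidity("GroupComparison", function(object) {
  msg <- character()
  pairing <- c("ANOVA" = "Tukey", "Welch-ANOVA" = "Games-Howell",
               "Kruskal-Wallis" = "Dunn")
  if (!(object@omnibus %in% names(pairing)))
    msg <- c(msg, "unknown omnibus test")
  else if (object@postHoc != pairing[[object@omnibus]])
    msg <- c(msg, sprintf("omnibus %s must pair with %s post hoc",
                          object@omnibus, pairing[[object@omnibus]]))
  if (!is.na(object@p) && (object@p < 0 || object@p > 1))
    msg <- c(msg, "omnibus p must lie in [0, 1]")
  if (nrow(object@pairwise)) {
    pA <- object@pairwise$p_adj
    if (any(pA < 0 | pA > 1, na.rm = TRUE))
      msg <- c(msg, "adjusted p values must lie in [0, 1]")
  }
  if (length(object@trace) < 1L)
    msg <- c(msg, "decision trace must be non-empty")
  if (length(msg)) msg else TRUE
})
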