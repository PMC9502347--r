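## Synthetic vertical skin-section renderer with full ground truth.

#' Effective generator values after the hydration coupling
#'
#' Applies the hydration coupling to the nominal parameters: a more hydrated
#' stratum corneum is thicker and less autofluorescent,
#' \code{sctEffUm = sctUm * (0.8 + 0.4 * h)} and
#' \code{afScEff = afScLevel * (1.2 - 0.4 * h)}.
#'
#' @param params a [GeneratorParams-class].
#' @return named numeric vector of effective values, including the SC band
#'   thickness in pixels (\code{sctPx}).
#' @export
effectiveParams <- function(params) {
  stopifnot(is(params, "GeneratorParams"))
  h <- params@hydrationIndex
  sctEffUm <- params@sctUm * (0.8 + 0.4 * h)
  afScEff <- params@afScLevel * (1.2 - 0.4 * h)
  c(imageHeightPx = params@imageHeightPx,
    imageWidthPx = params@imageWidthPx,
    scaleUmPerPx = params@scaleUmPerPx,
    surfaceRowMeanPx = params@surfaceRowMeanPx,
    surfaceRoughnessPx = params@surfaceRoughnessPx,
    hydrationIndex = h,
    sctEffUm = sctEffUm,
    sctPx = max(1, round(sctEffUm / params@scaleUmPerPx)),
    afScEff = afScEff,
    afTissueLevel = params@afTissueLevel,
    dyeAmount = params@dyeAmount,
    dyeDecayUm = params@dyeDecayUm,
    depositFactor = params@depositFactor,
    hotspotDensity = params@hotspotDensity,
    noiseSd = params@noiseSd,
    bitDepth = params@bitDepth)
}

#' Render one synthetic skin-section image
#'
#' Renders, top to bottom: dark exterior background, a thin bright dye film
#' just above the skin surface (when dye is present), the skin surface at
#' \code{surfaceRowMeanPx} with per-column Gaussian jitter, the stratum
#' corneum band (thickness \code{round(sctEffUm / scale)} px at the
#' effective SC autofluorescence level), viable tissue at the tissue
#' autofluorescence level, plus a dye signal decaying exponentially with
#' depth below the surface, Poisson-count sebum/bacteria hotspots, and
#' additive Gaussian camera noise. Grey values are rounded and clipped to
#' the bit depth. Rendering is bit-exact reproducible for a given seed.
#'
#' @param params a [GeneratorParams-class].
#' @param seed integer seed; same params + seed give pixel-identical images.
#' @param imageId,earId,condition,cutIndex identifiers stored in the image.
#' @return list with elements \code{image} ([SectionImage-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' r <- generateSectionImage(GeneratorParams(), seed = 1)
#' r$image
#' trueValues(r$truth)[["sctPx"]]
#' @export
generateSectionImage <- function(params, seed,
                                 imageId = NA_character_,
                                 earId = NA_character_,
                                 condition = NA_character_,
                                 cutIndex = NA_integer_) {
  stopifnot(is(params, "GeneratorParams"))
  validObject(params)
  seed <- as.integer(seed)
  eff <- effectiveParams(params)
  H <- params@imageHeightPx
  W <- params@imageWidthPx
  scl <- params@scaleUmPerPx
  sctPx <- as.integer(eff[["sctPx"]])

  set.seed(seed)
  surface <- round(stats::rnorm(W, params@surfaceRowMeanPx,
                                params@surfaceRoughnessPx))
  surface <- as.integer(pmin(pmax(surface, 3L), H - sctPx - 1L))

  rowIdx <- matrix(seq_len(H), H, W)
  surfMat <- matrix(surface, H, W, byrow = TRUE)
  rel <- rowIdx - surfMat                     # px below surface; < 0 exterior

  img <- matrix(0, H, W)
  img[rel >= 0 & rel < sctPx] <- eff[["afScEff"]]
  img[rel >= sctPx] <- params@afTissueLevel

  if (params@dyeAmount > 0) {
    below <- rel >= 0
    img[below] <- img[below] + params@dyeAmount *
      exp(-(rel[below] * scl) / params@dyeDecayUm)
    ## surface film: formulation remaining on top of the skin
    film <- rel >= -2 & rel < 0
    img[film] <- img[film] + params@depositFactor * params@dyeAmount
  }

  nSpots <- stats::rpois(1L, params@hotspotDensity)
  if (nSpots > 0 && H >= 5L && W >= 5L) {
    for (i in seq_len(nSpots)) {
      cc <- sample(2:(W - 1L), 1L)
      lo <- min(surface[cc] + 1L, H - 1L)
      rr <- sample(lo:(H - 1L), 1L)
      rows <- max(1L, rr - 1L):min(H, rr + 1L)
      cols <- max(1L, cc - 1L):min(W, cc + 1L)
      img[rows, cols] <- img[rows, cols] + 1.6 * eff[["afScEff"]]
    }
  }

  if (params@noiseSd > 0)
    img <- img + stats::rnorm(H * W, 0, params@noiseSd)

  maxGrey <- 2^params@bitDepth - 1
  img <- round(pmin(pmax(img, 0), maxGrey))

  image <- SectionImage(img, scaleUmPerPx = scl, channel = "gray",
                        imageId = imageId, earId = earId,
                        condition = condition, cutIndex = cutIndex)
  truth <- new("GroundTruth", effective = eff, seed = seed,
               surfaceRows = surface)
  list(image = image, truth = truth)
}

#' Embed a grayscale render into an RGB acquisition
#'
#' Places the grayscale pixel grid into the acquisition channel a colour
#' camera would record for the given surrogate: green for the hydrophilic
#' dye, red for the lipophilic dye. The other channels are zero.
#'
#' @param image a [SectionImage-class] (grayscale).
#' @param surrogate \code{"hydrophilic"} (green) or \code{"lipophilic"}
#'   (red).
#' @return numeric array \code{height x width x 3}.
#' @seealso [extractChannel()]
#' @export
renderRGB <- function(image, surrogate = c("hydrophilic", "lipophilic")) {
  surrogate <- match.arg(surrogate)
  px <- pixels(image)
  arr <- array(0, dim = c(nrow(px), ncol(px), 3L))
  arr[, , if (surrogate == "hydrophilic") 2L else 1L] <- px
  arr
}

## ---------------------------------------------------------------------------
## Presets
## ---------------------------------------------------------------------------

## map snake_case preset field names to GeneratorParams slots
.paramFieldMap <- c(
  image_height_px = "imageHeightPx", image_width_px = "imageWidthPx",
  scale_um_per_px = "scaleUmPerPx", surface_row_mean_px = "surfaceRowMeanPx",
  surface_roughness_px = "surfaceRoughnessPx", sct_um = "sctUm",
  hydration_index = "hydrationIndex", af_sc_level = "afScLevel",
  af_tissue_level = "afTissueLevel", dye_amount = "dyeAmount",
  dye_decay_um = "dyeDecayUm", deposit_factor = "depositFactor",
  hotspot_density = "hotspotDensity", noise_sd = "noiseSd")

#' Apply multiplicative modifiers to generator parameters
#'
#' Multiplies the named generator fields by the given factors. The hydration
#' index is clamped back into \[0, 1\] after modification.
#'
#' @param params a [GeneratorParams-class].
#' @param modifiers named numeric vector; names are snake_case generator
#'   field names (e.g. \code{dye_amount}, \code{dye_decay_um},
#'   \code{hydration_index}).
#' @return a modified, validated [GeneratorParams-class].
#' @export
applyModifiers <- function(params, modifiers) {
  if (length(modifiers) == 0L) return(params)
  if (is.null(names(modifiers)) || any(names(modifiers) == ""))
    stop("modifiers must be named")
  unknown <- setdiff(names(modifiers), names(.paramFieldMap))
  if (length(unknown))
    stop("unknown generator fields in modifiers: ",
         paste(unknown, collapse = ", "))
  for (nm in names(modifiers)) {
    slotName <- .paramFieldMap[[nm]]
    value <- slot(params, slotName) * modifiers[[nm]]
    if (slotName == "hydrationIndex") value <- min(max(value, 0), 1)
    if (slotName %in% c("imageHeightPx", "imageWidthPx"))
      value <- as.integer(round(value))
    slot(params, slotName) <- value
  }
  validObject(params)
  params
}

#' Condition presets of the canonical study design
#'
#' Reads the versioned preset configuration and returns the twelve
#' [ConditionPreset-class] objects of the full design: three skin sections
#' (1 untreated control, 2 professional treatment without massage,
#' 3 professional treatment with massage) x two surrogates (hydrophilic /
#' lipophilic) x two application time points (during / after the
#' treatment). Surrogate-level factors (e.g. the dye's penetration depth
#' scale) apply to every condition of that surrogate including its control,
#' so control presets still carry no treatment modification.
#'
#' @param file YAML preset file; defaults to the configuration shipped with
#'   the package.
#' @return list of [ConditionPreset-class] objects.
#' @export
defaultPresets <- function(file = system.file("extdata", "presets.yaml",
                                              package = "dermaquant")) {
  cfg <- yaml::read_yaml(file)
  surro <- cfg$surrogates
  out <- list()
  for (cond in cfg$conditions) {
    sFac <- unlist(surro[[cond$surrogate]])
    mods <- unlist(cond$modifiers)
    if (is.null(mods)) mods <- numeric(0)
    ## combine surrogate-level factors with treatment modifiers; the
    ## treatment modifiers alone define the preset invariants (control = 1)
    comb <- mods
    for (nm in names(sFac)) {
      comb[nm] <- if (nm %in% names(comb)) comb[[nm]] * sFac[[nm]] else sFac[[nm]]
    }
    p <- ConditionPreset(cond$skin_section, cond$surrogate, cond$timepoint,
                         modifiers = mods)
    attr(p, "combinedModifiers") <- comb
    out[[p@label]] <- p
  }
  out
}

## effective modifiers for rendering: surrogate factors x treatment modifiers
.combinedModifiers <- function(preset) {
  cm <- attr(preset, "combinedModifiers")
  if (is.null(cm)) preset@modifiers else cm
}

## ---------------------------------------------------------------------------
## Study generation
## ---------------------------------------------------------------------------

#' Generate a full synthetic study
#'
#' Renders images for every (ear x condition) cell of the manifest. Each
#' biopsy contributes \code{imagesPerBiopsy} images spread over
#' \code{cutsPerBiopsy} skin cuts, so with the default three ears and 40
#' images per biopsy every condition holds at least 120 images. Per-ear
#' biological variability is emulated with multiplicative log-normal random
#' effects: one factor per ear on both autofluorescence levels (preserving
#' the SC > tissue contrast) and one on the SC thickness.
#'
#' All randomness flows from \code{seed}: ear effects and per-image seeds
#' are drawn once from it, so the same call is bit-reproducible.
#'
#' @param manifest a [StudyManifest-class].
#' @param base base [GeneratorParams-class]; per-condition presets multiply
#'   onto it.
#' @param seed integer root seed.
#' @param imagesPerBiopsy,cutsPerBiopsy images and cuts per (ear, condition)
#'   biopsy; default to the manifest minimums.
#' @param earSdLog SD of the log-normal per-ear random effects (default
#'   0.1, i.e. about 10\% biological variability).
#' @return a [PenetrationStudy-class] with an images list and a truth table
#'   (one row per image).
#' @examples
#' m <- StudyManifest(ears = "e1",
#'                    presets = defaultPresets()[c("s1_hydrophilic_after",
#'                                                 "s3_hydrophilic_after")],
#'                    minCuts = 1, minImages = 2)
#' st <- generateStudy(m, GeneratorParams(imageHeightPx = 96,
#'                                        imageWidthPx = 64), seed = 1)
#' st
#' @export
generateStudy <- function(manifest, base = GeneratorParams(), seed = 1L,
                          imagesPerBiopsy = manifest@minImages,
                          cutsPerBiopsy = manifest@minCuts,
                          earSdLog = 0.1) {
  stopifnot(is(manifest, "StudyManifest"), is(base, "GeneratorParams"))
  validObject(manifest)
  if (length(manifest@presets) == 0L) stop("empty preset list")
  labels <- vapply(manifest@presets, function(p) p@label, character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")

  set.seed(as.integer(seed))
  nEars <- length(manifest@ears)
  earAfFac <- exp(stats::rnorm(nEars, 0, earSdLog))
  earSctFac <- exp(stats::rnorm(nEars, 0, earSdLog))
  names(earAfFac) <- names(earSctFac) <- manifest@ears

  nTotal <- nEars * length(manifest@presets) * imagesPerBiopsy
  imageSeeds <- sample.int(.Machine$integer.max - 1L, nTotal)

  images <- vector("list", nTotal)
  truthRows <- vector("list", nTotal)
  k <- 0L
  for (ear in manifest@ears) {
    for (preset in manifest@presets) {
      cond <- applyModifiers(base, .combinedModifiers(preset))
      cond@afScLevel <- cond@afScLevel * earAfFac[[ear]]
      cond@afTissueLevel <- cond@afTissueLevel * earAfFac[[ear]]
      cond@sctUm <- cond@sctUm * earSctFac[[ear]]
      validObject(cond)
      cuts <- rep(seq_len(cutsPerBiopsy), length.out = imagesPerBiopsy)
      for (i in seq_len(imagesPerBiopsy)) {
        k <- k + 1L
        id <- sprintf("%s_%s_c%02d_i%03d", ear, preset@label, cuts[i], i)
        r <- generateSectionImage(cond, imageSeeds[k], imageId = id,
                                  earId = ear, condition = preset@label,
                                  cutIndex = cuts[i])
        images[[k]] <- r$image
        eff <- trueValues(r$truth)
        truthRows[[k]] <- data.frame(
          image_id = id, ear = ear, condition = preset@label,
          section = preset@skinSection, surrogate = preset@surrogate,
          timepoint = preset@timepoint, cut = cuts[i], seed = imageSeeds[k],
          t(eff), stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  new("PenetrationStudy", images = images, truth = truth,
      manifest = manifest)
}

## ---------------------------------------------------------------------------
## Dataset I/O
## ---------------------------------------------------------------------------

#' Write a synthetic study to disk
#'
#' Writes one TIFF per image (bit depth preserved), the truth table as CSV
#' and the manifest as JSON into \code{dir}. The layout is re-loadable with
#' [readDataset()] and by the pipeline.
#'
#' @param study a [PenetrationStudy-class].
#' @param dir target directory (created if needed).
#' @param overwrite overwrite an existing dataset in \code{dir}?
#' @return invisibly, a list with the written \code{images}, \code{truth}
#'   and \code{manifest} paths.
#' @export
writeDataset <- function(study, dir, overwrite = FALSE) {
  stopifnot(is(study, "PenetrationStudy"))
  truthPath <- file.path(dir, "truth.csv")
  if (file.exists(truthPath) && !overwrite)
    stop("dataset already exists in '", dir, "'; use overwrite = TRUE")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory '", dir, "'")

  bits <- as.integer(study@truth$bitDepth[1])
  maxGrey <- 2^bits - 1
  paths <- character(length(study@images))
  for (i in seq_along(study@images)) {
    im <- study@images[[i]]
    paths[i] <- file.path(dir, "images", paste0(im@imageId, ".tif"))
    tiff::writeTIFF(pixels(im) / maxGrey, paths[i], bits.per.sample = bits)
  }
  utils::write.csv(study@truth, truthPath, row.names = FALSE)
  m <- study@manifest
  manifestPath <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(
    ears = m@ears, min_cuts = m@minCuts, min_images = m@minImages,
    presets = lapply(m@presets, function(p) list(
      label = p@label, skin_section = p@skinSection,
      surrogate = p@surrogate, timepoint = p@timepoint,
      modifiers = as.list(p@modifiers),
      combined_modifiers = as.list(.combinedModifiers(p))))),
    manifestPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(images = paths, truth = truthPath,
                 manifest = manifestPath))
}

#' Read a study written by writeDataset
#'
#' @param dir dataset directory containing \code{images/}, \code{truth.csv}
#'   and \code{manifest.json}.
#' @return a [PenetrationStudy-class].
#' @export
readDataset <- function(dir) {
  truthPath <- file.path(dir, "truth.csv")
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(truthPath) || !file.exists(manifestPath))
    stop("'", dir, "' does not contain a dermaquant dataset")
  truth <- utils::read.csv(truthPath, stringsAsFactors = FALSE)
  mj <- jsonlite::read_json(manifestPath, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  presets <- lapply(mj$presets, function(p) {
    cp <- ConditionPreset(p$skin_section, p$surrogate, p$timepoint,
                          modifiers = unlist(p$modifiers), label = p$label)
    attr(cp, "combinedModifiers") <- unlist(p$combined_modifiers)
    cp
  })
  names(presets) <- vapply(presets, function(p) p@label, character(1))
  manifest <- new("StudyManifest", ears = as.character(mj$ears),
                  presets = presets, minCuts = as.integer(mj$min_cuts),
                  minImages = as.integer(mj$min_images))
  images <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    f <- file.path(dir, "images", paste0(truth$image_id[i], ".tif"))
    if (!file.exists(f)) stop("missing image file: ", f)
    px <- tiff::readTIFF(f, as.is = TRUE)
    storage.mode(px) <- "double"
    images[[i]] <- SectionImage(px,
      scaleUmPerPx = truth$scaleUmPerPx[i], channel = "gray",
      imageId = truth$image_id[i], earId = truth$ear[i],
      condition = truth$condition[i], cutIndex = truth$cut[i])
  }
  new("PenetrationStudy", images = images, truth = truth,
      manifest = manifest)
}
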