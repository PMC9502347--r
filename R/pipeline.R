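## End-to-end orchestration: dataset generation or ingestion -> per-image
## metrics -> aggregation / normalization / compartment calls -> statistics
## -> CSV/JSON artifacts with a persisted effective config and log.

#' Create a pipeline configuration
#'
#' All knobs of one pipeline run. The defaults reproduce the canonical
#' study constants: 2.84 um/px, alpha 0.05, three ears, at least 12 cuts
#' and 40 images per biopsy, control-statistics thresholding with k = 3 and
#' an epidermis thickness of 110 um. The configuration is a plain named
#' list and round-trips through YAML.
#'
#' @param inputDir dataset directory from [writeDataset()], or \code{NULL}
#'   to generate a synthetic study.
#' @param presetFile preset YAML for synthetic generation.
#' @param outDir output directory for run artifacts.
#' @param seed root seed; all randomness of the run flows from it.
#' @param ears number of ears for synthetic generation.
#' @param imagesPerBiopsy,cutsPerBiopsy synthetic design counts.
#' @param scaleUmPerPx pixel scale (um/px).
#' @param thresholdMethod \code{"control_stats"} or \code{"otsu"}.
#' @param thresholdK SD multiplier for control-statistics thresholding.
#' @param nLines lines per image for the SCT measurement.
#' @param smoothingWindowPx,backgroundQuantile,backgroundMarginPx,offset
#'   surface-detection parameters, see [detectSurface()].
#' @param boundaryFraction SC lower-boundary fraction, see [measureSct()].
#' @param epidermisUm epidermis thickness for compartment calls (um).
#' @param alpha significance level.
#' @param baseParams named list overriding [GeneratorParams()] defaults for
#'   synthetic generation.
#' @return named list of class \code{"dermaquantConfig"}.
#' @export
pipelineConfig <- function(inputDir = NULL,
                           presetFile = system.file("extdata", "presets.yaml",
                                                    package = "dermaquant"),
                           outDir = tempfile("dermaquant_run_"),
                           seed = 1L, ears = 3L,
                           imagesPerBiopsy = 40L, cutsPerBiopsy = 12L,
                           scaleUmPerPx = 2.84,
                           thresholdMethod = "control_stats",
                           thresholdK = 3,
                           nLines = 10L, smoothingWindowPx = 5L,
                           backgroundQuantile = 0.99,
                           backgroundMarginPx = 12L, offset = 6,
                           boundaryFraction = 0.5, epidermisUm = 110,
                           alpha = 0.05, baseParams = list()) {
  cfg <- list(inputDir = inputDir, presetFile = presetFile, outDir = outDir,
              seed = as.integer(seed), ears = as.integer(ears),
              imagesPerBiopsy = as.integer(imagesPerBiopsy),
              cutsPerBiopsy = as.integer(cutsPerBiopsy),
              scaleUmPerPx = scaleUmPerPx,
              thresholdMethod = thresholdMethod, thresholdK = thresholdK,
              nLines = as.integer(nLines),
              smoothingWindowPx = as.integer(smoothingWindowPx),
              backgroundQuantile = backgroundQuantile,
              backgroundMarginPx = as.integer(backgroundMarginPx),
              offset = offset, boundaryFraction = boundaryFraction,
              epidermisUm = epidermisUm, alpha = alpha,
              baseParams = baseParams)
  class(cfg) <- c("dermaquantConfig", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param file YAML path.
#' @return [readPipelineConfig()] returns a \code{"dermaquantConfig"} list;
#'   [writePipelineConfig()] returns \code{file} invisibly.
#' @export
readPipelineConfig <- function(file) {
  raw <- yaml::read_yaml(file)
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param config a configuration from [pipelineConfig()].
#' @export
writePipelineConfig <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

.logLine <- function(log, ...) c(log, paste0(format(length(log) + 1L,
                                                    width = 4), " INFO ",
                                             sprintf(...)))

#' Run the full penetration-efficacy pipeline
#'
#' Executes, in order: synthetic study generation (or dataset ingestion),
#' per-image measurement (surface, SCT/AF-SC, autofluorescence-removal
#' threshold, AROSA, MPD), condition aggregation with control
#' normalization and compartment classification, and the statistical
#' comparison of conditions within each (surrogate, timepoint) stratum —
#' on pooled images and on per-ear means. Thresholds are computed per
#' (ear, stratum) from dye-free renders of that ear's control parameters
#' when generating synthetically, or from the section-1 control images when
#' ingesting a dataset.
#'
#' Artifacts written to \code{config$outDir}: \code{per_image_metrics.csv},
#' \code{condition_summary.csv} (absolute and relative blocks),
#' \code{compartment_calls.csv}, \code{stats_report.csv},
#' \code{pairwise_tests.csv}, \code{run_log.txt} and
#' \code{effective_config.yaml}. Identical config and seed give
#' byte-identical CSVs.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return invisibly, a list with the in-memory tables and the output paths.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "dermaquantConfig"))
  t0 <- proc.time()[["elapsed"]]
  log <- character(0)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  ## --- stage 1: images -----------------------------------------------------
  if (is.null(config$inputDir)) {
    base <- do.call(GeneratorParams,
                    c(list(scaleUmPerPx = config$scaleUmPerPx),
                      config$baseParams))
    manifest <- StudyManifest(
      ears = sprintf("ear%d", seq_len(config$ears)),
      presets = defaultPresets(config$presetFile),
      minCuts = config$cutsPerBiopsy, minImages = config$imagesPerBiopsy)
    log <- .logLine(log, "generating synthetic study: %d ears x %d conditions x %d images",
                    config$ears, length(manifest@presets),
                    config$imagesPerBiopsy)
    study <- generateStudy(manifest, base, seed = config$seed,
                           imagesPerBiopsy = config$imagesPerBiopsy,
                           cutsPerBiopsy = config$cutsPerBiopsy)
  } else {
    log <- .logLine(log, "reading dataset from %s", config$inputDir)
    study <- readDataset(config$inputDir)
    manifest <- study@manifest
  }
  images <- study@images
  truth <- study@truth
  log <- .logLine(log, "%d images loaded", length(images))

  ## --- stage 2: thresholds per (ear, stratum) ------------------------------
  condTab <- .conditionTable(manifest)
  strata <- unique(condTab[c("surrogate", "timepoint")])
  thresholds <- list()
  detectArgs <- list(smoothingWindowPx = config$smoothingWindowPx,
                     backgroundQuantile = config$backgroundQuantile,
                     backgroundMarginPx = config$backgroundMarginPx,
                     offset = config$offset)
  imgByCond <- split(seq_along(images), truth$condition)
  for (ear in manifest@ears) {
    for (si in seq_len(nrow(strata))) {
      ctrlLab <- condTab$condition[condTab$surrogate == strata$surrogate[si] &
                                     condTab$timepoint == strata$timepoint[si] &
                                     condTab$section == 1L]
      key <- paste(ear, strata$surrogate[si], strata$timepoint[si], sep = "|")
      idx <- imgByCond[[ctrlLab]]
      idx <- idx[truth$ear[idx] == ear]
      if (config$thresholdMethod == "control_stats") {
        ## dye-free control renders: blank re-renders of the control images'
        ## own parameters (same ear effects, same seeds, no dye)
        ctrlImages <- lapply(idx[seq_len(min(8L, length(idx)))], function(i) {
          tr <- truth[i, ]
          p <- GeneratorParams(
            imageHeightPx = tr$imageHeightPx, imageWidthPx = tr$imageWidthPx,
            scaleUmPerPx = tr$scaleUmPerPx,
            surfaceRowMeanPx = tr$surfaceRowMeanPx,
            surfaceRoughnessPx = tr$surfaceRoughnessPx,
            sctUm = tr$sctEffUm / (0.8 + 0.4 * tr$hydrationIndex),
            hydrationIndex = tr$hydrationIndex,
            afScLevel = tr$afScEff / (1.2 - 0.4 * tr$hydrationIndex),
            afTissueLevel = tr$afTissueLevel, dyeAmount = 0,
            dyeDecayUm = tr$dyeDecayUm, hotspotDensity = 0,
            noiseSd = tr$noiseSd, bitDepth = tr$bitDepth)
          generateSectionImage(p, seed = tr$seed)$image
        })
        thr <- tryCatch(
          do.call(computeThreshold,
                  c(list(ctrlImages, method = "control_stats",
                         k = config$thresholdK), detectArgs)),
          error = function(e) {
            structure(NA_real_, method = "control_stats", failed = TRUE)
          })
      } else {
        thr <- NA_real_  # per-image Otsu, resolved in stage 3
      }
      thresholds[[key]] <- thr
      if (is.finite(thr))
        log <- .logLine(log, "threshold[%s] = %.3f (%s, k = %.2g)", key,
                        thr, config$thresholdMethod, config$thresholdK)
    }
  }

  ## --- stage 3: per-image metrics ------------------------------------------
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    im <- images[[i]]
    key <- paste(truth$ear[i], truth$surrogate[i], truth$timepoint[i],
                 sep = "|")
    rows[[i]] <- tryCatch({
      thr <- thresholds[[key]]
      if (config$thresholdMethod == "otsu" || !is.finite(thr)) {
        sf <- do.call(detectSurface, c(list(im), detectArgs))
        thr <- computeThreshold(im, method = "otsu", surfaceRows = sf)
      }
      r <- do.call(measureImage,
                   c(list(im, thr, nLines = config$nLines), detectArgs))
      r$row
    }, error = function(e) {
      data.frame(image_id = im@imageId, ear = im@earId,
                 condition = im@condition, cut = im@cutIndex,
                 sct_um = NA_real_, sct_um_sd = NA_real_, af_sc = NA_real_,
                 threshold = NA_real_, arosa = NA_real_, mpd_um = NA_real_,
                 n_signal_px = NA_integer_,
                 flags = paste0("MEASUREMENT_ERROR:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  metrics <- do.call(rbind, rows)
  nErr <- sum(grepl("MEASUREMENT_ERROR", metrics$flags))
  if (nErr > 0L)
    log <- .logLine(log, "%d image(s) failed measurement and were flagged",
                    nErr)
  ok <- !grepl("MEASUREMENT_ERROR", metrics$flags)

  ## --- stage 4: aggregation ------------------------------------------------
  agg <- aggregateMetrics(metrics[ok, , drop = FALSE], manifest)
  summary <- relativeToControl(agg$conditions)
  compart <- cbind(summary[c("condition", "section", "surrogate",
                             "timepoint")],
                   classifyCompartment(summary$mpd_um_mean,
                                       summary$sct_um_mean,
                                       config$epidermisUm))
  log <- .logLine(log, "aggregated %d conditions; control normalization done",
                  nrow(summary))

  ## --- stage 5: statistics -------------------------------------------------
  statRows <- list(); pairRows <- list()
  for (si in seq_len(nrow(strata))) {
    conds <- condTab$condition[condTab$surrogate == strata$surrogate[si] &
                                 condTab$timepoint == strata$timepoint[si]]
    stratumLab <- paste(strata$surrogate[si], strata$timepoint[si], sep = "_")
    for (metric in .metricCols) {
      for (unit in c("pooled", "per_ear")) {
        df <- if (unit == "pooled") metrics[ok, ] else agg$perEar
        groups <- lapply(conds, function(cc)
          df[[metric]][df$condition == cc])
        names(groups) <- conds
        groups <- groups[lengths(groups) > 0L]
        if (length(groups) < 2L || any(lengths(groups) < 2L)) {
          log <- .logLine(log,
                          "stats[%s,%s,%s] skipped: insufficient groups",
                          stratumLab, metric, unit)
          statRows[[length(statRows) + 1L]] <- data.frame(
            stratum = stratumLab, metric = metric, unit = unit,
            omnibus = "skipped (insufficient groups)", statistic = NA_real_,
            p = NA_real_, post_hoc = NA_character_,
            stringsAsFactors = FALSE)
          next
        }
        cmp <- compareGroups(groups, alpha = config$alpha, metric = metric)
        for (tr in cmp@trace)
          log <- .logLine(log, "stats[%s,%s,%s] %s", stratumLab, metric,
                          unit, tr)
        statRows[[length(statRows) + 1L]] <- data.frame(
          stratum = stratumLab, metric = metric, unit = unit,
          omnibus = cmp@omnibus, statistic = cmp@statistic, p = cmp@p,
          post_hoc = cmp@postHoc, stringsAsFactors = FALSE)
        pw <- cmp@pairwise
        if (nrow(pw)) {
          pw <- cbind(data.frame(stratum = stratumLab, metric = metric,
                                 unit = unit, stringsAsFactors = FALSE), pw)
          pairRows[[length(pairRows) + 1L]] <- pw
        }
      }
    }
  }
  statsReport <- do.call(rbind, statRows)
  pairReport <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame()

  ## --- artifacts ------------------------------------------------------------
  paths <- list(
    metrics = file.path(config$outDir, "per_image_metrics.csv"),
    summary = file.path(config$outDir, "condition_summary.csv"),
    compartments = file.path(config$outDir, "compartment_calls.csv"),
    stats = file.path(config$outDir, "stats_report.csv"),
    pairwise = file.path(config$outDir, "pairwise_tests.csv"),
    log = file.path(config$outDir, "run_log.txt"),
    config = file.path(config$outDir, "effective_config.yaml"))
  utils::write.csv(metrics[order(metrics$image_id), ], paths$metrics,
                   row.names = FALSE)
  utils::write.csv(summary[order(summary$condition), ], paths$summary,
                   row.names = FALSE)
  utils::write.csv(compart[order(compart$condition), ], paths$compartments,
                   row.names = FALSE)
  utils::write.csv(statsReport, paths$stats, row.names = FALSE)
  utils::write.csv(pairReport, paths$pairwise, row.names = FALSE)
  log <- .logLine(log, "run complete in %.1f s",
                  proc.time()[["elapsed"]] - t0)
  writeLines(log, paths$log)
  writePipelineConfig(config, paths$config)

  invisible(list(metrics = metrics, summary = summary,
                 compartments = compart, stats = statsReport,
                 pairwise = pairReport, truth = truth, paths = paths,
                 log = log))
}

#' Validate a manifest against a metrics table or image directory
#'
#' Report-only check of study completeness: images that map to no manifest
#' cell, manifest cells without any image, and biopsies below the design
#' minimums (at least \code{minCuts} skin cuts and \code{minImages} images
#' per biopsy).
#'
#' @param manifest a [StudyManifest-class].
#' @param x a tidy per-image metrics (or truth) data.frame with
#'   \code{image_id}, \code{ear}, \code{condition}, \code{cut} columns, or
#'   a dataset directory readable by [readDataset()].
#' @return data.frame with columns \code{type} (\code{unmapped_image},
#'   \code{missing_cell}, \code{below_minimum}), \code{cell} and
#'   \code{message}; zero rows when the study is complete.
#' @export
validateManifest <- function(manifest, x) {
  stopifnot(is(manifest, "StudyManifest"))
  if (is.character(x)) x <- readDataset(x)@truth
  stopifnot(is.data.frame(x))
  report <- list()
  add <- function(type, cell, msg)
    report[[length(report) + 1L]] <<- data.frame(
      type = type, cell = cell, message = msg, stringsAsFactors = FALSE)
  labs <- vapply(manifest@presets, function(p) p@label, character(1))
  unknown <- unique(x$condition[!(x$condition %in% labs)])
  for (u in unknown)
    add("unmapped_image", u,
        sprintf("%d image(s) labelled '%s' map to no manifest condition",
                sum(x$condition == u), u))
  for (ear in manifest@ears) {
    for (lab in labs) {
      cell <- sprintf("%s/%s", ear, lab)
      sub <- x[x$ear == ear & x$condition == lab, , drop = FALSE]
      if (nrow(sub) == 0L) {
        add("missing_cell", cell, "no images for this (ear, condition) cell")
        next
      }
      if (nrow(sub) < manifest@minImages)
        add("below_minimum", cell,
            sprintf("%d image(s), below the %d-image floor per biopsy",
                    nrow(sub), manifest@minImages))
      nCuts <- length(unique(sub$cut))
      if (nCuts < manifest@minCuts)
        add("below_minimum", cell,
            sprintf("%d skin cut(s), below the %d-cut floor per biopsy",
                    nCuts, manifest@minCuts))
    }
  }
  if (length(report)) do.call(rbind, report) else
    data.frame(type = character(0), cell = character(0),
               message = character(0), stringsAsFactors = FALSE)
}
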