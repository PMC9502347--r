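## Study-level aggregation: condition summaries, control normalization and
## penetration-compartment classification.

.metricCols <- c("sct_um", "af_sc", "arosa", "mpd_um")

## condition lookup table from a manifest
.conditionTable <- function(manifest) {
  do.call(rbind, lapply(manifest@presets, function(p) data.frame(
    condition = p@label, section = p@skinSection, surrogate = p@surrogate,
    timepoint = p@timepoint, stringsAsFactors = FALSE)))
}

#' Aggregate per-image metrics into condition summaries
#'
#' Pools all image rows of each condition (rows flagged \code{NO_SIGNAL}
#' enter with their zero metric values, so conditions with rare penetration
#' are not upward-biased) and reports n, mean and SD for each metric (SCT,
#' AF-SC, AROSA, MPD). Per-ear means are also returned, since the ear is
#' the independent biological unit for statistics.
#'
#' @param metrics tidy per-image data.frame with columns \code{image_id},
#'   \code{ear}, \code{condition} and the metric columns \code{sct_um},
#'   \code{af_sc}, \code{arosa}, \code{mpd_um}.
#' @param manifest a [StudyManifest-class]; every metrics row must map to
#'   one of its conditions, and every condition must have images.
#' @return list with data.frames \code{conditions} (one row per condition:
#'   n_images plus \code{<metric>_mean} / \code{<metric>_sd}) and
#'   \code{perEar} (one row per ear x condition).
#' @export
aggregateMetrics <- function(metrics, manifest) {
  stopifnot(is.data.frame(metrics), is(manifest, "StudyManifest"))
  need <- c("image_id", "ear", "condition", .metricCols)
  miss <- setdiff(need, names(metrics))
  if (length(miss))
    stop("metrics table lacks columns: ", paste(miss, collapse = ", "))
  condTab <- .conditionTable(manifest)
  unknown <- setdiff(unique(metrics$condition), condTab$condition)
  if (length(unknown))
    stop("metrics rows map to no manifest cell: ",
         paste(unknown, collapse = ", "))
  empty <- setdiff(condTab$condition, unique(metrics$condition))
  if (length(empty))
    stop("condition(s) with zero images: ", paste(empty, collapse = ", "))

  minTotal <- manifest@minImages * length(manifest@ears)
  rows <- lapply(condTab$condition, function(cond) {
    sub <- metrics[metrics$condition == cond, , drop = FALSE]
    if (nrow(sub) < minTotal)
      warning("condition '", cond, "' has ", nrow(sub),
              " images, below the design minimum of ", minTotal,
              call. = FALSE)
    out <- data.frame(condition = cond, n_images = nrow(sub),
                      stringsAsFactors = FALSE)
    for (m in .metricCols) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(sub[[m]])
    }
    out
  })
  conditions <- merge(condTab, do.call(rbind, rows), by = "condition",
                      sort = TRUE)

  agg <- stats::aggregate(metrics[.metricCols],
                          by = list(ear = metrics$ear,
                                    condition = metrics$condition),
                          FUN = mean)
  agg <- agg[order(agg$condition, agg$ear), , drop = FALSE]
  rownames(agg) <- NULL
  list(conditions = conditions, perEar = agg)
}

#' Normalize condition summaries to the untreated control
#'
#' Expresses each condition mean as a percentage of the control mean of the
#' same (surrogate, timepoint) stratum: the untreated skin (section 1) is
#' set to exactly 100\%. The spread of a relative value is the condition's
#' own relative standard deviation, \code{RSD = 100 * SD / mean}.
#'
#' @param summaries the \code{conditions} data.frame from
#'   [aggregateMetrics()].
#' @param metricsToNormalize metric names to normalize (default all four).
#' @return \code{summaries} with added \code{rel_<metric>} and
#'   \code{rsd_<metric>} columns (percent).
#' @section Errors: a control mean of zero makes the normalization
#'   undefined and is an error.
#' @export
relativeToControl <- function(summaries, metricsToNormalize = .metricCols) {
  stopifnot(is.data.frame(summaries),
            all(c("condition", "section", "surrogate", "timepoint")
                %in% names(summaries)))
  out <- summaries
  for (m in metricsToNormalize) {
    out[[paste0("rel_", m)]] <- NA_real_
    out[[paste0("rsd_", m)]] <- NA_real_
  }
  strata <- unique(summaries[c("surrogate", "timepoint")])
  for (i in seq_len(nrow(strata))) {
    inStratum <- summaries$surrogate == strata$surrogate[i] &
      summaries$timepoint == strata$timepoint[i]
    ctrl <- inStratum & summaries$section == 1L
    if (sum(ctrl) != 1L)
      stop("stratum ", strata$surrogate[i], "/", strata$timepoint[i],
           " needs exactly one section-1 control row")
    for (m in metricsToNormalize) {
      cm <- summaries[[paste0(m, "_mean")]][ctrl]
      if (!is.finite(cm) || cm <= 0)
        stop("control mean of '", m, "' is not positive; ",
             "normalization undefined")
      rel <- 100 * summaries[[paste0(m, "_mean")]][inStratum] / cm
      rel[summaries$section[inStratum] == 1L] <- 100
      out[[paste0("rel_", m)]][inStratum] <- rel
      mu <- summaries[[paste0(m, "_mean")]][inStratum]
      sdv <- summaries[[paste0(m, "_sd")]][inStratum]
      out[[paste0("rsd_", m)]][inStratum] <- ifelse(mu > 0, 100 * sdv / mu,
                                                    NA_real_)
    }
  }
  out
}

#' Classify the penetration compartment
#'
#' Compares the mean penetration depth with the stratum corneum thickness
#' and the epidermis thickness: a formulation whose MPD does not exceed the
#' SCT stayed within the stratum corneum; an MPD beyond the SCT but within
#' the epidermis reached the viable epidermis; an MPD beyond the epidermis
#' indicates transdermal penetration. The porcine-ear epidermis is about
#' 100-110 um thick; the default uses the conservative upper end.
#'
#' @param mpdUm mean penetration depth(s), um.
#' @param sctUm stratum corneum thickness(es), um.
#' @param epidermisUm epidermis thickness, um (default 110).
#' @return data.frame with columns \code{mpd_um}, \code{sct_um},
#'   \code{epidermis_um} and \code{compartment} (factor with levels
#'   \code{within_SC}, \code{viable_epidermis}, \code{transdermal}).
#' @examples
#' classifyCompartment(c(150, 80, 10), 15)$compartment
#' @export
classifyCompartment <- function(mpdUm, sctUm, epidermisUm = 110) {
  n <- max(length(mpdUm), length(sctUm))
  mpdUm <- rep_len(mpdUm, n); sctUm <- rep_len(sctUm, n)
  if (any(!is.finite(mpdUm)) || any(!is.finite(sctUm)) ||
      !is.finite(epidermisUm))
    stop("all inputs must be finite")
  if (any(mpdUm < 0) || any(sctUm < 0) || epidermisUm < 0)
    stop("negative thickness or depth rejected")
  comp <- ifelse(mpdUm <= sctUm, "within_SC",
                 ifelse(mpdUm <= epidermisUm, "viable_epidermis",
                        "transdermal"))
  data.frame(mpd_um = mpdUm, sct_um = sctUm, epidermis_um = epidermisUm,
             compartment = factor(comp, levels = c("within_SC",
                                                   "viable_epidermis",
                                                   "transdermal")))
}
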