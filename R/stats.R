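## Assumption-driven statistical comparison workflow: Shapiro-Wilk and
## Levene checks route to ANOVA + Tukey, Welch ANOVA + Games-Howell or
## Kruskal-Wallis + Dunn; two-group tests and star annotation.

.asGroups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("condition", "value") %in% names(groups)))
    groups <- split(groups$value, groups$condition)
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  lapply(groups, function(x) as.numeric(x[is.finite(x)]))
}

#' Significance stars
#'
#' Maps p values to the conventional star annotation with strict
#' thresholds: \code{p < 0.001} three stars, \code{p < 0.01} two,
#' \code{p < 0.05} one, otherwise \code{"ns"}.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @return character vector of \code{"***"}, \code{"**"}, \code{"*"},
#'   \code{"ns"}.
#' @examples
#' annotateSignificance(c(0.0005, 0.03, 0.05))
#' @export
annotateSignificance <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*",
                                                         "ns")))
}

#' Per-group Shapiro-Wilk normality checks
#'
#' Runs the Shapiro-Wilk test on each group. Groups that cannot be tested
#' are refused with an explicit code instead of a p value: fewer than 3
#' observations (\code{"too_few"}), zero variance (\code{"degenerate"}), or
#' more than 5000 observations (\code{"too_large"}, where the test is
#' unreliable). Refused groups are treated as non-normal downstream.
#'
#' @param groups named list of numeric vectors, or a long data.frame with
#'   \code{condition} and \code{value} columns.
#' @param alpha flag level (default 0.05).
#' @return data.frame with columns \code{group}, \code{n}, \code{p},
#'   \code{code} (\code{"ok"} or a refusal code) and \code{normal}.
#' @export
testNormality <- function(groups, alpha = 0.05) {
  groups <- .asGroups(groups)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    n <- length(x)
    if (n < 3L)
      return(data.frame(group = g, n = n, p = NA_real_, code = "too_few",
                        normal = FALSE, stringsAsFactors = FALSE))
    if (n > 5000L)
      return(data.frame(group = g, n = n, p = NA_real_, code = "too_large",
                        normal = FALSE, stringsAsFactors = FALSE))
    if (stats::sd(x) == 0)
      return(data.frame(group = g, n = n, p = NA_real_, code = "degenerate",
                        normal = FALSE, stringsAsFactors = FALSE))
    p <- stats::shapiro.test(x)$p.value
    data.frame(group = g, n = n, p = p, code = "ok", normal = p >= alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Levene's test of variance homogeneity
#'
#' Levene's test on the absolute deviations from the group centre. The
#' centre defaults to the group mean (the classical Levene statistic);
#' \code{"median"} gives the Brown-Forsythe variant.
#'
#' @param groups named list of numeric vectors or a long data.frame.
#' @param center \code{"mean"} (default) or \code{"median"}.
#' @return list with \code{statistic}, \code{df}, \code{p} and
#'   \code{center}.
#' @export
testVarianceHomogeneity <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- .asGroups(groups)
  if (length(groups) < 2L) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop("every group needs n >= 2 for Levene's test (got n = ",
         paste(ns, collapse = ", "), ")")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  centerFun <- if (center == "mean") mean else stats::median
  lt <- car::leveneTest(y, g, center = centerFun)
  list(statistic = lt[1, "F value"], df = c(lt[1, "Df"], lt[2, "Df"]),
       p = lt[1, "Pr(>F)"], center = center)
}

## ---------------------------------------------------------------------------
## Post hoc procedures
## ---------------------------------------------------------------------------

#' Games-Howell post hoc test
#'
#' All pairwise comparisons after a Welch ANOVA: Welch's t statistic per
#' pair, referred to the studentized range distribution with
#' Welch-Satterthwaite degrees of freedom (so no variance pooling and no
#' equal-n assumption).
#'
#' @param groups named list of numeric vectors or a long data.frame.
#' @return data.frame: \code{group1}, \code{group2}, \code{estimate} (mean
#'   difference), \code{statistic} (t), \code{df}, \code{p_adj},
#'   \code{stars}.
#' @export
gamesHowellTest <- function(groups) {
  groups <- .asGroups(groups)
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  nm <- names(groups)
  m <- vapply(groups, mean, numeric(1))
  v <- vapply(groups, stats::var, numeric(1))
  n <- lengths(groups)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = nm[i], group2 = nm[j], estimate = m[i] - m[j],
               statistic = tstat, df = df, p_adj = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$stars <- annotateSignificance(out$p_adj)
  out
}

#' Dunn's post hoc test
#'
#' All pairwise rank comparisons after a Kruskal-Wallis test: z statistics
#' on the mean ranks with the usual tie correction, with a configurable
#' multiplicity adjustment (Holm by default).
#'
#' @param groups named list of numeric vectors or a long data.frame.
#' @param p.adjust.method any [stats::p.adjust] method (default
#'   \code{"holm"}).
#' @return data.frame: \code{group1}, \code{group2}, \code{estimate} (mean
#'   rank difference), \code{statistic} (z), \code{p_adj}, \code{stars};
#'   the adjustment method is recorded in \code{attr(, "p.adjust.method")}.
#' @export
dunnTest <- function(groups, p.adjust.method = "holm") {
  groups <- .asGroups(groups)
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  nm <- names(groups)
  n <- lengths(groups)
  N <- sum(n)
  r <- rank(unlist(groups, use.names = FALSE))
  gidx <- rep(seq_len(k), n)
  rbar <- tapply(r, gidx, mean)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2base <- N * (N + 1) / 12 - tieCorr
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    z <- (rbar[i] - rbar[j]) / sqrt(sigma2base * (1 / n[i] + 1 / n[j]))
    data.frame(group1 = nm[i], group2 = nm[j],
               estimate = unname(rbar[i] - rbar[j]), statistic = unname(z),
               df = NA_real_, p_raw = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = p.adjust.method)
  out$p_raw <- NULL
  out$stars <- annotateSignificance(out$p_adj)
  attr(out, "p.adjust.method") <- p.adjust.method
  out
}

.tukeyTest <- function(groups) {
  groups <- .asGroups(groups)
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  pairNames <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(
    group1 = vapply(pairNames, `[`, character(1), 1L),
    group2 = vapply(pairNames, `[`, character(1), 2L),
    estimate = tk[, "diff"], statistic = NA_real_, df = NA_real_,
    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$stars <- annotateSignificance(out$p_adj)
  out
}

## ---------------------------------------------------------------------------
## Omnibus decision tree
## ---------------------------------------------------------------------------

#' Compare groups with the assumption-driven decision tree
#'
#' Implements the workflow: Shapiro-Wilk normality per group and Levene's
#' variance-homogeneity test choose the omnibus test and its matching post
#' hoc procedure —
#' all groups normal and homogeneous: ANOVA with Tukey's HSD;
#' all normal but inhomogeneous: Welch ANOVA with Games-Howell;
#' any group non-normal (or untestable): Kruskal-Wallis with Dunn's test.
#' Every rule firing is recorded in the decision trace.
#'
#' @param groups named list of numeric vectors (>= 2 groups) or a long
#'   data.frame with \code{condition} and \code{value} columns.
#' @param alpha significance level (default 0.05), used both for the
#'   assumption gates and the star annotation.
#' @param metric name stored in the result.
#' @param leveneCenter \code{"mean"} or \code{"median"}.
#' @param dunnAdjust p-adjustment for Dunn's test (default \code{"holm"}).
#' @return a [GroupComparison-class].
#' @examples
#' set.seed(1)
#' g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20, 2))
#' compareGroups(g)
#' @export
compareGroups <- function(groups, alpha = 0.05, metric = "value",
                          leveneCenter = "mean", dunnAdjust = "holm") {
  groups <- .asGroups(groups)
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(lengths(groups) < 2L))
    stop("every group needs at least two observations")
  trace <- character(0)
  sw <- testNormality(groups, alpha = alpha)
  for (i in seq_len(nrow(sw))) {
    trace <- c(trace, if (sw$code[i] == "ok")
      sprintf("shapiro[%s]: p = %.4g -> %s", sw$group[i], sw$p[i],
              ifelse(sw$normal[i], "normal", "non-normal"))
      else
        sprintf("shapiro[%s]: refused (%s) -> treated non-normal",
                sw$group[i], sw$code[i]))
  }
  allNormal <- all(sw$normal)
  lev <- NULL
  if (allNormal) {
    lev <- testVarianceHomogeneity(groups, center = leveneCenter)
    homo <- lev$p >= alpha
    trace <- c(trace, sprintf("levene(center=%s): p = %.4g -> %s",
                              lev$center, lev$p,
                              ifelse(homo, "homogeneous", "inhomogeneous")))
    y <- unlist(groups, use.names = FALSE)
    g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
    if (homo) {
      om <- stats::oneway.test(y ~ g, var.equal = TRUE)
      omnibus <- "ANOVA"; postHoc <- "Tukey"
      pairwise <- .tukeyTest(groups)
    } else {
      om <- stats::oneway.test(y ~ g, var.equal = FALSE)
      omnibus <- "Welch-ANOVA"; postHoc <- "Games-Howell"
      pairwise <- gamesHowellTest(groups)
    }
    stat <- unname(om$statistic); p <- om$p.value
  } else {
    trace <- c(trace, "at least one group non-normal -> non-parametric path")
    om <- stats::kruskal.test(groups)
    omnibus <- "Kruskal-Wallis"; postHoc <- "Dunn"
    pairwise <- dunnTest(groups, p.adjust.method = dunnAdjust)
    trace <- c(trace, sprintf("dunn adjustment: %s", dunnAdjust))
    stat <- unname(om$statistic); p <- om$p.value
  }
  trace <- c(trace, sprintf("omnibus %s: stat = %.4g, p = %.4g -> %s + %s",
                            omnibus, stat, p,
                            ifelse(p < alpha, "significant",
                                   "not significant"), postHoc))
  new("GroupComparison", metric = metric, omnibus = omnibus,
      statistic = stat, p = p,
      assumptions = list(shapiro = sw, levene = lev),
      postHoc = postHoc, pairwise = pairwise, trace = trace, alpha = alpha)
}

#' Two-group test with automatic parametric/non-parametric choice
#'
#' A t test when both groups pass the Shapiro-Wilk normality check (Welch
#' variant when Levene's test flags variance inhomogeneity, pooled variant
#' otherwise), the Mann-Whitney test otherwise. Paired designs use the
#' paired t test / Wilcoxon signed-rank test. The choice is recorded.
#'
#' @param groupA,groupB numeric vectors (n >= 2 each).
#' @param paired paired design?
#' @param alpha level for the assumption gates and stars.
#' @return list with \code{method}, \code{statistic}, \code{p},
#'   \code{stars} and \code{trace}.
#' @export
pairwiseTest <- function(groupA, groupB, paired = FALSE, alpha = 0.05) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least two observations")
  if (paired && length(groupA) != length(groupB))
    stop("paired groups must have equal length")
  sw <- testNormality(list(A = groupA, B = groupB), alpha = alpha)
  bothNormal <- all(sw$normal)
  trace <- sprintf("shapiro: A %s, B %s",
                   ifelse(sw$normal[1], "normal", "non-normal"),
                   ifelse(sw$normal[2], "normal", "non-normal"))
  if (bothNormal) {
    if (paired) {
      ht <- stats::t.test(groupA, groupB, paired = TRUE)
      method <- "paired t"
    } else {
      lev <- testVarianceHomogeneity(list(A = groupA, B = groupB))
      varEqual <- lev$p >= alpha
      trace <- c(trace, sprintf("levene: p = %.4g -> %s", lev$p,
                                ifelse(varEqual, "pooled t", "Welch t")))
      ht <- stats::t.test(groupA, groupB, var.equal = varEqual)
      method <- if (varEqual) "t" else "Welch t"
    }
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(groupA, groupB, paired = paired, exact = FALSE,
                         correct = TRUE))
    method <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney"
  }
  trace <- c(trace, sprintf("%s test: p = %.4g", method, ht$p.value))
  list(method = method, statistic = unname(ht$statistic), p = ht$p.value,
       stars = annotateSignificance(ht$p.value), trace = trace)
}
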