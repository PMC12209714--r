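#' Two-sample t test from printed summaries
#'
#' Computes the standard two-sample test from (mean, SD, n) per group, as
#' when re-analysing published tables. Identical to \code{\link{twoSampleT}}
#' on any raw data having those exact summaries.
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries (\code{n >= 2}).
#' @param variant \code{"pooled"} (default) or \code{"welch"}.
#' @return named list \code{t}, \code{df}, \code{p}.
#' @export
tTestFromSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopIf(nA < 2 || nB < 2, "each group needs n >= 2")
  stopIf(sdA < 0 || sdB < 0, "SDs must be >= 0")
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) return(list(t = 0, df = nA + nB - 2, p = 1))
    res <- list(t = sign(meanA - meanB) * Inf, df = nA + nB - 2, p = 0)
    attr(res, "degenerate") <- "zero variance with unequal means"
    return(res)
  }
  if (variant == "pooled") {
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
  } else {
    vA <- sdA^2 / nA
    vB <- sdB^2 / nB
    se <- sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  }
  t <- (meanA - meanB) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample t test from means with 95\% confidence intervals
#'
#' Recovers each group's SD from its 95\% CI half-width — half-width equals
#' \code{qt(0.975, n-1) * SD / sqrt(n)} — then applies
#' \code{\link{tTestFromSummary}}. Useful for published tables reporting
#' mean (95\% CI).
#'
#' @param meanA,loA,hiA,nA,meanB,loB,hiB,nB per-group mean, CI bounds, n.
#' @param variant passed to \code{\link{tTestFromSummary}}.
#' @return named list \code{t}, \code{df}, \code{p}.
#' @export
tTestFromCI <- function(meanA, loA, hiA, nA, meanB, loB, hiB, nB,
                        variant = c("pooled", "welch")) {
  stopIf(loA > hiA || loB > hiB, "inverted CI bounds")
  stopIf(meanA < loA || meanA > hiA || meanB < loB || meanB > hiB,
         "mean must lie inside its CI")
  stopIf(nA < 2 || nB < 2, "each group needs n >= 2")
  sdFromCI <- function(lo, hi, n) (hi - lo) / 2 / stats::qt(0.975, n - 1) * sqrt(n)
  tTestFromSummary(meanA, sdFromCI(loA, hiA, nA), nA,
                   meanB, sdFromCI(loB, hiB, nB), nB,
                   variant = match.arg(variant))
}

#' Covariate-adjusted partial correlation
#'
#' Residualizes \code{x} and \code{y} on the covariate set by least squares
#' and computes the Pearson correlation of the residuals; the p-value comes
#' from \code{t = r * sqrt(df / (1 - r^2))} with
#' \code{df = n - 2 - #covariates}.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data.frame of covariates (may
#'   be empty, giving the plain Pearson correlation).
#' @return list \code{r}, \code{n}, \code{nCovariates}, \code{df}, \code{p}.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopIf(length(y) != n, "x and y lengths differ")
  Z <- if (is.null(covariates) || (is.matrix(covariates) && ncol(covariates) == 0))
    matrix(numeric(0), n, 0) else as.matrix(covariates)
  k <- ncol(Z)
  stopIf(n <= k + 2, "insufficient observations: n must exceed #covariates + 2")
  if (k > 0) {
    stopIf(any(apply(Z, 2, stats::var) == 0), "constant covariate")
    Zc <- cbind(1, Z)
    stopIf(qr(Zc)$rank < ncol(Zc), "perfect collinearity among covariates")
    x <- stats::lm.fit(Zc, x)$residuals
    y <- stats::lm.fit(Zc, y)$residuals
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  stopIf(df < 1, "insufficient degrees of freedom")
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, n = n, nCovariates = k, df = df,
       p = 2 * stats::pt(-abs(t), df))
}

#' Compare clinical measures between two subtypes
#'
#' Per measure: group means and SDs, a two-sample test, Cohen's d, and the
#' mean difference with its 95\% confidence interval, in the style of a
#' clinical characteristics table.
#'
#' @param clinical data.frame with a \code{subject_id} column and one numeric
#'   column per measure.
#' @param subtypes named integer vector (names = subject ids) of subtype
#'   labels; exactly the labels 1 and 2 are compared.
#' @param measures measure column names (default: all numeric columns).
#' @param variant t-test variant.
#' @return data.frame, one row per measure: per-group mean/sd/n, t, df, p,
#'   d, diff, ci_lo, ci_hi.
#' @export
compareSubtypes <- function(clinical, subtypes,
                            measures = NULL,
                            variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopIf(!"subject_id" %in% colnames(clinical), "clinical table needs subject_id")
  lab <- subtypes[clinical$subject_id]
  stopIf(all(is.na(lab)), "no clinical subjects have subtype labels")
  if (is.null(measures))
    measures <- setdiff(colnames(clinical)[vapply(clinical, is.numeric, logical(1))],
                        "subject_id")
  bad <- setdiff(measures, colnames(clinical))
  stopIf(length(bad) > 0, "unknown measure(s): %s", paste(bad, collapse = ", "))
  g1 <- which(lab == 1L)
  g2 <- which(lab == 2L)
  stopIf(length(g1) < 2 || length(g2) < 2, "each subtype needs n >= 2")
  rows <- lapply(measures, function(m) {
    a <- clinical[[m]][g1]
    b <- clinical[[m]][g2]
    stopIf(!is.numeric(a), "measure %s is not numeric", m)
    tt <- twoSampleT(a, b, variant = variant)
    se <- if (variant == "pooled") {
      sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
        (length(a) + length(b) - 2)
      sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    } else sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    hw <- stats::qt(0.975, tt$df) * se
    data.frame(measure = m,
               mean1 = mean(a), sd1 = stats::sd(a), n1 = length(a),
               mean2 = mean(b), sd2 = stats::sd(b), n2 = length(b),
               t = tt$t, df = tt$df, p = tt$p,
               d = cohensD(mean(a), stats::sd(a), length(a),
                           mean(b), stats::sd(b), length(b)),
               diff = mean(a) - mean(b),
               ci_lo = mean(a) - mean(b) - hw,
               ci_hi = mean(a) - mean(b) + hw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate clinical scores for a subtyped cohort
#'
#' Draws per-subject clinical scores from Gaussian models whose default
#' means and SDs are realistic for a chronic-pain cohort (pain VAS ~ 6,
#' perceived stress ~ 25-31, etc.), with subtype-specific means where a
#' planted difference is requested.
#'
#' @param subtypes named integer vector of subtype labels (1 or 2).
#' @param means list: measure -> length-2 numeric (mean for subtype 1, 2).
#' @param sds named numeric of per-measure SDs (recycled across subtypes).
#' @param seed RNG seed.
#' @return data.frame with \code{subject_id} and one column per measure.
#' @export
simulateClinicalScores <- function(subtypes,
                                   means = list(age = c(43.3, 48.4),
                                                duration = c(79.7, 51.9),
                                                pain_vas = c(6.1, 6.2),
                                                pss = c(30.7, 25.0)),
                                   sds = c(age = 10.3, duration = 60,
                                           pain_vas = 1.5, pss = 9.1),
                                   seed = 1L) {
  ids <- names(subtypes)
  stopIf(is.null(ids), "subtypes must be a named vector")
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  withSeed(seed, {
    for (m in names(means)) {
      mu <- means[[m]][pmin(subtypes, 2L)]
      out[[m]] <- stats::rnorm(length(ids), mu, sds[[m]])
    }
  })
  out
}
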