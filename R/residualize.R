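#' Covariate residualization and control standardization
#'
#' For every region, a least-squares fit of volume on the covariates is
#' estimated on controls only and subtracted from all subjects, so that
#' nuisance effects (age-related decline, head size) are removed without
#' absorbing disease effects. Residuals are then standardized by the control
#' mean and SD per region.
#'
#' @param ms a \linkS4class{MorphometrySet} with at least one patient and one
#'   control.
#' @param covariates covariate names to adjust for, from \code{colData};
#'   default \code{c("age", "tiv")}.
#' @return an \linkS4class{AdjustedFeatures} object (subjects x regions).
#' @export
residualizeCovariates <- function(ms, covariates = c("age", "tiv")) {
  cd <- colData(ms)
  miss <- setdiff(covariates, colnames(cd))
  stopIf(length(miss) > 0, "covariate(s) not found: %s", paste(miss, collapse = ", "))
  grp <- subjectGroups(ms)
  stopIf(!any(grp == "patient") || !any(grp == "control"),
         "need at least one patient and one control")
  ctrl <- grp == "control"
  nC <- sum(ctrl)
  stopIf(nC < length(covariates) + 1L,
         "fewer controls (%d) than covariates + 1 (%d)", nC, length(covariates) + 1L)
  Z <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(cd[covariates], optional = TRUE)))
  colnames(Z) <- c("(Intercept)", covariates)
  for (cv in covariates)
    stopIf(stats::var(Z[ctrl, cv]) == 0, "constant covariate among controls: %s", cv)
  Y <- t(volumes(ms))                      # subjects x regions
  fit <- stats::lm.fit(Z[ctrl, , drop = FALSE], Y[ctrl, , drop = FALSE])
  betas <- fit$coefficients
  resid <- Y - Z %*% betas
  ctr <- colMeans(resid[ctrl, , drop = FALSE])
  scl <- apply(resid[ctrl, , drop = FALSE], 2, stats::sd)
  stopIf(any(scl == 0), "zero control variance in %d region(s)", sum(scl == 0))
  feat <- sweep(sweep(resid, 2, ctr), 2, scl, "/")
  rownames(feat) <- subjectIds(ms)
  new("AdjustedFeatures", features = feat,
      group = stats::setNames(ifelse(grp == "patient", 1L, -1L), subjectIds(ms)),
      betas = betas, center = ctr, scale = scl,
      covariates = as.character(covariates),
      parcellation = as.character(parcellationName(ms)))
}
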