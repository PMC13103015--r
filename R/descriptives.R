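## Descriptive layer: univariate spline-LME trajectories, paired change
## tests from discharge, and reference-marker Spearman correlations.

## single-outcome design bundle sharing the bivariate conventions
assembleUnivariateDesign <- function(ds, variableId, structure) {
  m <- measurements(ds)
  cv <- covariates(ds)
  mv <- m[m$variable_id == variableId, , drop = FALSE]
  if (!nrow(mv)) stop("unknown variable: ", variableId)
  tAll <- mv$time_months
  nDistinct <- length(unique(tAll))
  splineSpec <- tryCatch(makeSplineSpec(tAll), error = function(e) NULL)
  if (structure == "intercept_spline2" && is.null(splineSpec))
    stop("identifiability: too few distinct times for spline structure")
  if (structure == "intercept_slope" && nDistinct < 2)
    stop("identifiability: too few distinct times for slope structure")

  pats <- sort(unique(mv$patient_id))
  mv <- mv[order(match(mv$patient_id, pats), mv$time_months), ]
  age <- setNames(cv$age_years, cv$patient_id)
  sexF <- setNames(as.numeric(cv$sex == "female"), cv$patient_id)
  n <- nrow(mv)
  X <- cbind(intercept = rep(1, n), age = age[mv$patient_id],
             sexF = sexF[mv$patient_id],
             fixedTimeBasis(mv$time_months, splineSpec, nDistinct))
  Z <- zColumns(structure, mv$time_months, splineSpec)
  counts <- table(factor(mv$patient_id, levels = pats))
  ptr <- as.integer(c(0, cumsum(counts)))
  list(y = mv$value, X = X, Z = Z, ptr = ptr,
       grp = rep(0L, n), patients = pats, qP = ncol(Z), qE = 0L,
       n = n, splineSpec = splineSpec, nDistinct = nDistinct,
       structure = structure)
}

#' Fit a univariate natural-spline trajectory model for one variable
#'
#' ML fit of a single-outcome linear mixed model with the same design
#' conventions as the bivariate pair model (fixed part: intercept, age, sex
#' and a df=2 natural-spline time basis; random part: the richest structure
#' in spline -> slope -> intercept order that satisfies the convergence
#' contract).  Returns population-average predictions at the requested times
#' (covariates at the sample mean age and sex proportion) together with the
#' modeled marginal SD, `sqrt(z(t)' D z(t) + sigma^2)`.
#'
#' @param ds a [CohortDataset-class].
#' @param variableId variable identifier.
#' @param evalTimes times (months) at which to report modeled mean and SD.
#' @param tol,restarts,seed convergence-contract parameters.
#' @return A `TrajectoryFit` list: `variableId`, `structure`, `beta`, `D`,
#'   `sigma2`, `loglik`, `converged`, and a data.frame `profile` with
#'   columns `time`, `mean`, `sd`, `extrapolated`.
#' @export
fitUnivariateTrajectory <- function(ds, variableId, evalTimes = c(0, 3, 12),
                                    tol = 1e-4, restarts = 2L, seed = 1L) {
  stopifnot(is(ds, "CohortDataset"))
  fit <- NULL
  bundle <- NULL
  for (structure in c("intercept_spline2", "intercept_slope", "intercept")) {
    bundle <- tryCatch(assembleUnivariateDesign(ds, variableId, structure),
                       error = function(e)
                         if (grepl("identifiability", conditionMessage(e)))
                           NULL else stop(e))
    if (is.null(bundle)) next
    f <- fitCore(bundle, blockDims = bundle$qP, nSigma = 1L, tol = tol,
                 restarts = restarts, seed = seed)
    if (f$converged) { fit <- f; break }
    if (is.null(fit)) fit <- f   # keep best-effort non-converged fit
  }
  if (is.null(bundle)) stop("unknown variable: ", variableId)

  cv <- covariates(ds)
  meanAge <- mean(cv$age_years)
  meanSexF <- mean(cv$sex == "female")
  obsRange <- range(measurements(ds)$time_months[
    measurements(ds)$variable_id == variableId])
  xt <- fixedTimeBasis(evalTimes, bundle$splineSpec, bundle$nDistinct)
  Xeval <- cbind(1, meanAge, meanSexF, xt)
  mu <- drop(Xeval %*% fit$beta)
  Zeval <- zColumns(bundle$structure, evalTimes, bundle$splineSpec)
  sdv <- sqrt(rowSums((Zeval %*% fit$D) * Zeval) + fit$sigma2[1])
  structure(list(
    variableId = variableId, structure = bundle$structure,
    beta = fit$beta, D = fit$D, sigma2 = fit$sigma2[1],
    betaVcov = fit$betaVcov,
    loglik = fit$loglik, converged = fit$converged,
    profile = data.frame(time = evalTimes, mean = mu, sd = sdv,
                         extrapolated = evalTimes < obsRange[1] |
                           evalTimes > obsRange[2])),
    class = "TrajectoryFit")
}

#' @export
print.TrajectoryFit <- function(x, ...) {
  cat(sprintf("Trajectory fit for %s (%s), converged %s\n", x$variableId,
              x$structure, x$converged))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

## pick, per patient, the measurement nearest a nominal visit time within
## a tolerance window
valuesAtVisit <- function(m, variableId, t0, window) {
  mv <- m[m$variable_id == variableId & abs(m$time_months - t0) <= window, ]
  if (!nrow(mv)) return(setNames(numeric(0), character(0)))
  mv <- mv[order(abs(mv$time_months - t0)), ]
  mv <- mv[!duplicated(mv$patient_id), ]
  setNames(mv$value, mv$patient_id)
}

#' Paired t-test of change between two nominal visit times
#'
#' Classical paired t-test on within-patient differences
#' `value(tCmp) - value(tRef)`; patients missing either visit are excluded
#' and counted.  Visits are matched by nominal time within a tolerance
#' window (default +/- 0.5 months).
#'
#' @param ds a [CohortDataset-class].
#' @param variableId variable identifier.
#' @param tRef,tCmp reference and comparison times (months).
#' @param window visit-matching half-width (months).
#' @return list: `statistic`, `df`, `pValue`, `meanDifference`, `nPairs`,
#'   `nExcluded`.
#' @export
pairedChangeTest <- function(ds, variableId, tRef = 0, tCmp = 12,
                             window = 0.5) {
  stopifnot(is(ds, "CohortDataset"))
  m <- measurements(ds)
  if (!any(m$variable_id == variableId))
    stop("unknown variable: ", variableId)
  vr <- valuesAtVisit(m, variableId, tRef, window)
  vc <- valuesAtVisit(m, variableId, tCmp, window)
  common <- intersect(names(vr), names(vc))
  nExcluded <- length(union(names(vr), names(vc))) - length(common)
  if (length(common) < 2)
    stop("data: fewer than 2 patients with measurements at both times")
  d <- vc[common] - vr[common]
  if (sd(d) == 0)
    stop("degenerate: zero variance of within-patient differences")
  tt <- t.test(vc[common], vr[common], paired = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       pValue = tt$p.value, meanDifference = unname(tt$estimate),
       nPairs = length(common), nExcluded = nExcluded)
}

#' Within-patient-mean Spearman correlations against reference markers
#'
#' For each (echo, marker) pair, the Spearman correlation across patients of
#' within-patient mean echo values against within-patient mean log-marker
#' levels (see [withinPatientMeanSpearman()]).  Marker means may be Z-scored
#' for plotting-scale parity; Z-scoring is rank-invariant and cannot change
#' the correlation (asserted internally).
#'
#' @param ds a [CohortDataset-class] (markers on log scale).
#' @param echoIds echo variable identifiers.
#' @param markerIds reference protein marker identifiers.
#' @param zscore logical; Z-score the marker means (no effect on `r`).
#' @return data.frame: `echo_id`, `marker_id`, `spearman`, `ci_low`,
#'   `ci_high`, `p_value`, `n`.
#' @export
referenceMarkerCorrelations <- function(ds, echoIds, markerIds,
                                        zscore = TRUE) {
  rows <- list()
  for (e in echoIds) for (mk in markerIds) {
    sp <- withinPatientMeanSpearman(ds, mk, e)
    if (zscore) {
      ## rank invariance: Z-scoring the marker means must leave r unchanged
      m <- measurements(ds)
      mm <- tapply(m$value[m$variable_id == mk & m$variable_type == "protein"],
                   m$patient_id[m$variable_id == mk & m$variable_type == "protein"],
                   mean)
      me <- tapply(m$value[m$variable_id == e & m$variable_type == "echo"],
                   m$patient_id[m$variable_id == e & m$variable_type == "echo"],
                   mean)
      common <- intersect(names(mm), names(me))
      rz <- cor(scale(mm[common])[, 1], me[common], method = "spearman")
      stopifnot(abs(rz - sp$estimate) < 1e-12)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      echo_id = e, marker_id = mk, spearman = sp$estimate,
      ci_low = sp$ciLow, ci_high = sp$ciHigh, p_value = sp$pValue,
      n = sp$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
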