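## Synthetic cohort generator: cohorts with the exact statistical structure
## the analysis assumes (bivariate LME with correlated patient-level random
## effects), with known ground truth, for calibration and recovery studies.

defaultEchoVars <- function(echoTimes) {
  stopifnot(length(echoTimes) == 3)
  ## anchor means qualitatively mimic post-MI remodeling: atrial and
  ## ventricular volumes rise then flatten, ejection fraction recovers
  data.frame(
    name = c("AV", "LVEDV", "LVEF"),
    ageEffect = c(0.05, 0.10, -0.05),
    sexEffect = c(-1.5, -4.0, 1.5),
    reSD = c(5.5, 13.0, 7.5),
    residSD = c(2.5, 6.0, 4.0),
    stringsAsFactors = FALSE
  ) -> ev
  ev$anchorMeans <- list(c(20.5, 24.6, 25.4), c(52.3, 59.4, 62.3),
                         c(49.3, 53.9, 55.2))
  ev
}

#' Configuration of a synthetic post-MI cohort
#'
#' Defines a cohort of `nPatients` patients with echocardiographic variables
#' measured at `echoTimes` (discharge coded 0) and a protein panel measured
#' at `proteinTimes` (no baseline protein sample, mirroring the exclusion of
#' acute-phase measurements).  Ages are Uniform(40, 80), sex is Bernoulli
#' (19% female by default).  Each variable follows the generative bivariate
#' mixed model: a natural-spline population curve through its anchor means,
#' age and sex main effects, patient-level random effects, and Gaussian
#' residual noise.  Each "true" protein's random intercept is correlated
#' (`rho`) with its target echo variable's random intercept; remaining
#' proteins are null.  Protein trajectories are generated on the log scale
#' and exponentiated on output (assay-like strictly positive units), so the
#' pipeline's log-transform step is exercised end to end.
#'
#' @param nPatients cohort size (default 246, the study scale).
#' @param nProteins panel size.
#' @param nTrue number of proteins with a nonzero cross-correlation.
#' @param rho cross-outcome random-intercept correlation of true proteins.
#' @param targetEcho echo variable the true proteins couple to.
#' @param echoTimes,proteinTimes visit grids in months (protein times must
#'   be positive).
#' @param structureP,structureE generative random-effect structures (see
#'   [structureDim()]); the cross-correlation always links the intercepts.
#' @param echoVars data.frame of echo variable definitions (`name`,
#'   `anchorMeans` list-column, `ageEffect`, `sexEffect`, `reSD`,
#'   `residSD`).
#' @param proteinReSD,proteinResidSD,proteinAgeEffect,proteinSexEffect
#'   protein-side generative parameters (log scale).
#' @param proteinAnchorMeans log-scale population means at `proteinTimes`.
#' @param reSDExtraP,reSDExtraE SDs of non-intercept random components when
#'   structures richer than `"intercept"` are requested.
#' @param femaleProb probability of female sex.
#' @param missingness visit-level missingness probability in `[0, 1)`.
#' @param missLevel `"visit"` (a missed visit drops all of a modality's
#'   variables at that time) or `"variable"` (independent per row).
#' @param seed integer seed; generation is deterministic given the config.
#' @return An object of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nPatients = 246L, nProteins = 20L, nTrue = 5L,
                            rho = 0.6, targetEcho = "AV",
                            echoTimes = c(0, 3, 12),
                            proteinTimes = c(1, 3, 12),
                            structureP = "intercept",
                            structureE = "intercept",
                            echoVars = NULL,
                            proteinReSD = 0.35, proteinResidSD = 0.25,
                            proteinAgeEffect = 0.005,
                            proteinSexEffect = 0.1,
                            proteinAnchorMeans = NULL,
                            reSDExtraP = NULL, reSDExtraE = NULL,
                            femaleProb = 0.19,
                            missingness = 0.05,
                            missLevel = c("visit", "variable"),
                            seed = 1L) {
  missLevel <- match.arg(missLevel)
  structureP <- match.arg(structureP, names(RE_KINDS))
  structureE <- match.arg(structureE, names(RE_KINDS))
  if (is.null(echoVars)) echoVars <- defaultEchoVars(echoTimes)
  if (is.null(proteinAnchorMeans))
    proteinAnchorMeans <- 7 + 0.02 * seq_along(proteinTimes)
  stopifnot(nPatients >= 2, nProteins >= 1, nTrue >= 0, nTrue <= nProteins,
            abs(rho) < 1, all(proteinTimes > 0), all(echoTimes >= 0),
            missingness >= 0, missingness < 1,
            length(proteinAnchorMeans) == length(proteinTimes),
            targetEcho %in% echoVars$name)
  qP <- structureDim(structureP)
  qE <- structureDim(structureE)
  if (is.null(reSDExtraP)) reSDExtraP <- rep(0.15, qP - 1)
  if (is.null(reSDExtraE)) reSDExtraE <- rep(0.3, qE - 1)
  stopifnot(length(reSDExtraP) == qP - 1, length(reSDExtraE) == qE - 1)

  proteins <- data.frame(
    protein_id = sprintf("PROT%04d", seq_len(nProteins)),
    target_echo = c(rep(targetEcho, nTrue),
                    rep(NA_character_, nProteins - nTrue)),
    rho = c(rep(rho, nTrue), rep(0, nProteins - nTrue)),
    stringsAsFactors = FALSE)

  cfg <- structure(list(
    nPatients = as.integer(nPatients), echoTimes = echoTimes,
    proteinTimes = proteinTimes, echoVars = echoVars, proteins = proteins,
    structureP = structureP, structureE = structureE,
    proteinReSD = proteinReSD, proteinResidSD = proteinResidSD,
    proteinAgeEffect = proteinAgeEffect,
    proteinSexEffect = proteinSexEffect,
    proteinAnchorMeans = proteinAnchorMeans,
    reSDExtraP = reSDExtraP, reSDExtraE = reSDExtraE,
    femaleProb = femaleProb, missingness = missingness,
    missLevel = missLevel, seed = as.integer(seed)),
    class = "SyntheticConfig")
  validateSyntheticConfig(cfg)
  cfg
}

## per-pair joint random-effects covariance (intercept cross-link only)
pairTruthD <- function(cfg, echoRow, rho) {
  qP <- structureDim(cfg$structureP)
  qE <- structureDim(cfg$structureE)
  DP <- diag(c(cfg$proteinReSD, cfg$reSDExtraP)^2, qP)
  DE <- diag(c(echoRow$reSD, cfg$reSDExtraE)^2, qE)
  D <- matrix(0, qP + qE, qP + qE)
  D[seq_len(qP), seq_len(qP)] <- DP
  D[qP + seq_len(qE), qP + seq_len(qE)] <- DE
  D[1, qP + 1] <- D[qP + 1, 1] <- rho * cfg$proteinReSD * echoRow$reSD
  D
}

validateSyntheticConfig <- function(cfg) {
  for (i in seq_len(nrow(cfg$proteins))) {
    te <- cfg$proteins$target_echo[i]
    if (is.na(te)) next
    erow <- cfg$echoVars[cfg$echoVars$name == te, ]
    D <- pairTruthD(cfg, erow, cfg$proteins$rho[i])
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-12)
      stop("config: joint random-effects covariance for protein ",
           cfg$proteins$protein_id[i], " is not positive semi-definite")
  }
  invisible(cfg)
}

#' Zero all cross-outcome correlations of a synthetic config
#'
#' Returns an identical config whose every protein has `rho = 0` and no
#' target echo variable (the within-outcome covariance blocks are
#' unchanged).  Idempotent; used as the truth for null-calibration runs.
#'
#' @param cfg a `SyntheticConfig`.
#' @return the null config.
#' @export
makeNullConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  cfg$proteins$rho <- 0
  cfg$proteins$target_echo <- NA_character_
  cfg
}

## intercept + time-basis design at the grid times; degrades to a linear
## (or constant) basis for grids with fewer than 3 distinct times
curveBasis <- function(times, splineSpec) {
  if (!is.null(splineSpec)) cbind(1, evaluateBasis(splineSpec, times))
  else if (length(unique(times)) >= 2) cbind(1, times)
  else matrix(1, length(times), 1)
}

## population curve coefficients reproducing the anchor means at the grid
## times, at reference covariates (age 60, male); least squares when the
## grid has more times than basis columns
curveCoefs <- function(times, anchorMeans, splineSpec, ageEffect) {
  qr.solve(curveBasis(times, splineSpec), anchorMeans - ageEffect * 60)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a cohort under the generative model of [syntheticConfig()] and
#' returns both the dataset (protein values exponentiated to assay-like
#' positive units, `proteinLogApplied = FALSE`) and a `SyntheticTruth`
#' record of every generating parameter and realized random effect.  The
#' truth object is for test harnesses only and is never consumed by any
#' fitting code path.
#'
#' @param cfg a `SyntheticConfig`.
#' @return list with elements `dataset` ([CohortDataset-class]) and `truth`
#'   (`SyntheticTruth`).
#' @export
generateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  validateSyntheticConfig(cfg)
  oldseed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed, .GlobalEnv),
          add = TRUE)
  set.seed(cfg$seed)

  n <- cfg$nPatients
  ids <- sprintf("P%04d", seq_len(n))
  age <- runif(n, 40, 80)
  sex <- ifelse(rbinom(n, 1, cfg$femaleProb) == 1, "female", "male")
  sexF <- as.numeric(sex == "female")
  qP <- structureDim(cfg$structureP)
  qE <- structureDim(cfg$structureE)

  eSpec <- tryCatch(makeSplineSpec(rep(cfg$echoTimes, 2)),
                    error = function(e) NULL)
  pSpec <- tryCatch(makeSplineSpec(rep(cfg$proteinTimes, 2)),
                    error = function(e) NULL)
  if (cfg$structureE == "intercept_spline2" && is.null(eSpec))
    stop("config: spline structure needs >= 3 distinct echo times")
  if (cfg$structureP == "intercept_spline2" && is.null(pSpec))
    stop("config: spline structure needs >= 3 distinct protein times")
  zE <- zColumns(cfg$structureE, cfg$echoTimes, eSpec)
  zP <- zColumns(cfg$structureP, cfg$proteinTimes, pSpec)

  rows <- list()
  bE <- list()
  curves <- list()
  for (i in seq_len(nrow(cfg$echoVars))) {
    ev <- cfg$echoVars[i, ]
    beta <- curveCoefs(cfg$echoTimes, ev$anchorMeans[[1]], eSpec,
                       ev$ageEffect)
    curves[[ev$name]] <- beta
    sdsE <- c(ev$reSD, cfg$reSDExtraE)
    b <- matrix(rnorm(n * qE), n, qE) %*% diag(sdsE, qE)
    bE[[ev$name]] <- b
    mu <- outer(rep(1, n), drop(curveBasis(cfg$echoTimes, eSpec) %*% beta)) +
      age * ev$ageEffect + sexF * ev$sexEffect + b %*% t(zE)
    val <- mu + matrix(rnorm(n * length(cfg$echoTimes), 0, ev$residSD),
                       n, length(cfg$echoTimes))
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = rep(ids, times = length(cfg$echoTimes)),
      time_months = rep(cfg$echoTimes, each = n),
      variable_id = ev$name, variable_type = "echo",
      value = as.vector(val), stringsAsFactors = FALSE)
  }

  bP <- list()
  pCurve <- curveCoefs(cfg$proteinTimes, cfg$proteinAnchorMeans, pSpec,
                       cfg$proteinAgeEffect)
  muFixedP <- drop(curveBasis(cfg$proteinTimes, pSpec) %*% pCurve)
  for (i in seq_len(nrow(cfg$proteins))) {
    pid <- cfg$proteins$protein_id[i]
    rho <- cfg$proteins$rho[i]
    te <- cfg$proteins$target_echo[i]
    sP <- cfg$proteinReSD
    b <- matrix(rnorm(n * qP), n, qP) %*% diag(c(sP, cfg$reSDExtraP), qP)
    if (!is.na(te) && rho != 0) {
      sE <- cfg$echoVars$reSD[cfg$echoVars$name == te]
      ## conditional draw: bP1 | bE1 ~ N(rho sP/sE bE1, sP^2 (1 - rho^2))
      b[, 1] <- rho * (sP / sE) * bE[[te]][, 1] +
        sqrt(1 - rho^2) * b[, 1]
    }
    bP[[pid]] <- b
    mu <- outer(rep(1, n), muFixedP) + age * cfg$proteinAgeEffect +
      sexF * cfg$proteinSexEffect + b %*% t(zP)
    val <- mu + matrix(rnorm(n * length(cfg$proteinTimes), 0,
                             cfg$proteinResidSD),
                       n, length(cfg$proteinTimes))
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = rep(ids, times = length(cfg$proteinTimes)),
      time_months = rep(cfg$proteinTimes, each = n),
      variable_id = pid, variable_type = "protein",
      value = as.vector(exp(val)), stringsAsFactors = FALSE)
  }

  m <- do.call(rbind, rows)

  if (cfg$missingness > 0) {
    if (cfg$missLevel == "visit") {
      ## one Bernoulli per (patient, modality, time): a missed echo visit
      ## drops all echo variables at that time, likewise protein samples
      grid <- rbind(
        expand.grid(patient_id = ids, time_months = cfg$echoTimes,
                    variable_type = "echo", stringsAsFactors = FALSE),
        expand.grid(patient_id = ids, time_months = cfg$proteinTimes,
                    variable_type = "protein", stringsAsFactors = FALSE))
      grid$miss <- runif(nrow(grid)) < cfg$missingness
      key <- paste(grid$patient_id, grid$time_months, grid$variable_type)
      missKey <- key[grid$miss]
      keep <- !(paste(m$patient_id, m$time_months, m$variable_type) %in%
                  missKey)
    } else {
      keep <- runif(nrow(m)) >= cfg$missingness
    }
    m <- m[keep, , drop = FALSE]
  }

  cv <- data.frame(patient_id = ids, age_years = age, sex = sex,
                   stringsAsFactors = FALSE)
  ds <- CohortDataset(m, cv, proteinLogApplied = FALSE)
  truth <- structure(list(
    config = cfg, ages = age, sex = sex, curves = curves,
    proteinCurve = pCurve, bE = bE, bP = bP,
    pairD = lapply(seq_len(nrow(cfg$proteins)), function(i) {
      te <- cfg$proteins$target_echo[i]
      erow <- cfg$echoVars[cfg$echoVars$name ==
                             (if (is.na(te)) cfg$echoVars$name[1] else te), ]
      pairTruthD(cfg, erow, cfg$proteins$rho[i])
    })), class = "SyntheticTruth")
  list(dataset = ds, truth = truth)
}
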