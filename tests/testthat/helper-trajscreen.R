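# Shared fixtures and independent oracles, all built in code.

# Independent dense-covariance oracle: per-patient log density of the
# stacked response under N(X beta, Z D Z' + R), assembling and factorizing
# the full n_i x n_i marginal covariance (the implementation never does).
denseLoglik <- function(bundle, beta, sigma2P, sigma2E, D) {
  rvar <- ifelse(bundle$grp == 0L, sigma2P, sigma2E)
  ll <- 0
  for (i in seq_along(bundle$patients)) {
    idx <- (bundle$ptr[i] + 1):bundle$ptr[i + 1]
    Zi <- bundle$Z[idx, , drop = FALSE]
    V <- Zi %*% D %*% t(Zi) + diag(rvar[idx], length(idx))
    r <- bundle$y[idx] - drop(bundle$X[idx, , drop = FALSE] %*% beta)
    L <- chol(V)
    ll <- ll - 0.5 * (length(idx) * log(2 * pi) + 2 * sum(log(diag(L))) +
                        sum(backsolve(L, r, transpose = TRUE)^2))
  }
  ll
}

# random small design bundle (not via assemblePairDesign): 3 patients with
# up to 4 observations each, random designs and a random PD D
randomBundle <- function(seed, q = 2L, p = 3L) {
  set.seed(seed)
  nObs <- sample(2:4, 3, replace = TRUE)
  n <- sum(nObs)
  A <- matrix(rnorm(q * q), q)
  list(y = rnorm(n), X = matrix(rnorm(n * p), n, p),
       Z = matrix(rnorm(n * q), n, q),
       ptr = as.integer(c(0, cumsum(nObs))),
       grp = sample(0:1, n, replace = TRUE),
       patients = paste0("P", 1:3), qP = q, qE = 0L, n = n,
       D = crossprod(A) + 0.1 * diag(q),
       beta = rnorm(p), sigma2P = exp(rnorm(1)), sigma2E = exp(rnorm(1)))
}

# single-echo-variable cohort definition (keeps generation cheap)
avOnlyEchoVars <- function(anchors = c(20.5, 24.6, 25.4), residSD = 2.5) {
  ev <- data.frame(name = "AV", ageEffect = 0.05, sexEffect = -1.5,
                   reSD = 5.5, residSD = residSD, stringsAsFactors = FALSE)
  ev$anchorMeans <- list(anchors)
  ev
}

# generate + log-transform + design filters in one step
preparedCohort <- function(cfg) {
  suppressMessages(
    applyDesignFilters(logTransformProteins(generateCohort(cfg)$dataset)))
}

riLadder <- list(c("intercept", "intercept"))

# hand-built toy measurement/covariate tables (2 patients, echo + protein)
toyMeasurements <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2", "P2"),
    time_months = c(0, 3, 3, 0, 3, 12),
    variable_id = c("LVEF", "LVEF", "PROTA", "LVEF", "PROTA", "PROTA"),
    variable_type = c("echo", "echo", "protein", "echo", "protein", "protein"),
    value = c(49, 54, 1200, 45, 1100, 1350),
    stringsAsFactors = FALSE)
}

toyCovariates <- function() {
  data.frame(patient_id = c("P1", "P2"), age_years = c(61, 55),
             sex = c("female", "male"), stringsAsFactors = FALSE)
}

writeToyFiles <- function(m = toyMeasurements(), cv = toyCovariates(),
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "measurements.csv")
  cp <- file.path(dir, "covariates.csv")
  write.csv(m, mp, row.names = FALSE, na = "")
  write.csv(cv, cp, row.names = FALSE, na = "")
  list(measurements = mp, covariates = cp)
}

# fit one (protein, echo) pair under both constraints with the nesting-safe
# null-embedded start, returning fits and the LRT
fitBothAndTest <- function(ds, proteinId, echoId,
                           structP = "intercept", structE = "intercept",
                           seed = 1L) {
  spec <- pairModelSpec(ds, proteinId, echoId, structP, structE)
  b <- assemblePairDesign(ds, proteinId, echoId, spec)
  fn <- fitPair(b, "block_diagonal", seed = seed)
  ff <- fitPair(b, "full", seed = seed + 1L,
                extraInits = list(trajscreen:::embedNullTheta(fn, b$qP, b$qE)))
  list(bundle = b, fitNull = fn, fitFull = ff,
       lrt = if (fn$converged && ff$converged) lrtCrossBlock(ff, fn) else NULL)
}

crossCorr <- function(fit) {
  qP <- fit$qP
  fit$D[1, qP + 1] / sqrt(fit$D[1, 1] * fit$D[qP + 1, qP + 1])
}
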