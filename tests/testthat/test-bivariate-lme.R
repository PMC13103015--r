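test_that("stacked pair design has the forced dimensions and indicator blocks", {
  cfg <- syntheticConfig(nPatients = 8, nProteins = 1, nTrue = 0,
                         echoVars = avOnlyEchoVars(), missingness = 0,
                         seed = 5)
  ds <- preparedCohort(cfg)
  spec <- pairModelSpec(ds, "PROT0001", "AV", "intercept", "intercept")
  b <- assemblePairDesign(ds, "PROT0001", "AV", spec)
  expect_equal(b$n, 8 * 6)
  expect_equal(ncol(b$Z), 2)          # RI + RI
  expect_equal(ncol(b$X), 10)         # (intercept, age, sex, 2 spline) x 2
  # per patient: protein rows then echo rows, indicators zero off-outcome
  idx <- (b$ptr[1] + 1):b$ptr[2]
  expect_equal(b$grp[idx], c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(b$Z[idx, 1], c(1, 1, 1, 0, 0, 0))
  expect_equal(b$Z[idx, 2], c(0, 0, 0, 1, 1, 1))

  # patient observed on one outcome only still contributes
  m <- measurements(ds)
  drop <- m$patient_id == "P0001" & m$variable_type == "protein"
  ds2 <- CohortDataset(m[!drop, ], covariates(ds), proteinLogApplied = TRUE)
  b2 <- assemblePairDesign(ds2, "PROT0001", "AV", spec)
  idx2 <- (b2$ptr[1] + 1):b2$ptr[2]
  expect_equal(length(idx2), 3)
  expect_true(all(b2$Z[idx2, 1] == 0))

  expect_error(assemblePairDesign(ds, "PROT0001", "NOPE"), "unknown echo")
  expect_error(assemblePairDesign(ds, "NOPE", "AV"), "unknown protein")
})

test_that("marginal log-likelihood matches closed form and dense oracle", {
  # single standard-normal observation
  b1 <- list(y = 0, X = matrix(0, 1, 1), Z = matrix(0, 1, 1),
             ptr = c(0L, 1L), grp = 1L, patients = "P1", n = 1)
  expect_equal(marginalLoglik(b1, beta = 0, sigma2P = 1, sigma2E = 1,
                              D = diag(1)),
               -0.5 * log(2 * pi), tolerance = 1e-10)

  # structured (Woodbury) evaluation vs dense multivariate-normal density
  for (seed in 1:10) {
    rb <- randomBundle(seed)
    ll <- marginalLoglik(rb, rb$beta, rb$sigma2P, rb$sigma2E, rb$D)
    expect_equal(ll, denseLoglik(rb, rb$beta, rb$sigma2P, rb$sigma2E, rb$D),
                 tolerance = 1e-8)
  }

  # permuting a patient's observation rows leaves the loglik unchanged
  rb <- randomBundle(99)
  idx <- (rb$ptr[2] + 1):rb$ptr[3]
  perm <- sample(idx)
  rb2 <- rb
  rb2$y[idx] <- rb$y[perm]
  rb2$X[idx, ] <- rb$X[perm, ]
  rb2$Z[idx, ] <- rb$Z[perm, ]
  rb2$grp[idx] <- rb$grp[perm]
  expect_equal(marginalLoglik(rb, rb$beta, rb$sigma2P, rb$sigma2E, rb$D),
               marginalLoglik(rb2, rb$beta, rb$sigma2P, rb$sigma2E, rb$D),
               tolerance = 1e-10)

  # non-PD covariance is a numerical error
  expect_error(marginalLoglik(rb, rb$beta, rb$sigma2P, rb$sigma2E,
                              matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("likelihood is invariant to invertible reparameterization of the basis", {
  cfg <- syntheticConfig(nPatients = 40, nProteins = 1, nTrue = 1, rho = 0.5,
                         echoVars = avOnlyEchoVars(), missingness = 0,
                         seed = 31)
  ds <- preparedCohort(cfg)
  spec <- pairModelSpec(ds, "PROT0001", "AV", "intercept", "intercept")
  b <- assemblePairDesign(ds, "PROT0001", "AV", spec)
  beta <- rnorm(ncol(b$X), 0, 0.3)
  D <- matrix(c(0.2, 0.1, 0.1, 4), 2)
  ll0 <- marginalLoglik(b, beta, 0.05, 6, D)

  # transform the two protein spline fixed columns by an invertible map
  Tm <- matrix(c(2, 0.5, -1, 1.5), 2)
  b2 <- b
  cols <- match(c("P.ns1", "P.ns2"), colnames(b$X))
  b2$X[, cols] <- b$X[, cols] %*% Tm
  beta2 <- beta
  beta2[cols] <- solve(Tm) %*% beta[cols]
  expect_equal(marginalLoglik(b2, beta2, 0.05, 6, D), ll0, tolerance = 1e-6)

  # transform the random design; map D accordingly
  b3 <- b
  b3$Z <- b$Z %*% Tm
  D3 <- solve(Tm) %*% D %*% t(solve(Tm))
  D3 <- (D3 + t(D3)) / 2
  expect_equal(marginalLoglik(b3, beta, 0.05, 6, D3), ll0, tolerance = 1e-6)
})

test_that("ML fit recovers a known cross-correlation and nests properly", {
  cfg <- syntheticConfig(nPatients = 500, nProteins = 1, nTrue = 1,
                         rho = 0.6, echoVars = avOnlyEchoVars(),
                         seed = 42)
  ds <- preparedCohort(cfg)
  r <- fitBothAndTest(ds, "PROT0001", "AV")
  expect_true(r$fitFull$converged && r$fitNull$converged)
  expect_lt(abs(crossCorr(r$fitFull) - 0.6), 0.08)
  # nesting: full likelihood dominates the constrained one
  expect_gte(r$fitFull$loglik, r$fitNull$loglik - 1e-6)
  # the off-block of the null fit is exactly zero
  expect_identical(r$fitNull$D[1, 2], 0)
  expect_true(r$lrt$statistic >= 0)
})

test_that("LRT degrees of freedom equal the cross-block size and p is chi-squared",
{
  fakeFit <- function(ll, constraint, qP = 1L, qE = 1L)
    structure(list(loglik = ll, constraint = constraint, converged = TRUE,
                   qP = qP, qE = qE), class = "FitResult")
  # statistic 3.8415 on 1 df sits at the 5% point
  lrt <- lrtCrossBlock(fakeFit(-100 + 3.8415 / 2, "full"),
                       fakeFit(-100, "block_diagonal"))
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$pValue, 0.05, tolerance = 1e-3)
  # (RI+spline2, RI+slope) crosses 3 x 2 = 6 covariances
  lrt6 <- lrtCrossBlock(fakeFit(-50, "full", 3L, 2L),
                        fakeFit(-52, "block_diagonal", 3L, 2L))
  expect_equal(lrt6$df, 6L)
  # non-converged input is a state error
  nc <- fakeFit(-49, "full"); nc$converged <- FALSE
  expect_error(lrtCrossBlock(nc, fakeFit(-50, "block_diagonal")), "state")
  # a clearly negative statistic is a numerical error
  expect_error(lrtCrossBlock(fakeFit(-51, "full"),
                             fakeFit(-50, "block_diagonal")), "negative")
})

test_that("echo rescaling scales sigma_E and leaves the LRT statistic invariant", {
  cfg <- syntheticConfig(nPatients = 120, nProteins = 1, nTrue = 1,
                         rho = 0.5, echoVars = avOnlyEchoVars(),
                         missingness = 0, seed = 8)
  ds <- preparedCohort(cfg)
  r1 <- fitBothAndTest(ds, "PROT0001", "AV")
  cmul <- 3.7
  m <- measurements(ds)
  m$value[m$variable_type == "echo"] <- cmul * m$value[m$variable_type == "echo"]
  ds2 <- CohortDataset(m, covariates(ds), proteinLogApplied = TRUE)
  r2 <- fitBothAndTest(ds2, "PROT0001", "AV")
  expect_equal(sqrt(r2$fitFull$sigma2E) / sqrt(r1$fitFull$sigma2E), cmul,
               tolerance = 1e-3)
  expect_equal(r2$lrt$statistic, r1$lrt$statistic, tolerance = 1e-4)
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  cfg <- syntheticConfig(nPatients = 80, nProteins = 1, nTrue = 1, rho = 0.5,
                         echoVars = avOnlyEchoVars(), missingness = 0,
                         seed = 21)
  ds <- preparedCohort(cfg)

  # univariate: random-intercept trajectory model
  b <- trajscreen:::assembleUnivariateDesign(ds, "AV", "intercept")
  f <- trajscreen:::fitCore(b, blockDims = 1L, nSigma = 1L, seed = 1)
  df1 <- data.frame(y = b$y, b$X[, -1], pat = rep(b$patients, diff(b$ptr)))
  m1 <- nlme::lme(y ~ age + sexF + ns1 + ns2, random = ~ 1 | pat,
                  data = df1, method = "ML")
  expect_equal(f$loglik, as.numeric(stats::logLik(m1)), tolerance = 1e-4)
  expect_equal(unname(f$beta), unname(nlme::fixef(m1)), tolerance = 1e-5)
  expect_equal(f$sigma2[1], m1$sigma^2, tolerance = 1e-3)

  # bivariate full model vs stacked lme with outcome-indicator random effects
  r <- fitBothAndTest(ds, "PROT0001", "AV")
  bb <- r$bundle
  df2 <- data.frame(y = bb$y, bb$X, indP = as.numeric(bb$grp == 0),
                    indE = as.numeric(bb$grp == 1),
                    outc = ifelse(bb$grp == 0, "P", "E"),
                    pat = rep(bb$patients, diff(bb$ptr)))
  m2 <- nlme::lme(y ~ 0 + P.intercept + P.age + P.sexF + P.ns1 + P.ns2 +
                    E.intercept + E.age + E.sexF + E.ns1 + E.ns2,
                  random = ~ 0 + indP + indE | pat, data = df2,
                  method = "ML", weights = nlme::varIdent(form = ~ 1 | outc),
                  control = nlme::lmeControl(opt = "optim"))
  expect_equal(r$fitFull$loglik, as.numeric(stats::logLik(m2)),
               tolerance = 1e-3)
  vc <- suppressWarnings(nlme::VarCorr(m2))
  expect_equal(crossCorr(r$fitFull), as.numeric(vc["indE", "Corr"]),
               tolerance = 1e-2)
})

test_that("time-shift of the whole schedule leaves fitted trajectories unchanged", {
  cfg <- syntheticConfig(nPatients = 100, nProteins = 1, nTrue = 0,
                         echoVars = avOnlyEchoVars(), missingness = 0,
                         seed = 13)
  ds <- preparedCohort(cfg)
  fit0 <- fitUnivariateTrajectory(ds, "AV", evalTimes = c(0, 3, 12))
  m <- measurements(ds)
  m$time_months <- m$time_months + 5
  dsS <- CohortDataset(m, covariates(ds), proteinLogApplied = TRUE)
  fitS <- fitUnivariateTrajectory(dsS, "AV", evalTimes = c(0, 3, 12) + 5)
  expect_equal(fitS$profile$mean, fit0$profile$mean, tolerance = 1e-2)
})
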