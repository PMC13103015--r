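test_that("default ladder starts rich, never increases total dimension, ends at RI/RI", {
  lad <- defaultLadder()
  dims <- vapply(lad, function(x) structureDim(x[1]) + structureDim(x[2]),
                 numeric(1))
  expect_equal(dims[1], 6)
  expect_true(all(diff(dims) <= 0))
  expect_equal(lad[[length(lad)]], c("intercept", "intercept"))
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.3), 0.3)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "domain")

  # NA entries are excluded from the family and re-inserted as NA
  q <- bhAdjust(c(0.01, NA, 0.02, 0.03, NA, 0.04))
  expect_true(all(is.na(q[c(2, 5)])))
  expect_equal(q[!is.na(q)], rep(0.04, 4))

  # permutation invariance and monotonicity in the order statistics
  set.seed(3)
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("within-patient-mean Spearman matches the rank formula", {
  mkds <- function(protMeans, echoMeans) {
    n <- length(protMeans)
    ids <- paste0("P", seq_len(n))
    m <- rbind(
      data.frame(patient_id = ids, time_months = 3, variable_id = "PR",
                 variable_type = "protein", value = protMeans),
      data.frame(patient_id = ids, time_months = 3, variable_id = "AV",
                 variable_type = "echo", value = echoMeans))
    CohortDataset(m, data.frame(patient_id = ids, age_years = 60,
                                sex = "male"), proteinLogApplied = TRUE)
  }
  expect_equal(withinPatientMeanSpearman(mkds(1:3, c(10, 20, 30)),
                                         "PR", "AV")$estimate, 1)
  expect_equal(withinPatientMeanSpearman(mkds(1:3, c(30, 20, 10)),
                                         "PR", "AV")$estimate, -1)
  # sum d^2 = 4, n = 5: 1 - 6*4/(5*24) = 0.8
  sp <- withinPatientMeanSpearman(mkds(1:5, c(1, 3, 2, 5, 4)), "PR", "AV")
  expect_equal(sp$estimate, 0.8)
  expect_equal(sp$n, 5)
  # sum d^2 = 6, n = 5: 1 - 6*6/(5*24) = 0.7
  expect_equal(withinPatientMeanSpearman(mkds(1:5, c(1, 2, 4, 5, 3)),
                                         "PR", "AV")$estimate, 0.7)
  expect_true(sp$ciLow < 0.7 && sp$ciHigh > 0.7)
  expect_error(withinPatientMeanSpearman(mkds(1:2, 1:2), "PR", "AV"),
               "fewer than 3")

  # averaging over each patient's multiple visits comes first
  ds5 <- mkds(1:5, c(1, 3, 2, 5, 4))
  m <- measurements(ds5)
  extra <- data.frame(patient_id = "P1", time_months = 12, variable_id = "PR",
                      variable_type = "protein", value = 9)
  ds6 <- CohortDataset(rbind(m, extra), covariates(ds5),
                       proteinLogApplied = TRUE)
  # patient 1's protein mean becomes (1+9)/2 = 5 -> new rank order
  sp6 <- withinPatientMeanSpearman(ds6, "PR", "AV")
  expect_equal(sp6$estimate, cor(c(5, 2:5), c(1, 3, 2, 5, 4),
                                 method = "spearman"))
})

test_that("fallback ladder respects identifiability of the protein side", {
  # protein observed at only 2 distinct times: spline structures must be
  # skipped for the protein side
  cfg <- syntheticConfig(nPatients = 60, nProteins = 1, nTrue = 1, rho = 0.6,
                         proteinTimes = c(3, 12),
                         proteinAnchorMeans = c(7, 7.1),
                         echoVars = avOnlyEchoVars(), missingness = 0,
                         seed = 17)
  ds <- preparedCohort(cfg)
  expect_error(pairModelSpec(ds, "PROT0001", "AV",
                             structureP = "intercept_spline2"),
               "identifiability")
  res <- fitPairWithFallback(ds, "PROT0001", "AV", seed = 1)
  expect_false(identical(res$structureP, "intercept_spline2"))

  # single-visit data: no candidate is identifiable -> converged = FALSE
  ev <- avOnlyEchoVars(anchors = 20.5)
  cfg1 <- syntheticConfig(nPatients = 50, nProteins = 1, nTrue = 0,
                          echoTimes = 3, proteinTimes = 3, echoVars = ev,
                          missingness = 0, seed = 3)
  ds1 <- preparedCohort(cfg1)
  r1 <- fitPairWithFallback(ds1, "PROT0001", "AV", seed = 1)
  expect_false(r1$converged)
  expect_null(r1$lrt)
})

test_that("screen produces one tested row per pair with per-echo FDR families", {
  cfg <- syntheticConfig(nPatients = 120, nProteins = 3, nTrue = 1,
                         rho = 0.7, missingness = 0, seed = 23)
  ds <- preparedCohort(cfg)
  res <- suppressMessages(
    runScreen(ds, echoIds = c("AV", "LVEF"),
              proteinIds = paste0("PROT000", 1:3),
              config = list(ladder = riLadder, seed = 7)))
  expect_equal(nrow(res), 6)
  expect_equal(sort(unique(res$echo_id)), c("AV", "LVEF"))
  # FDR is applied within each echo family independently
  for (e in c("AV", "LVEF")) {
    idx <- res$echo_id == e
    expect_equal(res$fdr_q[idx], bhAdjust(res$p_value[idx]))
  }
  expect_true(all(res$fdr_q >= res$p_value, na.rm = TRUE))
  # the truly coupled protein is the top AV hit
  av <- res[res$echo_id == "AV", ]
  expect_equal(av$protein_id[which.min(av$p_value)], "PROT0001")

  # determinism: identical config and seed reproduce the table exactly
  res2 <- suppressMessages(
    runScreen(ds, echoIds = c("AV", "LVEF"),
              proteinIds = paste0("PROT000", 1:3),
              config = list(ladder = riLadder, seed = 7)))
  expect_identical(res, res2)

  expect_error(runScreen(ds, character(0), "PROT0001"), "config")
})

test_that("non-converged pairs are excluded from the BH family", {
  cfg <- syntheticConfig(nPatients = 100, nProteins = 2, nTrue = 0,
                         echoVars = avOnlyEchoVars(), missingness = 0,
                         seed = 29)
  ds <- preparedCohort(cfg)
  # cripple PROT0002: keep only its 3-month visit -> unidentifiable
  m <- measurements(ds)
  drop <- m$variable_id == "PROT0002" & m$time_months != 3
  ds2 <- CohortDataset(m[!drop, ], covariates(ds), proteinLogApplied = TRUE)
  expect_message(
    res <- runScreen(ds2, "AV", c("PROT0001", "PROT0002"),
                     config = list(ladder = riLadder, seed = 7)),
    "did not converge")
  bad <- res[res$protein_id == "PROT0002", ]
  expect_false(bad$converged)
  expect_true(is.na(bad$p_value) && is.na(bad$fdr_q))
  good <- res[res$protein_id == "PROT0001", ]
  # family size 1: q equals p
  expect_equal(good$fdr_q, good$p_value)
})
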