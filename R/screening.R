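## Panel-wide screening: fallback ladder, LRT per pair, BH-FDR, and the
## directional within-patient-mean Spearman summary.

#' Default fallback ladder of random-effect structure pairs
#'
#' Candidate (protein, echo) random-effect structures tried in order of
#' non-increasing total dimension, starting from the full 2-df spline
#' structure on both outcomes and terminating at (intercept, intercept).
#' Asymmetric combinations are included; within equal total dimension the
#' protein side is reduced first.
#'
#' @return list of length-2 character vectors `c(structureP, structureE)`.
#' @export
defaultLadder <- function() {
  list(c("intercept_spline2", "intercept_spline2"),
       c("intercept_spline2", "intercept_slope"),
       c("intercept_slope", "intercept_spline2"),
       c("intercept_slope", "intercept_slope"),
       c("intercept_spline2", "intercept"),
       c("intercept", "intercept_spline2"),
       c("intercept_slope", "intercept"),
       c("intercept", "intercept_slope"),
       c("intercept", "intercept"))
}

## deterministic per-pair seed independent of processing order
pairSeed <- function(baseSeed, proteinId, echoId) {
  h <- sum(utf8ToInt(paste(proteinId, echoId, sep = "|")) *
             (seq_along(utf8ToInt(paste(proteinId, echoId, sep = "|"))) %% 7 + 1))
  (as.integer(baseSeed) + (h %% 1000003L)) %% .Machine$integer.max
}

#' Fit one pair walking the fallback ladder
#'
#' For each candidate structure pair, fits the null (block-diagonal) and the
#' full model (the null solution, embedded exactly in the full
#' parameterization, is always among the full model's starting points, which
#' enforces the nesting inequality).  The first candidate for which both
#' fits satisfy the convergence contract is used for the likelihood-ratio
#' test.  Spline structures for a side with fewer than 3 distinct
#' observation times are skipped (identifiability).  If no candidate
#' converges the result is flagged `converged = FALSE` with no test.
#'
#' @param ds a [CohortDataset-class] (proteins on log scale).
#' @param proteinId,echoId variable identifiers.
#' @param ladder list of candidate structure pairs, see [defaultLadder()].
#' @param tol,restarts convergence-contract parameters passed to [fitPair()].
#' @param seed base seed for restart jitter.
#' @return A `PairTestResult` list: ids, structures used, `lrt`
#'   (`LrtResult` or `NULL`), `spearman` (within-patient-mean Spearman with
#'   CI, or `NULL` when too few complete patients), `converged`, and the two
#'   fits.
#' @export
fitPairWithFallback <- function(ds, proteinId, echoId, ladder = defaultLadder(),
                                tol = 1e-4, restarts = 2L, seed = 1L) {
  sp <- tryCatch(
    withinPatientMeanSpearman(ds, proteinId, echoId),
    error = function(e) NULL)
  for (cand in ladder) {
    spec <- tryCatch(
      pairModelSpec(ds, proteinId, echoId, structureP = cand[1],
                    structureE = cand[2]),
      error = function(e) if (grepl("identifiability", conditionMessage(e)))
        NULL else stop(e))
    if (is.null(spec)) next
    ## slope random effects also need >= 2 distinct times on their side
    if (cand[1] == "intercept_slope" && spec$nDistinctP < 2) next
    if (cand[2] == "intercept_slope" && spec$nDistinctE < 2) next
    bundle <- assemblePairDesign(ds, proteinId, echoId, spec)
    s <- pairSeed(seed, proteinId, echoId)
    fitNull <- fitPair(bundle, "block_diagonal", tol = tol,
                       restarts = restarts, seed = s)
    if (!fitNull$converged) next
    fitFull <- fitPair(bundle, "full", tol = tol, restarts = restarts,
                       seed = s + 1L,
                       extraInits = list(
                         embedNullTheta(fitNull, bundle$qP, bundle$qE)))
    if (!fitFull$converged) next
    lrt <- lrtCrossBlock(fitFull, fitNull)
    return(structure(list(
      proteinId = proteinId, echoId = echoId,
      structureP = cand[1], structureE = cand[2],
      lrt = lrt, spearman = sp, converged = TRUE,
      fitFull = fitFull, fitNull = fitNull), class = "PairTestResult"))
  }
  structure(list(proteinId = proteinId, echoId = echoId,
                 structureP = NA_character_, structureE = NA_character_,
                 lrt = NULL, spearman = sp, converged = FALSE,
                 fitFull = NULL, fitNull = NULL),
            class = "PairTestResult")
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up BH adjustment (via [stats::p.adjust()]); `NA` entries are
#' excluded from the family and re-inserted as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of q-values, each `>= p` and capped at 1.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("domain: p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  q
}

#' Spearman correlation of within-patient means
#'
#' The spline random effects driving the association test have no readily
#' interpretable direction, so the association's sign is summarized by the
#' Spearman rank correlation, across patients, between each patient's mean
#' log-protein level and mean echo value.  The confidence interval uses the
#' Fisher z transform with standard error `sqrt(1.06 / (n - 3))`.
#'
#' @param ds a [CohortDataset-class] (proteins on log scale).
#' @param proteinId,echoId variable identifiers.
#' @return list: `estimate`, `ciLow`, `ciHigh`, `pValue`, `n` (patients with
#'   both variables observed).
#' @export
withinPatientMeanSpearman <- function(ds, proteinId, echoId) {
  m <- measurements(ds)
  mp <- tapply(m$value[m$variable_id == proteinId & m$variable_type == "protein"],
               m$patient_id[m$variable_id == proteinId & m$variable_type == "protein"],
               mean)
  me <- tapply(m$value[m$variable_id == echoId & m$variable_type == "echo"],
               m$patient_id[m$variable_id == echoId & m$variable_type == "echo"],
               mean)
  common <- intersect(names(mp), names(me))
  if (length(common) < 3)
    stop("data: fewer than 3 patients with both '", proteinId, "' and '",
         echoId, "' observed")
  x <- mp[common]
  y <- me[common]
  r <- cor(x, y, method = "spearman")
  n <- length(common)
  pv <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
  if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- sqrt(1.06 / (n - 3))
    ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  } else ci <- c(NA_real_, NA_real_)
  list(estimate = unname(r), ciLow = ci[1], ciHigh = ci[2],
       pValue = unname(pv), n = n)
}

#' Run the panel-wide trajectory-association screen
#'
#' Fits every (protein, echo) pair through the fallback ladder, performs the
#' cross-block likelihood-ratio test, and applies Benjamini-Hochberg FDR
#' within each echo variable's family (or one pooled family) over the
#' converged pairs.  Non-converged pairs are excluded from the BH family and
#' carry `NA` test columns.  Deterministic given dataset and config: per-pair
#' seeds derive from the pair's identifiers, so results do not depend on
#' processing order.
#'
#' @param ds a [CohortDataset-class]; protein values must already be on the
#'   natural-log scale (see [logTransformProteins()]).
#' @param echoIds,proteinIds character vectors of variable identifiers.
#' @param config list of options: `ladder` (default [defaultLadder()]),
#'   `fdrLevel` (0.05), `family` (`"per-echo"` or `"pooled"`), `tol` (1e-4),
#'   `restarts` (2), `seed` (1), `verbose` (FALSE).
#' @return data.frame with one row per pair: `protein_id`, `echo_id`,
#'   `structure_protein`, `structure_echo`, `lrt_stat`, `df`, `p_value`,
#'   `fdr_q`, `spearman_of_means`, `spearman_lo`, `spearman_hi`,
#'   `converged`, `significant`.
#' @export
runScreen <- function(ds, echoIds, proteinIds, config = list()) {
  stopifnot(is(ds, "CohortDataset"))
  if (!length(echoIds) || !length(proteinIds))
    stop("config: echoIds and proteinIds must be non-empty")
  if (!proteinLogApplied(ds))
    stop("proteins must be log-transformed first (logTransformProteins)")
  cfg <- list(ladder = defaultLadder(), fdrLevel = 0.05, family = "per-echo",
              tol = 1e-4, restarts = 2L, seed = 1L, verbose = FALSE)
  cfg[names(config)] <- config
  cfg$family <- match.arg(cfg$family, c("per-echo", "pooled"))

  echoIds <- sort(unique(echoIds))
  proteinIds <- sort(unique(proteinIds))
  rows <- vector("list", length(echoIds) * length(proteinIds))
  k <- 0L
  for (e in echoIds) for (p in proteinIds) {
    k <- k + 1L
    t0 <- proc.time()[["elapsed"]]
    res <- fitPairWithFallback(ds, p, e, ladder = cfg$ladder, tol = cfg$tol,
                               restarts = cfg$restarts, seed = cfg$seed)
    if (isTRUE(cfg$verbose))
      message(sprintf("pair %s x %s: %s/%s converged=%s (%.2fs)", p, e,
                      res$structureP, res$structureE, res$converged,
                      proc.time()[["elapsed"]] - t0))
    rows[[k]] <- data.frame(
      protein_id = p, echo_id = e,
      structure_protein = res$structureP, structure_echo = res$structureE,
      lrt_stat = if (res$converged) res$lrt$statistic else NA_real_,
      df = if (res$converged) res$lrt$df else NA_integer_,
      p_value = if (res$converged) res$lrt$pValue else NA_real_,
      fdr_q = NA_real_,
      spearman_of_means = if (!is.null(res$spearman))
        res$spearman$estimate else NA_real_,
      spearman_lo = if (!is.null(res$spearman)) res$spearman$ciLow else NA_real_,
      spearman_hi = if (!is.null(res$spearman)) res$spearman$ciHigh else NA_real_,
      converged = res$converged, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  nNC <- sum(!out$converged)
  if (nNC > 0)
    message("runScreen: ", nNC, " pair(s) did not converge and are ",
            "excluded from the FDR family")
  if (cfg$family == "per-echo") {
    for (e in echoIds) {
      idx <- out$echo_id == e
      out$fdr_q[idx] <- bhAdjust(out$p_value[idx])
    }
  } else {
    out$fdr_q <- bhAdjust(out$p_value)
  }
  out$significant <- !is.na(out$fdr_q) & out$fdr_q < cfg$fdrLevel
  rownames(out) <- NULL
  out
}
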