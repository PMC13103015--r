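#' CohortDataset: long-format repeated measurements plus patient covariates
#'
#' The single input currency of every analysis stage.  Measurements are held
#' in long format (one row per patient, visit time and variable) together with
#' one covariate row per patient (age in years, sex).  Variables are typed as
#' either `"protein"` (biomarker; relative fluorescence units before the log
#' transform, natural-log units after) or `"echo"` (cardiac-function variable
#' on its clinical scale, e.g. mL/m2 or %).
#'
#' @slot measurements data.frame with columns `patient_id`, `time_months`,
#'   `variable_id`, `variable_type`, `value`.
#' @slot covariates data.frame with columns `patient_id`, `age_years`, `sex`
#'   (`"female"` / `"male"`), one row per patient.
#' @slot proteinLogApplied logical flag: have protein values been replaced by
#'   their natural logarithms?
#'
#' @seealso [loadCohort()], [logTransformProteins()], [applyDesignFilters()]
#' @export
setClass("CohortDataset",
  representation(
    measurements = "data.frame",
    covariates = "data.frame",
    proteinLogApplied = "logical"
  )
)

MEASUREMENT_COLS <- c("patient_id", "time_months", "variable_id",
                      "variable_type", "value")
COVARIATE_COLS <- c("patient_id", "age_years", "sex")

setValidity("CohortDataset", function(object) {
  m <- object@measurements
  cv <- object@covariates
  msgs <- character(0)
  miss <- setdiff(MEASUREMENT_COLS, names(m))
  if (length(miss))
    return(paste0("measurements missing column(s): ",
                  paste(miss, collapse = ", ")))
  miss <- setdiff(COVARIATE_COLS, names(cv))
  if (length(miss))
    return(paste0("covariates missing column(s): ",
                  paste(miss, collapse = ", ")))
  if (nrow(m)) {
    if (!is.numeric(m$time_months) || any(!is.finite(m$time_months)) ||
        any(m$time_months < 0))
      msgs <- c(msgs, "time_months must be finite and >= 0")
    if (!is.numeric(m$value) || any(!is.finite(m$value)))
      msgs <- c(msgs, "value must be finite")
    if (!all(m$variable_type %in% c("protein", "echo")))
      msgs <- c(msgs, "variable_type must be 'protein' or 'echo'")
    key <- paste(m$patient_id, m$time_months, m$variable_id, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, paste0("duplicate (patient, time, variable) rows: ",
                             paste(unique(m$patient_id[duplicated(key)]),
                                   collapse = ", ")))
    uncovered <- setdiff(unique(m$patient_id), cv$patient_id)
    if (length(uncovered))
      msgs <- c(msgs, paste0("no covariate row for patient(s): ",
                             paste(uncovered, collapse = ", ")))
  }
  if (nrow(cv)) {
    if (anyDuplicated(cv$patient_id))
      msgs <- c(msgs, "covariates must have one row per patient")
    if (!is.numeric(cv$age_years) || any(!is.finite(cv$age_years)) ||
        any(cv$age_years <= 0))
      msgs <- c(msgs, "age_years must be finite and positive")
    if (!all(cv$sex %in% c("female", "male")))
      msgs <- c(msgs, "sex must be 'female' or 'male'")
  }
  if (length(object@proteinLogApplied) != 1L ||
      is.na(object@proteinLogApplied))
    msgs <- c(msgs, "proteinLogApplied must be TRUE or FALSE")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a CohortDataset
#'
#' @param measurements data.frame of long-format measurements (see
#'   [CohortDataset-class]).
#' @param covariates data.frame of per-patient covariates.
#' @param proteinLogApplied logical; whether protein values are already on the
#'   natural-log scale.
#' @return A validated [CohortDataset-class] object.
#' @examples
#' m <- data.frame(patient_id = "P1", time_months = c(0, 3),
#'                 variable_id = "LVEF", variable_type = "echo",
#'                 value = c(49, 54))
#' cv <- data.frame(patient_id = "P1", age_years = 60, sex = "male")
#' CohortDataset(m, cv)
#' @export
CohortDataset <- function(measurements, covariates,
                          proteinLogApplied = FALSE) {
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  for (col in c("patient_id", "variable_id", "variable_type"))
    if (col %in% names(measurements))
      measurements[[col]] <- as.character(measurements[[col]])
  for (col in c("patient_id", "sex"))
    if (col %in% names(covariates))
      covariates[[col]] <- as.character(covariates[[col]])
  rownames(measurements) <- NULL
  rownames(covariates) <- NULL
  new("CohortDataset", measurements = measurements, covariates = covariates,
      proteinLogApplied = proteinLogApplied)
}

#' @describeIn CohortDataset-class measurement table accessor
#' @param object,x a `CohortDataset`
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname CohortDataset-class
#' @export
setMethod("measurements", "CohortDataset", function(object)
  object@measurements)

#' @rdname CohortDataset-class
#' @export
setGeneric("covariates", function(object) standardGeneric("covariates"))

#' @rdname CohortDataset-class
#' @export
setMethod("covariates", "CohortDataset", function(object) object@covariates)

#' @rdname CohortDataset-class
#' @export
setGeneric("proteinLogApplied", function(object)
  standardGeneric("proteinLogApplied"))

#' @rdname CohortDataset-class
#' @export
setMethod("proteinLogApplied", "CohortDataset", function(object)
  object@proteinLogApplied)

#' @rdname CohortDataset-class
#' @param type optional variable type filter (`"protein"` or `"echo"`)
#' @export
variableIds <- function(object, type = NULL) {
  m <- measurements(object)
  if (!is.null(type)) m <- m[m$variable_type == type, , drop = FALSE]
  sort(unique(m$variable_id))
}

setMethod("show", "CohortDataset", function(object) {
  m <- object@measurements
  cat("CohortDataset:", length(unique(m$patient_id)), "patients,",
      nrow(m), "measurements\n")
  for (tp in c("echo", "protein")) {
    v <- unique(m$variable_id[m$variable_type == tp])
    if (length(v))
      cat(sprintf("  %s: %d variable(s) [%s%s]\n", tp, length(v),
                  paste(head(v, 4), collapse = ", "),
                  if (length(v) > 4) ", ..." else ""))
  }
  cat("  protein log applied:", object@proteinLogApplied, "\n")
})

delimFor <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Load a cohort from delimited measurement and covariate files
#'
#' Reads two delimited text files (comma-separated for `.csv`, tab-separated
#' otherwise), validates the schema, drops rows with a missing value (empty
#' cell or `NA`) with a logged count, and returns a validated
#' [CohortDataset-class].
#'
#' @param measurementsPath path to the long-format measurement table with
#'   header columns `patient_id`, `time_months`, `variable_id`,
#'   `variable_type`, `value`.
#' @param covariatesPath path to the covariate table with header columns
#'   `patient_id`, `age_years`, `sex`.
#' @return A [CohortDataset-class] with `proteinLogApplied = FALSE`.
#' @export
loadCohort <- function(measurementsPath, covariatesPath) {
  for (p in c(measurementsPath, covariatesPath))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- read.table(measurementsPath, header = TRUE, sep = delimFor(measurementsPath),
                  stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  quote = "\"", comment.char = "")
  cv <- read.table(covariatesPath, header = TRUE, sep = delimFor(covariatesPath),
                   stringsAsFactors = FALSE, na.strings = c("", "NA"),
                   quote = "\"", comment.char = "")
  miss <- setdiff(MEASUREMENT_COLS, names(m))
  if (length(miss))
    stop("measurement file missing required column(s): ",
         paste(miss, collapse = ", "))
  miss <- setdiff(COVARIATE_COLS, names(cv))
  if (length(miss))
    stop("covariate file missing required column(s): ",
         paste(miss, collapse = ", "))
  nDropped <- sum(is.na(m$value))
  if (nDropped > 0) {
    message("loadCohort: dropped ", nDropped, " row(s) with missing value")
    m <- m[!is.na(m$value), , drop = FALSE]
  }
  uncovered <- setdiff(unique(m$patient_id), cv$patient_id)
  if (length(uncovered))
    stop("covariate row missing for measured patient(s): ",
         paste(uncovered, collapse = ", "))
  ds <- CohortDataset(m, cv, proteinLogApplied = FALSE)
  for (v in variableIds(ds)) {
    tms <- unique(m$time_months[m$variable_id == v])
    if (length(tms) < 2)
      warning("variable '", v, "' observed at fewer than 2 distinct times")
  }
  ds
}

#' Natural-log transform of all protein measurements
#'
#' Replaces every protein value by its natural logarithm, leaving echo values
#' untouched, and sets the `proteinLogApplied` flag.  The model downstream is
#' specified on log-protein scale (multiplicative assay units such as relative
#' fluorescence are right-skewed; the log restores approximate normality).
#'
#' @param ds a [CohortDataset-class] with `proteinLogApplied = FALSE`.
#' @return The transformed dataset.
#' @export
logTransformProteins <- function(ds) {
  stopifnot(is(ds, "CohortDataset"))
  if (proteinLogApplied(ds))
    stop("log transform already applied to this dataset")
  m <- measurements(ds)
  isProt <- m$variable_type == "protein"
  bad <- which(isProt & m$value <= 0)
  if (length(bad))
    stop("non-positive protein value(s) at row(s) ",
         paste(head(bad, 5), collapse = ", "),
         " (patient ", m$patient_id[bad[1]], ", variable ",
         m$variable_id[bad[1]], ")")
  m$value[isProt] <- log(m$value[isProt])
  CohortDataset(m, covariates(ds), proteinLogApplied = TRUE)
}

#' Remove protein measurements taken at the baseline visit
#'
#' Drops protein rows at `time_months == 0`.  The acute phase immediately
#' after infarction produces large transient protein fluctuations that do not
#' reflect chronic remodeling, so baseline protein samples are excluded by
#' design; echo measurements at discharge (time 0) are retained.  Idempotent.
#'
#' @param ds a [CohortDataset-class].
#' @return The filtered dataset.
#' @export
applyDesignFilters <- function(ds) {
  stopifnot(is(ds, "CohortDataset"))
  m <- measurements(ds)
  drop <- m$variable_type == "protein" & m$time_months == 0
  if (any(drop))
    message("applyDesignFilters: removed ", sum(drop),
            " baseline protein measurement(s)")
  CohortDataset(m[!drop, , drop = FALSE], covariates(ds),
                proteinLogApplied = proteinLogApplied(ds))
}

RESULT_COLS <- c("protein_id", "echo_id", "structure_protein",
                 "structure_echo", "lrt_stat", "df", "p_value", "fdr_q",
                 "spearman_of_means", "converged")

#' Write screening results to a tab-separated file
#'
#' One row per (protein, echo) pair with columns `protein_id`, `echo_id`,
#' `structure_protein`, `structure_echo`, `lrt_stat`, `df`, `p_value`,
#' `fdr_q`, `spearman_of_means`, `converged`, sorted by `fdr_q` then
#' `p_value` (NA last).  Non-converged pairs carry `NA` in the test columns.
#'
#' @param results data.frame as returned by [runScreen()].
#' @param path output path.
#' @export
writeResults <- function(results, path) {
  results <- as.data.frame(results)
  if (!nrow(results)) stop("results must be non-empty")
  miss <- setdiff(RESULT_COLS, names(results))
  if (length(miss))
    stop("results missing column(s): ", paste(miss, collapse = ", "))
  out <- results[order(results$fdr_q, results$p_value, results$protein_id,
                       results$echo_id, na.last = TRUE), RESULT_COLS]
  ok <- tryCatch({
    write.table(format(out, digits = 15, trim = TRUE, scientific = NA),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) stop("cannot write results to '", path, "': ",
                              conditionMessage(e)))
  invisible(ok)
}
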