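# Long-format dataset handling (NONMEM-style conventions): comma-separated,
# "." for missing, dose rows EVID = 1 with AMT, observation rows EVID = 0
# with DV. Unknown columns are carried along as extra covariates.

.mandatory_cols <- c("ID", "TIME", "DV", "AMT", "EVID")

#' Read a long-format concentration-time dataset
#'
#' Reads a comma-separated dataset with NONMEM-style conventions: columns
#' `ID`, `TIME` (h since last dose), `DV` (concentration, ug/mL; `.` on
#' dose rows), `AMT` (dose, mg; `.` on observation rows), `EVID` (1 dose,
#' 0 observation) plus any covariate columns (e.g. `AGE`, `SEX`, `BW`,
#' `LBW`, `DM`, `FED`). A `BLQ` column flags concentrations below the
#' quantification limit; raw values are retained and imputation is a
#' separate explicit step ([impute_blq()]).
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `"pza_data"`.
#' @seealso [write_pk_dataset()], [impute_blq()], [pk_observations()]
#' @export
read_pk_dataset <- function(path) {
  raw <- utils::read.csv(path, na.strings = c(".", "NA", ""),
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty dataset: ", path)
  miss <- setdiff(.mandatory_cols, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  .validate_pk_dataset(raw)
  class(raw) <- c("pza_data", "data.frame")
  raw
}

#' Write a long-format dataset
#'
#' Inverse of [read_pk_dataset()]; missing values are written as `"."` so
#' the file round-trips losslessly.
#'
#' @param data Data frame in the long format.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(data, path) {
  miss <- setdiff(.mandatory_cols, names(data))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(data, path, row.names = FALSE, na = ".", quote = FALSE)
  invisible(path)
}

.validate_pk_dataset <- function(d) {
  if (!all(d$EVID %in% c(0, 1)))
    stop("EVID must be 0 (observation) or 1 (dose)")
  obs <- d$EVID == 0
  if (any(is.na(d$DV[obs])))
    stop("observation rows must carry a DV value (row ",
         which(obs & is.na(d$DV))[1], ")")
  if (any(d$DV[obs] < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed (row ",
         which(obs & d$DV < 0)[1], ")")
  if (any(d$TIME < 0, na.rm = TRUE)) stop("TIME must be non-negative")
  invisible(TRUE)
}

#' Impute below-quantification-limit observations (M5)
#'
#' Replaces every observed concentration strictly below the lower limit of
#' quantification by half the limit (LLOQ/2 = 1 ug/mL at the assay's
#' LLOQ of 2 ug/mL) and flags the row; values at or above the limit are
#' untouched. The imputed rows then enter the likelihood as ordinary
#' observations, which is the definition of the M5 method.
#'
#' @param data Long-format dataset (data frame with `DV`, `EVID`) or an
#'   observation table from [pk_observations()].
#' @param lloq Lower limit of quantification (ug/mL, > 0).
#' @return `data` with sub-LLOQ `DV` set to `lloq/2` and logical columns
#'   `BLQ` and `IMP` updated.
#' @export
impute_blq <- function(data, lloq = 2) {
  if (lloq <= 0) stop("lloq must be positive")
  obs <- if ("EVID" %in% names(data)) data$EVID == 0 else rep(TRUE, nrow(data))
  if (any(data$DV[obs] < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed")
  hit <- obs & !is.na(data$DV) & data$DV < lloq
  data$BLQ <- hit
  data$IMP <- hit
  data$DV[hit] <- lloq / 2
  data
}

#' Collapse a long-format dataset to one-row-per-observation form
#'
#' Merges each subject's dose row (EVID = 1) into its observation rows,
#' producing the internal table used by the estimation engine: one row per
#' observation with `ID`, `TIME`, `DV`, `DOSE` and all covariate columns.
#'
#' @param data Long-format dataset (from [read_pk_dataset()] or
#'   [simulate_cohort()]).
#' @return Data frame with one row per observation.
#' @export
pk_observations <- function(data) {
  if (!all(.mandatory_cols %in% names(data)))
    stop("not a long-format dataset")
  doses <- data[data$EVID == 1, c("ID", "AMT")]
  if (anyDuplicated(doses$ID))
    stop("each subject must have exactly one dose row")
  obs <- data[data$EVID == 0, setdiff(names(data), "AMT"), drop = FALSE]
  obs$DOSE <- doses$AMT[match(obs$ID, doses$ID)]
  if (any(is.na(obs$DOSE)))
    stop("subject(s) without a dose row: ",
         paste(unique(obs$ID[is.na(obs$DOSE)]), collapse = ", "))
  obs$EVID <- NULL
  rownames(obs) <- NULL
  obs
}

#' Read a YAML run configuration
#'
#' Loads estimation/simulation settings from a YAML file. Recognised
#' top-level keys: `model` (arguments to [pza_model()]), `seed`,
#' `estimation` (control settings for [pza_fit()]), `vpc` and `bootstrap`
#' settings. Unknown keys raise an error so typos do not silently alter a
#' run.
#'
#' @param path Path to a YAML file.
#' @return Named list with the recognised components.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("model", "seed", "estimation", "vpc", "bootstrap",
             "comparators")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(cfg$model)) cfg$model_object <- do.call(pza_model, cfg$model)
  cfg
}
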