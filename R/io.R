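## Delimited-file interfaces. All files are UTF-8 CSV with a header row and
## ISO-8601 dates. Schemas (versioned as "longsig-cohort v1"):
##   participants.csv: id, sex, birth_date, enrolment_date [, exit_date,
##                     covariate columns]
##   exposures.csv:    participant_id, drug, class, start_date, end_date
##   events.csv:       participant_id, category, subtype, event_date
##   labs.csv:         participant_id, date, analyte, value, lln, uln
##   edss.csv:         participant_id, date, edss            (optional)

COHORT_FILES <- c(participants = "participants.csv", episodes = "exposures.csv",
                  events = "events.csv", labs = "labs.csv", edss = "edss.csv")

#' Write a cohort to a directory of delimited files
#'
#' @param cohort named list with `participants`, `episodes`, `events`, and
#'   optionally `labs` and `edss` tables (as produced by [simulate_cohort()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(COHORT_FILES)) {
    tab <- cohort[[nm]]
    if (is.null(tab)) next
    out <- as.data.table(tab)
    if (nm == "episodes" && "drug_class" %in% names(out)) {
      setnames(copy(out), "drug_class", "class") -> out
    }
    fwrite(out, file.path(dir, COHORT_FILES[[nm]]), dateTimeAs = "ISO")
  }
  invisible(dir)
}

#' Read a cohort from a directory of delimited files
#'
#' @param dir directory containing the files written by [write_cohort()].
#' @return Named list of data.tables (`participants`, `episodes`, `events`,
#'   plus `labs`/`edss` when present).
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (nm in names(COHORT_FILES)) {
    path <- file.path(dir, COHORT_FILES[[nm]])
    if (!file.exists(path)) {
      if (nm %in% c("labs", "edss")) next
      stop_longsig("missing required cohort file: %s", path)
    }
    tab <- fread(path, colClasses = list(character = 1L))
    if (nm == "episodes" && "class" %in% names(tab)) {
      setnames(tab, "class", "drug_class")
    }
    out[[nm]] <- tab
  }
  out
}

#' Write a patient-month panel to a delimited file
#'
#' One row per patient-month, schema `longsig-panel v1`: identifier and month
#' index, anchor date, exposure flags, class labels, covariates.
#' @param panel a `pm_panel`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  fwrite(as.data.table(panel), path, dateTimeAs = "ISO")
  invisible(path)
}
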