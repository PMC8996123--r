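#' Disease-modifying therapy vocabulary
#'
#' Reference classification of MS disease-modifying therapies (DMTs) into
#' first-generation (injectable interferons and glatiramer acetate) and
#' second-generation (all newer agents) classes. Any drug code not in this
#' table must be registered by passing a custom vocabulary to [build_panel()].
#'
#' @return A `data.table` with columns `drug` (code) and `drug_class`
#'   (`"FIRST_GEN"` or `"SECOND_GEN"`).
#' @export
#' @examples
#' dmt_vocabulary()[drug_class == "FIRST_GEN"]
dmt_vocabulary <- function() {
  data.table(
    drug = c(
      "GLATIRAMER_ACETATE", "IFN_BETA_1A_IM", "IFN_BETA_1A_SC",
      "PEG_IFN_BETA_1A", "IFN_BETA_1B",
      "ALEMTUZUMAB", "CLADRIBINE", "DACLIZUMAB", "DIMETHYL_FUMARATE",
      "FINGOLIMOD", "NATALIZUMAB", "OCRELIZUMAB", "OFATUMUMAB",
      "RITUXIMAB", "SIPONIMOD", "TERIFLUNOMIDE"
    ),
    drug_class = c(rep("FIRST_GEN", 5L), rep("SECOND_GEN", 11L))
  )
}

TREATMENT_CLASSES <- c("NONE", "FIRST_GEN", "SECOND_GEN")

#' Adverse-event categories analyzed by the signal detection machinery
#'
#' Serious adverse event (SAE) categories; `RELAPSE` is recorded in event
#' files (and used as a time-varying covariate) but excluded from signal
#' detection.
#' @return Character vector of category codes.
#' @export
sae_categories <- function() {
  c("INFECTION", "OPPORTUNISTIC_INFECTION", "MALIGNANCY_TREATMENT_RELATED",
    "DEATH", "COVID19", "OTHER_SAE")
}

ALL_EVENT_CATEGORIES <- c("INFECTION", "OPPORTUNISTIC_INFECTION",
                          "MALIGNANCY_TREATMENT_RELATED", "DEATH", "COVID19",
                          "RELAPSE", "OTHER_SAE")

drug_class_of <- function(drugs, vocab = dmt_vocabulary()) {
  cls <- vocab$drug_class[match(drugs, vocab$drug)]
  if (anyNA(cls)) {
    stop_longsig("unknown drug code(s): %s",
                 paste(unique(drugs[is.na(cls)]), collapse = ", "))
  }
  cls
}
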