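#' Namespace of the ChronometricAge extension terms
#' @keywords internal
CHRONO_IRI_BASE <- "http://rs.tdwg.org/chrono/terms/"

#' Row type IRI of the ChronometricAge extension
#' @keywords internal
CHRONO_ROWTYPE <- "http://rs.tdwg.org/chrono/terms/ChronometricAge"

DWC_IRI_BASE <- "http://rs.tdwg.org/dwc/terms/"
DWC_OCCURRENCE_ROWTYPE <- "http://rs.tdwg.org/dwc/terms/Occurrence"

# The 18 ratified property terms, in the order the standard lists them.
# The class term chronometricAge (the record itself) is kept separately.
CHRONO_PROPERTY_TERMS <- c(
  "chronometricAgeID",
  "chronometricAgeReferences",
  "chronometricAgeRemarks",
  "materialDated",
  "materialDatedID",
  "materialDatedRelationship",
  "chronometricAgeProtocol",
  "uncalibratedChronometricAge",
  "verbatimChronometricAge",
  "earliestChronometricAge",
  "earliestChronometricAgeReferenceSystem",
  "latestChronometricAge",
  "latestChronometricAgeReferenceSystem",
  "chronometricAgeConversionProtocol",
  "chronometricAgeUncertaintyInYears",
  "chronometricAgeUncertaintyMethod",
  "chronometricAgeDeterminedBy",
  "chronometricAgeDeterminedDate"
)

CHRONO_CLASS_TERM <- "chronometricAge"

# Property terms whose values are numbers when present.
CHRONO_NUMERIC_TERMS <- c(
  "earliestChronometricAge",
  "latestChronometricAge",
  "chronometricAgeUncertaintyInYears"
)

#' Property terms of the ChronometricAge extension
#'
#' Returns the local names of the extension's ratified property terms in
#' standard order.  The class term `chronometricAge` names the record itself
#' and is not included.
#'
#' @return A character vector of 18 term local names.
#' @export
#' @examples
#' chronometric_age_terms()
chronometric_age_terms <- function() CHRONO_PROPERTY_TERMS
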