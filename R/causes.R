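#' Condemnation cause registry
#'
#' A cause registry is a tibble with one row per condemnation cause recorded at
#' post-mortem inspection. Each cause carries a short machine code, a display
#' label, a `technological` flag (failures of catching, transport, hanging,
#' scalding or evisceration, as opposed to causes involving pathogens, hygiene
#' or climate) and an `asi_eligible` flag marking the non-technological causes
#' that enter seasonal-index analysis (cachexia and contagious epithelioma are
#' excluded for low occurrence; so is the residual "others" bucket).
#'
#' @param codes character vector of cause codes
#' @param labels display names, same length as `codes`
#' @param technological logical vector (NA allowed for mixed residual buckets)
#' @param asi_eligible logical vector; must be FALSE wherever
#'   `technological` is TRUE
#' @return a tibble of class `cause_registry` with columns `code`, `label`,
#'   `technological`, `asi_eligible`
#' @examples
#' cause_registry("contamination", "Contamination", TRUE, FALSE)
#' @export
cause_registry <- function(codes, labels = codes, technological, asi_eligible) {
  stopifnot(
    is.character(codes), !anyDuplicated(codes),
    length(labels) == length(codes),
    length(technological) == length(codes),
    length(asi_eligible) == length(codes)
  )
  if (any(asi_eligible & technological, na.rm = TRUE)) {
    stop("technological causes cannot be ASI-eligible", call. = FALSE)
  }
  out <- tibble::tibble(
    code = codes,
    label = as.character(labels),
    technological = as.logical(technological),
    asi_eligible = as.logical(asi_eligible)
  )
  class(out) <- c("cause_registry", class(out))
  out
}

#' Default condemnation cause registry
#'
#' The twelve causes routinely recorded in Brazilian federal-inspection
#' condemnation spreadsheets for poultry. Technological causes are
#' contamination, contusion/traumatic injury and excessive scalding (delayed
#' evisceration, also technological, is folded into "others" here).
#' ASI-eligible causes are the seven non-technological ones with material
#' occurrence: dermatosis, aerosacculitis, arthritis, septicemia, disgusting
#' aspects, cellulitis and ascitic syndrome.
#'
#' @return a `cause_registry` tibble with 12 rows
#' @export
default_causes <- function() {
  cause_registry(
    codes = c(
      "contamination", "contusion", "dermatosis", "aerosacculitis",
      "arthritis", "septicemia", "disgusting_aspects", "excessive_scalding",
      "cellulitis", "ascitic_syndrome", "cachexia", "others"
    ),
    labels = c(
      "Contamination", "Contusion / Traumatic Injury", "Dermatosis",
      "Aerosacculitis", "Arthritis", "Septicemia", "Disgusting aspects",
      "Excessive scalding", "Cellulitis", "Ascitic syndrome", "Cachexia",
      "Others"
    ),
    technological = c(
      TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
      FALSE, NA
    ),
    asi_eligible = c(
      FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE,
      FALSE, FALSE
    )
  )
}

#' Species categories slaughtered at the plant
#'
#' @return character vector of the three species codes: turkey, griller
#'   (broiler slaughtered at up to 35 days) and heavy chicken
#' @export
species_codes <- function() c("turkey", "griller", "heavy")
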