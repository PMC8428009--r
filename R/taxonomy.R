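#' Diagnostic concept taxonomy
#'
#' The five cardiovascular comorbidity concepts and their subcategories.
#' Every category is written `concept.subcategory` (e.g. `cad.mi`,
#' `htn` is not a valid spelling -- the concept enum uses full names).
#' Concepts with no clinically useful sublevels (hypertension,
#' dyslipidemia) carry a single `present` subcategory so all five
#' concepts share one annotation schema.
#'
#' @return Named list mapping each concept to the character vector of its
#'   valid subcategories.
#' @examples
#' concept_taxonomy()$cad
#' @export
concept_taxonomy <- function() {
  list(
    hypertension = "present",
    dyslipidemia = "present",
    diabetes     = c("type1", "type2", "unspecified"),
    cad          = c("unspecified", "stenosis_gt50", "unstable_angina",
                     "mi", "stemi", "revascularization"),
    stroke_tia   = c("ischemic", "embolic", "unspecified", "tia")
  )
}

#' All valid category labels
#'
#' @return Character vector of `concept.subcategory` strings.
#' @export
all_categories <- function() {
  tax <- concept_taxonomy()
  unlist(lapply(names(tax), function(cn) paste(cn, tax[[cn]], sep = ".")),
         use.names = FALSE)
}

#' Split a category label into concept and subcategory
#'
#' @param category character vector of `concept.subcategory` labels.
#' @return data.frame with columns `concept` and `subcategory`.
#' @export
split_category <- function(category) {
  parts <- regmatches(category, regexpr("\\.", category), invert = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("malformed category label(s): ",
         paste(category[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    concept = vapply(parts, `[`, "", 1L),
    subcategory = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
}

#' Validate category labels against the taxonomy
#'
#' @param category character vector of labels to check.
#' @return invisibly `TRUE`; errors describing every invalid label otherwise.
#' @export
check_categories <- function(category) {
  ok <- category %in% all_categories()
  if (!all(ok)) {
    stop("categories not in taxonomy: ",
         paste(unique(category[!ok]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

concept_names <- function() names(concept_taxonomy())

`%||%` <- function(a, b) if (is.null(a)) b else a
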