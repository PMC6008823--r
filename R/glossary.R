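#' Control categories recognised by a glossary
#'
#' The closed set of activity categories a control identifier may carry.
#'
#' @return Character vector of valid category labels.
#' @export
control_categories <- function() {
  c("drug", "diagnostic_test", "lab_test", "procedure", "other")
}

#' Define a glossary of controls and monitored properties
#'
#' A glossary fixes the structure of every state vector in a process bank:
#' the ordered set of control identifiers (diagnostic and treatment
#' activities, stored as cumulative non-negative quantities) and the ordered
#' set of monitored patient properties (numeric or categorical, possibly
#' missing at any step).
#'
#' @param control_ids Character vector of unique control identifiers.
#' @param category Named character vector mapping each control id to one of
#'   [control_categories()], or a single label recycled to all controls.
#' @param unit Optional named character vector of unit labels per control
#'   (unified dose units or counts). Defaults to `"unit"` for all.
#' @param monitored_ids Character vector of unique monitored-property ids,
#'   disjoint from `control_ids`. May be empty.
#' @param monitored_kind Named character vector mapping each monitored id to
#'   `"numeric"` or `"categorical"`; single value recycled. Default numeric.
#' @param monitored_levels Named list of level label vectors for categorical
#'   monitored properties; values are stored as 1-based level indices in
#'   glossary order.
#'
#' @return An object of class `dtp_glossary`.
#' @examples
#' gl <- control_glossary(c("amoxicillin", "cbc"),
#'                        category = c(amoxicillin = "drug", cbc = "lab_test"),
#'                        monitored_ids = "temperature")
#' @export
control_glossary <- function(control_ids,
                             category = "other",
                             unit = NULL,
                             monitored_ids = character(),
                             monitored_kind = "numeric",
                             monitored_levels = list()) {
  control_ids <- as.character(control_ids)
  monitored_ids <- as.character(monitored_ids)
  if (anyDuplicated(control_ids)) stop("control ids must be unique")
  if (anyDuplicated(monitored_ids)) stop("monitored ids must be unique")
  if (length(intersect(control_ids, monitored_ids)) > 0L) {
    stop("control and monitored id sets must be disjoint")
  }
  if (length(category) == 1L && is.null(names(category))) {
    category <- stats::setNames(rep(category, length(control_ids)), control_ids)
  }
  category <- category[control_ids]
  names(category) <- control_ids
  if (anyNA(category) || !all(category %in% control_categories())) {
    stop("every control needs a category from control_categories()")
  }
  if (is.null(unit)) {
    unit <- stats::setNames(rep("unit", length(control_ids)), control_ids)
  } else {
    unit <- unit[control_ids]
    names(unit) <- control_ids
  }
  if (length(monitored_ids) > 0L) {
    if (length(monitored_kind) == 1L && is.null(names(monitored_kind))) {
      monitored_kind <- stats::setNames(rep(monitored_kind, length(monitored_ids)),
                                        monitored_ids)
    }
    monitored_kind <- monitored_kind[monitored_ids]
    names(monitored_kind) <- monitored_ids
    if (anyNA(monitored_kind) || !all(monitored_kind %in% c("numeric", "categorical"))) {
      stop("monitored_kind must be 'numeric' or 'categorical' for every monitored id")
    }
    cat_ids <- names(monitored_kind)[monitored_kind == "categorical"]
    missing_lv <- setdiff(cat_ids, names(monitored_levels))
    if (length(missing_lv) > 0L) {
      stop("categorical monitored properties need level lists: ",
           paste(missing_lv, collapse = ", "))
    }
  } else {
    monitored_kind <- stats::setNames(character(), character())
  }
  structure(
    list(control_ids = control_ids,
         category = category,
         unit = unit,
         monitored_ids = monitored_ids,
         monitored_kind = monitored_kind,
         monitored_levels = monitored_levels[intersect(names(monitored_levels),
                                                       monitored_ids)]),
    class = "dtp_glossary"
  )
}

#' @export
print.dtp_glossary <- function(x, ...) {
  cat("DTP glossary:", length(x$control_ids), "controls,",
      length(x$monitored_ids), "monitored properties\n")
  tab <- table(factor(x$category, levels = control_categories()))
  cat("  controls by category:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  if (length(x$monitored_ids) > 0L) {
    cat("  monitored:", paste(x$monitored_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' State-vector dimension implied by a glossary
#'
#' @param glossary A [control_glossary()].
#' @return Integer: number of controls plus number of monitored properties.
#' @export
state_dim <- function(glossary) {
  stopifnot(inherits(glossary, "dtp_glossary"))
  length(glossary$control_ids) + length(glossary$monitored_ids)
}
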