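#' Construct a treatment process
#'
#' A process is one patient's trajectory through a diagnostic-treatment
#' episode: an ordered sequence of state vectors, one per step (by the
#' package's convention one step is one inpatient day). Each state carries
#' the cumulative control vector U — the full dose of every drug, the running
#' count of every test, up to and including that step — and the monitored
#' vector X. A zero control component means that activity has never been
#' applied so far; because controls are integral quantities they are
#' component-wise non-decreasing along the sequence.
#'
#' @param process_id Identifier string.
#' @param nosology ICD-10-style disease code (e.g. `"J13"`).
#' @param controls Numeric matrix, steps x controls, columns named by the
#'   glossary's control ids; cumulative non-negative values.
#' @param monitored Numeric matrix, steps x monitored properties (may have
#'   zero columns); `NA` marks a missing observation; categorical properties
#'   are stored as 1-based level indices.
#' @param glossary The shared [control_glossary()].
#' @param validate Check invariants on construction (default `TRUE`).
#'
#' @return An object of class `dtp_process`.
#' @export
dtp_process <- function(process_id, nosology, controls, monitored = NULL,
                        glossary, validate = TRUE) {
  stopifnot(inherits(glossary, "dtp_glossary"))
  controls <- as.matrix(controls)
  if (is.null(colnames(controls))) colnames(controls) <- glossary$control_ids
  if (is.null(monitored)) {
    monitored <- matrix(numeric(), nrow = nrow(controls), ncol = 0L)
  }
  monitored <- as.matrix(monitored)
  if (ncol(monitored) > 0L && is.null(colnames(monitored))) {
    colnames(monitored) <- glossary$monitored_ids
  }
  p <- structure(
    list(process_id = as.character(process_id),
         nosology = as.character(nosology),
         controls = controls,
         monitored = monitored),
    class = "dtp_process"
  )
  if (validate) {
    v <- validate_process(p, glossary)
    if (nrow(v) > 0L) {
      stop("invalid process '", process_id, "': ", v$message[1L],
           if (nrow(v) > 1L) sprintf(" (and %d more violations)", nrow(v) - 1L))
    }
  }
  p
}

#' Number of steps in a process
#' @param process A [dtp_process()].
#' @return Integer step count `T`.
#' @export
n_steps <- function(process) nrow(process$controls)

#' @export
print.dtp_process <- function(x, ...) {
  cat(sprintf("DTP process '%s' (%s): %d steps, %d controls, %d monitored\n",
              x$process_id, x$nosology, n_steps(x), ncol(x$controls),
              ncol(x$monitored)))
  invisible(x)
}

#' Extract one state vector from a process
#'
#' @param process A [dtp_process()].
#' @param step 0-based step index.
#' @return A `dtp_state`: list with `step_index`, named `controls` vector and
#'   named `monitored` vector (`NA` = missing).
#' @export
state_at <- function(process, step) {
  t1 <- step + 1L
  if (t1 < 1L || t1 > n_steps(process)) {
    stop("step ", step, " outside process of length ", n_steps(process))
  }
  structure(
    list(step_index = as.integer(step),
         controls = process$controls[t1, ],
         monitored = if (ncol(process$monitored) > 0L)
           process$monitored[t1, ] else stats::setNames(numeric(), character())),
    class = "dtp_state"
  )
}

#' Validate a process against its glossary
#'
#' Checks the structural invariants of the process model: state vectors match
#' the glossary's component sets, control values are non-negative and
#' component-wise non-decreasing over steps (controls are cumulative), and
#' the process has at least one step. Reporting only — never throws.
#'
#' @param process A [dtp_process()] (or a bare list with the same fields).
#' @param glossary The [control_glossary()] to validate against.
#' @return A data frame of violations with columns `component`, `step`
#'   (0-based, `NA` for structural problems) and `message`; zero rows iff the
#'   process is valid.
#' @export
validate_process <- function(process, glossary) {
  viol <- function(component, step, message)
    data.frame(component = component, step = step, message = message,
               stringsAsFactors = FALSE)
  out <- list()
  ctl <- process$controls
  mon <- process$monitored
  if (!is.matrix(ctl) || nrow(ctl) < 1L) {
    out[[length(out) + 1L]] <- viol(NA_character_, NA_integer_,
                                    "process must have at least one state")
    return(do.call(rbind, out))
  }
  if (ncol(ctl) != length(glossary$control_ids) ||
      !identical(colnames(ctl), glossary$control_ids)) {
    out[[length(out) + 1L]] <- viol(
      NA_character_, NA_integer_,
      sprintf("control block has %d columns; glossary defines %d",
              ncol(ctl), length(glossary$control_ids)))
  }
  nm <- if (is.matrix(mon)) ncol(mon) else length(glossary$monitored_ids)
  if (nm != length(glossary$monitored_ids)) {
    out[[length(out) + 1L]] <- viol(
      NA_character_, NA_integer_,
      sprintf("monitored block has %d columns; glossary defines %d",
              nm, length(glossary$monitored_ids)))
  }
  if (length(out) == 0L) {
    neg <- which(ctl < 0, arr.ind = TRUE)
    if (nrow(neg) > 0L) {
      for (i in seq_len(nrow(neg))) {
        out[[length(out) + 1L]] <- viol(
          colnames(ctl)[neg[i, 2L]], neg[i, 1L] - 1L,
          sprintf("negative control value for '%s' at step %d",
                  colnames(ctl)[neg[i, 2L]], neg[i, 1L] - 1L))
      }
    }
    if (nrow(ctl) > 1L) {
      d <- diff(ctl)
      drop <- which(d < 0, arr.ind = TRUE)
      if (nrow(drop) > 0L) {
        for (i in seq_len(nrow(drop))) {
          comp <- colnames(ctl)[drop[i, 2L]]
          stp <- drop[i, 1L]  # violation surfaces at the later state
          out[[length(out) + 1L]] <- viol(
            comp, stp,
            sprintf("cumulative control '%s' decreases at step %d", comp, stp))
        }
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(component = character(), step = integer(), message = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Control delta between two states
#'
#' The recommended or observed action between two states of the same process:
#' the component-wise difference of their integral control vectors,
#' `U(later) - U(earlier)`. All components must be non-negative because
#' controls are cumulative.
#'
#' @param state_a Earlier `dtp_state` (see [state_at()]) or bare named
#'   control vector.
#' @param state_b Later state from the same process.
#' @param source Annotation string recording which engine (or neighbour
#'   process/step) produced the delta.
#' @return A named non-negative numeric vector of class `control_delta` with
#'   a `source` attribute.
#' @export
delta_control <- function(state_a, state_b, source = "observed") {
  ua <- if (inherits(state_a, "dtp_state")) state_a$controls else state_a
  ub <- if (inherits(state_b, "dtp_state")) state_b$controls else state_b
  if (length(ua) != length(ub)) stop("states have different control dimensions")
  d <- ub - ua
  if (any(d < 0)) {
    bad <- names(d)[which(d < 0)]
    if (is.null(bad)) bad <- which(d < 0)
    stop("monotonicity violated: control decreases for ",
         paste(bad, collapse = ", "))
  }
  structure(d, class = "control_delta", source = source)
}

#' Next-step control delta at a given step
#'
#' Convenience wrapper: the action the doctor took between step `t` and
#' `t + 1` of a process.
#'
#' @param process A [dtp_process()].
#' @param step 0-based step `t`; requires `t + 1` to exist.
#' @return A `control_delta`.
#' @export
step_delta <- function(process, step) {
  delta_control(state_at(process, step), state_at(process, step + 1L),
                source = sprintf("%s/step%d", process$process_id, step))
}

#' Binarize a control delta into an applied set
#'
#' The set of controls actually applied in a step: those whose delta exceeds
#' a tolerance. With the default `tol = 0` any positive increment counts as a
#' prescription.
#'
#' @param delta A `control_delta` or named numeric vector.
#' @param tol Non-negative threshold; components must be strictly greater.
#' @return Character vector of applied control ids.
#' @export
applied_set <- function(delta, tol = 0) {
  stopifnot(tol >= 0)
  names(delta)[which(as.numeric(delta) > tol)]
}

#' Assemble a process bank
#'
#' An ensemble of processes sharing one nosology and one glossary — the array
#' of previously observed treatment precedents the engines are taught from.
#'
#' @param glossary Shared [control_glossary()].
#' @param processes List of [dtp_process()] objects.
#' @param nosology Disease code; defaults to the first process's code.
#' @param provenance Free-text tag recording data origin (synthetic generator
#'   config or source label).
#' @param validate Validate every process against the glossary.
#' @return An object of class `dtp_bank`.
#' @export
process_bank <- function(glossary, processes, nosology = NULL,
                         provenance = "unspecified", validate = TRUE) {
  stopifnot(inherits(glossary, "dtp_glossary"), length(processes) >= 1L)
  if (is.null(nosology)) nosology <- processes[[1L]]$nosology
  if (validate) {
    for (p in processes) {
      if (!identical(p$nosology, nosology)) {
        stop("process '", p$process_id, "' has nosology '", p$nosology,
             "', bank is '", nosology, "'")
      }
      v <- validate_process(p, glossary)
      if (nrow(v) > 0L) {
        stop("process '", p$process_id, "' violates bank glossary: ",
             v$message[1L])
      }
    }
  }
  structure(
    list(glossary = glossary, processes = processes, nosology = nosology,
         provenance = provenance),
    class = "dtp_bank"
  )
}

#' @export
print.dtp_bank <- function(x, ...) {
  ns <- vapply(x$processes, n_steps, integer(1))
  cat(sprintf("DTP bank (%s): %d processes, %d states, %d controls, %d monitored\n",
              x$nosology, length(x$processes), sum(ns),
              length(x$glossary$control_ids), length(x$glossary$monitored_ids)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Total number of states in a bank
#' @param bank A [process_bank()].
#' @return Integer sum of process lengths.
#' @export
n_states <- function(bank) {
  sum(vapply(bank$processes, n_steps, integer(1)))
}
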