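#' Split a bank into teaching and control precedents
#'
#' Process-level random split: `round(control_fraction * N)` processes are
#' held out as control precedents, the rest teach the engines. Deterministic
#' given the seed.
#'
#' @param bank A [process_bank()] with at least 2 processes.
#' @param control_fraction Fraction held out, in (0, 1); default 0.1.
#' @param seed Integer seed.
#' @return List with elements `teaching` and `control`, both banks, plus
#'   `control_idx` (indices of held-out processes).
#' @export
split_bank <- function(bank, control_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(bank, "dtp_bank"))
  N <- length(bank$processes)
  if (N < 2L) stop("need at least 2 processes to split")
  if (control_fraction <= 0 || control_fraction >= 1) {
    stop("control_fraction must be in (0, 1)")
  }
  n_ctrl <- round(control_fraction * N)
  if (n_ctrl < 1L || n_ctrl >= N) {
    stop("degenerate split: ", n_ctrl, " of ", N, " processes held out")
  }
  set.seed(seed)
  idx <- sort(sample.int(N, n_ctrl))
  mk <- function(ii, tag) {
    process_bank(bank$glossary, bank$processes[ii], nosology = bank$nosology,
                 provenance = paste0(bank$provenance, ":", tag),
                 validate = FALSE)
  }
  list(teaching = mk(setdiff(seq_len(N), idx), "teaching"),
       control = mk(idx, "control"),
       control_idx = idx)
}

#' Confusion matrix of binary recommendations
#'
#' The accounting used to score both networks: every (state, control) pair
#' is one binary decision. The positive share is the fraction of issued
#' positive recommendations that match the doctor's actual action
#' (precision over positives); the negative share is its analogue over
#' negative recommendations — not sensitivity/specificity.
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_matrix` with fields `tp`, `fp`,
#'   `tn`, `fn`, `total`, `positive_share`, `negative_share`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         total = tp + fp + tn + fn,
         positive_share = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         negative_share = if (tn + fn > 0) tn / (tn + fn) else NA_real_),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Binary recommendation accounting (", x$total, " decisions)\n", sep = "")
  cat(sprintf("  TP %6d    FP %6d\n  TN %6d    FN %6d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  positive share (correct among positive recs): %.2f%%\n",
              100 * x$positive_share))
  cat(sprintf("  negative share (correct among negative recs): %.2f%%\n",
              100 * x$negative_share))
  invisible(x)
}

#' Score binary predictions against actual applied sets
#'
#' @param predictions Integer/logical matrix, evaluated states x controls.
#' @param actual Logical matrix of the same shape: was the control actually
#'   applied at the next step?
#' @return A [confusion_matrix()].
#' @export
evaluate_binary <- function(predictions, actual) {
  if (!all(dim(predictions) == dim(actual))) {
    stop("prediction and actual matrices differ in shape")
  }
  pred <- predictions > 0
  confusion_matrix(tp = sum(pred & actual), fp = sum(pred & !actual),
                   tn = sum(!pred & !actual), fn = sum(!pred & actual))
}

#' Case-based recommendation report
#'
#' The case engine's accounting over actually applied activities: an actual
#' activity is *correct* if the recommended applied set contains it,
#' *unable* otherwise (including explicit no-recommendation outcomes).
#' Among correct activities, those whose recommended amount differs from
#' the actual amount by more than `level_tolerance` (relative, with a
#' one-unit absolute floor) are additionally counted as *different control
#' level*. Identities: `correct + unable = total_activities` and
#' `different_level <= correct`.
#'
#' @param recommended List of recommended deltas (named numeric vectors /
#'   `control_delta`s, or `NULL` for no-recommendation), one per evaluated
#'   state.
#' @param actual List of actual next-step deltas, parallel to `recommended`.
#' @param level_tolerance Relative tolerance for "same level" (default 0.1).
#' @param unit Absolute floor for the tolerance (default 1 unit).
#' @return An object of class `case_report` with counts and shares.
#' @export
evaluate_case <- function(recommended, actual, level_tolerance = 0.1,
                          unit = 1) {
  stopifnot(length(recommended) == length(actual), level_tolerance >= 0)
  total <- 0L; correct <- 0L; diff_level <- 0L; unable <- 0L
  for (i in seq_along(actual)) {
    act <- actual[[i]]
    ids <- applied_set(act)
    total <- total + length(ids)
    rec <- recommended[[i]]
    if (is.null(rec)) {
      unable <- unable + length(ids)
      next
    }
    rec_ids <- applied_set(rec)
    for (id in ids) {
      if (id %in% rec_ids) {
        correct <- correct + 1L
        a <- as.numeric(act[id])
        r <- as.numeric(rec[id])
        if (abs(r - a) > level_tolerance * max(a, unit)) {
          diff_level <- diff_level + 1L
        }
      } else {
        unable <- unable + 1L
      }
    }
  }
  structure(
    list(total_activities = total, correct = correct,
         different_level = diff_level, unable = unable,
         correct_share = if (total > 0) correct / total else NA_real_,
         different_level_share = if (total > 0) diff_level / total else NA_real_,
         unable_share = if (total > 0) unable / total else NA_real_),
    class = "case_report"
  )
}

#' @export
print.case_report <- function(x, ...) {
  cat("Case-based recommendation report (",
      x$total_activities, " actual activities)\n", sep = "")
  cat(sprintf("  correct:          %6d  (%.1f%%)\n", x$correct,
              100 * x$correct_share))
  cat(sprintf("  different level:  %6d  (%.1f%%)\n", x$different_level,
              100 * x$different_level_share))
  cat(sprintf("  unable:           %6d  (%.1f%%)\n", x$unable,
              100 * x$unable_share))
  invisible(x)
}

#' ROC curve over a threshold sweep
#'
#' For each threshold a (state, control) pair is called positive iff its
#' score reaches the threshold; TPR and FPR are computed against the actual
#' labels. Below the minimum score the curve is at (1, 1), above the
#' maximum at (0, 0), and both coordinates are non-increasing in the
#' threshold.
#'
#' @param scores Numeric scores (activations or posteriors), one per
#'   decision.
#' @param labels Logical (or 0/1) actual labels, parallel to `scores`; both
#'   classes must be present.
#' @param thresholds Optional threshold grid; defaults to the sorted unique
#'   scores bracketed by sentinels below/above all scores.
#' @return A data frame of class `roc_curve` with columns `threshold`,
#'   `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, thresholds = NULL) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!any(labels) || all(labels)) {
    stop("ROC undefined: labels must contain both classes")
  }
  if (is.null(thresholds)) {
    u <- sort(unique(scores))
    thresholds <- c(min(u) - 1, u, max(u) + 1)
  } else {
    thresholds <- sort(thresholds)
  }
  P <- sum(labels); Ng <- sum(!labels)
  tpr <- fpr <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    pos <- scores >= thresholds[i]
    tpr[i] <- sum(pos & labels) / P
    fpr[i] <- sum(pos & !labels) / Ng
  }
  structure(data.frame(threshold = thresholds, fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"))
}

#' Area under a ROC curve
#'
#' Trapezoidal integral of TPR over FPR.
#'
#' @param roc A [roc_curve()] result.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlab = "False positive rate",
       ylab = "True positive rate", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Evaluate an engine on a control bank
#'
#' Runs an engine over every non-terminal state of the control precedents
#' and scores it against the doctors' actual next-step actions. For the
#' networks this produces the binary confusion accounting plus raw scores
#' (for ROC sweeps); for the case graph it produces the case report.
#'
#' @param model A fitted [slnn()], [pnn()], or [case_graph()].
#' @param control_bank Held-out [process_bank()].
#' @param ... Engine options: `threshold` for the networks;
#'   `n_restarts`, `seed`, `layered` (logical: search only the query's own
#'   step layer) and `level_tolerance` for the case graph.
#' @return For networks: list with `confusion`, `scores`, `labels`. For the
#'   case graph: list with `report` (a `case_report`) and `confusion` (the
#'   same decisions in binary accounting).
#' @export
evaluate_engine <- function(model, control_bank, ...) {
  UseMethod("evaluate_engine")
}

eval_design <- function(model, control_bank) {
  teaching_design(control_bank, model$stats)
}

#' @export
evaluate_engine.slnn <- function(model, control_bank, threshold = NULL, ...) {
  vd <- eval_design(model, control_bank)
  pred <- predict(model, vd$X[, -ncol(vd$X), drop = FALSE],
                  threshold = threshold)
  actual <- vd$targets > 0.5
  list(confusion = evaluate_binary(pred, actual),
       scores = as.numeric(attr(pred, "activations")),
       labels = as.logical(actual))
}

#' @export
evaluate_engine.pnn <- function(model, control_bank, threshold = NULL, ...) {
  vd <- eval_design(model, control_bank)
  pred <- predict(model, vd$X[, -ncol(vd$X), drop = FALSE],
                  threshold = threshold)
  actual <- vd$targets > 0.5
  list(confusion = evaluate_binary(pred, actual),
       scores = as.numeric(attr(pred, "posteriors")),
       labels = as.logical(actual))
}

#' @export
evaluate_engine.case_graph <- function(model, control_bank, n_restarts = NULL,
                                       seed = NULL, layered = FALSE,
                                       level_tolerance = 0.1, ...) {
  recs <- list(); acts <- list()
  pred_rows <- list(); act_rows <- list()
  ids <- model$stats$ids[seq_len(model$stats$n_control)]
  if (!is.null(seed)) set.seed(seed)
  for (p in control_bank$processes) {
    if (n_steps(p) < 2L) next
    E <- embed_process(p, model$stats, model$which)
    for (t in seq_len(n_steps(p) - 1L) - 1L) {
      lay <- if (layered && any(model$step == t)) t else NULL
      r <- recommend_case(model, E[t + 1L, ], n_restarts = n_restarts,
                          layer = lay, embedded = TRUE)
      a <- step_delta(p, t)
      recs[length(recs) + 1L] <- list(r$delta)  # keep NULL as an element
      acts[[length(acts) + 1L]] <- a
      pred_rows[[length(pred_rows) + 1L]] <- ids %in% r$applied
      act_rows[[length(act_rows) + 1L]] <- ids %in% applied_set(a)
    }
  }
  list(report = evaluate_case(recs, acts, level_tolerance = level_tolerance),
       confusion = evaluate_binary(do.call(rbind, pred_rows),
                                   do.call(rbind, act_rows)))
}
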