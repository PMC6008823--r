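#' Fit normalization statistics on a teaching bank
#'
#' Computes per-component population means and standard deviations over all
#' states of the bank (controls and monitored components uniformly), the
#' fill values used to impute missing monitored observations (the teaching
#' means), and a mask of zero-variance components. These statistics define
#' the embedded state space in which all engines measure distance.
#'
#' @param bank A [process_bank()].
#' @param sd_floor Standard deviations below this are treated as zero
#'   variance (default `1e-9`).
#' @return An object of class `dtp_normalizer` with fields `ids`, `mean`,
#'   `sd`, `fill`, `zero_var`, `n_control`.
#' @export
fit_normalizer <- function(bank, sd_floor = 1e-9) {
  stopifnot(inherits(bank, "dtp_bank"), length(bank$processes) >= 1L)
  X <- raw_state_matrix(bank)
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0  # all-missing component: fill with 0
  # population variance over observed values
  v <- colMeans(sweep(X, 2L, mu)^2, na.rm = TRUE)
  v[is.nan(v)] <- 0  # all-missing component
  s <- sqrt(v)
  structure(
    list(ids = colnames(X), mean = mu, sd = s, fill = mu,
         zero_var = s < sd_floor,
         n_control = length(bank$glossary$control_ids)),
    class = "dtp_normalizer"
  )
}

#' @export
print.dtp_normalizer <- function(x, ...) {
  cat(sprintf("DTP normalizer: %d components (%d controls), %d zero-variance\n",
              length(x$ids), x$n_control, sum(x$zero_var)))
  invisible(x)
}

# all states of a bank as one matrix (rows = states), controls then monitored
raw_state_matrix <- function(bank) {
  do.call(rbind, lapply(bank$processes, function(p) {
    cbind(p$controls, p$monitored)
  }))
}

#' Embed states into the normalized metric space
#'
#' Missing components are replaced by teaching means, every component is
#' z-scored with the teaching population sd, and zero-variance components
#' are set to 0 (they carry no information). Output is always finite.
#'
#' @param x A `dtp_state`, a numeric state vector (controls then monitored
#'   in glossary order), or a matrix of such rows.
#' @param stats A [fit_normalizer()] result.
#' @param which `"all"` (default) embeds the full state; `"monitored"` or
#'   `"controls"` zero out the other block for sensitivity studies.
#' @return A numeric vector (or matrix) of the same width as `stats$ids`.
#' @export
embed_state <- function(x, stats, which = c("all", "monitored", "controls")) {
  which <- match.arg(which)
  if (inherits(x, "dtp_state")) x <- c(x$controls, x$monitored)
  if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1L)
    drop_out <- TRUE
  } else {
    drop_out <- FALSE
  }
  if (ncol(x) != length(stats$ids)) {
    stop("state has ", ncol(x), " components; normalizer expects ",
         length(stats$ids))
  }
  fill <- matrix(stats$fill, nrow(x), ncol(x), byrow = TRUE)
  x[is.na(x)] <- fill[is.na(x)]
  s <- ifelse(stats$zero_var, 1, pmax(stats$sd, 1e-9))
  z <- sweep(sweep(x, 2L, stats$mean), 2L, s, "/")
  z[, stats$zero_var] <- 0
  if (which == "monitored") {
    z[, seq_len(stats$n_control)] <- 0
  } else if (which == "controls") {
    if (ncol(z) > stats$n_control) {
      z[, (stats$n_control + 1L):ncol(z)] <- 0
    }
  }
  colnames(z) <- stats$ids
  if (drop_out) z[1L, ] else z
}

#' Embed every state of a process
#'
#' @param process A [dtp_process()].
#' @param stats A [fit_normalizer()] result.
#' @param which Component restriction, see [embed_state()].
#' @return Matrix with one embedded row per step.
#' @export
embed_process <- function(process, stats, which = "all") {
  embed_state(cbind(process$controls, process$monitored), stats, which)
}

#' Distance between embedded states
#'
#' The state-space metric underlying the case graph and both networks'
#' neighbourhood structure: the Euclidean norm of the difference of two
#' embedded vectors. Symmetric, zero iff the inputs are equal, and satisfies
#' the triangle inequality.
#'
#' @param u,v Equal-length embedded numeric vectors.
#' @return Non-negative real.
#' @export
state_distance <- function(u, v) {
  if (length(u) != length(v)) stop("embedded vectors differ in length")
  sqrt(sum((u - v)^2))
}
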