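#' Fit a probabilistic neural network on a teaching bank
#'
#' Every non-terminal teaching state becomes a Gaussian kernel centre in
#' embedded space. For each control `L` the kernels are partitioned into two
#' classes: `KL1`, the states where the doctor applied `L` at the next step
#' (positive next-step delta), and `KL0`, the rest — `2m` classes in total
#' for `m` controls. Class densities are Parzen mixtures of a single kernel
#' shape shared by all states: a multivariate Gaussian with diagonal
#' covariance `sigma^2 * diag(s^2)`, where `s` holds the per-component
#' teaching standard deviations (floored at `1e-6`) and `sigma` is the width
#' multiplier. Priors are empirical class frequencies.
#'
#' @param bank Teaching [process_bank()].
#' @param stats Optional [fit_normalizer()]; fitted on `bank` when `NULL`.
#' @param sigma Width multiplier (> 0); the packaged grid is
#'   `c(0.1, 0.5, 1, 2.5)`.
#' @param threshold Posterior decision threshold (default 0.5).
#' @return An object of class `pnn` with `centers`, `scale`, `sigma`,
#'   `labels` (kernels x controls logical: kernel in `KL1`), `prior1`
#'   (per-control empirical prior of `KL1`), `threshold`, `stats`.
#' @export
pnn <- function(bank, stats = NULL, sigma = 1, threshold = 0.5) {
  stopifnot(inherits(bank, "dtp_bank"), sigma > 0)
  if (is.null(stats)) stats <- fit_normalizer(bank)
  td <- teaching_design(bank, stats)
  centers <- td$X[, -ncol(td$X), drop = FALSE]  # drop bias column
  labels <- td$targets > 0.5
  s <- pmax(apply(centers, 2L, function(z) sqrt(mean((z - mean(z))^2))), 1e-6)
  structure(
    list(centers = centers, scale = s, sigma = sigma, labels = labels,
         prior1 = colMeans(labels), threshold = threshold, stats = stats),
    class = "pnn"
  )
}

#' @export
print.pnn <- function(x, ...) {
  cat(sprintf("Probabilistic neural network: %d kernels x %d dims, %d controls (2m = %d classes), sigma = %g\n",
              nrow(x$centers), ncol(x$centers), ncol(x$labels),
              2L * ncol(x$labels), x$sigma))
  invisible(x)
}

#' Log kernel density at a query
#'
#' Log of the shared multivariate Gaussian kernel with diagonal covariance
#' `sigma^2 * diag(s^2)` centred at `center`, evaluated at `query`:
#' `sum_k [ -(q_k - c_k)^2 / (2 sigma^2 s_k^2) - log(sigma s_k) - log(2 pi)/2 ]`.
#'
#' @param center,query Equal-length numeric vectors.
#' @param sigma Positive width multiplier.
#' @param s Positive per-component scale vector (recycled if scalar).
#' @return Log density (real).
#' @export
log_kernel <- function(center, query, sigma, s = 1) {
  if (length(center) != length(query)) stop("center/query length mismatch")
  if (sigma <= 0 || any(s <= 0)) stop("sigma and scales must be positive")
  s <- rep_len(s, length(center))
  sum(-(query - center)^2 / (2 * sigma^2 * s^2) - log(sigma * s) -
        0.5 * log(2 * pi))
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log kernel values of all centers for each query row: nq x N matrix
pnn_log_kernels <- function(model, Q) {
  sc <- model$sigma * model$scale
  Cs <- sweep(model$centers, 2L, sc, "/")
  Qs <- sweep(Q, 2L, sc, "/")
  d2 <- outer(rowSums(Qs^2), rowSums(Cs^2), "+") - 2 * tcrossprod(Qs, Cs)
  d2[d2 < 0] <- 0
  const <- -sum(log(sc)) - ncol(Q) / 2 * log(2 * pi)
  -d2 / 2 + const
}

#' Posterior probability that a control should be applied
#'
#' Restores the class density of `KL1` and `KL0` for control `L` as the mean
#' of the class's kernels and applies Bayes' formula with the empirical
#' priors: `p = pi1 f1 / (pi1 f1 + pi0 f0)`. All arithmetic is done in log
#' space with log-sum-exp, so high-dimensional kernel products cannot
#' underflow. Degenerate classes are handled explicitly: an empty `KL1`
#' yields 0, an empty `KL0` yields 1.
#'
#' @param model A fitted [pnn()].
#' @param query Embedded query vector (or matrix of rows).
#' @param control Control id or column index.
#' @return Posterior probability (vector over query rows) in `[0,1]`.
#' @export
pnn_posterior <- function(model, query, control) {
  P <- pnn_posteriors(model, query)
  if (is.character(control)) control <- match(control, colnames(P))
  P[, control]
}

#' Posterior matrix over all controls
#'
#' @param model A fitted [pnn()].
#' @param query Embedded query vector or matrix of query rows.
#' @return Matrix (queries x controls) of posteriors of class `KL1`.
#' @export
pnn_posteriors <- function(model, query) {
  if (!is.matrix(query)) query <- matrix(query, nrow = 1L)
  LK <- pnn_log_kernels(model, query)     # nq x N
  m <- ncol(model$labels)
  nq <- nrow(query)
  P <- matrix(NA_real_, nq, m, dimnames = list(NULL, colnames(model$labels)))
  n1 <- colSums(model$labels)
  N <- nrow(model$centers)
  for (q in seq_len(nq)) {
    lk <- LK[q, ]
    mx <- max(lk)
    w <- exp(lk - mx)                      # common rescale cancels in Bayes
    s1 <- as.numeric(crossprod(model$labels, w))       # sum of KL1 kernels
    s0 <- sum(w) - s1
    # pi1 * f1 = (n1/N) * (s1/n1) * scale = s1/N * scale; likewise for s0:
    # with empirical priors the posterior reduces to s1 / (s1 + s0)
    p <- ifelse(n1 == 0L, 0, ifelse(n1 == N, 1, s1 / (s1 + s0)))
    P[q, ] <- p
  }
  P
}

#' PNN recommendation for a query state
#'
#' Recommends every control whose posterior probability of class `KL1`
#' reaches the model's decision threshold.
#'
#' @param model A fitted [pnn()].
#' @param query Embedded query vector, or a `dtp_state`/raw state with
#'   `embedded = FALSE`.
#' @param threshold Optional override of the model's threshold.
#' @param embedded Is the query already embedded?
#' @return A `dtp_recommendation` with the binary `applied` set and a
#'   `posteriors` field.
#' @export
recommend_pnn <- function(model, query, threshold = NULL, embedded = TRUE) {
  if (is.null(threshold)) threshold <- model$threshold
  if (!embedded) query <- embed_state(query, model$stats)
  p <- pnn_posteriors(model, query)[1L, ]
  rec <- names(p)[p >= threshold]
  structure(
    list(delta = NULL, applied = rec, posteriors = p, neighbor = NULL,
         distance = NA_real_, engine = "pnn"),
    class = "dtp_recommendation"
  )
}

#' Binary recommendations from the PNN
#'
#' @param object A fitted [pnn()].
#' @param newdata Embedded state rows (no bias column).
#' @param threshold Posterior threshold; defaults to the model's.
#' @param embedded Is `newdata` already embedded?
#' @param ... Unused.
#' @return Integer 0/1 matrix with a `"posteriors"` attribute.
#' @export
predict.pnn <- function(object, newdata, threshold = NULL, embedded = TRUE,
                        ...) {
  if (is.null(threshold)) threshold <- object$threshold
  if (!embedded) newdata <- embed_state(newdata, object$stats)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  P <- pnn_posteriors(object, newdata)
  out <- (P >= threshold) + 0L
  attr(out, "posteriors") <- P
  out
}

#' Select the kernel width multiplier on a validation split
#'
#' Splits the bank into teaching and validation processes, fits a PNN per
#' grid value on the teaching side, and scores each width by balanced
#' accuracy — the mean of true-positive and true-negative rates — over all
#' (state, control) decisions on the validation side. Ties go to the
#' smaller width. Deterministic given the seed.
#'
#' @param bank A [process_bank()].
#' @param grid Candidate widths (default `c(0.1, 0.5, 1, 2.5)`).
#' @param split_seed Seed for the process-level split.
#' @param validation_fraction Fraction of processes held out (default 0.2).
#' @param threshold Posterior decision threshold used for scoring.
#' @return The best `sigma` (numeric scalar) with attribute `"scores"` — a
#'   data frame of `sigma` and validation balanced accuracy.
#' @export
select_sigma <- function(bank, grid = c(0.1, 0.5, 1, 2.5), split_seed = 1L,
                         validation_fraction = 0.2, threshold = 0.5) {
  if (length(grid) == 0L) stop("sigma grid is empty")
  if (length(grid) == 1L) {
    return(structure(grid,
                     scores = data.frame(sigma = grid, balanced_accuracy = NA)))
  }
  sp <- split_bank(bank, control_fraction = validation_fraction,
                   seed = split_seed)
  stats <- fit_normalizer(sp$teaching)
  vd <- teaching_design(sp$control, stats)
  Q <- vd$X[, -ncol(vd$X), drop = FALSE]
  actual <- vd$targets > 0.5
  scores <- numeric(length(grid))
  for (i in seq_along(grid)) {
    model <- pnn(sp$teaching, stats = stats, sigma = grid[i],
                 threshold = threshold)
    pred <- pnn_posteriors(model, Q) >= threshold
    scores[i] <- balanced_accuracy(pred, actual)
  }
  ord <- order(-scores, grid)
  structure(grid[ord[1L]],
            scores = data.frame(sigma = grid, balanced_accuracy = scores))
}

# mean of TPR and TNR over pooled binary decisions; falls back to the
# available class's rate when one class is absent
balanced_accuracy <- function(pred, actual) {
  tp <- sum(pred & actual); fn <- sum(!pred & actual)
  tn <- sum(!pred & !actual); fp <- sum(pred & !actual)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  mean(c(tpr, tnr), na.rm = TRUE)
}
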