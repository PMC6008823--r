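#' Number of weights of the single-layer network
#'
#' One adder per control output, fully connected to the embedded state plus
#' a bias input: the weight count is simply the product of the two
#' dimensions.
#'
#' @param n_inputs_with_bias Input dimension including the bias component.
#' @param n_outputs Number of control outputs (`m`).
#' @return Integer product.
#' @export
count_weights <- function(n_inputs_with_bias, n_outputs) {
  if (n_inputs_with_bias < 1L || n_outputs < 1L) {
    stop("both dimensions must be positive")
  }
  as.integer(n_inputs_with_bias) * as.integer(n_outputs)
}

#' Encode teaching targets for a process
#'
#' For every non-terminal state the target is the binary indicator of the
#' next-step action, pushed into the open interval (0,1): component `j` is
#' `1 - eps` if control `j` received a positive delta at the next step and
#' `eps` otherwise. Terminal states have no observable next action and are
#' excluded.
#'
#' @param process A [dtp_process()].
#' @param glossary Its [control_glossary()].
#' @param eps Interior margin in `(0, 0.5)` (default 0.01).
#' @return Matrix `(T-1) x m` of targets in `(0,1)`; zero rows for length-1
#'   processes.
#' @export
encode_targets <- function(process, glossary, eps = 0.01) {
  if (eps <= 0 || eps >= 0.5) stop("eps must be in (0, 0.5)")
  T_ <- n_steps(process)
  m <- length(glossary$control_ids)
  if (T_ < 2L) {
    return(matrix(numeric(), 0L, m, dimnames = list(NULL, glossary$control_ids)))
  }
  d <- diff(process$controls)
  tgt <- matrix(eps, T_ - 1L, m, dimnames = list(NULL, glossary$control_ids))
  tgt[d > 0] <- 1 - eps
  tgt
}

# design matrix of all non-terminal embedded states with bias column,
# plus their binary applied-next labels
teaching_design <- function(bank, stats, eps = 0.01, which = "all") {
  Xs <- list(); Ts <- list(); meta <- list()
  for (i in seq_along(bank$processes)) {
    p <- bank$processes[[i]]
    if (n_steps(p) < 2L) next
    E <- embed_process(p, stats, which)
    Xs[[length(Xs) + 1L]] <- E[-nrow(E), , drop = FALSE]
    Ts[[length(Ts) + 1L]] <- encode_targets(p, bank$glossary, eps)
    meta[[length(meta) + 1L]] <- data.frame(
      proc = i, step = seq_len(n_steps(p) - 1L) - 1L)
  }
  if (length(Xs) == 0L) stop("bank has no non-terminal states")
  X <- cbind(do.call(rbind, Xs), bias = 1)
  list(X = X, targets = do.call(rbind, Ts), meta = do.call(rbind, meta))
}

slnn_loss_grad <- function(W, X, Tm, want_grad = TRUE) {
  A <- X %*% t(W)           # n x m pre-activations
  Y <- exp(-A^2 / 2)
  R <- Y - Tm
  loss <- sum(R^2)
  if (!want_grad) return(list(loss = loss, Y = Y))
  G <- 2 * R * (-A) * Y     # dE/dA
  list(loss = loss, grad = t(G) %*% X, Y = Y)
}

#' Forward pass of the single-layer network
#'
#' Each output neuron computes the weighted sum `a_j = w_j . x` of the
#' embedded state (with bias) and applies the Gaussian bell activation
#' `y_j = exp(-a_j^2 / 2)`. The bell shape reflects that integral controls
#' have protocol-imposed limits: the response peaks in a region of state
#' space and decays beyond it.
#'
#' @param model A fitted or freshly constructed [slnn()] model.
#' @param x Embedded state vector with bias component 1 appended (length
#'   `d + 1`), or a matrix of such rows.
#' @return Activation vector (or matrix) with values in `(0, 1]`.
#' @export
slnn_forward <- function(model, x) {
  W <- model$weights
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(W)) {
    stop("input length ", ncol(x), " does not match weight columns ", ncol(W))
  }
  A <- x %*% t(W)
  Y <- exp(-A^2 / 2)
  colnames(Y) <- rownames(W)
  if (nrow(Y) == 1L) Y[1L, ] else Y
}

#' Fit the single-layer Gaussian-activation network
#'
#' Trains one output neuron per control on all non-terminal states of the
#' teaching bank by full-batch steepest descent with an explicitly computed
#' gradient and Armijo backtracking line search. The objective is the
#' quadratic residual `E(W) = sum_states sum_j (y_j - t_j)^2` between the
#' Gaussian-bell activations and the interior-coded binary targets of the
#' observed next-step actions.
#'
#' Weights start at a deterministic configuration with all state weights 0
#' and bias weights 0.5. (The all-zero matrix is a stationary point of this
#' objective — the activation derivative `-a * y` vanishes at `a = 0` — so
#' descent must start off it.)
#'
#' @param bank Teaching [process_bank()].
#' @param stats Optional [fit_normalizer()]; fitted on `bank` when `NULL`.
#' @param eps Target interior margin, see [encode_targets()].
#' @param threshold Decision threshold on activations (default 0.1).
#' @param max_iters Maximum descent iterations (default 2000).
#' @param tol Relative loss-improvement stopping tolerance (default 1e-8).
#' @param init `"bias"` (default, deterministic) or `"random"`; random init
#'   draws N(0, 0.1) weights and requires `seed`.
#' @param seed Seed for random init.
#' @return An object of class `slnn` with `weights` (`m x (d+1)`),
#'   `threshold`, `trace` (loss per accepted iteration, non-increasing),
#'   `stats`, `iterations`, `converged`.
#' @export
slnn <- function(bank, stats = NULL, eps = 0.01, threshold = 0.1,
                 max_iters = 2000L, tol = 1e-8, init = c("bias", "random"),
                 seed = NULL) {
  stopifnot(inherits(bank, "dtp_bank"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  init <- match.arg(init)
  if (is.null(stats)) stats <- fit_normalizer(bank)
  td <- teaching_design(bank, stats, eps)
  X <- td$X
  Tm <- td$targets
  d1 <- ncol(X)
  m <- ncol(Tm)
  W <- matrix(0, m, d1, dimnames = list(colnames(Tm), colnames(X)))
  if (init == "bias") {
    W[, d1] <- 0.5
  } else {
    if (is.null(seed)) stop("random init requires a seed")
    set.seed(seed)
    W[] <- stats::rnorm(m * d1, 0, 0.1)
  }
  lg <- slnn_loss_grad(W, X, Tm)
  trace <- lg$loss
  step <- 1
  converged <- FALSE
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    g <- lg$grad
    gnorm2 <- sum(g^2)
    if (!is.finite(lg$loss)) {
      stop("non-finite loss at iteration ", it, "; aborting")
    }
    if (gnorm2 == 0) { converged <- TRUE; break }
    # Armijo backtracking along the steepest-descent direction
    t_ls <- step
    accepted <- FALSE
    for (h in 1:60) {
      Wn <- W - t_ls * g
      ln <- slnn_loss_grad(Wn, X, Tm, want_grad = FALSE)$loss
      if (is.finite(ln) && ln <= lg$loss - 1e-4 * t_ls * gnorm2) {
        accepted <- TRUE
        break
      }
      t_ls <- t_ls / 2
    }
    if (!accepted) { converged <- TRUE; break }
    W <- Wn
    prev <- lg$loss
    lg <- slnn_loss_grad(W, X, Tm)
    trace <- c(trace, lg$loss)
    step <- t_ls * 2  # let the next line search start a bit larger
    if (prev - lg$loss <= tol * max(prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(weights = W, threshold = threshold, eps = eps, trace = trace,
         stats = stats, iterations = it, converged = converged,
         final_loss = lg$loss),
    class = "slnn"
  )
}

#' @export
print.slnn <- function(x, ...) {
  cat(sprintf(
    "Single-layer Gaussian-activation network: %d outputs x %d inputs (bias incl.) = %d weights\n",
    nrow(x$weights), ncol(x$weights), length(x$weights)))
  cat(sprintf("  %d descent iterations, final loss %.6g, threshold %.2g\n",
              x$iterations, x$final_loss, x$threshold))
  invisible(x)
}

#' Binary recommendations from the single-layer network
#'
#' A control is recommended (output 1) iff its activation reaches the
#' decision threshold; the boundary is inclusive.
#'
#' @param object A fitted [slnn()].
#' @param newdata Embedded state rows *without* bias (bias appended
#'   internally), a `dtp_state`/raw state (set `embedded = FALSE`), or `NULL`.
#' @param threshold Decision threshold in `(0,1)`; defaults to the model's.
#' @param embedded Is `newdata` already embedded?
#' @param ... Unused.
#' @return Integer 0/1 matrix (states x controls) with an `"activations"`
#'   attribute holding the raw outputs.
#' @export
predict.slnn <- function(object, newdata, threshold = NULL, embedded = TRUE,
                         ...) {
  if (is.null(threshold)) threshold <- object$threshold
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (!embedded) newdata <- embed_state(newdata, object$stats)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  X <- cbind(newdata, bias = 1)
  Y <- slnn_forward(object, X)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L, dimnames = list(NULL, names(Y)))
  out <- (Y >= threshold) + 0L
  attr(out, "activations") <- Y
  out
}
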