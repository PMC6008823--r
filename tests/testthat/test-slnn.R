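test_that("weight count is the product of input and output dimensions", {
  expect_identical(count_weights(224, 222), 49728L)
  expect_identical(count_weights(2, 1), 2L)
  expect_identical(count_weights(6, 3), 18L)
  expect_error(count_weights(0, 3), "positive")
})

test_that("targets are interior-coded indicators of the next-step action", {
  gl <- tiny_glossary(6, 0)
  ctl <- matrix(0, 3, 6, dimnames = list(NULL, gl$control_ids))
  ctl[2, c(2, 5)] <- 1          # step 0 -> 1 applies controls 2 and 5
  ctl[3, ] <- ctl[2, ]          # step 1 -> 2 applies nothing
  p <- dtp_process("p", "X", ctl, glossary = gl)
  tgt <- encode_targets(p, gl, eps = 0.01)
  expect_equal(dim(tgt), c(2L, 6L))
  expect_equal(unname(tgt[1, ]), c(0.01, 0.99, 0.01, 0.01, 0.99, 0.01))
  expect_true(all(tgt[2, ] == 0.01))
  expect_error(encode_targets(p, gl, eps = 0), "eps")
  expect_error(encode_targets(p, gl, eps = 0.5), "eps")
})

test_that("the forward pass is the Gaussian bell of the weighted sum", {
  model <- structure(list(weights = rbind(c(1, 0))), class = "slnn")
  expect_equal(unname(slnn_forward(model, c(2, 1))), exp(-2))
  z <- structure(list(weights = matrix(0, 3, 2)), class = "slnn")
  expect_equal(unname(slnn_forward(z, c(5, 1))), rep(1, 3))
  big <- structure(list(weights = rbind(c(100, 0))), class = "slnn")
  expect_lt(slnn_forward(big, c(10, 1)), 1e-300)
  expect_error(slnn_forward(model, c(1, 2, 3)), "match")
})

test_that("the explicit gradient matches central finite differences", {
  # random 10-state, 5-control toy
  set.seed(31)
  X <- cbind(matrix(stats::rnorm(10 * 4), 10, 4), bias = 1)
  Tm <- matrix(stats::runif(10 * 5, 0.01, 0.99), 10, 5)
  W <- matrix(stats::rnorm(5 * 5, 0, 0.5), 5, 5)
  lg <- dtprec:::slnn_loss_grad(W, X, Tm)
  h <- 1e-5
  fd <- matrix(0, nrow(W), ncol(W))
  for (j in seq_len(nrow(W))) {
    for (k in seq_len(ncol(W))) {
      Wp <- W; Wp[j, k] <- W[j, k] + h
      Wm <- W; Wm[j, k] <- W[j, k] - h
      fd[j, k] <- (dtprec:::slnn_loss_grad(Wp, X, Tm, FALSE)$loss -
                     dtprec:::slnn_loss_grad(Wm, X, Tm, FALSE)$loss) / (2 * h)
    }
  }
  expect_lt(max(abs(lg$grad - fd)) / max(abs(fd)), 1e-5)
})

test_that("training decreases the loss monotonically and deterministically", {
  bank <- pneumonia_bank(n = 15, seed = 23, omit_prob = 0.1)
  m1 <- slnn(bank, max_iters = 60)
  expect_true(all(diff(m1$trace) <= 0))
  m2 <- slnn(bank, max_iters = 60)
  expect_identical(m1$weights, m2$weights)
  expect_lt(m1$final_loss, m1$trace[1L])
})

test_that("a reachable one-neuron target is driven to its grid-search optimum", {
  gl <- tiny_glossary(1, 0)
  p <- dtp_process("p", "X", cbind(c01 = c(0, 1)), glossary = gl)
  bank <- process_bank(gl, list(p))
  m <- slnn(bank, eps = 0.01, max_iters = 500, tol = 1e-14)
  expect_lt(m$final_loss, 1e-6)
  # independent oracle: dense grid search over the two weights; the fitted
  # loss must reach (up to tolerance) the best loss on the grid
  x <- dtprec:::teaching_design(bank, m$stats)$X[1, ]  # embedded state + bias
  target <- 0.99
  grid <- as.matrix(expand.grid(w1 = seq(-1, 1, by = 0.01),
                                wb = seq(-1, 1, by = 0.01)))
  grid_loss <- (exp(-(grid %*% x)^2 / 2) - target)^2
  expect_lte(m$final_loss, min(grid_loss) + 1e-9)
  # and the fitted activation hits the target
  a <- sum(m$weights[1, ] * x)
  expect_equal(exp(-a^2 / 2), target, tolerance = 1e-3)
})

test_that("prediction thresholds activations with an inclusive boundary", {
  gl <- tiny_glossary(2, 0)
  ctl <- cbind(c01 = c(0, 1, 1), c02 = c(0, 0, 2))
  bank <- process_bank(gl, list(dtp_process("p", "X", ctl, glossary = gl)))
  m <- slnn(bank, max_iters = 10)
  # boundary rule: activation exactly at the threshold counts as recommended
  m$weights[] <- 0
  m$weights[1, ncol(m$weights)] <- sqrt(-2 * log(0.1))  # y = 0.1 exactly
  pr <- predict(m, matrix(0, 1, ncol(m$weights) - 1L), threshold = 0.1)
  expect_identical(pr[1, 1][[1]], 1L)
  # zero weights activate everything below threshold 1
  m$weights[] <- 0
  expect_true(all(predict(m, matrix(0, 1, ncol(m$weights) - 1L),
                          threshold = 0.9) == 1L))
  expect_error(predict(m, matrix(0, 1, ncol(m$weights) - 1L), threshold = 1),
               "threshold")
})

test_that("the recommendation count is monotone non-increasing in the threshold", {
  bank <- pneumonia_bank(n = 12, seed = 25, omit_prob = 0.15)
  sp <- split_bank(bank, 0.25, seed = 2)
  m <- slnn(sp$teaching, max_iters = 120)
  vd <- dtprec:::teaching_design(sp$control, m$stats)
  X <- vd$X[, -ncol(vd$X), drop = FALSE]
  counts <- vapply(c(0.05, 0.1, 0.3, 0.5, 0.7, 0.9),
                   function(th) sum(predict(m, X, threshold = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})
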