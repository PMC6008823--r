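test_that("kernels are the non-terminal states and classes partition them", {
  gl <- tiny_glossary(3, 0)
  mk <- function(id, n) {
    ctl <- matrix(cumsum(rep(1, n)), n, 3, dimnames = list(NULL, gl$control_ids))
    dtp_process(id, "X", ctl, glossary = gl)
  }
  bank <- process_bank(gl, list(mk("a", 3), mk("b", 4)))
  m <- pnn(bank, sigma = 1)
  expect_equal(nrow(m$centers), (3 - 1) + (4 - 1))  # terminal states excluded
  # every kernel is in exactly one of KL1 / KL0 for every control
  expect_true(all(m$labels %in% c(TRUE, FALSE)))
  expect_equal(dim(m$labels), c(5L, 3L))
  expect_equal(unname(m$prior1), unname(colMeans(m$labels)))
})

test_that("a control never applied has an empty positive class and is never recommended", {
  gl <- tiny_glossary(2, 0)
  ctl <- cbind(c01 = c(0, 1, 2), c02 = c(0, 0, 0))
  bank <- process_bank(gl, list(dtp_process("p", "X", ctl, glossary = gl)))
  m <- pnn(bank, sigma = 1)
  expect_equal(unname(m$prior1[["c02"]]), 0)
  q <- m$centers[1L, ]
  expect_equal(unname(pnn_posterior(m, q, "c02")), 0)
  expect_equal(unname(pnn_posterior(m, q, "c01")), 1)  # empty KL0 -> 1
  rec <- recommend_pnn(m, q)
  expect_false("c02" %in% rec$applied)
  expect_true("c01" %in% rec$applied)
})

test_that("log kernel matches the closed-form diagonal Gaussian", {
  # peak value at the centre
  expect_equal(log_kernel(c(1, 2), c(1, 2), sigma = 1, s = c(1, 1)),
               -2 * log(sqrt(2 * pi)))
  # 1-D, unit scales, offset 1
  expect_equal(log_kernel(0, 1, sigma = 1, s = 1), -0.5 - 0.5 * log(2 * pi))
  # doubling sigma at the centre lowers the log density by d * log 2
  d <- 4
  c0 <- rep(0, d)
  expect_equal(log_kernel(c0, c0, sigma = 2, s = rep(1, d)) -
                 log_kernel(c0, c0, sigma = 1, s = rep(1, d)),
               -d * log(2))
  expect_error(log_kernel(0, 1, sigma = 0), "positive")
})

test_that("posteriors agree with direct density arithmetic to 1e-12", {
  # 1-D and 2-D toys, evaluated against an oracle built from dnorm products
  for (dim_d in 1:2) {
    set.seed(40 + dim_d)
    n <- 12
    centers <- matrix(stats::rnorm(n * dim_d), n, dim_d)
    labels <- matrix(c(rep(TRUE, 5), rep(FALSE, 7)), n, 1)
    colnames(labels) <- "c01"
    m <- structure(list(centers = centers, scale = rep(1, dim_d),
                        sigma = 0.8, labels = labels,
                        prior1 = colMeans(labels), threshold = 0.5),
                   class = "pnn")
    for (rep_i in 1:10) {
      q <- stats::rnorm(dim_d)
      dens <- vapply(seq_len(n), function(i) {
        prod(stats::dnorm(q, centers[i, ], 0.8))
      }, numeric(1))
      f1 <- mean(dens[labels[, 1]]); f0 <- mean(dens[!labels[, 1]])
      pi1 <- mean(labels[, 1]); pi0 <- 1 - pi1
      oracle <- pi1 * f1 / (pi1 * f1 + pi0 * f0)
      expect_equal(unname(pnn_posterior(m, q, "c01")), oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("two mirrored kernels with equal priors give posterior one half", {
  labels <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(NULL, "c01"))
  m <- structure(list(centers = rbind(-1, 1), scale = 1, sigma = 1,
                      labels = labels, prior1 = 0.5, threshold = 0.5),
                 class = "pnn")
  expect_equal(unname(pnn_posterior(m, 0, "c01")), 0.5)
  # complementary class probabilities sum to one
  p1 <- pnn_posterior(m, 0.3, "c01")
  m_flip <- m
  m_flip$labels[, 1] <- !m$labels[, 1]
  p0 <- pnn_posterior(m_flip, 0.3, "c01")
  expect_equal(unname(p1 + p0), 1)
})

test_that("posteriors survive extreme dimensionality without underflow", {
  # products of hundreds of kernel factors underflow in direct arithmetic;
  # the log-space path must stay finite and normalized
  set.seed(50)
  d <- 639
  centers <- matrix(stats::rnorm(20 * d), 20, d)
  labels <- matrix(rep(c(TRUE, FALSE), 10), 20, 1,
                   dimnames = list(NULL, "c01"))
  m <- structure(list(centers = centers, scale = rep(1, d), sigma = 0.5,
                      labels = labels, prior1 = 0.5, threshold = 0.5),
                 class = "pnn")
  p <- pnn_posterior(m, stats::rnorm(d), "c01")
  expect_true(is.finite(p))
  expect_gte(p, 0); expect_lte(p, 1)
})

test_that("as sigma grows the posterior converges to the class prior", {
  gl <- tiny_glossary(1, 0)
  ctl1 <- cbind(c01 = c(0, 1, 1, 2))   # applies at steps 0 and 2
  ctl2 <- cbind(c01 = c(0, 0, 0))      # never applies
  bank <- process_bank(gl, list(dtp_process("a", "X", ctl1, glossary = gl),
                                dtp_process("b", "X", ctl2, glossary = gl)))
  m_inf <- pnn(bank, sigma = 1e8)
  q <- m_inf$centers[1L, ] + 0.37
  expect_equal(unname(pnn_posterior(m_inf, q, "c01")),
               unname(m_inf$prior1[["c01"]]), tolerance = 1e-6)
})

test_that("sigma selection is deterministic, tie-broken low, and prefers wide kernels on noise", {
  bank <- pneumonia_bank(n = 40, seed = 27, omit_prob = 0.2,
                         spurious_prob = 0.05)
  expect_equal(as.numeric(select_sigma(bank, grid = 2.5)), 2.5)
  expect_error(select_sigma(bank, grid = numeric()), "empty")
  # duplicated grid values force a tie; the smaller (first) wins
  tie <- select_sigma(bank, grid = c(1, 1), split_seed = 3)
  expect_equal(as.numeric(tie), 1)

  best <- select_sigma(bank, split_seed = 5)
  sc <- attr(best, "scores")
  expect_identical(select_sigma(bank, split_seed = 5)[1], best[1])
  expect_gte(sc$balanced_accuracy[sc$sigma == as.numeric(best)][1],
             sc$balanced_accuracy[sc$sigma == 0.1][1])
})
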