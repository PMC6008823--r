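test_that("graph construction yields one node per state with exact wiring", {
  gl <- tiny_glossary(2, 0)
  p <- dtp_process("solo", "X",
                   cbind(c01 = c(0, 1, 2, 3, 4), c02 = c(0, 0, 1, 1, 2)),
                   glossary = gl)
  g <- case_graph(process_bank(gl, list(p)), n_neighbors = 2)
  expect_equal(nrow(g$emb), 5L)
  expect_equal(sum(!is.na(g$succ)), 4L)  # k - 1 sequence links
  expect_equal(g$succ[1:4], 2:5)

  # ten processes of ten fixed-length states -> 100 nodes, full 8-NN lists
  tmpl <- flat_template()
  tmpl$length_base <- 10
  bank <- generate_bank(generator_config(tmpl, n_processes = 10, seed = 3))
  g2 <- case_graph(bank, n_neighbors = 8)
  expect_equal(nrow(g2$emb), 100L)
  expect_true(all(rowSums(!is.na(g2$nn)) == 8L))
  expect_error(case_graph(process_bank(gl, list(
    dtp_process("one", "X", cbind(c01 = 0, c02 = 0), glossary = gl))),
    n_neighbors = 2), "at least 2")
})

test_that("neighbour lists are sorted by distance with id tie-breaks", {
  bank <- pneumonia_bank(n = 6, seed = 12, omit_prob = 0.1)
  g <- case_graph(bank, n_neighbors = 5)
  for (i in seq_len(nrow(g$emb))) {
    nb <- g$nn[i, ]
    nb <- nb[!is.na(nb)]
    d <- vapply(nb, function(j) state_distance(g$emb[i, ], g$emb[j, ]),
                numeric(1))
    expect_true(all(diff(d) >= -1e-12))
  }
})

test_that("greedy search with full restarts equals brute-force nearest neighbour", {
  bank <- pneumonia_bank(n = 20, seed = 14, omit_prob = 0.15,
                         dose_jitter_sd = 0.2)
  g <- case_graph(bank)
  N <- nrow(g$emb)
  set.seed(99)
  for (i in 1:30) {
    q <- g$emb[sample.int(N, 1L), ] + stats::rnorm(ncol(g$emb), 0, 0.3)
    res <- greedy_search(g, q, n_restarts = N, seed = i)
    oracle <- brute_nn(g$emb, q)
    expect_identical(res$node, oracle$node)
    expect_equal(res$distance, oracle$distance)
  }
})

test_that("a query equal to an existing node is found at distance zero", {
  bank <- pneumonia_bank(n = 8, seed = 15)
  g <- case_graph(bank)
  N <- nrow(g$emb)
  res <- greedy_search(g, g$emb[17L, ], n_restarts = N, seed = 1)
  expect_equal(res$distance, 0)
  expect_equal(g$emb[res$node, ], g$emb[17L, ])
})

test_that("descent paths are strictly decreasing in distance to the query", {
  bank <- pneumonia_bank(n = 15, seed = 16, omit_prob = 0.2)
  g <- case_graph(bank)
  set.seed(7)
  for (i in 1:20) {
    q <- stats::rnorm(ncol(g$emb), 0, 1)
    res <- greedy_search(g, q, n_restarts = 10, seed = i)
    for (pth in res$paths) {
      if (length(pth) > 1L) expect_true(all(diff(pth) < 0))
    }
  }
})

test_that("incremental teaching follows the k*m metric and (k-1 + k*n) edge accounting", {
  tmpl <- flat_template()
  tmpl$length_base <- 10
  bank <- generate_bank(generator_config(tmpl, n_processes = 10, seed = 5))
  g <- case_graph(bank, n_neighbors = 8)   # m = 100 nodes
  m <- nrow(g$emb)
  expect_equal(m, 100L)
  p_new <- generate_process(tmpl, seed = 123, process_id = "new")
  p_new$controls <- p_new$controls[1:3, , drop = FALSE]  # k = 3 states
  p_new$monitored <- p_new$monitored[1:3, , drop = FALSE]
  before_d <- g$dist_count
  before_e <- graph_edge_count(g)
  g2 <- add_process(g, p_new)
  expect_equal(g2$dist_count - before_d, 3 * 100)            # k * m
  expect_equal(nrow(g2$emb) - m, 3L)                         # k new nodes
  expect_equal(graph_edge_count(g2) - before_e, (3 - 1) + 3 * 8)

  # arbitrary (k, m, n): second process, different n_neighbors
  g3 <- case_graph(bank, n_neighbors = 4)
  k <- n_steps(p_new)
  d0 <- g3$dist_count; e0 <- graph_edge_count(g3)
  g4 <- add_process(g3, p_new)
  expect_equal(g4$dist_count - d0, k * 100)
  expect_equal(graph_edge_count(g4) - e0, (k - 1) + k * 4)
})

test_that("newly added knowledge is retrievable immediately", {
  bank <- pneumonia_bank(n = 10, seed = 18)
  g <- case_graph(bank)
  p_new <- generate_process(default_template("pneumonia_like"), seed = 555,
                            process_id = "fresh")
  g2 <- add_process(g, p_new)
  E <- embed_process(p_new, g2$stats)
  res <- greedy_search(g2, E[2L, ], n_restarts = nrow(g2$emb), seed = 4)
  expect_equal(res$distance, 0)
  expect_equal(g2$process_ids[g2$proc[res$node]], "fresh")
})

test_that("recommendation recalls the training successor's delta", {
  bank <- pneumonia_bank(n = 10, seed = 19)
  g <- case_graph(bank)
  p <- bank$processes[[3L]]
  st <- state_at(p, 2)
  rec <- recommend_case(g, st, n_restarts = nrow(g$emb), seed = 2)
  expect_s3_class(rec, "dtp_recommendation")
  expect_equal(as.numeric(rec$delta), as.numeric(step_delta(p, 2)))
})

test_that("terminal-only graphs yield the explicit no-recommendation outcome", {
  gl <- tiny_glossary(2, 0)
  mk <- function(id, v) dtp_process(id, "X", matrix(v, 1, 2,
                                                    dimnames = list(NULL, gl$control_ids)),
                                    glossary = gl)
  bank <- process_bank(gl, list(mk("a", c(0, 1)), mk("b", c(2, 3)),
                                mk("c", c(4, 5))))
  g <- case_graph(bank, n_neighbors = 2)
  rec <- recommend_case(g, stats::setNames(c(0, 1), gl$control_ids),
                        n_restarts = 3, seed = 1)
  expect_null(rec$delta)
  expect_length(rec$applied, 0L)
})

test_that("terminal nearest neighbours fall back to the best non-terminal minimum", {
  gl <- tiny_glossary(1, 0)
  # the nearest node to the query is a terminal singleton; with one-edge
  # neighbour lists a restart inside the far process sticks at a
  # non-terminal local minimum, which the fallback must use
  p1 <- dtp_process("single", "X", cbind(c01 = 0), glossary = gl)
  p2 <- dtp_process("far", "X", cbind(c01 = c(5, 6, 7)), glossary = gl)
  bank <- process_bank(gl, list(p1, p2))
  g <- case_graph(bank, n_neighbors = 1)
  q <- embed_state(0, g$stats)
  rec <- recommend_case(g, q, n_restarts = 4, seed = 1, embedded = TRUE)
  expect_false(is.null(rec$delta))   # fell back to a non-terminal precedent
  expect_equal(rec$neighbor$process_id, "far")
  expect_equal(as.numeric(rec$delta), 1)
})

test_that("layered search honours the layer and rejects absent layers", {
  bank <- pneumonia_bank(n = 10, seed = 20)
  g <- case_graph(bank)
  q <- g$emb[5L, ]
  res <- greedy_search(g, q, n_restarts = 50, seed = 3, layer = g$step[5L])
  expect_equal(res$distance, 0)
  expect_error(greedy_search(g, q, layer = 999), "layer")
})
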