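#' Build the case graph of a process bank
#'
#' Realizes the case-based engine's knowledge structure: one node per state
#' of every teaching process, each node linked to its `n_neighbors` nearest
#' nodes under the embedded-state metric (a navigable small-world style
#' k-NN graph), plus sequence links from each state to its successor within
#' the same process. Neighbour lists are exact (brute-force construction),
#' sorted ascending by distance with ties broken by lower node id.
#'
#' @param bank Teaching [process_bank()].
#' @param n_neighbors Edges per node (graph parameter `n`, default 8).
#' @param stats Optional [fit_normalizer()]; fitted on `bank` when `NULL`.
#' @param which Embedding restriction (`"all"`, `"monitored"`, `"controls"`),
#'   see [embed_state()].
#' @return An object of class `case_graph` with fields `emb` (node
#'   embeddings), `controls` (raw cumulative controls per node), `proc`,
#'   `step`, `nn` (neighbour index matrix), `succ` (successor node or `NA`),
#'   `n_neighbors`, `stats`, `dist_count` (metric-evaluation counter) and
#'   `process_ids`.
#' @export
case_graph <- function(bank, n_neighbors = 8L, stats = NULL, which = "all") {
  stopifnot(inherits(bank, "dtp_bank"), n_neighbors >= 1L)
  if (is.null(stats)) stats <- fit_normalizer(bank)
  lens <- vapply(bank$processes, n_steps, integer(1))
  N <- sum(lens)
  if (N < 2L) stop("case graph needs at least 2 states")
  emb <- do.call(rbind, lapply(bank$processes, embed_process,
                               stats = stats, which = which))
  ctl <- do.call(rbind, lapply(bank$processes, function(p) p$controls))
  proc <- rep.int(seq_along(lens), lens)
  step <- unlist(lapply(lens, function(l) seq_len(l) - 1L), use.names = FALSE)
  succ <- rep(NA_integer_, N)
  last <- cumsum(lens)
  nonterm <- setdiff(seq_len(N), last)
  succ[nonterm] <- nonterm + 1L
  g <- structure(
    list(emb = emb, controls = ctl, proc = proc, step = step,
         nn = NULL, succ = succ, n_neighbors = as.integer(n_neighbors),
         stats = stats, which = which,
         dist_count = N * (N - 1) / 2,
         process_ids = vapply(bank$processes, function(p) p$process_id,
                              character(1))),
    class = "case_graph"
  )
  g$nn <- knn_lists(emb, n_neighbors)
  g
}

# exact k-NN lists, ascending distance, ties -> lower node id
knn_lists <- function(emb, k) {
  N <- nrow(emb)
  D <- as.matrix(stats::dist(emb))
  k_eff <- min(k, N - 1L)
  nn <- matrix(NA_integer_, N, k)
  for (i in seq_len(N)) {
    ord <- order(D[i, -i], seq_len(N)[-i])
    nn[i, seq_len(k_eff)] <- (seq_len(N)[-i])[ord[seq_len(k_eff)]]
  }
  nn
}

#' @export
print.case_graph <- function(x, ...) {
  cat(sprintf("Case graph: %d nodes, %d neighbour edges + %d sequence links, n = %d\n",
              nrow(x$emb), sum(!is.na(x$nn)), sum(!is.na(x$succ)),
              x$n_neighbors))
  cat(sprintf("  metric evaluations so far: %g\n", x$dist_count))
  invisible(x)
}

#' Total edge count of a case graph
#'
#' Neighbour edges plus within-process sequence links.
#'
#' @param graph A [case_graph()].
#' @return Integer edge count.
#' @export
graph_edge_count <- function(graph) {
  sum(!is.na(graph$nn)) + sum(!is.na(graph$succ))
}

#' Greedy nearest-neighbour search on the case graph
#'
#' From each of several randomly selected start nodes, descends the graph:
#' repeatedly moves to the neighbour strictly closer to the query (the
#' closest improving neighbour; ties broken by lower node id) until no
#' neighbour improves. The best terminal node over all restarts is returned
#' as the query's nearest neighbour. With `n_restarts` equal to the node
#' count the result provably equals the exhaustive nearest neighbour.
#'
#' @param graph A [case_graph()].
#' @param query Embedded query vector (use [embed_state()]).
#' @param n_restarts Number of random starts; default
#'   `max(5, ceiling(0.005 * N))` — half a percent of the node count — for
#'   global search, 10 when restricted to a layer.
#' @param seed Optional seed for start selection.
#' @param layer Optional step index; restricts starts to nodes at that step
#'   (layered search for queries that know their own day).
#' @return List with `node` (best node id), `distance`, `minima` (data frame
#'   of all restart termini), `path_lengths` (descent steps per restart),
#'   `paths` (distance-to-query sequence of each descent, strictly
#'   decreasing) and `n_dist_evals` (distances computed, memoized per
#'   query).
#' @export
greedy_search <- function(graph, query, n_restarts = NULL, seed = NULL,
                          layer = NULL) {
  N <- nrow(graph$emb)
  if (N < 1L) stop("empty graph")
  if (is.null(n_restarts)) {
    # global: half a percent of the node count; layered: 10 starts suffice
    n_restarts <- if (is.null(layer)) max(5L, ceiling(0.005 * N)) else 10L
  }
  stopifnot(n_restarts >= 1L)
  pool <- seq_len(N)
  if (!is.null(layer)) {
    pool <- which(graph$step == layer)
    if (length(pool) == 0L) stop("no nodes in layer ", layer)
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- if (length(pool) <= n_restarts) {
    rep_len(pool, n_restarts)
  } else {
    sample(pool, n_restarts)
  }
  # distances to the query are memoized: each node's distance computed once
  dq <- rep(NA_real_, N)
  evals <- 0L
  dget <- function(idx) {
    todo <- idx[is.na(dq[idx])]
    if (length(todo) > 0L) {
      diffs <- graph$emb[todo, , drop = FALSE] -
        matrix(query, length(todo), length(query), byrow = TRUE)
      dq[todo] <<- sqrt(rowSums(diffs^2))
      evals <<- evals + length(todo)
    }
    dq[idx]
  }
  term_node <- integer(n_restarts)
  term_dist <- numeric(n_restarts)
  path_len <- integer(n_restarts)
  paths <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    cur <- starts[r]
    dcur <- dget(cur)
    dpath <- dcur
    steps <- 0L
    repeat {
      nbrs <- graph$nn[cur, ]
      nbrs <- nbrs[!is.na(nbrs)]
      if (length(nbrs) == 0L) break
      dn <- dget(nbrs)
      best <- which(dn == min(dn))
      b <- nbrs[best[which.min(nbrs[best])]]
      if (dq[b] < dcur) {
        cur <- b
        dcur <- dq[b]
        dpath <- c(dpath, dcur)
        steps <- steps + 1L
      } else break
    }
    term_node[r] <- cur
    term_dist[r] <- dcur
    path_len[r] <- steps
    paths[[r]] <- dpath
  }
  ord <- order(term_dist, term_node)
  list(node = term_node[ord[1L]], distance = term_dist[ord[1L]],
       minima = data.frame(node = term_node, distance = term_dist),
       path_lengths = path_len, paths = paths, n_dist_evals = evals)
}

#' Add a new process to an existing case graph (incremental teaching)
#'
#' The case engine digests new knowledge immediately: the `k` states of the
#' new process become `k` new nodes whose neighbour lists are computed
#' against the `m` pre-existing nodes only (exactly `k * m` metric
#' evaluations, added to the graph's counter), connected by `k - 1` sequence
#' links, contributing `k * n` neighbour edges. Existing nodes' neighbour
#' lists are not refreshed; use [refresh_neighbors()] for a full rebuild.
#'
#' @param graph A [case_graph()].
#' @param process A valid [dtp_process()] on the same glossary.
#' @return The updated `case_graph`.
#' @export
add_process <- function(graph, process) {
  E <- embed_process(process, graph$stats, graph$which)
  if (ncol(E) != ncol(graph$emb)) stop("process does not match graph glossary")
  m <- nrow(graph$emb)
  k <- nrow(E)
  nnew <- matrix(NA_integer_, k, ncol(graph$nn))
  k_eff <- min(graph$n_neighbors, m)
  for (i in seq_len(k)) {
    diffs <- graph$emb - matrix(E[i, ], m, ncol(E), byrow = TRUE)
    d <- sqrt(rowSums(diffs^2))
    ord <- order(d, seq_len(m))
    nnew[i, seq_len(k_eff)] <- ord[seq_len(k_eff)]
  }
  graph$dist_count <- graph$dist_count + k * m
  graph$emb <- rbind(graph$emb, E)
  graph$controls <- rbind(graph$controls, process$controls)
  graph$proc <- c(graph$proc, rep.int(length(graph$process_ids) + 1L, k))
  graph$step <- c(graph$step, seq_len(k) - 1L)
  new_ids <- m + seq_len(k)
  graph$succ <- c(graph$succ,
                  c(if (k > 1L) new_ids[-1L] else integer(), NA_integer_))
  graph$nn <- rbind(graph$nn, nnew)
  graph$process_ids <- c(graph$process_ids, process$process_id)
  graph
}

#' Rebuild all neighbour lists from scratch
#'
#' Maintenance operation compensating for the fact that incremental teaching
#' never refreshes old nodes' neighbour lists.
#'
#' @param graph A [case_graph()].
#' @return The graph with exact neighbour lists over all current nodes.
#' @export
refresh_neighbors <- function(graph) {
  N <- nrow(graph$emb)
  graph$nn <- knn_lists(graph$emb, graph$n_neighbors)
  graph$dist_count <- graph$dist_count + N * (N - 1) / 2
  graph
}

#' Case-based next-step recommendation
#'
#' Finds the query state's nearest neighbour `t` on the case graph and
#' recommends the control delta its own process applied next:
#' `U(t+1) - U(t)`. If the nearest neighbour is a terminal state (no
#' successor), the best non-terminal restart terminus is used instead; if no
#' restart found a non-terminal node, an explicit no-recommendation outcome
#' is returned.
#'
#' @param graph A [case_graph()].
#' @param state A `dtp_state`, raw state vector, or already-embedded vector
#'   (set `embedded = TRUE`).
#' @param n_restarts,seed,layer Passed to [greedy_search()].
#' @param embedded Is `state` already in embedded coordinates?
#' @return A `dtp_recommendation`: list with `delta` (a `control_delta` or
#'   `NULL`), `applied` (recommended applied set), `neighbor`
#'   (process id / step of the precedent used), `distance`, `engine`.
#' @export
recommend_case <- function(graph, state, n_restarts = NULL, seed = NULL,
                           layer = NULL, embedded = FALSE) {
  q <- if (embedded) state else embed_state(state, graph$stats, graph$which)
  res <- greedy_search(graph, q, n_restarts = n_restarts, seed = seed,
                       layer = layer)
  node <- res$node
  if (is.na(graph$succ[node])) {
    mins <- res$minima
    ok <- !is.na(graph$succ[mins$node])
    if (!any(ok)) {
      return(structure(list(delta = NULL, applied = character(),
                            neighbor = NULL, distance = NA_real_,
                            engine = "case"),
                       class = "dtp_recommendation"))
    }
    mins <- mins[ok, , drop = FALSE]
    best <- order(mins$distance, mins$node)[1L]
    node <- mins$node[best]
  }
  s <- graph$succ[node]
  delta <- delta_control(graph$controls[node, ], graph$controls[s, ],
                         source = sprintf("case:%s/step%d",
                                          graph$process_ids[graph$proc[node]],
                                          graph$step[node]))
  structure(
    list(delta = delta, applied = applied_set(delta),
         neighbor = list(process_id = graph$process_ids[graph$proc[node]],
                         step = graph$step[node]),
         distance = res$distance, engine = "case"),
    class = "dtp_recommendation"
  )
}

#' @export
print.dtp_recommendation <- function(x, ...) {
  if (is.null(x$delta)) {
    cat("DTP recommendation (", x$engine, "): unable to recommend\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("DTP recommendation (%s): %d controls", x$engine,
              length(x$applied)))
  if (!is.null(x$neighbor)) {
    cat(sprintf(" [precedent %s, step %d, distance %.3f]",
                x$neighbor$process_id, x$neighbor$step, x$distance))
  }
  cat("\n")
  if (length(x$applied) > 0L) {
    d <- as.numeric(x$delta)[match(x$applied, names(x$delta))]
    cat(paste(sprintf("  %s +%g", x$applied, d), collapse = "\n"), "\n")
  }
  invisible(x)
}
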