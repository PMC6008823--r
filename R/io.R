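#' Write a process bank as JSON Lines
#'
#' First line is a header record carrying the glossary (and optionally the
#' normalization statistics so recommendation runs reuse teaching-time
#' normalization bit-exactly); every following line is one process:
#' `{"process_id": ..., "nosology": ..., "states": [{"step": t,
#' "controls": {id: value}, "monitored": {id: value|null}}]}`.
#' Numbers are written at full precision, so a write/read round trip
#' reproduces the bank exactly.
#'
#' @param bank A [process_bank()].
#' @param path Output file path.
#' @param stats Optional [fit_normalizer()] to embed in the header.
#' @return `path`, invisibly.
#' @export
write_bank <- function(bank, path, stats = NULL) {
  gl <- bank$glossary
  header <- list(
    type = "glossary", nosology = bank$nosology, provenance = bank$provenance,
    control_ids = gl$control_ids,
    category = as.list(gl$category), unit = as.list(gl$unit),
    monitored_ids = gl$monitored_ids,
    monitored_kind = as.list(gl$monitored_kind),
    monitored_levels = gl$monitored_levels)
  if (!is.null(stats)) {
    header$stats <- list(ids = stats$ids, mean = stats$mean, sd = stats$sd,
                         fill = stats$fill, zero_var = stats$zero_var,
                         n_control = stats$n_control)
  }
  lines <- character(1L + length(bank$processes))
  lines[1L] <- jsonlite::toJSON(header, auto_unbox = TRUE, digits = I(17), na = "null",
                                null = "null")
  for (i in seq_along(bank$processes)) {
    p <- bank$processes[[i]]
    states <- lapply(seq_len(n_steps(p)), function(t1) {
      mon <- if (ncol(p$monitored) > 0L) as.list(p$monitored[t1, ]) else
        stats::setNames(list(), character())
      list(step = t1 - 1L, controls = as.list(p$controls[t1, ]),
           monitored = mon)
    })
    lines[i + 1L] <- jsonlite::toJSON(
      list(process_id = p$process_id, nosology = p$nosology, states = states),
      auto_unbox = TRUE, digits = I(17), na = "null", null = "null")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a process bank from JSON Lines
#'
#' @param path File written by [write_bank()].
#' @return A [process_bank()]; if the header carried normalization stats
#'   they are attached as attribute `"stats"`.
#' @export
read_bank <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty bank file: ", path)
  header <- tryCatch(jsonlite::fromJSON(lines[1L], simplifyVector = TRUE),
                     error = function(e) stop("malformed header at line 1: ",
                                              conditionMessage(e)))
  if (!identical(header$type, "glossary")) {
    stop("line 1 is not a glossary header record")
  }
  gl <- control_glossary(
    header$control_ids,
    category = unlist(header$category),
    unit = if (length(header$unit) > 0) unlist(header$unit) else NULL,
    monitored_ids = header$monitored_ids %||% character(),
    monitored_kind = if (length(header$monitored_kind) > 0)
      unlist(header$monitored_kind) else "numeric",
    monitored_levels = header$monitored_levels %||% list())
  if (length(lines) < 2L) stop("bank file has a header but no processes")
  procs <- vector("list", length(lines) - 1L)
  for (i in seq.int(2L, length(lines))) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) stop("malformed record at line ", i,
                                             ": ", conditionMessage(e)))
    T_ <- length(rec$states)
    ctl <- matrix(0, T_, length(gl$control_ids),
                  dimnames = list(NULL, gl$control_ids))
    mon <- matrix(NA_real_, T_, length(gl$monitored_ids),
                  dimnames = list(NULL, gl$monitored_ids))
    for (t1 in seq_len(T_)) {
      st <- rec$states[[t1]]
      cids <- names(st$controls)
      unknown <- setdiff(cids, gl$control_ids)
      if (length(unknown) > 0L) {
        stop("line ", i, ": unknown control id(s) ",
             paste(unknown, collapse = ", "))
      }
      ctl[t1, cids] <- unlist(st$controls)
      mids <- names(st$monitored)
      unknown_m <- setdiff(mids, gl$monitored_ids)
      if (length(unknown_m) > 0L) {
        stop("line ", i, ": unknown monitored id(s) ",
             paste(unknown_m, collapse = ", "))
      }
      for (id in mids) {
        v <- st$monitored[[id]]
        mon[t1, id] <- if (is.null(v)) NA_real_ else as.numeric(v)
      }
    }
    procs[[i - 1L]] <- dtp_process(rec$process_id, rec$nosology, ctl, mon,
                                   gl, validate = FALSE)
  }
  bank <- process_bank(gl, procs, nosology = header$nosology,
                       provenance = header$provenance %||% "unspecified",
                       validate = TRUE)
  if (!is.null(header$stats)) {
    st <- header$stats
    attr(bank, "stats") <- structure(
      list(ids = st$ids, mean = stats::setNames(st$mean, st$ids),
           sd = stats::setNames(st$sd, st$ids),
           fill = stats::setNames(st$fill, st$ids),
           zero_var = stats::setNames(as.logical(st$zero_var), st$ids),
           n_control = st$n_control),
      class = "dtp_normalizer")
  }
  bank
}

#' Export a bank's states as CSV
#'
#' One row per state: process id, step, control columns, monitored columns.
#'
#' @param bank A [process_bank()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bank_csv <- function(bank, path) {
  rows <- lapply(bank$processes, function(p) {
    data.frame(process_id = p$process_id, step = seq_len(n_steps(p)) - 1L,
               p$controls, p$monitored, check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Save or load a fitted engine as a JSON archive
#'
#' Serializes an [slnn()], [pnn()] or [case_graph()] (weights/centres/
#' adjacency plus their normalization statistics) to plain-text JSON.
#'
#' @param model A fitted engine.
#' @param path Archive path.
#' @return `write_model`: `path` invisibly; `read_model`: the engine.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  payload <- switch(
    kind,
    slnn = list(weights = model$weights, threshold = model$threshold,
                eps = model$eps, trace = model$trace,
                iterations = model$iterations, converged = model$converged,
                final_loss = model$final_loss,
                weight_names = list(rownames(model$weights),
                                    colnames(model$weights))),
    pnn = list(centers = model$centers, scale = model$scale,
               sigma = model$sigma, labels = model$labels,
               prior1 = model$prior1, threshold = model$threshold,
               center_names = colnames(model$centers),
               control_names = colnames(model$labels)),
    case_graph = list(emb = model$emb, controls = model$controls,
                      proc = model$proc, step = model$step, nn = model$nn,
                      succ = model$succ, n_neighbors = model$n_neighbors,
                      which = model$which, dist_count = model$dist_count,
                      process_ids = model$process_ids,
                      emb_names = colnames(model$emb),
                      control_names = colnames(model$controls)),
    stop("cannot serialize model of class ", kind))
  st <- model$stats
  obj <- list(kind = kind, payload = payload,
              stats = list(ids = st$ids, mean = st$mean, sd = st$sd,
                           fill = st$fill, zero_var = st$zero_var,
                           n_control = st$n_control))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17), na = "null",
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  st <- obj$stats
  stats <- structure(
    list(ids = st$ids, mean = stats::setNames(st$mean, st$ids),
         sd = stats::setNames(st$sd, st$ids),
         fill = stats::setNames(st$fill, st$ids),
         zero_var = stats::setNames(as.logical(st$zero_var), st$ids),
         n_control = st$n_control),
    class = "dtp_normalizer")
  pl <- obj$payload
  switch(
    obj$kind,
    slnn = structure(
      list(weights = matrix(unlist(pl$weights), nrow = length(pl$weight_names[[1]]),
                            dimnames = pl$weight_names),
           threshold = pl$threshold, eps = pl$eps, trace = pl$trace,
           stats = stats, iterations = pl$iterations,
           converged = pl$converged, final_loss = pl$final_loss),
      class = "slnn"),
    pnn = structure(
      list(centers = `colnames<-`(as.matrix(pl$centers), pl$center_names),
           scale = stats::setNames(pl$scale, pl$center_names),
           sigma = pl$sigma,
           labels = `colnames<-`(as.matrix(pl$labels), pl$control_names),
           prior1 = stats::setNames(pl$prior1, pl$control_names),
           threshold = pl$threshold, stats = stats),
      class = "pnn"),
    case_graph = structure(
      list(emb = `colnames<-`(as.matrix(pl$emb), pl$emb_names),
           controls = `colnames<-`(as.matrix(pl$controls), pl$control_names),
           proc = pl$proc, step = pl$step, nn = as.matrix(pl$nn),
           succ = pl$succ, n_neighbors = pl$n_neighbors, stats = stats,
           which = pl$which, dist_count = pl$dist_count,
           process_ids = pl$process_ids),
      class = "case_graph"),
    stop("unknown model kind in archive: ", obj$kind))
}
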