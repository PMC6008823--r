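# Small deterministic fixtures shared across the suite. Everything is built
# in code; nothing is read from disk.

tiny_glossary <- function(nc = 3, nm = 1) {
  control_glossary(
    sprintf("c%02d", seq_len(nc)),
    category = "drug",
    monitored_ids = if (nm > 0) sprintf("m%02d", seq_len(nm)) else character())
}

# hand-built two-process bank on a 3-control glossary
tiny_bank <- function() {
  gl <- tiny_glossary(3, 1)
  p1 <- dtp_process("p1", "X01",
                    controls = rbind(c(0, 0, 0), c(1, 0, 0), c(2, 1, 0)),
                    monitored = cbind(c(1, 2, 3)), glossary = gl)
  p2 <- dtp_process("p2", "X01",
                    controls = rbind(c(0, 1, 0), c(0, 2, 2), c(0, 2, 4),
                                     c(1, 2, 4)),
                    monitored = cbind(c(1, 2, NA, 4)), glossary = gl)
  process_bank(gl, list(p1, p2))
}

# protocol template with two controls, no branches, fully deterministic
flat_template <- function() {
  gl <- tiny_glossary(2, 1)
  nosology_template(
    "X02", gl,
    rules = list(protocol_rule("c01", 0, 9, daily_amount = 1),
                 protocol_rule("c02", 2, 4, daily_amount = 2)),
    length_base = 6, length_scale = 0, length_noise = 0, length_min = 2,
    monitored_models = list(m01 = list(type = "counter")))
}

pneumonia_bank <- function(n = 30, seed = 1, ...) {
  generate_bank(generator_config(default_template("pneumonia_like"),
                                 n_processes = n,
                                 noise = noise_profile(...), seed = seed))
}

# brute-force nearest neighbour oracle, independent of the graph machinery
brute_nn <- function(emb, query) {
  d <- sqrt(rowSums(sweep(emb, 2L, query)^2))
  ord <- order(d, seq_len(nrow(emb)))
  list(node = ord[1L], distance = d[ord[1L]])
}
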