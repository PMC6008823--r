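#' Protocol rule for the synthetic generator
#'
#' One line of a synthetic treatment protocol: a control prescribed daily at
#' a fixed amount over an inclusive day window, optionally gated on the
#' patient's latent severity so that different severity strata follow
#' different protocol branches.
#'
#' @param control_id Control the rule prescribes.
#' @param start_day,end_day Inclusive 0-based day window; `start <= end`.
#' @param daily_amount Positive amount added to the cumulative control per
#'   firing day (dose units or counts).
#' @param adherence_prob Probability in `[0,1]` that the rule fires on an
#'   active day (default 1).
#' @param severity_gate Optional numeric length-2 interval in `[0,1]`; the
#'   rule is active only for latent severity inside `[lo, hi)` (the upper
#'   bound is closed at 1 so the top stratum is reachable).
#' @return A `protocol_rule` list.
#' @export
protocol_rule <- function(control_id, start_day, end_day, daily_amount,
                          adherence_prob = 1, severity_gate = NULL) {
  stopifnot(start_day <= end_day, daily_amount > 0,
            adherence_prob >= 0, adherence_prob <= 1)
  if (!is.null(severity_gate)) {
    stopifnot(length(severity_gate) == 2L, severity_gate[1] <= severity_gate[2])
  }
  structure(
    list(control_id = as.character(control_id),
         start_day = as.integer(start_day), end_day = as.integer(end_day),
         daily_amount = daily_amount, adherence_prob = adherence_prob,
         severity_gate = severity_gate),
    class = "protocol_rule"
  )
}

#' Nosology template for the synthetic generator
#'
#' Describes one synthetic disease entity: its glossary, protocol rules,
#' length-of-stay model and monitored-property models. Process length is
#' `base + round(severity * scale) +/- noise`, floored at `min_length`.
#' Monitored models are per-property lists with a `type`:
#' `"counter"` (deterministic inpatient-day counter, value `step + 1`) or
#' `"recovery"` (`baseline + effect * severity * exp(-rate * step)` plus
#' Gaussian observation noise `noise_sd`, missing with `missing_prob`).
#'
#' @param nosology_code Disease code for generated processes.
#' @param glossary [control_glossary()] the rules refer to.
#' @param rules List of [protocol_rule()]s.
#' @param length_base,length_scale,length_noise,length_min Length-of-stay
#'   model parameters (days); `length_noise` is the half-width of a uniform
#'   integer jitter.
#' @param monitored_models Named list (by monitored id) of model lists.
#' @return A `nosology_template`.
#' @export
nosology_template <- function(nosology_code, glossary, rules,
                              length_base = 8, length_scale = 4,
                              length_noise = 1, length_min = 2,
                              monitored_models = list()) {
  stopifnot(inherits(glossary, "dtp_glossary"), length_min >= 2)
  rule_ids <- vapply(rules, function(r) r$control_id, character(1))
  unknown <- setdiff(rule_ids, glossary$control_ids)
  if (length(unknown) > 0L) {
    stop("rules reference controls absent from glossary: ",
         paste(unique(unknown), collapse = ", "))
  }
  unknown_m <- setdiff(names(monitored_models), glossary$monitored_ids)
  if (length(unknown_m) > 0L) {
    stop("monitored models for unknown properties: ",
         paste(unknown_m, collapse = ", "))
  }
  structure(
    list(nosology_code = nosology_code, glossary = glossary, rules = rules,
         length_base = length_base, length_scale = length_scale,
         length_noise = length_noise, length_min = length_min,
         monitored_models = monitored_models),
    class = "nosology_template"
  )
}

#' Noise profile for synthetic generation
#'
#' @param omit_prob Probability a scheduled prescription is omitted.
#' @param spurious_prob Probability a step gains one unit of a uniformly
#'   random control that was not scheduled by protocol.
#' @param missing_prob Extra probability a monitored observation is missing
#'   (combined with the template's per-property probability as
#'   `1 - (1-a)(1-b)`).
#' @param dose_jitter_sd Log-normal sd of multiplicative jitter on daily
#'   amounts (0 = exact protocol doses).
#' @return A `noise_profile` list.
#' @export
noise_profile <- function(omit_prob = 0, spurious_prob = 0, missing_prob = 0,
                          dose_jitter_sd = 0) {
  stopifnot(omit_prob >= 0, omit_prob <= 1, spurious_prob >= 0,
            spurious_prob <= 1, missing_prob >= 0, missing_prob <= 1,
            dose_jitter_sd >= 0)
  structure(list(omit_prob = omit_prob, spurious_prob = spurious_prob,
                 missing_prob = missing_prob, dose_jitter_sd = dose_jitter_sd),
            class = "noise_profile")
}

#' Generator configuration
#'
#' @param template A [nosology_template()].
#' @param n_processes Number of processes to generate (>= 1).
#' @param noise A [noise_profile()] (or arguments forwarded to it via `...`).
#' @param seed Integer seed; the bank is byte-identical for equal seeds.
#' @param ... Passed to [noise_profile()] when `noise` is `NULL`.
#' @return A `generator_config`.
#' @export
generator_config <- function(template, n_processes, noise = NULL, seed = 1L, ...) {
  stopifnot(inherits(template, "nosology_template"), n_processes >= 1)
  if (is.null(noise)) noise <- noise_profile(...)
  structure(list(template = template, n_processes = as.integer(n_processes),
                 noise = noise, seed = as.integer(seed)),
            class = "generator_config")
}

# gate is [lo, hi), closed at the top when hi >= 1 so severity = 1 is covered
severity_branch_active <- function(rule, severity) {
  g <- rule$severity_gate
  if (is.null(g)) return(TRUE)
  severity >= g[1] && (severity < g[2] || g[2] >= 1)
}

# Active rule indices at a given day for a given severity (protocol truth,
# before adherence/omission noise). Used by the generator and by tests as
# the exact-recovery oracle.
#' Scheduled controls for a template step
#'
#' The protocol truth: which rules are active (and what the scheduled delta
#' is) at a given day for a given latent severity, before any noise.
#'
#' @param template A [nosology_template()].
#' @param day 0-based day.
#' @param severity Latent severity in `[0,1]`.
#' @return Named numeric vector of scheduled per-day amounts over all
#'   controls (zeros where nothing is scheduled).
#' @export
scheduled_deltas <- function(template, day, severity) {
  gl <- template$glossary
  d <- stats::setNames(numeric(length(gl$control_ids)), gl$control_ids)
  for (r in template$rules) {
    if (day >= r$start_day && day <= r$end_day &&
        severity_branch_active(r, severity)) {
      d[r$control_id] <- d[r$control_id] + r$daily_amount
    }
  }
  d
}

#' Generate one synthetic process
#'
#' Draws a latent severity ~ Uniform(0,1), a length of stay from the
#' template's length model, then simulates the day-by-day protocol: each
#' active rule fires with probability `adherence_prob * (1 - omit_prob)`,
#' adding its (jittered) daily amount to the cumulative control; with
#' probability `spurious_prob` a step also gains one unit of a uniformly
#' random control. Monitored trajectories follow the template's models with
#' observation noise and missingness. The result always passes
#' [validate_process()].
#'
#' @param template A [nosology_template()].
#' @param noise A [noise_profile()].
#' @param process_id Identifier for the generated process.
#' @param seed Optional integer seed applied before drawing (the bank
#'   generator passes per-process sub-seeds).
#' @return A [dtp_process()] with attributes `severity` and `length`.
#' @export
generate_process <- function(template, noise = noise_profile(),
                             process_id = "synthetic-1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gl <- template$glossary
  severity <- stats::runif(1)
  len <- template$length_base + round(severity * template$length_scale)
  if (template$length_noise > 0) {
    len <- len + sample.int(2L * template$length_noise + 1L, 1L) -
      template$length_noise - 1L
  }
  len <- max(template$length_min, len)
  nc <- length(gl$control_ids)
  inc <- matrix(0, nrow = len, ncol = nc, dimnames = list(NULL, gl$control_ids))
  for (t in seq_len(len) - 1L) {
    for (r in template$rules) {
      if (t >= r$start_day && t <= r$end_day &&
          severity_branch_active(r, severity)) {
        p_fire <- r$adherence_prob * (1 - noise$omit_prob)
        if (p_fire >= 1 || stats::runif(1) < p_fire) {
          amt <- r$daily_amount
          if (noise$dose_jitter_sd > 0) {
            amt <- amt * stats::rlnorm(1, 0, noise$dose_jitter_sd)
          }
          inc[t + 1L, r$control_id] <- inc[t + 1L, r$control_id] + amt
        }
      }
    }
    if (noise$spurious_prob > 0 && stats::runif(1) < noise$spurious_prob) {
      j <- sample.int(nc, 1L)
      inc[t + 1L, j] <- inc[t + 1L, j] + 1
    }
  }
  controls <- apply(inc, 2L, cumsum)
  if (len == 1L) controls <- matrix(controls, nrow = 1L,
                                    dimnames = list(NULL, gl$control_ids))
  nm <- length(gl$monitored_ids)
  monitored <- matrix(NA_real_, nrow = len, ncol = nm,
                      dimnames = list(NULL, gl$monitored_ids))
  for (id in gl$monitored_ids) {
    m <- template$monitored_models[[id]]
    if (is.null(m)) m <- list(type = "counter")
    if (identical(m$type, "counter")) {
      monitored[, id] <- seq_len(len)
    } else {
      t0 <- seq_len(len) - 1L
      val <- m$baseline + m$severity_effect * severity * exp(-m$recovery_rate * t0)
      if (!is.null(m$noise_sd) && m$noise_sd > 0) {
        val <- val + stats::rnorm(len, 0, m$noise_sd)
      }
      p_miss <- 1 - (1 - (m$missing_prob %||% 0)) * (1 - noise$missing_prob)
      if (p_miss > 0) {
        val[stats::runif(len) < p_miss] <- NA_real_
      }
      monitored[, id] <- val
    }
  }
  p <- dtp_process(process_id, template$nosology_code, controls, monitored,
                   gl, validate = FALSE)
  attr(p, "severity") <- severity
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic process bank
#'
#' Draws `n_processes` independent processes from the template. One master
#' seed drives the whole bank; each process gets a sub-seed drawn up front,
#' so generation is order-independent and the serialized bank is
#' byte-identical for equal seeds.
#'
#' @param config A [generator_config()].
#' @return A [process_bank()] with a provenance tag recording the config.
#' @export
generate_bank <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_processes
  if (n < 1L) stop("n_processes must be >= 1")
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, n)
  procs <- vector("list", n)
  for (i in seq_len(n)) {
    procs[[i]] <- generate_process(
      config$template, config$noise,
      process_id = sprintf("%s-%04d", config$template$nosology_code, i),
      seed = sub_seeds[i])
  }
  nz <- config$noise
  tag <- sprintf(
    "synthetic:%s:n=%d:seed=%d:omit=%g:spurious=%g:missing=%g:jitter=%g",
    config$template$nosology_code, n, config$seed, nz$omit_prob,
    nz$spurious_prob, nz$missing_prob, nz$dose_jitter_sd)
  process_bank(config$template$glossary, procs,
               nosology = config$template$nosology_code,
               provenance = tag, validate = FALSE)
}

#' Packaged nosology templates
#'
#' Deterministic fixtures for testing and demonstration. `"pneumonia_like"`
#' models an inpatient pneumonia-style episode: 60 controls (30 drugs, 20
#' lab tests, 10 procedures), an inpatient-day counter plus two recovery
#' markers (temperature, CRP) as monitored properties, a common protocol
#' backbone and three severity-gated branches (mild / moderate / severe),
#' and a length of stay averaging about ten days.
#'
#' @param name Template name; currently `"pneumonia_like"`.
#' @return A [nosology_template()]; identical on every call.
#' @export
default_template <- function(name = "pneumonia_like") {
  if (!identical(name, "pneumonia_like")) {
    stop("unknown template '", name, "'; available: pneumonia_like")
  }
  drugs <- sprintf("drug%02d", 1:30)
  labs <- sprintf("lab%02d", 1:20)
  procs <- sprintf("proc%02d", 1:10)
  gl <- control_glossary(
    c(drugs, labs, procs),
    category = stats::setNames(
      c(rep("drug", 30), rep("lab_test", 20), rep("procedure", 10)),
      c(drugs, labs, procs)),
    monitored_ids = c("inpatient_days", "temperature", "crp"))
  rules <- list()
  add <- function(r) rules[[length(rules) + 1L]] <<- r
  # backbone: daily antibiotics + supportive drugs for everyone
  for (i in 1:6) add(protocol_rule(drugs[i], 0, 14, daily_amount = 2))
  add(protocol_rule(drugs[7], 0, 4, daily_amount = 1))
  add(protocol_rule(drugs[8], 2, 9, daily_amount = 1.5))
  # admission work-up and periodic monitoring labs
  for (i in 1:4) add(protocol_rule(labs[i], 0, 0, daily_amount = 1))
  add(protocol_rule(labs[5], 0, 14, daily_amount = 1))
  add(protocol_rule(labs[6], 3, 3, daily_amount = 1))
  add(protocol_rule(labs[7], 6, 6, daily_amount = 1))
  add(protocol_rule(procs[1], 0, 0, daily_amount = 1))
  # mild branch: severity in [0, 1/3)
  for (i in 9:12) add(protocol_rule(drugs[i], 0, 5, daily_amount = 1,
                                    severity_gate = c(0, 1 / 3)))
  add(protocol_rule(labs[8], 2, 2, daily_amount = 1, severity_gate = c(0, 1 / 3)))
  # moderate branch: [1/3, 2/3)
  for (i in 13:18) add(protocol_rule(drugs[i], 0, 8, daily_amount = 1.5,
                                     severity_gate = c(1 / 3, 2 / 3)))
  add(protocol_rule(labs[9], 1, 7, daily_amount = 1,
                    severity_gate = c(1 / 3, 2 / 3)))
  add(protocol_rule(procs[2], 1, 2, daily_amount = 1,
                    severity_gate = c(1 / 3, 2 / 3)))
  # severe branch: [2/3, 1]
  for (i in 19:26) add(protocol_rule(drugs[i], 0, 14, daily_amount = 2,
                                     severity_gate = c(2 / 3, 1)))
  add(protocol_rule(labs[10], 0, 14, daily_amount = 1,
                    severity_gate = c(2 / 3, 1)))
  add(protocol_rule(procs[3], 0, 3, daily_amount = 1,
                    severity_gate = c(2 / 3, 1)))
  add(protocol_rule(procs[4], 2, 2, daily_amount = 1,
                    severity_gate = c(2 / 3, 1)))
  nosology_template(
    "J13-like", gl, rules,
    length_base = 8, length_scale = 4, length_noise = 1, length_min = 2,
    monitored_models = list(
      inpatient_days = list(type = "counter"),
      temperature = list(type = "recovery", baseline = 36.6,
                         severity_effect = 2.5, recovery_rate = 0.35,
                         noise_sd = 0.15, missing_prob = 0),
      crp = list(type = "recovery", baseline = 5, severity_effect = 90,
                 recovery_rate = 0.25, noise_sd = 4, missing_prob = 0)))
}
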