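.event_kinds <- c("cue", "feedback_tone", "reward", "decision",
                  "option_presented", "selection", "transcript_change",
                  "block_start", "block_end", "gate_result")

#' A timestamped session event
#'
#' @param t Seconds since session (or trial) start.
#' @param kind One of the closed event vocabulary: cue, feedback_tone, reward,
#'   decision, option_presented, selection, transcript_change, block_start,
#'   block_end, gate_result.
#' @param ... Kind-specific payload key-values.
#' @return An object of class `session_event`.
#' @export
session_event <- function(t, kind, ...) {
  if (!kind %in% .event_kinds)
    stop("unknown event kind: ", kind)
  structure(list(t = as.numeric(t), kind = kind, payload = list(...)),
            class = "session_event")
}

#' @export
print.session_event <- function(x, ...) {
  pl <- if (length(x$payload))
    paste(names(x$payload),
          vapply(x$payload, function(v) paste(format(v), collapse = ","),
                 character(1)),
          sep = "=", collapse = " ") else ""
  cat(sprintf("[%9.3f] %-17s %s\n", x$t, x$kind, pl))
  invisible(x)
}

#' Write / read a JSONL session event log
#'
#' One JSON object per line; the round trip through write and read is
#' lossless, and unknown payload keys are preserved as-is.
#'
#' @param events List of [session_event()] objects.
#' @param path File path of the log.
#' @return `write_event_log` returns `path` invisibly; `read_event_log`
#'   returns the list of events.
#' @export
write_event_log <- function(events, path) {
  lines <- vapply(events, function(ev) {
    stopifnot(inherits(ev, "session_event"))
    jsonlite::toJSON(unclass(ev), auto_unbox = TRUE, digits = NA,
                     null = "null", na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  last_t <- -Inf
  for (i in seq_along(lines)) {
    ev <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                   error = function(e)
                     stop("malformed event log at line ", i, ": ",
                          conditionMessage(e), call. = FALSE))
    if (is.null(ev$t) || is.null(ev$kind))
      stop("malformed event log at line ", i, ": missing t or kind",
           call. = FALSE)
    ev$t <- as.numeric(ev$t)
    if (is.null(ev$payload)) ev$payload <- list()
    class(ev) <- "session_event"
    out[[i]] <- ev
  }
  out
}

# Pull events of one kind out of a log.
events_of_kind <- function(events, kind) {
  Filter(function(e) identical(e$kind, kind), events)
}

#' Collect the event log of a feedback block
#'
#' Flattens per-trial events into one session-relative log bracketed by
#' block_start/block_end, with trial-relative times offset by each trial's
#' start (cue onset at the trial start plus the cue duration offset).
#'
#' @param block A `block_record`.
#' @param t0 Session time of the block start (default 0).
#' @param gate Optionally append a `gate_result` event with this criterion
#'   (set `NULL` to skip, default).
#' @return A list of [session_event()]s.
#' @export
block_event_log <- function(block, t0 = 0, gate = NULL) {
  stopifnot(inherits(block, "block_record"))
  events <- list(session_event(t0, "block_start", paradigm = block$paradigm,
                               n_trials = block$n_trials,
                               seed = block$seed %||% NA))
  t_cursor <- t0
  for (tr in block$trials) {
    cue_dur <- -tr$events[[1]]$t
    for (ev in tr$events) {
      ev$t <- ev$t + t_cursor + cue_dur
      events <- c(events, list(ev))
    }
    t_cursor <- t_cursor + cue_dur + tr$latency
  }
  events <- c(events, list(session_event(t_cursor, "block_end",
                                         accuracy = block$accuracy)))
  if (!is.null(gate))
    events <- c(events, list(session_event(t_cursor, "gate_result",
                                           criterion = gate,
                                           passed = gate_speller(block, gate))))
  events
}

#' Replay a session from its event log
#'
#' Reconstructs what was computed live: feedback trials (and their block
#' accuracy) from `decision` events, and the speller transcript by re-applying
#' the logged `selection` events. A log that ends inside an open block, or a
#' speller log without a terminal end-program selection, is flagged truncated.
#'
#' @param log A list of [session_event()]s or a path to a JSONL log.
#' @param config Optional [session_config()]; when given, its
#'   `schema_version` must match the package's.
#' @return A list of class `session_replay` with elements `trials`,
#'   `accuracy`, `table` (when decisions are present), `transcript`,
#'   `selections` (when selections are present), and `truncated`.
#' @export
replay_session <- function(log, config = NULL) {
  if (is.character(log)) log <- read_event_log(log)
  if (!is.null(config)) {
    stopifnot(inherits(config, "session_config"))
    if (!identical(config$schema_version, .schema_version))
      stop("config schema_version mismatch: log replay requires version ",
           .schema_version)
  }
  out <- list(truncated = FALSE)
  n_open <- length(events_of_kind(log, "block_start")) -
    length(events_of_kind(log, "block_end"))
  decisions <- events_of_kind(log, "decision")
  fb <- Filter(function(e) !is.null(e$payload$target), decisions)
  if (length(fb)) {
    trials <- lapply(fb, function(e) {
      structure(list(target = e$payload$target, outcome = e$payload$outcome,
                     correct = (e$payload$target == "up" &
                                  e$payload$outcome == "yes") ||
                       (e$payload$target == "down" &
                          e$payload$outcome == "no"),
                     latency = e$payload$latency %||% NA_real_),
                class = "trial_record")
    })
    acc <- block_accuracy(trials)
    out$trials <- trials
    out$accuracy <- acc$accuracy
    out$table <- acc$table
    if (n_open > 0) out$truncated <- TRUE
  }
  selections <- events_of_kind(log, "selection")
  if (length(selections) || length(events_of_kind(log, "option_presented"))) {
    transcript <- ""
    ended <- FALSE
    opts <- character(0)
    for (e in selections) {
      op <- e$payload$option
      opts <- c(opts, op)
      st <- structure(list(transcript = transcript, ended = FALSE),
                      class = "speller_state")
      st <- apply_speller_option(st, op)
      transcript <- st$transcript
      ended <- ended || st$ended
    }
    out$transcript <- transcript
    out$selections <- opts
    if (!ended) out$truncated <- TRUE
  }
  structure(out, class = "session_replay")
}

#' @export
print.session_replay <- function(x, ...) {
  cat("<session_replay>")
  if (x$truncated) cat(" [truncated log]")
  cat("\n")
  if (!is.null(x$accuracy))
    cat(sprintf("  %d feedback trials, accuracy %.1f%%\n", length(x$trials),
                100 * x$accuracy))
  if (!is.null(x$transcript))
    cat(sprintf("  %d selections, transcript: \"%s\"\n",
                length(x$selections), x$transcript))
  invisible(x)
}

.schema_version <- "1.0"

#' Assemble, validate, write and read a session configuration
#'
#' A session configuration gathers every parameter needed to rerun a session:
#' acquisition settings, mixer (channel selection and normalization), feedback
#' and decision thresholds, reward, speller menu, simulator truth, and the
#' seed. Serializes to JSON or YAML.
#'
#' @param acquisition An [acq_config()].
#' @param mixer A [mixer_config()] or `NULL`.
#' @param feedback A [feedback_config()].
#' @param decision A [decision_config()].
#' @param reward A [reward_config()] or `NULL`.
#' @param speller A [build_speller_menu()] result or `NULL`.
#' @param simulator Free-form list of simulator settings or `NULL`.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `session_config`.
#' @export
session_config <- function(acquisition = acq_config(), mixer = NULL,
                           feedback = feedback_config(),
                           decision = decision_config(), reward = NULL,
                           speller = NULL, simulator = NULL, seed = NULL) {
  cfg <- structure(list(schema_version = .schema_version, seed = seed,
                        acquisition = acquisition, mixer = mixer,
                        feedback = feedback, decision = decision,
                        reward = reward, speller = speller,
                        simulator = simulator), class = "session_config")
  validate_session_config(cfg)
  cfg
}

#' @rdname session_config
#' @param cfg A `session_config`.
#' @export
validate_session_config <- function(cfg) {
  if (!identical(cfg$schema_version, .schema_version))
    stop("unsupported schema_version: ", cfg$schema_version)
  stopifnot(inherits(cfg$acquisition, "acq_config"),
            inherits(cfg$feedback, "feedback_config"),
            inherits(cfg$decision, "decision_config"))
  if (!is.null(cfg$mixer)) stopifnot(inherits(cfg$mixer, "mixer_config"))
  if (!is.null(cfg$reward)) stopifnot(inherits(cfg$reward, "reward_config"))
  if (!is.null(cfg$speller)) stopifnot(inherits(cfg$speller, "speller_menu"))
  if (!is.null(cfg$seed)) stopifnot(is.numeric(cfg$seed))
  invisible(cfg)
}

config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    if (inherits(x, "speller_menu")) return(menu_to_list(x))
    if (inherits(x, "mixer_config"))
      return(list(channels = lapply(x$channels, unclass)))
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  list(schema_version = cfg$schema_version, seed = cfg$seed,
       acquisition = strip(cfg$acquisition), mixer = strip(cfg$mixer),
       feedback = strip(cfg$feedback), decision = strip(cfg$decision),
       reward = strip(cfg$reward), speller = strip(cfg$speller),
       simulator = strip(cfg$simulator))
}

config_from_list <- function(x) {
  build <- function(section, fn) {
    if (is.null(x[[section]])) return(NULL)
    do.call(fn, x[[section]])
  }
  mixer <- if (!is.null(x$mixer))
    mixer_config(lapply(x$mixer$channels, function(ch)
      channel_params(ch$channel_id, ch$a, ch$b, ch$c)))
  session_config(
    acquisition = do.call(acq_config, x$acquisition),
    mixer = mixer,
    feedback = do.call(feedback_config, x$feedback),
    decision = do.call(decision_config, x$decision),
    reward = build("reward", reward_config),
    speller = if (!is.null(x$speller)) menu_from_list(x$speller),
    simulator = x$simulator,
    seed = x$seed)
}

#' @rdname session_config
#' @param path File path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @export
write_session_config <- function(cfg, path) {
  validate_session_config(cfg)
  lst <- config_to_list(cfg)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    writeLines(jsonlite::toJSON(lst, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE), path)
  }
  invisible(path)
}

#' @rdname session_config
#' @export
read_session_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE,
                       simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  config_from_list(lst)
}
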