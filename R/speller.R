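# Relative letter frequencies in written German (percent), descending.
# Umlauts are transcribed as digraphs (ae, oe, ue) and ess-zett as ss, so the
# menu needs only the 26 base letters.
.de_letter_freq <- c(
  e = 17.40, n = 9.78, i = 7.55, s = 7.27, r = 7.00, a = 6.51, t = 6.15,
  d = 5.08, h = 4.76, u = 4.35, l = 3.44, c = 3.06, g = 3.01, m = 2.53,
  o = 2.51, b = 1.89, w = 1.89, f = 1.66, k = 1.21, z = 1.13, p = 0.79,
  v = 0.67, j = 0.27, y = 0.04, x = 0.03, q = 0.02)

#' German letter frequencies used to order the speller menu
#'
#' @return Named numeric vector of percent frequencies, descending.
#' @export
german_letter_frequencies <- function() .de_letter_freq

.speller_actions <- c("space", "delete", "question_mark", "end_program")

#' Build the group-scanning speller menu
#'
#' Letters are ordered by descending frequency in written German, so the most
#' likely selections are reached with the fewest scanning steps, and
#' partitioned into groups; the four actions (space, delete, question mark,
#' end program) form a trailing group. The default menu has 30 options.
#'
#' @param group_sizes Sizes of the letter groups (default `c(6, 6, 6, 6, 2)`);
#'   must sum to the number of letters.
#' @param letters Letter inventory in presentation order (default: 26 letters
#'   by descending German frequency).
#' @param actions Action options appended as the final group.
#' @return An object of class `speller_menu` with fields `groups` (list of
#'   character vectors), `actions`, and `n_options`.
#' @export
#' @examples
#' menu <- build_speller_menu()
#' menu$n_options       # 30
#' menu$groups[[1]][1]  # "e"
build_speller_menu <- function(group_sizes = c(6, 6, 6, 6, 2),
                               letters = names(german_letter_frequencies()),
                               actions = c("space", "delete", "question_mark",
                                           "end_program")) {
  if (sum(group_sizes) != length(letters))
    stop("group_sizes must sum to the number of letters")
  if (any(group_sizes < 1)) stop("group sizes must be positive")
  groups <- split(letters, rep(seq_along(group_sizes), group_sizes))
  groups <- unname(lapply(groups, as.character))
  if (length(actions)) groups <- c(groups, list(as.character(actions)))
  all_opts <- unlist(groups)
  if (anyDuplicated(all_opts))
    stop("duplicate options in menu: ",
         paste(unique(all_opts[duplicated(all_opts)]), collapse = ", "))
  structure(list(groups = groups, actions = as.character(actions),
                 n_options = length(all_opts)), class = "speller_menu")
}

#' @export
print.speller_menu <- function(x, ...) {
  cat(sprintf("<speller_menu> %d options in %d groups\n", x$n_options,
              length(x$groups)))
  for (i in seq_along(x$groups))
    cat(sprintf("  group %d: %s\n", i, paste(x$groups[[i]], collapse = " ")))
  invisible(x)
}

#' Serialize / restore a speller menu
#'
#' @param menu A [build_speller_menu()] result.
#' @param x A plain list as produced by `menu_to_list` (e.g. read back from
#'   JSON/YAML config).
#' @return `menu_to_list`: a plain list safe to serialize; `menu_from_list`:
#'   the reconstructed `speller_menu`.
#' @export
menu_to_list <- function(menu) {
  stopifnot(inherits(menu, "speller_menu"))
  list(groups = menu$groups, actions = menu$actions)
}

#' @rdname menu_to_list
#' @export
menu_from_list <- function(x) {
  groups <- lapply(x$groups, function(g) as.character(unlist(g)))
  all_opts <- unlist(groups)
  if (anyDuplicated(all_opts)) stop("duplicate options in menu")
  structure(list(groups = groups,
                 actions = as.character(unlist(x$actions)),
                 n_options = length(all_opts)), class = "speller_menu")
}

#' Fresh speller state
#'
#' @return An object of class `speller_state`: scanning starts at the first
#'   group with an empty transcript.
#' @export
speller_state <- function() {
  structure(list(phase = "scanning_groups", group_index = 1L,
                 option_index = 1L, transcript = "", ended = FALSE,
                 group_cycles = 0L, option_cycles = 0L, n_decisions = 0L,
                 n_timeouts = 0L, emitted = NULL, forced_timeout = FALSE,
                 selections = list()), class = "speller_state")
}

#' @export
print.speller_state <- function(x, ...) {
  cat(sprintf("<speller_state> %s (group %d, option %d)%s\n", x$phase,
              x$group_index, x$option_index, if (x$ended) " [ended]" else ""))
  cat(sprintf("  transcript: \"%s\"\n", x$transcript))
  invisible(x)
}

apply_speller_option <- function(state, option) {
  if (option %in% .speller_actions) {
    switch(option,
      space = { state$transcript <- paste0(state$transcript, " ") },
      question_mark = { state$transcript <- paste0(state$transcript, "?") },
      delete = {
        n <- nchar(state$transcript)
        if (n > 0) state$transcript <- substr(state$transcript, 1, n - 1)
      },
      end_program = { state$ended <- TRUE })
  } else {
    state$transcript <- paste0(state$transcript, option)
  }
  state
}

#' Advance the speller state machine by one yes/no decision
#'
#' While scanning groups, "yes" descends into the current group and "no"
#' advances to the next group (wrapping after the last). While scanning the
#' options of a group, "yes" selects the current option -- appending a letter,
#' a space or "?", deleting the last character, or ending the program -- and
#' "no" advances to the next option. A timeout is logged and then advances
#' like "no". When scanning has wrapped `max_cycles` times without a "yes",
#' the selection is abandoned (forced timeout) and scanning restarts at the
#' first group.
#'
#' @param state A [speller_state()]; must not be ended.
#' @param decision `"yes"`, `"no"`, or `"timeout"`.
#' @param menu A [build_speller_menu()] result.
#' @param max_cycles Scan cycles allowed per selection (default 3).
#' @return The updated `speller_state`; after a selection, `$emitted` holds
#'   the selected option and `$selections` gains a record with the decision
#'   count it took.
#' @export
step_speller <- function(state, decision, menu, max_cycles = 3) {
  stopifnot(inherits(state, "speller_state"), inherits(menu, "speller_menu"))
  if (state$ended) stop("cannot step an ended speller state")
  if (!decision %in% c("yes", "no", "timeout"))
    stop("decision must be yes, no, or timeout")
  state$emitted <- NULL
  state$forced_timeout <- FALSE
  state$n_decisions <- state$n_decisions + 1L
  if (decision == "timeout") {
    state$n_timeouts <- state$n_timeouts + 1L
    decision <- "no"
  }
  reset_scan <- function(s) {
    s$phase <- "scanning_groups"; s$group_index <- 1L; s$option_index <- 1L
    s$group_cycles <- 0L; s$option_cycles <- 0L; s$n_decisions <- 0L
    s
  }
  if (state$phase == "scanning_groups") {
    if (decision == "yes") {
      state$phase <- "scanning_options"
      state$option_index <- 1L
      state$option_cycles <- 0L
    } else {
      state$group_index <- state$group_index + 1L
      if (state$group_index > length(menu$groups)) {
        state$group_index <- 1L
        state$group_cycles <- state$group_cycles + 1L
        if (state$group_cycles >= max_cycles) {
          state$forced_timeout <- TRUE
          state <- reset_scan(state)
        }
      }
    }
  } else {  # scanning_options
    opts <- menu$groups[[state$group_index]]
    if (decision == "yes") {
      option <- opts[state$option_index]
      n_dec <- state$n_decisions
      state <- apply_speller_option(state, option)
      state$selections <- c(state$selections,
                            list(list(option = option, n_decisions = n_dec)))
      state <- reset_scan(state)
      state$emitted <- option
    } else {
      state$option_index <- state$option_index + 1L
      if (state$option_index > length(opts)) {
        state$option_index <- 1L
        state$option_cycles <- state$option_cycles + 1L
        if (state$option_cycles >= max_cycles) {
          state$forced_timeout <- TRUE
          state <- reset_scan(state)
        }
      }
    }
  }
  state
}

#' Locate an option and enumerate the decisions that select it
#'
#' @param menu A [build_speller_menu()] result.
#' @param option A letter or action name present in the menu.
#' @return `selection_path`: the character vector of yes/no decisions that
#'   selects `option` from a fresh state; `selection_cost`: its length, i.e.
#'   (group scan steps) + (within-group steps) + 2.
#' @export
selection_path <- function(menu, option) {
  stopifnot(inherits(menu, "speller_menu"))
  for (g in seq_along(menu$groups)) {
    k <- match(option, menu$groups[[g]])
    if (!is.na(k))
      return(c(rep("no", g - 1), "yes", rep("no", k - 1), "yes"))
  }
  stop("option not in menu: ", option)
}

#' @rdname selection_path
#' @export
selection_cost <- function(menu, option) length(selection_path(menu, option))

#' Run a speller session against a decision source
#'
#' Loops presentation -> decision -> state update until the end-program action
#' is selected or a limit is hit. The decision source stands for the whole
#' yes/no pipeline (or a scripted agent): it is called with the presented item
#' and the current state and must return `"yes"`, `"no"`, or `"timeout"`
#' (`NULL` ends the session as truncated).
#'
#' @param decision_source Function `(presented, state) -> decision`. The
#'   `presented` argument is a list with `phase`, `group_index`, `options`
#'   (the scanned group's options) and, in the option phase, `option`.
#' @param menu A [build_speller_menu()] result.
#' @param max_selections,max_decisions,max_time Session limits (defaults 100
#'   selections, 2000 decisions, unlimited time in seconds).
#' @param decision_duration Seconds charged per presentation + decision
#'   (default 5: spoken prompt plus response period).
#' @param max_cycles Scan-cycle limit per selection (default 3).
#' @return An object of class `speller_session` with the transcript, a
#'   selections data frame (`option`, `n_decisions`, `t`), the event log,
#'   `duration` (s), `n_decisions`, and flags `ended`/`truncated`.
#' @export
run_speller_session <- function(decision_source, menu = build_speller_menu(),
                                max_selections = 100, max_decisions = 2000,
                                max_time = Inf, decision_duration = 5,
                                max_cycles = 3) {
  state <- speller_state()
  events <- list()
  selections <- list()
  elapsed <- 0
  n_decisions <- 0L
  truncated <- FALSE
  while (!state$ended && length(selections) < max_selections &&
         n_decisions < max_decisions && elapsed < max_time) {
    presented <- list(phase = state$phase, group_index = state$group_index,
                      options = menu$groups[[state$group_index]])
    if (state$phase == "scanning_options")
      presented$option <- presented$options[state$option_index]
    events <- c(events, list(session_event(elapsed, "option_presented",
      phase = presented$phase, group_index = presented$group_index,
      option = presented$option %||% NA)))
    d <- decision_source(presented, state)
    if (is.null(d)) { truncated <- TRUE; break }
    elapsed <- elapsed + decision_duration
    n_decisions <- n_decisions + 1L
    events <- c(events, list(session_event(elapsed, "decision", outcome = d)))
    state <- step_speller(state, d, menu, max_cycles = max_cycles)
    if (!is.null(state$emitted)) {
      sel <- state$selections[[length(state$selections)]]
      sel$t <- elapsed
      selections <- c(selections, list(sel))
      events <- c(events, list(session_event(elapsed, "selection",
                                             option = sel$option,
                                             n_decisions = sel$n_decisions)))
      events <- c(events, list(session_event(elapsed, "transcript_change",
                                             transcript = state$transcript)))
    }
  }
  sel_df <- if (length(selections)) {
    data.frame(option = vapply(selections, `[[`, character(1), "option"),
               n_decisions = vapply(selections, function(s)
                 as.integer(s$n_decisions), integer(1)),
               t = vapply(selections, `[[`, numeric(1), "t"))
  } else {
    data.frame(option = character(0), n_decisions = integer(0), t = numeric(0))
  }
  structure(list(transcript = state$transcript, selections = sel_df,
                 events = events, duration = elapsed,
                 n_decisions = n_decisions, ended = state$ended,
                 truncated = truncated),
            class = "speller_session")
}

#' @export
print.speller_session <- function(x, ...) {
  cat(sprintf("<speller_session> %d selections, %d decisions, %.1f min%s%s\n",
              nrow(x$selections), x$n_decisions, x$duration / 60,
              if (x$ended) ", ended" else "",
              if (x$truncated) ", truncated" else ""))
  cat(sprintf("  transcript: \"%s\"\n", x$transcript))
  invisible(x)
}

#' @export
summary.speller_session <- function(object, ...) {
  print(object)
  nchars <- nchar(object$transcript)
  mins <- object$duration / 60
  if (mins > 0)
    cat(sprintf("  spelling rate: %.2f characters/min\n",
                spelling_rate(nchars, mins)))
  invisible(object)
}

#' Scripted decision source spelling a target text
#'
#' A deterministic (optionally noisy) stand-in for the patient: it answers
#' "yes" exactly when the presented group contains, or the presented option
#' is, the next character still needed to spell `text`; once the transcript
#' is long enough it selects end-program. Spaces map to the space action and
#' "?" to the question mark.
#'
#' @param text Target text (lowercase letters, spaces, "?").
#' @param menu The menu in use.
#' @param error_rate Probability of flipping a yes/no answer.
#' @param timeout_rate Probability of answering timeout instead.
#' @param seed Seed for the noise; `NULL` uses the current RNG stream.
#' @return A function suitable for [run_speller_session()].
#' @export
scripted_decision_source <- function(text, menu = build_speller_menu(),
                                     error_rate = 0, timeout_rate = 0,
                                     seed = NULL) {
  rng <- if (!is.null(seed)) {
    n_draws <- 0L
    function() with_seed(seed + (n_draws <<- n_draws + 1L), runif(2))
  } else {
    function() runif(2)
  }
  to_option <- function(ch) {
    if (ch == " ") "space" else if (ch == "?") "question_mark" else ch
  }
  function(presented, state) {
    pos <- nchar(state$transcript) + 1L
    target <- if (pos > nchar(text)) "end_program"
              else to_option(substr(text, pos, pos))
    want <- if (presented$phase == "scanning_groups") {
      if (target %in% presented$options) "yes" else "no"
    } else {
      if (identical(presented$option, target)) "yes" else "no"
    }
    u <- rng()
    if (u[1] < timeout_rate) return("timeout")
    if (u[2] < error_rate) want <- if (want == "yes") "no" else "yes"
    want
  }
}
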