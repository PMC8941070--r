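#' Five-cell contingency table for yes/no feedback trials
#'
#' Cell convention: `tp` up-target trials answered yes, `fp` up-target trials
#' answered no, `fn` down-target trials answered yes, `tn` down-target trials
#' answered no, plus unclassified (`timeout`) trials as their own cell.
#'
#' @param tp,fp,fn,tn,timeout Non-negative counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(tp = 0, fp = 0, fn = 0, tn = 0, timeout = 0) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn, timeout = timeout)
  if (any(cells < 0)) stop("cell counts must be non-negative")
  structure(as.list(cells), total = sum(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %d trials\n", attr(x, "total")))
  cat(sprintf("  TP (up->yes)   %6d    FP (up->no)    %6d\n", x$tp, x$fp))
  cat(sprintf("  FN (down->yes) %6d    TN (down->no)  %6d\n", x$fn, x$tn))
  cat(sprintf("  timeout        %6d\n", x$timeout))
  invisible(x)
}

#' Block accuracy and contingency table
#'
#' Accuracy is `(tp + tn) / total`, with timeouts in the denominator (an
#' unclassified trial counts as not correct).
#'
#' @param x A `block_record`, a list of `trial_record`s, or a
#'   [contingency_table()].
#' @return A list with `accuracy` (fraction) and `table`
#'   (a [contingency_table()]).
#' @export
#' @examples
#' ct <- contingency_table(tp = 2500, fp = 300, fn = 350, tn = 2436,
#'                         timeout = 114)
#' round(100 * block_accuracy(ct)$accuracy, 1)  # 86.6
block_accuracy <- function(x) {
  if (inherits(x, "contingency_table")) {
    total <- attr(x, "total")
    if (total < 1) stop("empty contingency table")
    return(list(accuracy = (x$tp + x$tn) / total, table = x))
  }
  if (inherits(x, "block_record")) x <- x$trials
  if (!length(x)) stop("empty block: need at least one trial")
  targets <- vapply(x, `[[`, character(1), "target")
  outcomes <- vapply(x, `[[`, character(1), "outcome")
  ct <- contingency_table(
    tp = sum(targets == "up" & outcomes == "yes"),
    fp = sum(targets == "up" & outcomes == "no"),
    fn = sum(targets == "down" & outcomes == "yes"),
    tn = sum(targets == "down" & outcomes == "no"),
    timeout = sum(outcomes == "timeout"))
  list(accuracy = (ct$tp + ct$tn) / attr(ct, "total"), table = ct)
}

#' Spelling rate in characters per minute
#'
#' @param characters Number of characters produced.
#' @param minutes Time spent spelling, in minutes (> 0).
#' @return Characters per minute.
#' @export
#' @examples
#' round(spelling_rate(5747, 5338), 2)  # 1.08
spelling_rate <- function(characters, minutes) {
  if (any(minutes <= 0)) stop("minutes must be positive")
  if (any(characters < 0)) stop("characters must be non-negative")
  characters / minutes
}

#' Wolpaw information transfer rate
#'
#' Bits per selection for an `N`-way speller with probability `P` of a correct
#' selection:
#' \deqn{B = \log_2 N + P \log_2 P + (1 - P) \log_2 \frac{1 - P}{N - 1}}
#' with the convention that the `(1 - P)` term vanishes at `P = 1`. Multiplied
#' by the number of selections and divided by the session duration this yields
#' bits per minute.
#'
#' @param P Probability of a correct selection, in `(0, 1]`.
#' @param N Number of possible selections (default 30: 26 letters plus space,
#'   delete, question mark and end-program).
#' @param selections Optional number of selections made.
#' @param duration Optional session duration in minutes.
#' @return A list with `bits_per_selection` and (when `selections` and
#'   `duration` are supplied) `bits_per_minute`.
#' @export
#' @examples
#' information_transfer_rate(1)$bits_per_selection    # log2(30) = 4.907
#' information_transfer_rate(0.9)$bits_per_selection  # 3.952
information_transfer_rate <- function(P, N = 30, selections = NULL,
                                      duration = NULL) {
  if (N < 2) stop("N must be at least 2")
  if (any(P <= 0 | P > 1)) stop("P must lie in (0, 1]")
  B <- log2(N) + ifelse(P == 1, 0,
                        P * log2(P) + (1 - P) * log2((1 - P) / (N - 1)))
  out <- list(bits_per_selection = B)
  if (!is.null(selections) && !is.null(duration)) {
    if (duration <= 0) stop("duration must be positive")
    out$bits_per_minute <- B * selections / duration
  }
  out
}
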