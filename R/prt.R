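#' Tally one PRT block into signal-detection counts
#'
#' @param trials data frame of trial records with `stimulus` ("rich"/"lean"),
#'   `correct` (logical) and `rewarded` (logical) columns.
#' @return named numeric vector with `rich_correct`, `rich_incorrect`,
#'   `lean_correct`, `lean_incorrect`, `rich_rewarded`, `lean_rewarded`.
#' @export
tally_block <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("stimulus", "correct", "rewarded") %in% names(trials)))
  bad <- !trials$stimulus %in% c("rich", "lean")
  if (any(bad)) {
    stop("unknown stimulus label(s): ",
         paste(unique(trials$stimulus[bad]), collapse = ", "))
  }
  rich <- trials$stimulus == "rich"
  c(rich_correct = sum(rich & trials$correct),
    rich_incorrect = sum(rich & !trials$correct),
    lean_correct = sum(!rich & trials$correct),
    lean_incorrect = sum(!rich & !trials$correct),
    rich_rewarded = sum(rich & trials$rewarded),
    lean_rewarded = sum(!rich & trials$rewarded))
}

#' Signal-detection response bias (log b)
#'
#' The standard PRT response-bias statistic,
#' `log b = 0.5 * log10( ((rich_correct + 0.5) * (lean_incorrect + 0.5)) /
#' ((rich_incorrect + 0.5) * (lean_correct + 0.5)) )`.
#' The 0.5 added to every cell is the usual correction that keeps the
#' statistic finite when a cell is empty.  Positive values indicate a
#' preference for the more richly rewarded stimulus.
#'
#' @param counts named vector as returned by [tally_block()] (only the four
#'   correct/incorrect cells are used).
#' @param base logarithm base (default 10, the task literature's convention).
#' @return response bias in log units of `base`.
#' @examples
#' response_bias(c(rich_correct = 35, rich_incorrect = 5,
#'                 lean_correct = 25, lean_incorrect = 15))
#' @export
response_bias <- function(counts, base = 10) {
  need <- c("rich_correct", "rich_incorrect", "lean_correct", "lean_incorrect")
  stopifnot(all(need %in% names(counts)), all(counts[need] >= 0))
  x <- as.numeric(counts[need]) + 0.5
  0.5 * log((x[1] * x[4]) / (x[2] * x[3]), base = base)
}

#' Stress-induced change in response bias
#'
#' The double difference used as the behavioral anhedonia measure:
#' `(post block2 - post block1) - (pre block2 - pre block1)`.  Negative
#' values mean the stressor blunted the within-session growth of response
#' bias.
#'
#' @param pre,post numeric vectors of length 2: the block-1 and block-2
#'   response biases of the prestress and poststress sessions.
#' @return the stress-induced change score (same log units as the inputs).
#' @examples
#' stress_change_rb(pre = c(0.30, 0.20), post = c(0.25, 0.05))  # -0.10
#' @export
stress_change_rb <- function(pre, post) {
  if (length(pre) != 2L || length(post) != 2L || anyNA(c(pre, post))) {
    stop("all four block response biases (pre/post x block 1/2) must be present")
  }
  (post[2] - post[1]) - (pre[2] - pre[1])
}

#' Per-subject PRT summary across sessions
#'
#' Tallies every (subject, session, block) cell of a trial table, computes
#' the block response biases and the stress-induced change score.  Subjects
#' missing any of the four blocks get `NA` and are listed in the
#' `"dropped"` attribute; they are excluded from the behavioral unit only.
#'
#' @param trials data frame with `subject`, `session` ("pre"/"post"),
#'   `block` (1/2), `stimulus`, `correct`, `rewarded`.
#' @return data frame with one row per subject: `subject`, `rb_pre_b1`,
#'   `rb_pre_b2`, `rb_post_b1`, `rb_post_b2`, `stress_change`.
#' @export
prt_summary <- function(trials) {
  stopifnot(all(c("subject", "session", "block") %in% names(trials)))
  subjects <- unique(trials$subject)
  cell <- function(su, se, b) {
    tr <- trials[trials$subject == su & trials$session == se & trials$block == b, ]
    if (nrow(tr) == 0L) return(NA_real_)
    response_bias(tally_block(tr))
  }
  out <- data.frame(
    subject = subjects,
    rb_pre_b1 = vapply(subjects, cell, 0, se = "pre", b = 1),
    rb_pre_b2 = vapply(subjects, cell, 0, se = "pre", b = 2),
    rb_post_b1 = vapply(subjects, cell, 0, se = "post", b = 1),
    rb_post_b2 = vapply(subjects, cell, 0, se = "post", b = 2),
    stringsAsFactors = FALSE
  )
  has_all <- stats::complete.cases(out[, -1])
  out$stress_change <- NA_real_
  out$stress_change[has_all] <-
    (out$rb_post_b2 - out$rb_post_b1 - (out$rb_pre_b2 - out$rb_pre_b1))[has_all]
  attr(out, "dropped") <- out$subject[!has_all]
  out
}
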