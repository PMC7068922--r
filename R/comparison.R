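# Best-plan selection between competing plans with an equivalence
# threshold on the global-score difference, and concordance of the tool's
# verdicts with clinician choices.

#' Decide between two competing plans
#'
#' Lower global score wins. When the absolute score difference falls
#' strictly below the equivalence threshold (default 0.005 on the
#' global-score scale) the plans are judged dosimetrically equivalent:
#' below that difference the distinction carries no clinical meaning.
#' Exact ties are always equivalent, so `threshold = 0` reduces to pure
#' argmin with ties equivalent.
#'
#' @param score_a,score_b Global scores of plans A and B.
#' @param threshold Equivalence threshold (>= 0), default 0.005.
#' @param case_id Optional case identifier carried through.
#' @return A `plan_decision`: list with `case_id`, `score_a`, `score_b`,
#'   `delta` (= `score_a - score_b`) and `verdict` (`"A"`, `"B"` or
#'   `"equivalent"`).
#' @export
decide <- function(score_a, score_b, threshold = 0.005, case_id = NA) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    abort_validation("threshold must be a single nonnegative number")
  }
  delta <- score_a - score_b
  verdict <- if (delta == 0 || abs(delta) < threshold) {
    "equivalent"
  } else if (score_a < score_b) {
    "A"
  } else {
    "B"
  }
  structure(list(case_id = case_id, score_a = score_a, score_b = score_b,
                 delta = delta, verdict = verdict, threshold = threshold),
            class = "plan_decision")
}

#' @export
print.plan_decision <- function(x, ...) {
  cat(sprintf("Case %s: A = %.4f, B = %.4f, delta = %+.4f -> %s\n",
              as.character(x$case_id), x$score_a, x$score_b, x$delta,
              x$verdict))
  invisible(x)
}

#' Decide a table of paired cases
#'
#' Applies [decide()] to each row of a case table.
#'
#' @param scores Data frame with columns `case_id`, `score_a`, `score_b`.
#' @param threshold Equivalence threshold, default 0.005.
#' @return Data frame with columns `case_id`, `score_a`, `score_b`,
#'   `delta`, `verdict`.
#' @export
decision_table <- function(scores, threshold = 0.005) {
  req <- c("case_id", "score_a", "score_b")
  if (!all(req %in% names(scores))) {
    abort_validation("scores needs columns case_id, score_a, score_b")
  }
  if (nrow(scores) == 0L) abort_validation("no cases to decide")
  out <- scores[req]
  out$delta <- out$score_a - out$score_b
  out$verdict <- vapply(seq_len(nrow(out)), function(i) {
    decide(out$score_a[i], out$score_b[i], threshold,
           out$case_id[i])$verdict
  }, character(1))
  out
}

# Does one rater choice agree with one verdict?
# An equivalent verdict matches "both"/"neither" always, and any choice
# when lenient = TRUE; an A/B verdict matches only the same choice.
.choice_agrees <- function(verdict, choice, lenient) {
  if (verdict == "equivalent") {
    lenient || choice %in% c("both", "neither")
  } else {
    choice == verdict
  }
}

#' Concordance between plan decisions and rater choices
#'
#' Counts, per rater and pooled, the cases where the tool's verdict
#' matches the rater's selection. Two counts are reported: `raw` ignores
#' the equivalence threshold (sign of the score difference only; exact
#' ties equivalent) and `thresholded` applies it. When
#' `count_equivalent_as_agree` is set, an equivalent verdict under the
#' threshold is counted as agreement with any choice — a sub-threshold
#' score difference means either selection is acceptable. A rater's
#' `"both"`/`"neither"` matches only an equivalent verdict.
#'
#' @param decisions A [decision_table()] result (or data frame with
#'   `case_id`, `score_a`, `score_b`, `verdict`).
#' @param choices Data frame with columns `case_id`, `rater_id`, `choice`.
#' @param count_equivalent_as_agree Logical flag, default `TRUE`.
#' @return List with `per_rater` (data frame: rater_id, n, agree_raw,
#'   agree_thresholded), `pooled` (the column sums), and the flag.
#' @export
concordance <- function(decisions, choices, count_equivalent_as_agree = TRUE) {
  if (!all(c("case_id", "verdict") %in% names(decisions))) {
    abort_validation("decisions needs columns case_id and verdict")
  }
  if (!all(c("case_id", "rater_id", "choice") %in% names(choices))) {
    abort_validation("choices needs columns case_id, rater_id, choice")
  }
  orphan <- setdiff(unique(choices$case_id), decisions$case_id)
  if (length(orphan) > 0L) {
    abort_validation(paste0("choices reference undecided case(s): ",
                            paste(orphan, collapse = ", ")))
  }
  di <- match(choices$case_id, decisions$case_id)
  raw_verdict <- vapply(di, function(i) {
    decide(decisions$score_a[i], decisions$score_b[i], 0)$verdict
  }, character(1))
  thr_verdict <- decisions$verdict[di]

  agree_raw <- mapply(.choice_agrees, raw_verdict, choices$choice,
                      MoreArgs = list(lenient = FALSE))
  agree_thr <- mapply(.choice_agrees, thr_verdict, choices$choice,
                      MoreArgs = list(lenient = count_equivalent_as_agree))

  raters <- unique(choices$rater_id)
  per_rater <- data.frame(
    rater_id = raters,
    n = vapply(raters, function(r) sum(choices$rater_id == r), integer(1)),
    agree_raw = vapply(raters, function(r) {
      sum(agree_raw[choices$rater_id == r])
    }, integer(1)),
    agree_thresholded = vapply(raters, function(r) {
      sum(agree_thr[choices$rater_id == r])
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(per_rater) <- NULL
  list(per_rater = per_rater,
       pooled = list(n = nrow(choices),
                     agree_raw = sum(agree_raw),
                     agree_thresholded = sum(agree_thr)),
       count_equivalent_as_agree = count_equivalent_as_agree)
}
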