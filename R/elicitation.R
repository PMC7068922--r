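# Preference handling for automatic group-weight elicitation.
#
# Raters compare plans pairwise; majority-aggregated strict preferences
# form the ordered pair set Omega used by the ideal-point program: the
# model seeks weights w and an ideal point x in group-score space such
# that preferred plans lie closer (in weighted Euclidean distance) to x.

#' Aggregate per-rater plan choices into a majority preference set
#'
#' For each comparison case, each rater picks `"A"`, `"B"`, `"both"` or
#' `"neither"` (the last two express equivalence/abstention and contribute
#' no vote). An ordered pair (j, k) enters the preference set when strictly
#' more voting raters preferred j than k; ties emit no pair, so a pair and
#' its reverse can never coexist.
#'
#' @param choices Data frame with columns `case_id`, `rater_id`, `choice`
#'   (`"A"`, `"B"`, `"both"` or `"neither"`).
#' @param cases Data frame with columns `case_id`, `plan_a`, `plan_b`
#'   mapping each case to the two plan identifiers shown.
#' @return A `preference_set`: data frame with columns `preferred`, `other`
#'   and `case_id`.
#' @export
build_preference_set <- function(choices, cases) {
  req_ch <- c("case_id", "rater_id", "choice")
  req_ca <- c("case_id", "plan_a", "plan_b")
  if (!all(req_ch %in% names(choices))) {
    abort_validation("choices needs columns case_id, rater_id, choice")
  }
  if (!all(req_ca %in% names(cases))) {
    abort_validation("cases needs columns case_id, plan_a, plan_b")
  }
  if (nrow(choices) == 0L) abort_validation("empty choice table")
  bad <- setdiff(unique(choices$choice), c("A", "B", "both", "neither"))
  if (length(bad) > 0L) {
    abort_validation(paste0("invalid choice value(s): ",
                            paste(bad, collapse = ", ")))
  }
  orphan <- setdiff(unique(choices$case_id), cases$case_id)
  if (length(orphan) > 0L) {
    abort_validation(paste0("choices reference unknown case(s): ",
                            paste(orphan, collapse = ", ")))
  }

  out <- list()
  for (i in seq_len(nrow(cases))) {
    cid <- cases$case_id[i]
    ch <- choices$choice[choices$case_id == cid]
    if (length(ch) == 0L) next
    a <- sum(ch == "A")
    b <- sum(ch == "B")
    if (a == b) next  # tie or all abstentions: no majority pair
    pref <- if (a > b) cases$plan_a[i] else cases$plan_b[i]
    oth <- if (a > b) cases$plan_b[i] else cases$plan_a[i]
    out[[length(out) + 1L]] <- data.frame(
      preferred = as.character(pref), other = as.character(oth),
      case_id = as.character(cid), stringsAsFactors = FALSE)
  }
  omega <- if (length(out) > 0L) {
    do.call(rbind, out)
  } else {
    data.frame(preferred = character(), other = character(),
               case_id = character(), stringsAsFactors = FALSE)
  }
  class(omega) <- c("preference_set", "data.frame")
  omega
}

#' Weighted Euclidean distance to an ideal point
#'
#' \eqn{d = \sqrt{\sum_p w_p (y_p - x_p)^2}}. With unit weights this is the
#' ordinary Euclidean distance in group-score space.
#'
#' @param y Score vector of a plan (length t).
#' @param w Nonnegative weight per dimension (length t).
#' @param x Ideal point (length t).
#' @return Nonnegative scalar distance.
#' @export
weighted_distance <- function(y, w, x) {
  if (length(y) != length(w) || length(y) != length(x)) {
    abort_validation("y, w, x must share one length")
  }
  if (any(w < 0)) abort_validation("weights must be nonnegative")
  sqrt(sum(w * (y - x)^2))
}

# Squared weighted distances of every plan row of Y to x.
.sq_dists <- function(Y, w, x) {
  as.numeric((Y - matrix(x, nrow(Y), ncol(Y), byrow = TRUE))^2 %*% w)
}

# Map a preference_set's plan ids onto row indices of Y.
.omega_idx <- function(Y, omega) {
  ids <- rownames(Y)
  j <- match(omega$preferred, ids)
  k <- match(omega$other, ids)
  if (anyNA(j) || anyNA(k)) {
    abort_validation("preference set references plans absent from the score matrix")
  }
  cbind(j = j, k = k)
}

#' Count violated preference pairs under a candidate model
#'
#' A pair (j, k) — j preferred to k — is violated when plan j lies strictly
#' farther from the ideal point than plan k by more than the strictness
#' margin: \eqn{d_j^2 > d_k^2 + \epsilon}. Exact ties are not violations,
#' matching the weak inequality of the elicitation program's constraints.
#'
#' @param Y Score matrix (plans in rows, named; groups in columns).
#' @param omega A [build_preference_set()] result (or a data frame with
#'   columns `preferred`, `other`).
#' @param w Weight vector.
#' @param x Ideal point.
#' @param margin Strictness margin on squared distances (default 0).
#' @return Integer count of violated pairs.
#' @export
violation_count <- function(Y, omega, w, x, margin = 0) {
  Y <- as_score_matrix(Y)
  if (nrow(omega) == 0L) return(0L)
  idx <- .omega_idx(Y, omega)
  d2 <- .sq_dists(Y, w, x)
  sum(d2[idx[, "j"]] > d2[idx[, "k"]] + margin)
}

#' Coerce to a score matrix
#'
#' A score matrix holds one row per plan (rownames are plan identifiers)
#' and one column per structure group, each cell a nonnegative group score.
#'
#' @param x Matrix or data frame of nonnegative scores.
#' @return A numeric matrix with row and column names.
#' @export
as_score_matrix <- function(x) {
  Y <- as.matrix(x)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) abort_validation("score matrix must be complete (no NA)")
  if (any(Y < 0)) abort_validation("scores must be nonnegative")
  if (nrow(Y) < 2L) abort_validation("need at least two plans")
  if (ncol(Y) < 1L) abort_validation("need at least one group dimension")
  if (is.null(rownames(Y))) rownames(Y) <- paste0("plan", seq_len(nrow(Y)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("G", seq_len(ncol(Y)))
  Y
}
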