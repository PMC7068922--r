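# Synthetic plans, preferences and rating tables with known ground truth.
#
# The generator emulates the validation design of a paired-plan rater
# study: plans carry group scores in a range spanning compliant (< 1) and
# goal-violating (> 1) values, raters choose within paired cases according
# to an ideal-point model with optional choice noise, and rating tables
# realize a prescribed exact-agreement proportion.

#' Simulate a plan-by-group score matrix
#'
#' Independent uniform draws within `bounds` (default `c(0.3, 1.4)`,
#' spanning plans that beat their goals and plans that violate them).
#'
#' @param n_plans Number of plans (>= 2).
#' @param t_groups Number of structure groups (>= 1).
#' @param bounds Length-2 score range `c(lo, hi)`, `lo <= hi`.
#' @param seed Optional integer seed for reproducibility.
#' @return A score matrix (see [as_score_matrix()]) with plan rownames.
#' @export
simulate_scores <- function(n_plans, t_groups, bounds = c(0.3, 1.4),
                            seed = NULL) {
  if (length(bounds) != 2L || anyNA(bounds) || bounds[1] > bounds[2]) {
    abort_validation("bounds must be c(lo, hi) with lo <= hi")
  }
  if (n_plans < 2L) abort_validation("need at least two plans")
  if (t_groups < 1L) abort_validation("need at least one group")
  if (!is.null(seed)) set.seed(seed)
  Y <- matrix(runif(n_plans * t_groups, bounds[1], bounds[2]),
              nrow = n_plans, ncol = t_groups,
              dimnames = list(paste0("plan", seq_len(n_plans)),
                              paste0("G", seq_len(t_groups))))
  as_score_matrix(Y)
}

#' Simulate rater choices from an ideal-point preference model
#'
#' Pairs plans into comparison cases and lets each rater pick the plan
#' whose weighted distance to the true ideal point is smaller. With
#' probability `noise` a rater's choice flips to the other plan; exact
#' distance ties make every rater answer `"both"` (the plans are
#' equivalent under the model).
#'
#' @param Y Score matrix (plans in rows).
#' @param w_true True weight vector (nonnegative, one per group).
#' @param x_true True ideal point.
#' @param noise Per-rater choice flip probability in \[0, 1\] (default 0).
#' @param n_raters Number of raters (default 3).
#' @param cases `"paired"` (default) splits the plans into disjoint
#'   consecutive pairs, one case per pair, as in a paired-plan study;
#'   `"all"` compares every unordered plan pair.
#' @param seed Optional integer seed.
#' @return List with `cases` (data frame: case_id, plan_a, plan_b),
#'   `choices` (data frame: case_id, rater_id, choice) and `truth`
#'   (`w`, `x`).
#' @export
simulate_preferences <- function(Y, w_true, x_true, noise = 0, n_raters = 3,
                                 cases = c("paired", "all"), seed = NULL) {
  Y <- as_score_matrix(Y)
  cases <- match.arg(cases)
  if (length(w_true) != ncol(Y) || length(x_true) != ncol(Y)) {
    abort_validation("w_true and x_true must have one entry per group")
  }
  if (any(w_true < 0)) abort_validation("w_true must be nonnegative")
  if (noise < 0 || noise > 1) abort_validation("noise must be in [0, 1]")
  if (n_raters < 1L) abort_validation("need at least one rater")
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(Y)
  pair_idx <- if (cases == "paired") {
    k <- n %/% 2L
    cbind(2 * seq_len(k) - 1L, 2 * seq_len(k))
  } else {
    t(combn(n, 2))
  }
  case_df <- data.frame(case_id = paste0("case", seq_len(nrow(pair_idx))),
                        plan_a = rownames(Y)[pair_idx[, 1]],
                        plan_b = rownames(Y)[pair_idx[, 2]],
                        stringsAsFactors = FALSE)
  d2 <- .sq_dists(Y, w_true, x_true)

  rows <- vector("list", nrow(case_df) * n_raters)
  ri <- 0L
  for (i in seq_len(nrow(case_df))) {
    da <- d2[pair_idx[i, 1]]
    db <- d2[pair_idx[i, 2]]
    for (r in seq_len(n_raters)) {
      ch <- if (da == db) {
        "both"
      } else {
        base <- if (da < db) "A" else "B"
        if (noise > 0 && runif(1) < noise) {
          if (base == "A") "B" else "A"
        } else {
          base
        }
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(case_id = case_df$case_id[i],
                               rater_id = paste0("R", r),
                               choice = ch, stringsAsFactors = FALSE)
    }
  }
  list(cases = case_df,
       choices = do.call(rbind, rows),
       truth = list(w = w_true, x = x_true))
}

#' Simulate a rating table with a prescribed agreement proportion
#'
#' Builds two rating vectors over `n_items` items and `q` categories whose
#' exact-agreement proportion equals `target_po` (which must be a multiple
#' of `1/n_items`): agreements are placed at seeded random positions; at
#' every other item the second rating is forced to differ.
#'
#' @param n_items Number of items.
#' @param q Number of categories (>= 2).
#' @param target_po Target exact-agreement proportion.
#' @param scale `"nominal"` or `"ordinal"`.
#' @param categories Optional category labels (default `C1..Cq`).
#' @param seed Optional integer seed.
#' @return A [rating_table()].
#' @export
simulate_ratings <- function(n_items, q, target_po,
                             scale = c("nominal", "ordinal"),
                             categories = NULL, seed = NULL) {
  scale <- match.arg(scale)
  if (n_items < 1L) abort_validation("need at least one item")
  if (q < 2L) abort_validation("need q >= 2 categories")
  if (target_po < 0 || target_po > 1) {
    abort_validation("target_po must be in [0, 1]")
  }
  n_agree <- target_po * n_items
  if (abs(n_agree - round(n_agree)) > 1e-9) {
    abort_validation(paste0("target_po must be a multiple of 1/",
                            n_items, " to be achievable"))
  }
  n_agree <- as.integer(round(n_agree))
  if (is.null(categories)) categories <- paste0("C", seq_len(q))
  if (length(categories) != q) {
    abort_validation("categories must have length q")
  }
  if (!is.null(seed)) set.seed(seed)

  r1 <- sample(categories, n_items, replace = TRUE)
  r2 <- vapply(r1, function(c1) sample(setdiff(categories, c1), 1L),
               character(1))
  agree_at <- sample.int(n_items, n_agree)
  r2[agree_at] <- r1[agree_at]
  rating_table(r1, r2, categories = categories, scale = scale)
}
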