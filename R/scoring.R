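# Structure, group, and global plan scores.
#
# Per-structure scores express fulfilment of the planning goal: a score of
# 1 means the planned dose metric sits exactly at its tolerance; below 1,
# coverage or sparing is better than the goal; above 1, the goal is
# violated. Scores are deliberately not capped, so the magnitude of a
# violation stays visible. Lower is better throughout.

#' Target (PTV) coverage score
#'
#' Ratio of the tolerance dose to the planned dose for a coverage metric
#' (typically D98, with tolerance 95% of the prescription). Equals 1 at the
#' goal, falls below 1 when coverage exceeds the goal, and rises above 1
#' when the target is under-dosed.
#'
#' @param planned_dose Planned dose for the metric, Gy (> 0).
#' @param tolerance_dose Tolerance dose, Gy (> 0).
#' @return Nonnegative score `tolerance_dose / planned_dose`.
#' @export
score_target <- function(planned_dose, tolerance_dose) {
  if (any(tolerance_dose <= 0)) abort_validation("tolerance dose must be > 0")
  if (any(planned_dose <= 0)) {
    abort_validation("target score undefined for planned dose 0")
  }
  tolerance_dose / planned_dose
}

#' Organ-at-risk sparing score
#'
#' Ratio of the planned dose to the tolerance dose. Equals 1 at the
#' tolerance, below 1 when the organ is spared better than the goal, above
#' 1 when the tolerance is exceeded.
#'
#' @param planned_dose Planned dose for the metric, Gy (>= 0).
#' @param tolerance_dose Tolerance dose, Gy (> 0).
#' @return Nonnegative score `planned_dose / tolerance_dose`.
#' @export
score_oar <- function(planned_dose, tolerance_dose) {
  if (any(tolerance_dose <= 0)) abort_validation("tolerance dose must be > 0")
  if (any(planned_dose < 0)) abort_validation("planned dose must be >= 0")
  planned_dose / tolerance_dose
}

#' Score one plan against tolerances under a group configuration
#'
#' Computes one score per configured structure (by role, via
#' [score_target()] or [score_oar()]), aggregates them into group scores
#' with the structure weights, and into the global plan score with the
#' group weights:
#' \deqn{S = \sum_i w_{group(i)} \sum_j w_{struct(j)} s_j}
#'
#' Every configured structure must have a tolerance criterion and a
#' matching plan metric; a missing structure is an error (silently dropping
#' a weighted structure would distort the weighted sum and break
#' comparability across plans). Plan entries for unconfigured structures
#' are ignored with a warning. When a structure carries several criteria
#' (e.g. Dmax and Dmean), their per-criterion scores are averaged.
#'
#' @param plan A [plan_metrics()] object.
#' @param tolerances A [tolerance_table()].
#' @param config A [group_config()].
#' @return A `score_set`: list with `plan_id`, `structure_scores` (named),
#'   `group_scores` (named), `global_score`.
#' @export
score_plan <- function(plan, tolerances, config) {
  stopifnot(inherits(plan, "plan_metrics"),
            inherits(tolerances, "tolerance_table"),
            inherits(config, "group_config"))
  structures <- config_structures(config)

  extra <- setdiff(unique(plan$entries$structure), structures)
  if (length(extra) > 0L) {
    warning("ignoring plan structures not in the configuration: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }

  plan_key <- paste(plan$entries$structure, plan$entries$metric, sep = "\r")
  struct_score <- setNames(numeric(length(structures)), structures)
  for (s in structures) {
    crit <- tolerances[tolerances$structure == s, , drop = FALSE]
    if (nrow(crit) == 0L) {
      abort_validation(paste0("no tolerance criterion for structure '", s, "'"))
    }
    sc <- numeric(nrow(crit))
    for (r in seq_len(nrow(crit))) {
      idx <- match(paste(s, crit$metric[r], sep = "\r"), plan_key)
      if (is.na(idx)) {
        abort_validation(paste0(
          "plan '", plan$plan_id, "' has no ", crit$metric[r],
          " metric for structure '", s, "'"
        ))
      }
      planned <- plan$entries$dose_gy[idx]
      sc[r] <- if (crit$role[r] == "target") {
        score_target(planned, crit$dose_gy[r])
      } else {
        score_oar(planned, crit$dose_gy[r])
      }
    }
    struct_score[s] <- mean(sc)
  }

  group_score <- vapply(config$groups, function(g) {
    sum(g$structure_weights * struct_score[g$structures])
  }, numeric(1))
  names(group_score) <- vapply(config$groups, `[[`, character(1), "name")
  gw <- vapply(config$groups, `[[`, numeric(1), "weight")
  global <- sum(gw * group_score)

  structure(list(plan_id = plan$plan_id,
                 structure_scores = struct_score,
                 group_scores = group_score,
                 global_score = global),
            class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("Plan %s: global score %.4f\n", x$plan_id, x$global_score))
  cat("Group scores:\n")
  for (g in names(x$group_scores)) {
    cat(sprintf("  %-12s %.4f\n", g, x$group_scores[g]))
  }
  invisible(x)
}

#' Flatten a score set to a data frame
#'
#' One row per structure with its group and score; useful for CSV export
#' and plotting.
#'
#' @param score_set A `score_set` from [score_plan()].
#' @param config The [group_config()] used to compute it.
#' @return A data frame with columns `plan_id`, `structure`, `group`,
#'   `score`.
#' @export
score_set_table <- function(score_set, config) {
  stopifnot(inherits(score_set, "score_set"), inherits(config, "group_config"))
  structures <- config_structures(config)
  data.frame(plan_id = score_set$plan_id,
             structure = structures,
             group = config_structure_groups(config),
             score = as.numeric(score_set$structure_scores[structures]),
             stringsAsFactors = FALSE)
}

#' Write a score set to CSV and JSON
#'
#' Writes `<stem>.csv` (structure-level scores) and `<stem>.json` (plan id,
#' group scores, global score).
#'
#' @param score_set A `score_set` from [score_plan()].
#' @param config The matching [group_config()].
#' @param stem Output path without extension.
#' @return The two paths, invisibly.
#' @export
write_score_set <- function(score_set, config, stem) {
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  write.csv(score_set_table(score_set, config), csv,
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(plan_id = score_set$plan_id,
         group_scores = as.list(score_set$group_scores),
         global_score = score_set$global_score),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}
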