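# Domain types and readers/writers for tolerance criteria, plan dose
# metrics, and the grouped structure configuration.

# Metric vocabulary: the named DVH metrics plus dose-at-volume metrics of
# the form "D<v>%" (e.g. D50%). Carried as data; only the syntax is checked.
.metric_ok <- function(metric) {
  metric %in% c("D98", "Dmax", "Dmean") |
    grepl("^D[0-9]{1,2}(\\.[0-9]+)?%$", metric)
}

#' Build a tolerance-criteria table
#'
#' A tolerance table holds one protocol dose criterion per
#' (structure, metric) pair: the DVH metric it is stated on (e.g. `D98` for
#' target coverage, `Dmax` or `Dmean` for an organ at risk), the tolerance
#' dose in Gy, and the structure's role (`"target"` or `"oar"`), which
#' selects the scoring direction.
#'
#' @param df A data frame with columns `structure`, `metric`, `dose_gy` and
#'   `role`.
#' @return A validated `tolerance_table` (a data frame).
#' @seealso [load_tolerance_table()], [score_plan()]
#' @export
tolerance_table <- function(df) {
  req <- c("structure", "metric", "dose_gy", "role")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    abort_validation(paste0(
      "tolerance table is missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  df <- as.data.frame(df)[req]
  df$structure <- as.character(df$structure)
  df$metric <- as.character(df$metric)
  df$dose_gy <- as.numeric(df$dose_gy)
  df$role <- as.character(df$role)
  if (nrow(df) == 0L) abort_validation("tolerance table has no rows")
  if (anyNA(df$dose_gy)) abort_validation("tolerance dose contains NA")
  if (any(df$dose_gy <= 0)) {
    abort_validation("tolerance doses must be strictly positive")
  }
  if (!all(df$role %in% c("target", "oar"))) {
    abort_validation("role must be 'target' or 'oar'")
  }
  bad <- df$metric[!.metric_ok(df$metric)]
  if (length(bad) > 0L) {
    abort_validation(paste0(
      "unknown metric(s): ", paste(unique(bad), collapse = ", "),
      " (expected D98, Dmax, Dmean or D<v>%)"
    ))
  }
  key <- paste(df$structure, df$metric, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation(paste0(
      "duplicate (structure, metric) criterion: ",
      paste(unique(df$structure[duplicated(key)]), collapse = ", ")
    ))
  }
  rownames(df) <- NULL
  class(df) <- c("tolerance_table", "data.frame")
  df
}

#' Read a tolerance-criteria table from CSV
#'
#' Expects header columns `structure,metric,dose_gy,role` (UTF-8, dot
#' decimal separator). Doses are in Gy.
#'
#' @param path Path to the CSV file.
#' @return A [tolerance_table()].
#' @export
load_tolerance_table <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  tolerance_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a tolerance-criteria table to CSV
#'
#' @param x A [tolerance_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tolerance_table <- function(x, path) {
  stopifnot(inherits(x, "tolerance_table"))
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the dose-metric set of one treatment plan
#'
#' Holds the planned value of each DVH metric for each structure of one
#' plan, in Gy. Metrics must match the (structure, metric) keys of the
#' tolerance table for the plan to be scored.
#'
#' @param plan_id Identifier for the plan (e.g. `"A"`, `"planB"`).
#' @param df A data frame with columns `structure`, `metric`, `dose_gy`.
#' @return A `plan_metrics` object.
#' @export
plan_metrics <- function(plan_id, df) {
  req <- c("structure", "metric", "dose_gy")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    abort_validation(paste0(
      "plan metrics missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  df <- as.data.frame(df)[req]
  df$structure <- as.character(df$structure)
  df$metric <- as.character(df$metric)
  df$dose_gy <- as.numeric(df$dose_gy)
  if (nrow(df) == 0L) abort_validation("plan metrics table has no rows")
  if (anyNA(df$dose_gy)) abort_validation("planned dose contains NA")
  if (any(df$dose_gy < 0)) abort_validation("planned doses must be >= 0")
  key <- paste(df$structure, df$metric, sep = "\r")
  if (anyDuplicated(key)) {
    abort_validation(paste0(
      "duplicate (structure, metric) plan entry: ",
      paste(unique(df$structure[duplicated(key)]), collapse = ", ")
    ))
  }
  rownames(df) <- NULL
  structure(list(plan_id = as.character(plan_id), entries = df),
            class = "plan_metrics")
}

#' Read one plan's dose metrics from CSV
#'
#' Expects header columns `structure,metric,dose_gy`. The plan id defaults
#' to the file name without extension.
#'
#' @param path Path to the CSV file.
#' @param plan_id Plan identifier; default taken from the file name.
#' @return A [plan_metrics()] object.
#' @export
load_plan_metrics <- function(path, plan_id = NULL) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  if (is.null(plan_id)) plan_id <- sub("\\.[^.]*$", "", basename(path))
  plan_metrics(plan_id, read.csv(path, stringsAsFactors = FALSE))
}

#' Write one plan's dose metrics to CSV
#'
#' @param x A [plan_metrics()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plan_metrics <- function(x, path) {
  stopifnot(inherits(x, "plan_metrics"))
  write.csv(x$entries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.plan_metrics <- function(x, ...) {
  cat("Plan", x$plan_id, "-", nrow(x$entries), "dose metrics\n")
  print(x$entries, ...)
  invisible(x)
}

#' Normalize nonnegative raw weights to fractions
#'
#' Weights may be entered on any positive scale (percentages, counts,
#' fractions); they are rescaled proportionally to sum to one. The
#' operation is idempotent and scale-invariant.
#'
#' @param raw Numeric vector of nonnegative weights, at least one positive.
#' @return Numeric vector of the same length summing to 1.
#' @export
normalize_weights <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) == 0L) abort_validation("no weights supplied")
  if (anyNA(raw)) abort_validation("weights contain NA")
  if (any(raw < 0)) abort_validation("weights must be nonnegative")
  s <- sum(raw)
  if (s <= 0) abort_validation("all weights are zero")
  raw / s
}

#' Build a grouped structure configuration
#'
#' Targets and organs at risk are partitioned into clinically meaningful
#' groups (e.g. PTV, Critical, Salivary). Each group carries a relative
#' importance weight and each structure a relative weight within its group;
#' both levels are renormalized to sum to one, so weights can be entered as
#' percentages.
#'
#' @param groups A list; each element is a list with fields `name`,
#'   `weight`, and `structures`, itself a list of `list(name, weight)`
#'   entries (a structure given as a bare character string gets weight 1).
#' @return A `group_config` object.
#' @export
group_config <- function(groups) {
  if (length(groups) == 0L) abort_validation("config defines no groups")
  gnames <- vapply(groups, function(g) as.character(g$name %||% NA_character_),
                   character(1))
  if (anyNA(gnames)) abort_validation("every group needs a name")
  if (anyDuplicated(gnames)) abort_validation("duplicate group names")
  graw <- vapply(groups, function(g) as.numeric(g$weight %||% NA_real_),
                 numeric(1))
  if (anyNA(graw)) abort_validation("every group needs a weight")
  gw <- normalize_weights(graw)

  parsed <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    ss <- groups[[i]]$structures
    if (length(ss) == 0L) {
      abort_validation(paste0("group '", gnames[i], "' has no structures"))
    }
    snames <- vapply(ss, function(s) {
      if (is.character(s)) s else as.character(s$name %||% NA_character_)
    }, character(1))
    if (anyNA(snames)) {
      abort_validation(paste0("unnamed structure in group '", gnames[i], "'"))
    }
    sraw <- vapply(ss, function(s) {
      if (is.character(s)) 1 else as.numeric(s$weight %||% 1)
    }, numeric(1))
    parsed[[i]] <- list(name = gnames[i], weight = gw[i],
                        structures = snames,
                        structure_weights = normalize_weights(sraw))
  }
  all_s <- unlist(lapply(parsed, `[[`, "structures"))
  if (anyDuplicated(all_s)) {
    abort_validation(paste0(
      "structure(s) assigned to more than one group: ",
      paste(unique(all_s[duplicated(all_s)]), collapse = ", ")
    ))
  }
  structure(list(groups = parsed), class = "group_config")
}

#' Read a grouped structure configuration from YAML or JSON
#'
#' The file carries `groups: [{name, weight, structures: [{name, weight}]}]`.
#' Format is chosen by extension (`.json` for JSON, anything else parsed as
#' YAML, of which JSON is a subset). Weights are renormalized on load.
#'
#' @param path Path to the config file.
#' @return A [group_config()] object.
#' @export
load_group_config <- function(path) {
  if (!file.exists(path)) abort_validation(paste0("no such file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$groups)) abort_validation("config has no 'groups' key")
  group_config(raw$groups)
}

#' Write a grouped structure configuration to YAML
#'
#' Writes the normalized weights, so a round-trip reproduces the object.
#'
#' @param x A [group_config()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_group_config <- function(x, path) {
  stopifnot(inherits(x, "group_config"))
  out <- list(groups = lapply(x$groups, function(g) {
    list(name = g$name, weight = g$weight,
         structures = mapply(function(n, w) list(name = n, weight = w),
                             g$structures, g$structure_weights,
                             SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }))
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.group_config <- function(x, ...) {
  cat("Group configuration (", length(x$groups), " groups)\n", sep = "")
  for (g in x$groups) {
    cat(sprintf("  %s (w = %.3f): %s\n", g$name, g$weight,
                paste(g$structures, collapse = ", ")))
  }
  invisible(x)
}

# All structures of a config, in config order (groups contiguous).
config_structures <- function(config) {
  unlist(lapply(config$groups, `[[`, "structures"), use.names = FALSE)
}

# Group name of each structure, aligned with config_structures().
config_structure_groups <- function(config) {
  unlist(lapply(config$groups,
                function(g) rep(g$name, length(g$structures))),
         use.names = FALSE)
}
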