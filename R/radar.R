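# Radar diagrams of structure- and group-level scores.
#
# Each axis is one structure (grouped contiguously, in configuration
# order) or one group; each plan is one closed polyline whose radii are
# its scores, drawn against the unit reference contour (all goals exactly
# met). Radii map scores linearly and are never capped, so violated goals
# stick out beyond the unit ring.

#' Lay out a radar diagram for one or more score sets
#'
#' Computes the axis order, the per-plan series, and the radial limit
#' (`max(1.2, 1.1 * max score)`, so every point stays inside the frame and
#' the unit ring keeps visible margin). With fewer than 3 axes a polygon
#' is degenerate and the rendering falls back to bars.
#'
#' @param score_sets A `score_set` or list of them (shared configuration).
#' @param config The [group_config()] the scores were computed under.
#' @param level `"structure"` or `"group"`.
#' @return A `diagram_spec`: list with `axes` (data frame: axis, group),
#'   `series` (plans x axes matrix), `plan_labels`, `radial_max`,
#'   `reference` (= 1), `type` (`"polygon"` or `"bar"`).
#' @export
diagram_spec <- function(score_sets, config, level = c("structure", "group")) {
  level <- match.arg(level)
  if (inherits(score_sets, "score_set")) score_sets <- list(score_sets)
  if (length(score_sets) == 0L) abort_validation("no score sets to plot")
  stopifnot(all(vapply(score_sets, inherits, logical(1), "score_set")),
            inherits(config, "group_config"))

  axes <- if (level == "structure") {
    data.frame(axis = config_structures(config),
               group = config_structure_groups(config),
               stringsAsFactors = FALSE)
  } else {
    gn <- vapply(config$groups, `[[`, character(1), "name")
    data.frame(axis = gn, group = gn, stringsAsFactors = FALSE)
  }
  series <- t(vapply(score_sets, function(s) {
    v <- if (level == "structure") s$structure_scores else s$group_scores
    miss <- setdiff(axes$axis, names(v))
    if (length(miss) > 0L) {
      abort_validation(paste0("score set '", s$plan_id,
                              "' lacks scores for: ",
                              paste(miss, collapse = ", ")))
    }
    as.numeric(v[axes$axis])
  }, numeric(nrow(axes))))
  rownames(series) <- vapply(score_sets, `[[`, character(1), "plan_id")
  colnames(series) <- axes$axis

  labels <- vapply(score_sets, function(s) {
    sprintf("%s (global %.3f)", s$plan_id, s$global_score)
  }, character(1))
  structure(list(axes = axes, series = series, plan_labels = labels,
                 radial_max = max(1.2, 1.1 * max(series)),
                 reference = 1,
                 type = if (nrow(axes) >= 3L) "polygon" else "bar"),
            class = "diagram_spec")
}

# Polar coordinate system with straight spokes (no line munching), so the
# per-plan series render as true radar polygons.
coord_radar <- function() {
  ggplot2::ggproto(NULL, ggplot2::CoordPolar,
                   theta = "x", r = "y", start = 0,
                   direction = 1, clip = "off",
                   is_linear = function(coord) TRUE)
}

#' Turn a diagram spec into a ggplot object
#'
#' @param spec A [diagram_spec()].
#' @return A ggplot object.
#' @export
radar_plot <- function(spec) {
  stopifnot(inherits(spec, "diagram_spec"))
  n_axes <- nrow(spec$axes)
  long <- data.frame(
    plan = factor(rep(spec$plan_labels, each = n_axes), spec$plan_labels),
    axis = rep(seq_len(n_axes), times = nrow(spec$series)),
    score = as.numeric(t(spec$series)))

  if (spec$type == "bar") {
    return(
      ggplot2::ggplot(long, ggplot2::aes(
        x = factor(.data$axis, labels = spec$axes$axis),
        y = .data$score, fill = .data$plan)) +
        ggplot2::geom_col(position = "dodge") +
        ggplot2::geom_hline(yintercept = spec$reference, linetype = 2) +
        ggplot2::labs(x = NULL, y = "score", fill = NULL) +
        ggplot2::ylim(0, spec$radial_max) +
        ggplot2::theme_minimal()
    )
  }

  # close each polygon by repeating its first vertex
  closed <- do.call(rbind, lapply(split(long, long$plan), function(d) {
    rbind(d, transform(d[1, ], axis = n_axes + 1))
  }))
  ring <- data.frame(axis = c(seq_len(n_axes), n_axes + 1),
                     score = spec$reference)
  ggplot2::ggplot(closed,
                  ggplot2::aes(x = .data$axis, y = .data$score)) +
    ggplot2::geom_path(data = ring, linetype = 2, colour = "grey40") +
    ggplot2::geom_path(ggplot2::aes(colour = .data$plan), linewidth = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq_len(n_axes),
                                labels = spec$axes$axis,
                                limits = c(1, n_axes + 1)) +
    ggplot2::scale_y_continuous(limits = c(0, spec$radial_max)) +
    coord_radar() +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 7),
                   legend.position = "bottom")
}

.render_diagram <- function(score_sets, config, out, level) {
  spec <- diagram_spec(score_sets, config, level)
  p <- radar_plot(spec)
  ok <- tryCatch({
    ggplot2::ggsave(out, p, width = 7, height = 6, dpi = 120)
    TRUE
  }, error = function(e) {
    abort_validation(paste0("cannot write diagram to '", out, "': ",
                            conditionMessage(e)))
  })
  invisible(out)
}

#' Render the Structures Plan Diagram
#'
#' One axis per configured structure (groups contiguous, configuration
#' order), one closed polyline per plan, dashed unit reference contour.
#' Output format follows the file extension (png, svg, pdf).
#'
#' @param score_sets A `score_set` or list of them.
#' @param config The shared [group_config()].
#' @param out Output image path.
#' @return `out`, invisibly.
#' @export
render_structure_diagram <- function(score_sets, config, out) {
  .render_diagram(score_sets, config, out, "structure")
}

#' Render the Group Plan Diagram
#'
#' As [render_structure_diagram()], with one axis per structure group.
#'
#' @inheritParams render_structure_diagram
#' @return `out`, invisibly.
#' @export
render_group_diagram <- function(score_sets, config, out) {
  .render_diagram(score_sets, config, out, "group")
}
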