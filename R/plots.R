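# Static renderings of the analysis views. Colors follow the field
# convention used throughout: green = control, red = stroke, black = the
# highlighted individual. All plot builders are pure functions of their
# inputs; render_* wrappers write SVG via the cairo device.

kinegraph_group_colors <- c(
  stroke = "#c23b22", control = "#2e8b57", shared = "#7f7f7f",
  individual = "#000000"
)

save_svg <- function(plot, path, width = 8, height = 5) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  grDevices::svg(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(plot)
  invisible(path)
}

#' Arc diagram of filtered angle pairs
#'
#' Angles are laid out on a horizontal axis in display-rank order; each
#' distinct pair is connected by an arc whose thickness grows with its
#' support and whose color encodes the class (stroke-only red, control-only
#' green, shared grey).
#'
#' @param arcs tibble with `angle_i`, `angle_j`, optional `support` and
#'   `class` (one of "stroke", "control", "shared").
#' @param angles angle metadata tibble (`id`, `name`, `display_rank`).
#' @return a ggplot object.
#' @export
plot_arc_diagram <- function(arcs, angles) {
  pos <- setNames(rank(angles$display_rank), angles$id)
  axis_df <- tibble(
    x = unname(pos[as.character(angles$id)]),
    label = angles$name
  )
  base <- ggplot2::ggplot() +
    ggplot2::geom_point(data = axis_df, ggplot2::aes(x = .data$x, y = 0),
                        size = 2) +
    ggplot2::scale_x_continuous(breaks = axis_df$x, labels = axis_df$label) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  if (nrow(arcs) == 0) return(base)
  if (!"support" %in% names(arcs)) arcs$support <- 1L
  if (!"class" %in% names(arcs)) arcs$class <- "shared"
  arc_points <- purrr::pmap(
    list(arcs$angle_i, arcs$angle_j, arcs$support, arcs$class,
         seq_len(nrow(arcs))),
    function(i, j, support, cls, id) {
      x1 <- pos[[as.character(i)]]
      x2 <- pos[[as.character(j)]]
      t <- seq(0, pi, length.out = 50)
      tibble(
        x = (x1 + x2) / 2 + abs(x2 - x1) / 2 * cos(t),
        y = abs(x2 - x1) / 2 * sin(t),
        support = support, class = cls, arc_id = id
      )
    }
  ) |> bind_rows()
  cols <- c(stroke = unname(kinegraph_group_colors["stroke"]),
            control = unname(kinegraph_group_colors["control"]),
            shared = unname(kinegraph_group_colors["shared"]))
  base +
    ggplot2::geom_path(
      data = arc_points,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$arc_id,
                   color = .data$class, linewidth = .data$support)
    ) +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::scale_linewidth_continuous(range = c(0.4, 2.5))
}

#' Mirrored two-group comparison of a joint angle
#'
#' Group A's mean curve is drawn upright, group B's mirrored below the
#' horizontal axis; an optional individual series is overlaid un-mirrored
#' on its group's half. In "Proportional" mode each group's horizontal
#' extent is scaled by its display length.
#'
#' @param summary_a,summary_b `group_summary` objects (see
#'   [group_summary()]).
#' @param individual optional numeric vector (common length) drawn in black.
#' @param individual_group `"a"` or `"b"`: which half the individual
#'   belongs to.
#' @return a ggplot object.
#' @export
plot_mirrored_comparison <- function(summary_a, summary_b, individual = NULL,
                                     individual_group = "a") {
  stopifnot(inherits(summary_a, "group_summary"),
            inherits(summary_b, "group_summary"))
  proportional <- summary_a$mode == "Proportional"
  xa <- seq_len(nrow(summary_a$curve))
  xb <- seq_len(nrow(summary_b$curve))
  if (proportional) {
    xa <- xa / max(xa) * summary_a$display_length
    xb <- xb / max(xb) * summary_b$display_length
  }
  da <- mutate(summary_a$curve, x = xa, y = .data$mean,
               group = summary_a$group %||% "A")
  db <- mutate(summary_b$curve, x = xb, y = -.data$mean,
               group = summary_b$group %||% "B")
  p <- ggplot2::ggplot() +
    ggplot2::geom_ribbon(
      data = da,
      ggplot2::aes(x = .data$x, ymin = .data$y - .data$sd,
                   ymax = .data$y + .data$sd),
      fill = kinegraph_group_colors["control"], alpha = 0.25) +
    ggplot2::geom_ribbon(
      data = db,
      ggplot2::aes(x = .data$x, ymin = .data$y - .data$sd,
                   ymax = .data$y + .data$sd),
      fill = kinegraph_group_colors["stroke"], alpha = 0.25) +
    ggplot2::geom_line(data = da, ggplot2::aes(x = .data$x, y = .data$y),
                       color = kinegraph_group_colors["control"]) +
    ggplot2::geom_line(data = db, ggplot2::aes(x = .data$x, y = .data$y),
                       color = kinegraph_group_colors["stroke"]) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "time step", y = "angle (deg; lower group mirrored)") +
    ggplot2::theme_minimal()
  if (!is.null(individual)) {
    xi <- seq_along(individual)
    sgn <- if (individual_group == "a") 1 else -1
    disp <- if (individual_group == "a") summary_a$display_length
            else summary_b$display_length
    if (proportional) xi <- xi / max(xi) * disp
    p <- p + ggplot2::geom_line(
      data = tibble(x = xi, y = sgn * individual),
      ggplot2::aes(x = .data$x, y = .data$y),
      color = kinegraph_group_colors["individual"], linewidth = 0.4)
  }
  p
}

#' Per-angle mean +/- sd band summary
#'
#' One panel per angle (display-rank order) with each group's mean curve
#' and its +/- one standard deviation band, plus an optional individual's
#' curves in black.
#'
#' @param summaries tibble with columns `angle` (id), `group` ("stroke" /
#'   "control") and `summary` (list of `group_summary`).
#' @param angles angle metadata tibble.
#' @param individual optional tibble with `angle`, `values` (list column)
#'   for the highlighted individual.
#' @return a ggplot object (facetted).
#' @export
plot_band_summary <- function(summaries, angles, individual = NULL) {
  rank_of <- setNames(angles$display_rank, angles$id)
  name_of <- setNames(angles$name, angles$id)
  curves <- purrr::pmap(
    list(summaries$angle, summaries$group, summaries$summary),
    function(a, g, s) {
      mutate(s$curve, angle = a, group = g,
             panel = stats::reorder(name_of[[as.character(a)]],
                                    rank_of[[as.character(a)]]))
    }
  ) |> bind_rows()
  curves$panel <- stats::reorder(curves$panel,
                                 rank_of[as.character(curves$angle)])
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$t, y = .data$mean,
                                    color = .data$group,
                                    fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_color_manual(values = kinegraph_group_colors) +
    ggplot2::scale_fill_manual(values = kinegraph_group_colors) +
    ggplot2::labs(x = "time step", y = "angle (deg)") +
    ggplot2::theme_minimal()
  if (!is.null(individual)) {
    ind <- purrr::pmap(list(individual$angle, individual$values),
                       function(a, v) {
                         tibble(t = seq_along(v), y = v, angle = a)
                       }) |> bind_rows()
    ind$panel <- stats::reorder(name_of[as.character(ind$angle)],
                                rank_of[as.character(ind$angle)])
    p <- p + ggplot2::geom_line(
      data = ind, ggplot2::aes(x = .data$t, y = .data$y),
      inherit.aes = FALSE, color = kinegraph_group_colors["individual"],
      linewidth = 0.4)
  }
  p
}

#' Impairment-scaled radius map
#'
#' Affine-decreasing map from FMA total score to marker radius over the
#' cohort's observed score range: the most impaired participant gets the
#' largest marker. Missing scores get the midpoint radius (with a warning
#' for stroke participants, whose score is expected).
#'
#' @param fma_total integer vector (NA allowed).
#' @param group group labels, used only for the missing-score warning.
#' @param radius_range output radius range.
#' @return numeric radius vector.
#' @export
fma_radius <- function(fma_total, group = NULL,
                       radius_range = c(1.5, 6)) {
  obs <- range(fma_total, na.rm = TRUE)
  r <- if (diff(obs) == 0) {
    rep(mean(radius_range), length(fma_total))
  } else {
    radius_range[2] - (fma_total - obs[1]) / diff(obs) * diff(radius_range)
  }
  if (anyNA(fma_total)) {
    if (!is.null(group) && any(is.na(fma_total) & group == "stroke")) {
      warn("missing FMA score for stroke participant(s); using default radius")
    }
    r[is.na(r)] <- mean(radius_range)
  }
  r
}

#' Projection scatter plot
#'
#' One marker per participant-side: color by group (green control, red
#' stroke), radius affine-decreasing in the FMA total score (larger =
#' more impaired).
#'
#' @param coords tibble from [project_cohort()].
#' @return a ggplot object.
#' @export
plot_projection <- function(coords) {
  coords$radius <- fma_radius(coords$fma_total, coords$group)
  ggplot2::ggplot(coords,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               color = .data$group, size = .data$radius)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = kinegraph_group_colors) +
    ggplot2::scale_size_identity() +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
}

#' Render views to SVG files
#'
#' Thin wrappers writing the corresponding plot as an SVG document.
#'
#' @param path output file.
#' @param ... arguments passed to the plot builder.
#' @param width,height device size in inches.
#' @return `path`, invisibly.
#' @export
render_arc_diagram <- function(path, ..., width = 9, height = 5) {
  save_svg(plot_arc_diagram(...), path, width, height)
}

#' @rdname render_arc_diagram
#' @export
render_mirrored_comparison <- function(path, ..., width = 8, height = 5) {
  save_svg(plot_mirrored_comparison(...), path, width, height)
}

#' @rdname render_arc_diagram
#' @export
render_band_summary <- function(path, ..., width = 10, height = 7) {
  save_svg(plot_band_summary(...), path, width, height)
}

#' @rdname render_arc_diagram
#' @export
render_projection <- function(path, ..., width = 6, height = 5) {
  save_svg(plot_projection(...), path, width, height)
}

#' Autoplot methods
#'
#' `autoplot()` on a projection tibble draws the scatter; on a
#' `motion_network` it draws the network's arc diagram.
#'
#' @param object object to plot.
#' @param angles angle metadata for networks.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @exportS3Method ggplot2::autoplot
autoplot.motion_network <- function(object, angles = NULL, ...) {
  n <- nrow(object$weights)
  if (is.null(angles)) {
    angles <- tibble(id = seq_len(n), name = paste0("a", seq_len(n)),
                     display_rank = seq_len(n))
  }
  arcs <- mutate(object$edges, support = .data$weight, class = "shared")
  plot_arc_diagram(arcs, angles)
}

#' @export
ggplot2::autoplot
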