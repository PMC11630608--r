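# Network figures. The drawing decisions (node shades, which edges pass the
# threshold, arrow widths, colours) are computed by pure "frame" functions so
# they can be inspected and tested; rendering is a thin igraph/ggplot2 layer
# on top.

# four colour-blind-safe fills for the diagram node classes (Okabe-Ito)
NODE_TYPE_PALETTE <- c("#E69F00", "#56B4E9", "#009E73", "#F0E442")

#' Rendering options
#'
#' @param font_scale multiplier for node label size (default 0.7).
#' @param arrow_scale multiplier for edge widths (default 4).
#' @param threshold on the -4..4 change scale: in flow diagrams only nodes
#'   whose absolute change exceeds this draw their outgoing edges
#'   (default 0.2).
#' @param layout one of "grid", "sphere", "circle", "random",
#'   "fruchterman_reingold"; grid preserves the input node order.
#' @param format figure format, "pdf", "png" or "svg".
#' @param overwrite overwrite existing files (default TRUE; set FALSE to
#'   error instead of silently replacing a figure).
#' @return a `bbn_render_options` list.
#' @export
render_options <- function(font_scale = 0.7, arrow_scale = 4,
                           threshold = 0.2,
                           layout = c("grid", "sphere", "circle", "random",
                                      "fruchterman_reingold"),
                           format = c("pdf", "png", "svg"),
                           overwrite = TRUE) {
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (threshold < 0 || threshold > 4) {
    stop("`threshold` must lie in [0, 4]", call. = FALSE)
  }
  stopifnot(font_scale > 0, arrow_scale > 0)
  structure(list(font_scale = font_scale, arrow_scale = arrow_scale,
                 threshold = threshold, layout = layout, format = format,
                 overwrite = overwrite),
            class = "bbn_render_options")
}

igraph_layout <- function(g, layout) {
  switch(layout,
         grid = igraph::layout_on_grid(g),
         sphere = igraph::layout_on_sphere(g),
         circle = igraph::layout_in_circle(g),
         random = igraph::layout_randomly(g),
         fruchterman_reingold = igraph::layout_with_fr(g))
}

check_output_path <- function(path, overwrite) {
  if (!overwrite && file.exists(path)) {
    stop("output file exists and overwrite = FALSE: ", path, call. = FALSE)
  }
  path
}

save_figure <- function(p, path, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext, pdf = grDevices::pdf, png = function(file, width, height) {
    grDevices::png(file, width = width * 96, height = height * 96)
  }, svg = grDevices::svg,
  stop("unsupported figure format: ", ext, call. = FALSE))
  dev(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(p)
  invisible(path)
}

#' Drawing data for one timestep of an information-flow diagram
#'
#' Node shading is *ordinal*: nodes are ranked by their change value at the
#' timestep, the largest increase is pure black (grey level 0), the smallest
#' (possibly a decrease) pure white (grey level 1), intermediate ranks are
#' linearly interpolated and ties share a shade. If every node is tied the
#' whole network is mid-grey. An edge is drawn only when its *source* node's
#' absolute change exceeds the threshold; drawn widths are
#' `|strength| * arrow_scale` (relative units).
#'
#' @param network the `bbn_network` the timeseries was computed on.
#' @param ts a `bbn_timeseries` from [bbn_timeseries()].
#' @param t timestep index (column of `ts$values`).
#' @param opts a [render_options()] object.
#' @return list with data.frames `nodes` (node, change, rank, grey) and
#'   `edges` (parent, child, strength, width, drawn).
#' @export
flow_frame <- function(network, ts, t, opts = render_options()) {
  stopifnot(inherits(ts, "bbn_timeseries"),
            t >= 1, t <= ncol(ts$values))
  if (!identical(rownames(ts$values), network$nodes)) {
    stop("timeseries was not computed on this network", call. = FALSE)
  }
  change <- ts$values[, t]
  rk <- rank(change, ties.method = "average")
  if (max(rk) == min(rk)) {
    grey <- rep(0.5, length(rk))
  } else {
    # largest increase -> rank max -> grey 0 (black); smallest -> 1 (white)
    grey <- 1 - (rk - min(rk)) / (max(rk) - min(rk))
  }
  nodes <- data.frame(node = network$nodes, change = unname(change),
                      rank = unname(rk), grey = unname(grey))
  edges <- network$edges
  edges$width <- abs(edges$strength) * opts$arrow_scale
  src_change <- change[edges$parent]
  edges$drawn <- abs(src_change) > opts$threshold
  list(nodes = nodes, edges = edges)
}

#' Render information flow through the network, one figure per timestep
#'
#' @param network a `bbn_network`.
#' @param ts a `bbn_timeseries` computed on the same network.
#' @param opts a [render_options()] object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, default "flow".
#' @return character vector of the files written, invisibly.
#' @export
bbn_visualise <- function(network, ts, opts = render_options(),
                          dir = ".", prefix = "flow") {
  stopifnot(inherits(network, "bbn_network"), inherits(ts, "bbn_timeseries"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- igraph::graph_from_data_frame(
    network$edges[c("parent", "child")], directed = TRUE,
    vertices = network$nodes)
  lay <- igraph_layout(g, opts$layout)
  files <- character(0)
  for (t in seq_len(ncol(ts$values))) {
    fr <- flow_frame(network, ts, t, opts)
    path <- file.path(dir, sprintf("%s_t%02d.%s", prefix, t, opts$format))
    check_output_path(path, opts$overwrite)
    open_device(path)
    keep <- fr$edges$drawn
    igraph::plot.igraph(
      g, layout = lay,
      vertex.color = grDevices::grey(fr$nodes$grey),
      vertex.label.cex = opts$font_scale,
      vertex.label.color = "#555555",
      edge.width = ifelse(keep, fr$edges$width / 4, 0),
      edge.color = ifelse(keep,
                          ifelse(fr$edges$strength < 0, "red", "black"),
                          NA),
      edge.arrow.size = 0.5,
      main = sprintf("timestep %d", t))
    grDevices::dev.off()
    files <- c(files, path)
  }
  invisible(files)
}

open_device <- function(path, width = 7, height = 7) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         pdf = grDevices::pdf(path, width = width, height = height),
         png = grDevices::png(path, width = width * 96, height = height * 96),
         svg = grDevices::svg(path, width = width, height = height),
         stop("unsupported figure format: ", ext, call. = FALSE))
}

#' Drawing data for a full network diagram
#'
#' All nodes and all edges are drawn: node fill comes from the node's colour
#' class (1..4, a colour-blind-safe palette), edge colour from the sign of
#' the interaction (red negative, black positive) and edge width is
#' proportional to `|strength| * arrow_scale`.
#'
#' @param dn a `bbn_diagram_network`.
#' @param opts a [render_options()] object.
#' @return list with data.frames `nodes` (node, id, node_type, fill) and
#'   `edges` (parent, child, strength, width, colour).
#' @export
diagram_frame <- function(dn, opts = render_options()) {
  stopifnot(inherits(dn, "bbn_diagram_network"))
  nodes <- data.frame(node = dn$nodes, id = dn$id, node_type = dn$node_type,
                      fill = NODE_TYPE_PALETTE[dn$node_type])
  edges <- dn$edges
  edges$width <- abs(edges$strength) * opts$arrow_scale
  edges$colour <- ifelse(edges$strength < 0, "red", "black")
  list(nodes = nodes, edges = edges)
}

#' Render the full network diagram
#'
#' @param dn a `bbn_diagram_network` (see [read_diagram_network()]).
#' @param opts a [render_options()] object; `layout = "grid"` keeps nodes in
#'   input order, the other layouts are igraph's.
#' @param path output file; extension should match `opts$format`.
#' @return `path`, invisibly.
#' @export
bbn_network_diagram <- function(dn, opts = render_options(layout = "sphere"),
                                path = paste0("network_diagram.", opts$format)) {
  fr <- diagram_frame(dn, opts)
  check_output_path(path, opts$overwrite)
  g <- igraph::graph_from_data_frame(
    dn$edges[c("parent", "child")], directed = TRUE, vertices = dn$nodes)
  lay <- igraph_layout(g, opts$layout)
  open_device(path)
  igraph::plot.igraph(
    g, layout = lay,
    vertex.color = fr$nodes$fill,
    vertex.label.cex = opts$font_scale,
    edge.width = fr$edges$width / 4,
    edge.color = fr$edges$colour,
    edge.arrow.size = 0.5)
  grDevices::dev.off()
  invisible(path)
}

#' Plot predictions for up to 12 scenarios on one figure
#'
#' One panel per scenario (panels fill column-major: scenario 2 sits below
#' scenario 1), each a horizontal point chart of change per node, with error
#' bars when bootstrap confidence intervals are present.
#'
#' @param results a `bbn_prediction` or list of them (1..12).
#' @param path optional output file; NULL returns the ggplot object.
#' @return the ggplot object (invisibly when written).
#' @export
plot_predictions <- function(results, path = NULL) {
  if (inherits(results, "bbn_prediction")) results <- list(results)
  if (length(results) < 1L) stop("nothing to plot", call. = FALSE)
  if (length(results) > 12L) {
    stop("combined plotting supports at most 12 scenarios", call. = FALSE)
  }
  nodes <- names(results[[1]]$change)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(scenario = r$scenario_name, node = nodes,
               change = unname(r$change[nodes]),
               ci_low = if (is.null(r$ci_low)) NA_real_ else unname(r$ci_low[nodes]),
               ci_high = if (is.null(r$ci_high)) NA_real_ else unname(r$ci_high[nodes]))
  }))
  df$scenario <- factor(df$scenario, levels = unique(df$scenario))
  df$node <- factor(df$node, levels = rev(nodes))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = change, y = node)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60")
  if (any(!is.na(df$ci_low))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = ci_low, xmax = ci_high),
      height = 0.3, na.rm = TRUE)
  }
  p <- p + ggplot2::geom_point() +
    ggplot2::facet_wrap(~scenario, dir = "v") +
    ggplot2::coord_cartesian(xlim = c(-4, 4)) +
    ggplot2::labs(x = "predicted change (-4..4)", y = NULL) +
    ggplot2::theme_bw()
  if (is.null(path)) return(p)
  save_figure(p, path, width = 8, height = 6)
  invisible(p)
}
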