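#' Build the Sankey Node/Flow/Stage graph from trajectories
#'
#' The Sankey model has three parts: Nodes (severity categories at a cycle),
#' Flows (patient transitions between consecutive cycles), and Stages (the
#' cycles themselves). Node counts are the marginal state frequencies per
#' stage; link counts are the joint frequencies of consecutive-stage state
#' pairs. Three conservation identities hold by construction: node counts at
#' every stage sum to the cohort size; outflow from every non-terminal node
#' equals its count; inflow into every non-initial node equals its count.
#'
#' @param trajectories A rectangular [trajectory_matrix()] with at least one
#'   patient and at least two stages.
#' @return An object of class `flow_graph` with elements `stages`, `states`
#'   (full scale, zero-count states retained), `total`, `node_counts`
#'   (stages x states integer matrix) and `link_counts` (list of
#'   states x states matrices, one per consecutive stage pair).
#' @export
build_flow_graph <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_matrix"))
  st <- trajectories$states
  if (nrow(st) < 1L) {
    stop("at least one patient is required", call. = FALSE)
  }
  if (ncol(st) < 2L) {
    stop("at least two stages are required: no flows are definable on a ",
         "single stage", call. = FALSE)
  }
  states <- scale_states(trajectories$scale)
  S <- ncol(st)
  node_counts <- t(vapply(seq_len(S), function(s) {
    as.integer(table(factor(st[, s], levels = states)))
  }, integer(length(states))))
  dimnames(node_counts) <- list(trajectories$stages, states)
  link_counts <- lapply(seq_len(S - 1L), function(s) {
    m <- table(factor(st[, s], levels = states),
               factor(st[, s + 1L], levels = states))
    matrix(as.integer(m), nrow = length(states),
           dimnames = list(states, states))
  })
  structure(
    list(stages = trajectories$stages, states = states,
         total = nrow(st), node_counts = node_counts,
         link_counts = link_counts, scale = trajectories$scale),
    class = "flow_graph"
  )
}

#' @export
print.flow_graph <- function(x, ...) {
  cat("<flow_graph> ", x$total, " patients | ", length(x$stages),
      " stages | ", length(x$states), " states\n", sep = "")
  print(x$node_counts)
  invisible(x)
}

#' Serialize a flow graph to JSON
#'
#' Nodes are emitted for the full scale (zero counts retained so downstream
#' consumers see every category); links are emitted where patients actually
#' flowed.
#'
#' @param graph A [build_flow_graph()] result.
#' @param path Optional output file; if `NULL`, the JSON string is returned.
#' @return JSON string, or `path` invisibly when writing.
#' @export
flow_graph_json <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "flow_graph"))
  nodes <- tidyr::expand_grid(stage = graph$stages, state = graph$states)
  nodes$count <- as.integer(graph$node_counts[cbind(
    match(nodes$stage, graph$stages), match(nodes$state, graph$states))])
  links <- dplyr::bind_rows(lapply(seq_along(graph$link_counts), function(s) {
    m <- graph$link_counts[[s]]
    idx <- which(m > 0, arr.ind = TRUE)
    tibble::tibble(stage_index = s,
                   from = rownames(m)[idx[, 1]],
                   to = colnames(m)[idx[, 2]],
                   count = as.integer(m[idx]))
  }))
  if (nrow(links)) {
    links <- dplyr::arrange(links, .data$stage_index,
                            match(.data$from, graph$states),
                            match(.data$to, graph$states))
  }
  obj <- list(stages = graph$stages, nodes = nodes, links = links,
              total = graph$total)
  if (is.null(path)) {
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            dataframe = "rows"))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# Deterministic palette keyed by scale-level index: a diverging
# green-to-red ramp for severity levels, grey for the missing category.
sankey_palette <- function(scale) {
  n <- length(scale$levels)
  cols <- if (n == 1L) "#1B7837" else
    grDevices::hcl.colors(n, palette = "RdYlGn", rev = TRUE)
  stats::setNames(c(cols, "#B3B3B3"), c(scale$levels, scale$missing_level))
}

# Geometry shared by the SVG and PNG renderers. Nodes within a stage are
# ordered most-severe at top to least at bottom, with the missing level
# pinned last; zero-count nodes are omitted (no zero-height artifacts).
# Returns node rectangles and link ribbons in pixel coordinates.
sankey_layout <- function(graph, scale, width = NULL, height = 480,
                          node_width = 18, gap = 8,
                          margin = c(top = 44, right = 90, bottom = 34,
                                     left = 56)) {
  display <- c(rev(scale$levels), scale$missing_level)
  S <- length(graph$stages)
  if (is.null(width)) width <- max(420, 130 * S)
  plot_h <- height - margin[["top"]] - margin[["bottom"]]
  xs <- margin[["left"]] +
    (seq_len(S) - 0.5) / S * (width - margin[["left"]] - margin[["right"]])

  node_rows <- list()
  y_ranges <- vector("list", S)  # per stage: named list state -> c(y0, y1)
  units <- numeric(S)
  for (s in seq_len(S)) {
    counts <- graph$node_counts[s, display]
    present <- names(counts)[counts > 0]
    k <- length(present)
    unit <- (plot_h - gap * max(k - 1L, 0L)) / graph$total
    units[s] <- unit
    y <- margin[["top"]]
    rng <- list()
    for (state in present) {
      h <- counts[[state]] * unit
      node_rows[[length(node_rows) + 1L]] <- tibble::tibble(
        stage = graph$stages[s], stage_index = s, state = state,
        count = as.integer(counts[[state]]),
        x0 = xs[s] - node_width / 2, x1 = xs[s] + node_width / 2,
        y0 = y, y1 = y + h
      )
      rng[[state]] <- c(y, y + h)
      y <- y + h + gap
    }
    y_ranges[[s]] <- rng
  }
  nodes <- dplyr::bind_rows(node_rows)

  link_rows <- list()
  for (s in seq_len(S - 1L)) {
    m <- graph$link_counts[[s]]
    src_off <- stats::setNames(
      vapply(y_ranges[[s]], `[`, numeric(1), 1L), names(y_ranges[[s]]))
    dst_off <- stats::setNames(
      vapply(y_ranges[[s + 1L]], `[`, numeric(1), 1L),
      names(y_ranges[[s + 1L]]))
    for (a in display) {
      if (is.null(y_ranges[[s]][[a]])) next
      for (b in display) {
        cnt <- m[a, b]
        if (cnt == 0L || is.null(y_ranges[[s + 1L]][[b]])) next
        h_src <- cnt * units[s]
        h_dst <- cnt * units[s + 1L]
        link_rows[[length(link_rows) + 1L]] <- tibble::tibble(
          stage_index = s, from = a, to = b, count = as.integer(cnt),
          x0 = xs[s] + node_width / 2, x1 = xs[s + 1L] - node_width / 2,
          ys0 = src_off[[a]], ys1 = src_off[[a]] + h_src,
          yt0 = dst_off[[b]], yt1 = dst_off[[b]] + h_dst
        )
        src_off[[a]] <- src_off[[a]] + h_src
        dst_off[[b]] <- dst_off[[b]] + h_dst
      }
    }
  }
  links <- if (length(link_rows)) dplyr::bind_rows(link_rows) else
    tibble::tibble(stage_index = integer(), from = character(),
                   to = character(), count = integer(), x0 = numeric(),
                   x1 = numeric(), ys0 = numeric(), ys1 = numeric(),
                   yt0 = numeric(), yt1 = numeric())
  list(nodes = nodes, links = links, width = width, height = height,
       xs = xs, margin = margin, display = display)
}

sankey_svg <- function(graph, scale, title = "") {
  lay <- sankey_layout(graph, scale)
  pal <- sankey_palette(scale)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- c(
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                   'height="%s" viewBox="0 0 %s %s">'),
            fmt_num(lay$width), fmt_num(lay$height),
            fmt_num(lay$width), fmt_num(lay$height)),
    '<rect width="100%" height="100%" fill="white"/>',
    if (nzchar(title)) sprintf(
      paste0('<text x="%s" y="24" font-family="sans-serif" font-size="15" ',
             'text-anchor="middle" font-weight="bold">%s</text>'),
      fmt_num(lay$width / 2), esc(title))
  )
  for (i in seq_len(nrow(lay$links))) {
    l <- lay$links[i, ]
    mid <- (l$x0 + l$x1) / 2
    d <- sprintf("M %s %s C %s %s %s %s %s %s L %s %s C %s %s %s %s %s %s Z",
                 fmt_num(l$x0), fmt_num(l$ys0), fmt_num(mid), fmt_num(l$ys0),
                 fmt_num(mid), fmt_num(l$yt0), fmt_num(l$x1), fmt_num(l$yt0),
                 fmt_num(l$x1), fmt_num(l$yt1), fmt_num(mid), fmt_num(l$yt1),
                 fmt_num(mid), fmt_num(l$ys1), fmt_num(l$x0), fmt_num(l$ys1))
    out <- c(out, sprintf('<path d="%s" fill="%s" fill-opacity="0.45"/>',
                          d, pal[[l$from]]))
  }
  for (i in seq_len(nrow(lay$nodes))) {
    n <- lay$nodes[i, ]
    out <- c(out, sprintf(
      paste0('<rect x="%s" y="%s" width="%s" height="%s" fill="%s" ',
             'stroke="black" stroke-width="0.5"/>'),
      fmt_num(n$x0), fmt_num(n$y0), fmt_num(n$x1 - n$x0),
      fmt_num(n$y1 - n$y0), pal[[n$state]]))
    out <- c(out, sprintf(
      paste0('<text x="%s" y="%s" font-family="sans-serif" font-size="9" ',
             'dominant-baseline="middle">%s (%d)</text>'),
      fmt_num(n$x1 + 4), fmt_num((n$y0 + n$y1) / 2), esc(n$state), n$count))
  }
  for (s in seq_along(graph$stages)) {
    out <- c(out, sprintf(
      paste0('<text x="%s" y="%s" font-family="sans-serif" font-size="11" ',
             'text-anchor="middle">%s</text>'),
      fmt_num(lay$xs[s]), fmt_num(lay$height - 12),
      esc(graph$stages[s])))
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

# Cubic-bezier band approximated as a polygon for raster output.
bezier_band <- function(l, n = 40) {
  t <- seq(0, 1, length.out = n)
  ease <- (1 - t)^3 * 0 + 3 * (1 - t)^2 * t * 0.5 + 3 * (1 - t) * t^2 * 0.5 +
    t^3 * 1
  x <- l$x0 + t * (l$x1 - l$x0)
  top <- l$ys0 + ease * (l$yt0 - l$ys0)
  bot <- l$ys1 + ease * (l$yt1 - l$ys1)
  tibble::tibble(x = c(x, rev(x)), y = c(top, rev(bot)))
}

#' Render a flow graph as a Sankey diagram
#'
#' Node heights are proportional to node counts and band widths to link
#' counts. Nodes within a stage run most-severe at top to least at bottom,
#' with the missing level pinned last; colors are assigned deterministically
#' by level index. SVG is the canonical target: rendering the same graph
#' twice yields byte-identical files. PNG is rasterised from the same
#' layout; HTML embeds the SVG in a minimal standalone page.
#'
#' @param graph A [build_flow_graph()] result with at least one patient.
#' @param scale Scale governing ordering and colors; defaults to the scale
#'   the graph was built from.
#' @param title Figure title.
#' @param out Output file path.
#' @param format One of `"svg"`, `"png"`, `"html"`.
#' @return `out`, invisibly.
#' @export
render_sankey <- function(graph, scale = graph$scale, title = "", out,
                          format = c("svg", "png", "html")) {
  stopifnot(inherits(graph, "flow_graph"))
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unsupported format: ",
                                              format[1], call. = FALSE))
  if (graph$total == 0L || sum(graph$node_counts) == 0L) {
    stop("cannot render a zero-count graph", call. = FALSE)
  }
  if (format %in% c("svg", "html")) {
    svg <- sankey_svg(graph, scale, title)
    txt <- if (format == "html") {
      paste0("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/>",
             "<title>", title, "</title></head><body>\n", svg,
             "\n</body></html>")
    } else svg
    con <- file(out, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(paste0(txt, "\n")), con)
    return(invisible(out))
  }
  # png
  lay <- sankey_layout(graph, scale)
  pal <- sankey_palette(scale)
  bands <- dplyr::bind_rows(lapply(seq_len(nrow(lay$links)), function(i) {
    b <- bezier_band(lay$links[i, ])
    b$id <- i
    b$from <- lay$links$from[i]
    b
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = bands,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$id,
                   fill = .data$from),
      alpha = 0.45, show.legend = FALSE) +
    ggplot2::geom_rect(
      data = lay$nodes,
      ggplot2::aes(xmin = .data$x0, xmax = .data$x1, ymin = .data$y0,
                   ymax = .data$y1, fill = .data$state),
      colour = "black", linewidth = 0.25, show.legend = FALSE) +
    ggplot2::geom_text(
      data = lay$nodes,
      ggplot2::aes(x = .data$x1 + 4, y = (.data$y0 + .data$y1) / 2,
                   label = paste0(.data$state, " (", .data$count, ")")),
      hjust = 0, size = 2.6) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_x_continuous(
      breaks = lay$xs, labels = graph$stages,
      limits = c(0, lay$width)) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
  grDevices::png(out, width = lay$width * 2, height = lay$height * 2,
                 res = 150, type = "cairo")
  print(p)
  grDevices::dev.off()
  invisible(out)
}
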