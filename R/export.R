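#' Export a layout scene
#'
#' `"json"` writes a lossless scene description (re-import with
#' [read_scene()] reproduces all numeric fields to full double precision).
#' `"svg"` and `"png"` draw an orthographic projection along the cylinder
#' axis: columns collapse to points on the layout circle, residue sub-nodes
#' are drawn as concentric circles with radius encoding population
#' fraction, and edges are chords with opacity mapped linearly from their
#' residual over `[tr_min, 0.25]`. `"x3d"` embeds the 3D geometry (spheres
#' and an indexed line set) for external 3D viewers.
#'
#' @param scene a `coev_scene`.
#' @param path output path.
#' @param format `"json"`, `"svg"`, `"x3d"` or `"png"`.
#' @param width,height raster size in pixels (png only).
#' @return `path`, invisibly.
#' @export
export_scene <- function(scene, path, format = c("json", "svg", "x3d", "png"),
                         width = 800, height = 800) {
  format <- match.arg(format)
  stopifnot(inherits(scene, "coev_scene"))
  switch(format,
         json = export_scene_json(scene, path),
         svg = export_scene_svg(scene, path),
         x3d = export_scene_x3d(scene, path),
         png = export_scene_png(scene, path, width, height))
  invisible(path)
}

export_scene_json <- function(scene, path) {
  payload <- list(
    format = "coevnet-scene",
    version = 1L,
    note = "coordinates: angle in radians, axial in layout units; columns are 1-based",
    geometry = scene$geometry,
    n_marker = scene$n_marker,
    nodes = scene$nodes,
    edges = scene$edges
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
}

#' Re-import a scene written by [export_scene()] in JSON format
#'
#' @param path path to a scene JSON file.
#' @return A `coev_scene`.
#' @export
read_scene <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "coevnet-scene")) {
    stop("not a coevnet scene file: ", path, call. = FALSE)
  }
  nodes <- as.data.frame(p$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(p$edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), significance = numeric(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(geometry = p$geometry, nodes = nodes, edges = edges,
                 n_marker = p$n_marker),
            class = "coev_scene")
}

## opacity for an edge weight, linear over [tr_min, 0.25], clamped to
## [0.15, 1] so the weakest displayed links remain visible
edge_opacity <- function(weight, tr_min) {
  span <- max(0.25 - tr_min, 1e-9)
  pmin(1, pmax(0.15, 0.15 + 0.85 * (abs(weight) - tr_min) / span))
}

## significance band -> color (stronger significance darker)
edge_color <- function(p) {
  ifelse(p <= 0.005, "#99000d",
  ifelse(p <= 0.01,  "#cb181d",
  ifelse(p <= 0.05,  "#ef3b2c", "#fc9272")))
}

scene_xy <- function(scene) {
  r <- scene$geometry$radius
  list(x = r * cos(scene$nodes$angle), y = r * sin(scene$nodes$angle))
}

export_scene_svg <- function(scene, path) {
  r <- scene$geometry$radius
  pad <- 1.2
  scale <- 400 / (pad * r)
  cx <- function(x) 500 + x * scale
  cy <- function(y) 500 - y * scale
  xy <- scene_xy(scene)
  nodes <- scene$nodes
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="1000" height="1000" viewBox="0 0 1000 1000">',
    '<!-- orthographic projection along the cylinder axis; columns are 1-based -->',
    sprintf('<circle cx="500" cy="500" r="%.2f" fill="none" stroke="#dddddd"/>', r * scale)
  )
  ## edges first so nodes draw on top
  if (nrow(scene$edges) > 0L) {
    from_idx <- match(scene$edges$from, nodes$key)
    to_idx <- match(scene$edges$to, nodes$key)
    op <- edge_opacity(scene$edges$weight, scene$geometry$tr_min)
    col <- edge_color(scene$edges$significance)
    lines <- c(lines, '<g class="edges">',
               sprintf('<line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="%s" stroke-opacity="%.3f" stroke-width="1.5"/>',
                       cx(xy$x[from_idx]), cy(xy$y[from_idx]),
                       cx(xy$x[to_idx]), cy(xy$y[to_idx]), col, op),
               '</g>')
  }
  for (col_id in sort(unique(nodes$column))) {
    sel <- nodes$column == col_id
    sub <- nodes[sel, , drop = FALSE]
    ord <- order(-sub$size)
    sub <- sub[ord, , drop = FALSE]
    lines <- c(lines,
               sprintf('<g class="column" id="col-%d">', col_id),
               sprintf('<circle cx="%.3f" cy="%.3f" r="%.3f" fill="#4477aa" fill-opacity="0.35" stroke="#223355" stroke-width="0.4"/>',
                       cx(xy$x[sel][ord]), cy(xy$y[sel][ord]),
                       pmax(1, sub$size * scale * 0.12)),
               '</g>')
  }
  ## N-terminal marker: arrow head at angle_offset pointing along the layout
  a0 <- scene$n_marker$angle
  dir_sign <- if (identical(scene$n_marker$direction, "clockwise")) -1 else 1
  tip <- c(cx(1.1 * r * cos(a0 + dir_sign * 0.12)),
           cy(1.1 * r * sin(a0 + dir_sign * 0.12)))
  base <- c(cx(1.1 * r * cos(a0)), cy(1.1 * r * sin(a0)))
  lines <- c(lines,
             sprintf('<g class="n-marker"><line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="#000000" stroke-width="2"/><circle cx="%.2f" cy="%.2f" r="4" fill="#000000"/></g>',
                     base[1], base[2], tip[1], tip[2], tip[1], tip[2]),
             '</svg>')
  writeLines(lines, path)
}

export_scene_png <- function(scene, path, width, height) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  plot_scene(scene)
}

#' Plot an axial projection of a scene on the current device
#'
#' @param scene a `coev_scene`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_scene <- function(scene, ...) {
  r <- scene$geometry$radius
  xy <- scene_xy(scene)
  graphics::plot(NA, xlim = c(-1.3, 1.3) * r, ylim = c(-1.3, 1.3) * r,
                 asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(r * cos(th), r * sin(th), col = "grey85")
  if (nrow(scene$edges) > 0L) {
    fi <- match(scene$edges$from, scene$nodes$key)
    ti <- match(scene$edges$to, scene$nodes$key)
    op <- edge_opacity(scene$edges$weight, scene$geometry$tr_min)
    col <- edge_color(scene$edges$significance)
    graphics::segments(xy$x[fi], xy$y[fi], xy$x[ti], xy$y[ti],
                       col = grDevices::adjustcolor(col, alpha.f = 1) ,
                       lwd = 0.5 + 2 * op)
  }
  graphics::points(xy$x, xy$y, cex = 2.5 * scene$nodes$size,
                   pch = 21, bg = grDevices::adjustcolor("#4477aa", 0.35),
                   col = "#223355")
  a0 <- scene$n_marker$angle
  graphics::arrows(1.15 * r * cos(a0), 1.15 * r * sin(a0),
                   1.15 * r * cos(a0 + 0.25), 1.15 * r * sin(a0 + 0.25),
                   length = 0.08)
  invisible(scene)
}

export_scene_x3d <- function(scene, path) {
  xy <- scene_xy(scene)
  nodes <- scene$nodes
  ## 3D: x = r cos(angle), z = r sin(angle), y = axial position
  coords <- sprintf("%.6f %.6f %.6f", xy$x, nodes$axial, xy$y)
  spheres <- sprintf(
    '<Transform translation="%s"><Shape><Appearance><Material diffuseColor="0.27 0.47 0.67" transparency="0.3"/></Appearance><Sphere radius="%.4f"/></Shape></Transform>',
    coords, pmax(0.05, nodes$size * 0.4))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<X3D profile="Interchange" version="3.3">',
    '<Scene>',
    spheres
  )
  if (nrow(scene$edges) > 0L) {
    fi <- match(scene$edges$from, nodes$key)
    ti <- match(scene$edges$to, nodes$key)
    pts <- paste(coords[rbind(fi, ti)], collapse = " ")
    idx <- paste(sprintf("%d %d -1", seq_along(fi) * 2L - 2L,
                         seq_along(fi) * 2L - 1L), collapse = " ")
    lines <- c(lines,
               '<Shape><IndexedLineSet coordIndex="', idx, '">',
               sprintf('<Coordinate point="%s"/>', pts),
               '</IndexedLineSet></Shape>')
  }
  lines <- c(lines, '</Scene>', '</X3D>')
  writeLines(lines, path)
}
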