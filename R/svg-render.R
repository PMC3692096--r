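#' Scene configuration
#'
#' Geometry and style constants shared by layout and rendering. Ring
#' radial thickness is equal for all rings of a glyph: the annulus between
#' `inner_radius` and `glyph_radius` is divided evenly.
#'
#' @param glyph_radius outer radius of a CircleMap glyph (scene units).
#' @param inner_radius radius of the central disc carrying the gene label.
#' @param shape_radius half-size of the plain shapes drawn for nodes
#'   without data (complexes, families, small molecules, processes).
#' @param node_sep minimum center-to-center distance enforced between
#'   laid-out nodes.
#' @param margin canvas margin around the layout bounding box.
#' @param missing_color fill for missing cells.
#' @param background canvas background color.
#' @param font_family label font.
#' @param stroke_width edge stroke width.
#' @param equal_width_segments aggregated segments all get equal angular
#'   extent instead of extents proportional to group size.
#' @return a list of class `scene_config`.
#' @export
scene_config <- function(glyph_radius = 60, inner_radius = 18, shape_radius = 26,
                         node_sep = 2 * glyph_radius + 24, margin = 90,
                         missing_color = "#BBBBBB", background = "#FFFFFF",
                         font_family = "Helvetica", stroke_width = 2,
                         equal_width_segments = FALSE) {
  structure(list(glyph_radius = glyph_radius, inner_radius = inner_radius,
                 shape_radius = shape_radius, node_sep = node_sep, margin = margin,
                 missing_color = missing_color, background = background,
                 font_family = font_family, stroke_width = stroke_width,
                 equal_width_segments = equal_width_segments),
            class = "scene_config")
}

#' Deterministic force-directed graph layout
#'
#' Fruchterman-Reingold placement (via igraph) from a seed-determined
#' random initial configuration, run for a fixed iteration budget, followed
#' by a deterministic separation pass that pushes any two nodes closer than
#' `config$node_sep` apart until every pairwise distance clears the glyph
#' diameter. Identical (graph, seed, config) gives identical coordinates.
#'
#' @param graph a nonempty [pathway_graph].
#' @param seed integer seed.
#' @param config a [scene_config].
#' @return a `scene_layout`: coordinate matrix (rows named by node) plus
#'   canvas width/height.
#' @export
layout_graph <- function(graph, seed = 1L, config = scene_config()) {
  stopifnot(inherits(graph, "pathway_graph"))
  n <- nrow(graph$nodes)
  if (n == 0L) stop("cannot lay out an empty graph", call. = FALSE)
  nm <- graph$nodes$name
  if (n == 1L) {
    coords <- matrix(c(config$margin + config$glyph_radius,
                       config$margin + config$glyph_radius), 1L, 2L)
  } else {
    set.seed(as.integer(seed))
    init <- matrix(stats::runif(2L * n, -1, 1), ncol = 2L)
    ig <- igraph::graph_from_data_frame(
      unique(graph$edges[, c("from", "to")]),
      directed = FALSE,
      vertices = data.frame(name = nm)
    )
    coords <- igraph::layout_with_fr(ig, coords = init, niter = 500L,
                                     start.temp = sqrt(n))
    # spread to physical units before enforcing separation
    rng <- apply(coords, 2L, function(v) diff(range(v)))
    scale <- config$node_sep * max(1, sqrt(n)) / max(rng, 1e-9)
    coords <- coords * scale
    coords <- .separate_nodes(coords, config$node_sep)
    coords[, 1L] <- coords[, 1L] - min(coords[, 1L]) + config$margin
    coords[, 2L] <- coords[, 2L] - min(coords[, 2L]) + config$margin
  }
  rownames(coords) <- nm
  structure(list(coords = coords,
                 width = max(coords[, 1L]) + config$margin,
                 height = max(coords[, 2L]) + config$margin + 40),
            class = "scene_layout")
}

# push overlapping node pairs apart along their connecting vector; a
# coincident pair is split along a direction fixed by its indices, so the
# pass is deterministic
.separate_nodes <- function(coords, d_min, max_pass = 400L) {
  n <- nrow(coords)
  for (pass in seq_len(max_pass)) {
    moved <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        dx <- coords[j, 1L] - coords[i, 1L]
        dy <- coords[j, 2L] - coords[i, 2L]
        d <- sqrt(dx^2 + dy^2)
        if (d >= d_min) next
        if (d < 1e-9) {
          ang <- 2 * pi * (i + j) / (2 * n)
          dx <- cos(ang); dy <- sin(ang); d <- 1
        }
        push <- (d_min - d) / 2 + 1e-6
        ux <- dx / d; uy <- dy / d
        coords[i, 1L] <- coords[i, 1L] - ux * push
        coords[i, 2L] <- coords[i, 2L] - uy * push
        coords[j, 1L] <- coords[j, 1L] + ux * push
        coords[j, 2L] <- coords[j, 2L] + uy * push
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  coords
}

.fmt <- function(x) sprintf("%.3f", x)

# point on a circle: angle in degrees clockwise from 12 o'clock
.polar <- function(cx, cy, r, ang) {
  a <- ang * pi / 180
  c(cx + r * sin(a), cy - r * cos(a))
}

# SVG path for an annular sector between radii r0 < r1 spanning
# [start, start + extent] degrees; a full turn becomes two joined
# half-annuli so the arc flags stay well-defined
.sector_path <- function(cx, cy, r0, r1, start, extent) {
  if (extent >= 360 - 1e-9) {
    p1 <- .polar(cx, cy, r1, 0); p2 <- .polar(cx, cy, r1, 180)
    q1 <- .polar(cx, cy, r0, 0); q2 <- .polar(cx, cy, r0, 180)
    return(paste0(
      "M", .fmt(p1[1]), ",", .fmt(p1[2]),
      " A", .fmt(r1), ",", .fmt(r1), " 0 0 1 ", .fmt(p2[1]), ",", .fmt(p2[2]),
      " A", .fmt(r1), ",", .fmt(r1), " 0 0 1 ", .fmt(p1[1]), ",", .fmt(p1[2]),
      " M", .fmt(q1[1]), ",", .fmt(q1[2]),
      " A", .fmt(r0), ",", .fmt(r0), " 0 0 0 ", .fmt(q2[1]), ",", .fmt(q2[2]),
      " A", .fmt(r0), ",", .fmt(r0), " 0 0 0 ", .fmt(q1[1]), ",", .fmt(q1[2]), " Z"))
  }
  large <- if (extent > 180) 1L else 0L
  a0 <- start; a1 <- start + extent
  o0 <- .polar(cx, cy, r1, a0); o1 <- .polar(cx, cy, r1, a1)
  i1 <- .polar(cx, cy, r0, a1); i0 <- .polar(cx, cy, r0, a0)
  paste0("M", .fmt(o0[1]), ",", .fmt(o0[2]),
         " A", .fmt(r1), ",", .fmt(r1), " 0 ", large, " 1 ", .fmt(o1[1]), ",", .fmt(o1[2]),
         " L", .fmt(i1[1]), ",", .fmt(i1[2]),
         " A", .fmt(r0), ",", .fmt(r0), " 0 ", large, " 0 ", .fmt(i0[1]), ",", .fmt(i0[2]),
         " Z")
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render one node as an SVG fragment
#'
#' Protein nodes carrying a glyph become a CircleMap: one filled
#' annular-sector path per cell (class `spoke` in full mode, `segment` in
#' aggregated mode), rings inner to outer, with the gene symbol centered
#' in the inner disc. Nodes without data render as entity-type-specific
#' plain shapes (complex: rectangle; family: dashed rectangle; small
#' molecule: diamond; process: ellipse; protein: circle).
#'
#' @param name node name.
#' @param type entity type.
#' @param glyph a [build_glyph] result or `NULL`.
#' @param layout a `scene_layout` containing the node.
#' @param config a [scene_config].
#' @return character vector of SVG lines wrapped in a `<g class="node">`.
#' @export
render_node <- function(name, type, glyph, layout, config = scene_config()) {
  if (!name %in% rownames(layout$coords))
    stop("node '", name, "' has no layout coordinates", call. = FALSE)
  cx <- layout$coords[name, 1L]
  cy <- layout$coords[name, 2L]
  out <- sprintf('<g class="node" data-name="%s" data-type="%s">',
                 .xml_escape(name), type)
  if (!is.null(glyph)) {
    cls <- if (glyph$mode == "full") "spoke" else "segment"
    k <- length(glyph$rings)
    thick <- (config$glyph_radius - config$inner_radius) / k
    geom <- glyph$geometry
    for (ri in seq_len(k)) {
      r0 <- config$inner_radius + (ri - 1L) * thick
      r1 <- r0 + thick
      cols <- glyph$rings[[ri]]$colors
      for (ci in seq_len(nrow(geom))) {
        out <- c(out, sprintf('<path class="%s" fill="%s" stroke="none" d="%s"/>',
                              cls, cols[ci],
                              .sector_path(cx, cy, r0, r1, geom$start[ci], geom$extent[ci])))
      }
    }
    out <- c(out,
             sprintf('<circle class="hub" cx="%s" cy="%s" r="%s" fill="#FFFFFF" stroke="#333333" stroke-width="0.8"/>',
                     .fmt(cx), .fmt(cy), .fmt(config$inner_radius)),
             sprintf('<circle class="rim" cx="%s" cy="%s" r="%s" fill="none" stroke="#333333" stroke-width="0.8"/>',
                     .fmt(cx), .fmt(cy), .fmt(config$glyph_radius)))
  } else {
    s <- config$shape_radius
    shape <- switch(type,
      complex = sprintf('<rect class="shape" x="%s" y="%s" width="%s" height="%s" fill="#EAEAEA" stroke="#333333"/>',
                        .fmt(cx - s), .fmt(cy - s * 0.6), .fmt(2 * s), .fmt(1.2 * s)),
      family = sprintf('<rect class="shape" x="%s" y="%s" width="%s" height="%s" fill="#F5F5F5" stroke="#333333" stroke-dasharray="4,3"/>',
                       .fmt(cx - s), .fmt(cy - s * 0.6), .fmt(2 * s), .fmt(1.2 * s)),
      smallmolecule = sprintf('<path class="shape" d="M%s,%s L%s,%s L%s,%s L%s,%s Z" fill="#EFEFEF" stroke="#333333"/>',
                              .fmt(cx), .fmt(cy - s), .fmt(cx + s), .fmt(cy),
                              .fmt(cx), .fmt(cy + s), .fmt(cx - s), .fmt(cy)),
      process = sprintf('<ellipse class="shape" cx="%s" cy="%s" rx="%s" ry="%s" fill="#F0F0F8" stroke="#333333"/>',
                        .fmt(cx), .fmt(cy), .fmt(1.2 * s), .fmt(0.7 * s)),
      sprintf('<circle class="shape" cx="%s" cy="%s" r="%s" fill="#F0F0F0" stroke="#333333"/>',
              .fmt(cx), .fmt(cy), .fmt(s))
    )
    out <- c(out, shape)
  }
  font <- max(8, round(config$inner_radius * 0.6))
  out <- c(out,
           sprintf('<text class="label" x="%s" y="%s" text-anchor="middle" dominant-baseline="middle" font-family="%s" font-size="%d">%s</text>',
                   .fmt(cx), .fmt(cy), config$font_family, font, .xml_escape(name)),
           "</g>")
  out
}

# rim-to-rim endpoints for an edge, with a perpendicular offset separating
# parallel edges between the same pair
.edge_endpoints <- function(p1, p2, r1, r2, offset) {
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  d <- sqrt(dx^2 + dy^2)
  if (d < 1e-9) { dx <- 1; dy <- 0; d <- 1 }
  ux <- dx / d; uy <- dy / d
  px <- -uy; py <- ux
  a <- c(p1[1] + ux * r1 + px * offset, p1[2] + uy * r1 + py * offset)
  b <- c(p2[1] - ux * r2 + px * offset, p2[2] - uy * r2 + py * offset)
  list(a = a, b = b, u = c(ux, uy), p = c(px, py))
}

#' Render one edge as an SVG fragment
#'
#' Activating edges end in an arrowhead, inhibiting edges in a T-bar (a
#' short perpendicular terminal segment); component/member edges are
#' dashed plain lines, undirected edges solid plain lines. The stroke
#' color is the edge's track color; edges run rim to rim, and parallel
#' edges between the same pair are offset so none coincides.
#'
#' @param edge one row of [graph_edges] (list or 1-row data.frame).
#' @param layout a `scene_layout`.
#' @param track_colors named color vector keyed by track name.
#' @param config a [scene_config].
#' @param node_radii named numeric vector of rim radii per node.
#' @param offset perpendicular offset in scene units for parallel-edge
#'   separation.
#' @return character vector of SVG lines wrapped in a `<g class="edge">`.
#' @export
render_edge <- function(edge, layout, track_colors, config = scene_config(),
                        node_radii = NULL, offset = 0) {
  edge <- as.list(edge)
  if (!edge$type %in% edge_types())
    stop("unknown edge type: ", edge$type, call. = FALSE)
  col <- track_colors[[edge$track]]
  if (is.null(col) || is.na(col))
    stop("no color configured for track '", edge$track, "'", call. = FALSE)
  p1 <- layout$coords[edge$from, ]
  p2 <- layout$coords[edge$to, ]
  r1 <- if (!is.null(node_radii)) node_radii[[edge$from]] else config$glyph_radius
  r2 <- if (!is.null(node_radii)) node_radii[[edge$to]] else config$glyph_radius
  ep <- .edge_endpoints(p1, p2, r1, r2, offset)
  dash <- if (edge$type %in% c("component", "member")) ' stroke-dasharray="7,4"' else ""
  out <- c(sprintf('<g class="edge" data-type="%s" data-track="%s">',
                   edge$type, .xml_escape(edge$track)),
           sprintf('<line class="edge-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"%s/>',
                   .fmt(ep$a[1]), .fmt(ep$a[2]), .fmt(ep$b[1]), .fmt(ep$b[2]),
                   col, .fmt(config$stroke_width), dash))
  hw <- 5 * config$stroke_width  # head size scales with stroke width
  if (edge$type == "activates") {
    tip <- ep$b
    base <- c(tip[1] - ep$u[1] * hw, tip[2] - ep$u[2] * hw)
    l <- c(base[1] + ep$p[1] * hw * 0.6, base[2] + ep$p[2] * hw * 0.6)
    r <- c(base[1] - ep$p[1] * hw * 0.6, base[2] - ep$p[2] * hw * 0.6)
    out <- c(out, sprintf('<path class="arrowhead" d="M%s,%s L%s,%s L%s,%s Z" fill="%s"/>',
                          .fmt(tip[1]), .fmt(tip[2]), .fmt(l[1]), .fmt(l[2]),
                          .fmt(r[1]), .fmt(r[2]), col))
  } else if (edge$type == "inhibits") {
    tip <- ep$b
    l <- c(tip[1] + ep$p[1] * hw * 0.8, tip[2] + ep$p[2] * hw * 0.8)
    r <- c(tip[1] - ep$p[1] * hw * 0.8, tip[2] - ep$p[2] * hw * 0.8)
    out <- c(out, sprintf('<line class="tbar" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
                          .fmt(l[1]), .fmt(l[2]), .fmt(r[1]), .fmt(r[2]),
                          col, .fmt(config$stroke_width * 1.5)))
  }
  c(out, "</g>")
}

#' Assemble a renderable scene
#'
#' Validates the scene invariants — every glyph's gene is a graph node,
#' every edge's track has a color — and bundles graph, glyphs, layout and
#' legend data into a `circlemap_scene` ready for [write_svg]. The legend
#' lists each ring inner to outer and each track with its color.
#'
#' @param graph the displayed (post-overlay) [pathway_graph].
#' @param glyphs named list of [build_glyph] results keyed by gene; may be
#'   empty.
#' @param layout a `scene_layout`, or `NULL` only for an empty graph.
#' @param track_colors named color vector keyed by track name; tracks
#'   present in the graph but absent here get palette colors.
#' @param config a [scene_config].
#' @return a `circlemap_scene`.
#' @export
assemble_scene <- function(graph, glyphs = list(), layout = NULL,
                           track_colors = character(0L), config = scene_config()) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (is.null(layout)) {
    if (nrow(graph$nodes) > 0L)
      stop("a nonempty graph needs a layout", call. = FALSE)
    layout <- structure(list(coords = matrix(numeric(0L), 0L, 2L),
                             width = 400, height = 300),
                        class = "scene_layout")
  }
  stray <- setdiff(names(glyphs), graph$nodes$name)
  if (length(stray))
    stop("glyph for gene absent from graph: ", stray[1L], call. = FALSE)
  missing_nodes <- setdiff(graph$nodes$name, rownames(layout$coords))
  if (length(missing_nodes))
    stop("node without layout coordinates: ", missing_nodes[1L], call. = FALSE)
  tr <- unique(graph$edges$track)
  unseen <- setdiff(tr, names(track_colors))
  if (length(unseen)) {
    extra <- track_palette(length(track_colors) + length(unseen))
    extra <- extra[seq.int(length(track_colors) + 1L, length.out = length(unseen))]
    track_colors <- c(track_colors, stats::setNames(extra, unseen))
  }
  ring_legend <- if (length(glyphs)) {
    vapply(glyphs[[1L]]$rings, function(r) r$platform, character(1L))
  } else character(0L)
  structure(list(graph = graph, glyphs = glyphs, layout = layout,
                 track_colors = track_colors, ring_legend = ring_legend,
                 config = config),
            class = "circlemap_scene")
}

.render_legend <- function(scene) {
  cfg <- scene$config
  x <- cfg$margin * 0.25 + 4
  y <- scene$layout$height - 14
  out <- '<g class="legend">'
  for (i in seq_along(scene$ring_legend)) {
    out <- c(out, sprintf('<text class="legend-ring" x="%s" y="%s" font-family="%s" font-size="11">ring %d (inner to outer): %s</text>',
                          .fmt(x), .fmt(y - 14 * (length(scene$ring_legend) - i + length(scene$track_colors))),
                          cfg$font_family, i, .xml_escape(scene$ring_legend[i])))
  }
  tn <- names(scene$track_colors)
  for (i in seq_along(tn)) {
    yy <- y - 14 * (length(tn) - i)
    out <- c(out,
             sprintf('<line class="legend-track-swatch" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="3"/>',
                     .fmt(x), .fmt(yy - 4), .fmt(x + 24), .fmt(yy - 4),
                     scene$track_colors[[i]]),
             sprintf('<text class="legend-track" x="%s" y="%s" font-family="%s" font-size="11">%s</text>',
                     .fmt(x + 30), .fmt(yy), cfg$font_family, .xml_escape(tn[i])))
  }
  c(out, "</g>")
}

#' Serialize a scene to SVG
#'
#' Produces a deterministic, well-formed SVG 1.1 document: identical scene
#' and configuration give a byte-identical stream. Element classes
#' (`node`, `edge`, `spoke`, `segment`, `legend`) are stable and
#' machine-queryable. Edges are drawn beneath nodes; parallel edges
#' between a pair are fanned out perpendicular to the connecting line.
#'
#' @param scene a `circlemap_scene` from [assemble_scene].
#' @param stream file path or connection; `NULL` returns the document as a
#'   single string.
#' @return invisibly, the SVG document as one string.
#' @export
write_svg <- function(scene, stream = NULL) {
  if (!inherits(scene, "circlemap_scene"))
    stop("scene is not laid out; call assemble_scene() first", call. = FALSE)
  cfg <- scene$config
  lay <- scene$layout
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="%s" height="%s" viewBox="0 0 %s %s">',
            .fmt(lay$width), .fmt(lay$height), .fmt(lay$width), .fmt(lay$height)),
    sprintf('<rect class="canvas" x="0" y="0" width="%s" height="%s" fill="%s"/>',
            .fmt(lay$width), .fmt(lay$height), cfg$background)
  )
  glyph_genes <- names(scene$glyphs)
  radii <- stats::setNames(
    ifelse(scene$graph$nodes$name %in% glyph_genes, cfg$glyph_radius, cfg$shape_radius),
    scene$graph$nodes$name
  )
  e <- scene$graph$edges
  if (nrow(e)) {
    pair_key <- paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
    for (i in seq_len(nrow(e))) {
      sibs <- which(pair_key == pair_key[i])
      k <- length(sibs)
      off <- (match(i, sibs) - (k + 1) / 2) * 9
      lines <- c(lines, render_edge(e[i, ], lay, scene$track_colors, cfg,
                                    node_radii = radii, offset = off))
    }
  }
  for (i in seq_len(nrow(scene$graph$nodes))) {
    nm <- scene$graph$nodes$name[i]
    lines <- c(lines, render_node(nm, scene$graph$nodes$type[i],
                                  scene$glyphs[[nm]], lay, cfg))
  }
  lines <- c(lines, .render_legend(scene), "</svg>")
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(stream)) {
    if (is.character(stream)) {
      con <- file(stream, open = "wb")
      on.exit(close(con))
      writeBin(charToRaw(doc), con)
    } else {
      writeLines(doc, stream, sep = "", useBytes = TRUE)
    }
  }
  invisible(doc)
}
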