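# Static SVG export of a projected pathway graph.
#
# Visual grammar: gene_protein nodes are rectangles, compounds circles,
# pathway nodes rounded rectangles, misc nodes gray rectangles; group nodes
# are polygons around the convex hull of their members' corner points. The
# four visually distinct edge classes get distinct stroke dashes / markers
# (activation: solid + arrowhead; inhibition: solid + T-bar; binding /
# association: dashed, no head; indirect: long-dashed + arrowhead; everything
# else: plain solid). PTM nodes are small colored ellipses, summary nodes
# circles labeled with their count. Anchor edges (PTM -> reference) are not
# drawn. Kinase-substrate overlay edges are drawn dotted with an arrowhead,
# and highlight marks are colored rings.

NODE_W <- 46
NODE_H <- 17

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

num <- function(x) formatC(x, format = "f", digits = 2)

edge_style_table <- function() {
  data.frame(
    visual_class = c("activation", "inhibition", "binding_association",
                     "indirect", "other"),
    stroke = c("#000000", "#000000", "#555555", "#555555", "#888888"),
    dash = c("", "", "4,4", "8,4", ""),
    marker = c("arrow", "tee", "", "arrow", ""),
    stringsAsFactors = FALSE
  )
}

#' Convex hull of a point set
#'
#' Vertices of the convex hull in counter-clockwise order (Andrew-monotone
#' convention as provided by [grDevices::chull()]).
#'
#' @param points Two-column matrix of x/y coordinates.
#' @return Matrix of hull vertices (subset of input rows).
#' @export
convex_hull <- function(points) {
  points <- as.matrix(points)
  idx <- grDevices::chull(points[, 1], points[, 2])
  points[idx, , drop = FALSE]
}

node_corners <- function(node) {
  w2 <- NODE_W / 2
  h2 <- NODE_H / 2
  cbind(x = node$x + c(-w2, w2, w2, -w2),
        y = node$y + c(-h2, -h2, h2, h2))
}

# Resolve an endpoint reference (node or edge id) to drawing coordinates:
# node center, group-member centroid, or midpoint of the referenced edge.
endpoint_xy <- function(skeleton, ref, depth = 0) {
  if (depth > 10) stop(sprintf("endpoint reference chain too deep at '%s'", ref))
  n <- skeleton_node_by_id(skeleton, ref)
  if (!is.null(n)) {
    if (n$node_type == "group") {
      pts <- t(vapply(n$members, function(m) {
        mm <- skeleton_node_by_id(skeleton, m)
        c(mm$x, mm$y)
      }, numeric(2)))
      return(colMeans(pts))
    }
    return(c(n$x, n$y))
  }
  for (e in skeleton$edges) {
    if (e$edge_id == ref) {
      a <- endpoint_xy(skeleton, e$source, depth + 1)
      b <- endpoint_xy(skeleton, e$target, depth + 1)
      return((a + b) / 2)
    }
  }
  stop(sprintf("endpoint reference '%s' does not resolve", ref))
}

svg_node_element <- function(n) {
  id <- sprintf('id="node-%s"', svg_escape(n$node_id))
  lbl <- sprintf('<text id="label-%s" x="%s" y="%s" text-anchor="middle" font-size="9" font-family="sans-serif">%s</text>',
                 svg_escape(n$node_id), num(n$x), num(n$y + 3),
                 svg_escape(n$label))
  shape <- switch(n$node_type,
    gene_protein = sprintf('<rect %s x="%s" y="%s" width="%d" height="%d" fill="#bfffbf" stroke="#000000"/>',
                           id, num(n$x - NODE_W / 2), num(n$y - NODE_H / 2),
                           NODE_W, NODE_H),
    compound = sprintf('<circle %s cx="%s" cy="%s" r="8" fill="#ffffff" stroke="#000000"/>',
                       id, num(n$x), num(n$y)),
    pathway = sprintf('<rect %s x="%s" y="%s" width="%d" height="%d" rx="8" fill="#e0e8ff" stroke="#000000"/>',
                      id, num(n$x - NODE_W / 2), num(n$y - NODE_H / 2),
                      NODE_W, NODE_H),
    sprintf('<rect %s x="%s" y="%s" width="%d" height="%d" fill="#f0f0f0" stroke="#aaaaaa"/>',
            id, num(n$x - NODE_W / 2), num(n$y - NODE_H / 2), NODE_W, NODE_H)
  )
  paste0(shape, if (nzchar(n$label)) lbl else "")
}

#' Render a projected graph as SVG
#'
#' Produces a standalone SVG 1.1 document with one element per visible node,
#' edge, hull polygon and label, each with a stable id derived from the
#' graph ids. The graph must have been laid out first when it carries PTM or
#' summary nodes (see [layout_ptm_nodes()]).
#'
#' @param graph A `projected_graph` or a bare [pathway_skeleton()].
#' @param show_site_labels Draw the residue+position label above each PTM
#'   node.
#' @return A single string containing the SVG document.
#' @export
render_svg <- function(graph, show_site_labels = FALSE) {
  if (inherits(graph, "pathway_skeleton")) {
    graph <- list(base = graph,
                  ptm_nodes = data.frame(), summary_nodes = data.frame(),
                  overlay_edges = data.frame(),
                  highlights = data.frame(), collapse = FALSE,
                  laid_out = TRUE)
  }
  skeleton <- graph$base
  n_float <- nrow(graph$ptm_nodes) + nrow(graph$summary_nodes)
  if (n_float > 0 && !isTRUE(graph$laid_out)) {
    stop("graph has no layout; run layout_ptm_nodes() first")
  }

  regular <- Filter(function(n) n$node_type != "group", skeleton$nodes)
  groups <- Filter(function(n) n$node_type == "group", skeleton$nodes)

  xs <- vapply(regular, function(n) n$x, numeric(1))
  ys <- vapply(regular, function(n) n$y, numeric(1))
  if (n_float > 0) {
    xs <- c(xs, graph$ptm_nodes$x, graph$summary_nodes$x)
    ys <- c(ys, graph$ptm_nodes$y, graph$summary_nodes$y)
  }
  pad <- 60
  x0 <- min(xs) - pad; y0 <- min(ys) - pad
  width <- max(xs) - x0 + pad
  height <- max(ys) - y0 + pad

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" viewBox="%s %s %s %s" width="%s" height="%s">',
            num(x0), num(y0), num(width), num(height), num(width), num(height)),
    '<defs>',
    '<marker id="marker-arrow" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="7" markerHeight="7" orient="auto-start-reverse"><path d="M 0 0 L 10 5 L 0 10 z"/></marker>',
    '<marker id="marker-tee" viewBox="0 0 10 10" refX="5" refY="5" markerWidth="8" markerHeight="8" orient="auto-start-reverse"><path d="M 4 0 L 6 0 L 6 10 L 4 10 z"/></marker>',
    '</defs>'
  )

  # group hulls first (background)
  for (g in groups) {
    pts <- do.call(rbind, lapply(g$members, function(m) {
      node_corners(skeleton_node_by_id(skeleton, m))
    }))
    hull <- convex_hull(pts)
    out <- c(out, sprintf(
      '<polygon id="hull-%s" points="%s" fill="#fff7d0" fill-opacity="0.6" stroke="#c0a000"/>',
      svg_escape(g$node_id),
      paste(sprintf("%s,%s", num(hull[, 1]), num(hull[, 2])), collapse = " ")
    ))
  }

  styles <- edge_style_table()
  for (e in skeleton$edges) {
    a <- endpoint_xy(skeleton, e$source)
    b <- endpoint_xy(skeleton, e$target)
    st <- styles[styles$visual_class == e$visual_class, ]
    dash <- if (nzchar(st$dash)) sprintf(' stroke-dasharray="%s"', st$dash) else ""
    marker <- if (nzchar(st$marker)) {
      sprintf(' marker-end="url(#marker-%s)"', st$marker)
    } else ""
    out <- c(out, sprintf(
      '<line id="edge-%s" class="edge-%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s"%s%s/>',
      svg_escape(e$edge_id), e$visual_class, num(a[1]), num(a[2]),
      num(b[1]), num(b[2]), st$stroke, dash, marker
    ))
  }

  for (n in regular) out <- c(out, svg_node_element(n))

  # overlay kinase-substrate edges (dotted, drawn above skeleton)
  if (NROW(graph$overlay_edges)) {
    for (r in seq_len(nrow(graph$overlay_edges))) {
      oe <- graph$overlay_edges[r, ]
      a <- endpoint_xy(skeleton, oe$source)
      k <- match(oe$target, graph$ptm_nodes$ptm_node_id)
      b <- c(graph$ptm_nodes$x[k], graph$ptm_nodes$y[k])
      out <- c(out, sprintf(
        '<line id="%s" class="edge-overlay" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#e07000" stroke-dasharray="2,3" marker-end="url(#marker-arrow)"/>',
        svg_escape(oe$edge_id), num(a[1]), num(a[2]), num(b[1]), num(b[2])
      ))
    }
  }

  if (NROW(graph$ptm_nodes)) {
    for (r in seq_len(nrow(graph$ptm_nodes))) {
      p <- graph$ptm_nodes[r, ]
      out <- c(out, sprintf(
        '<ellipse id="%s" cx="%s" cy="%s" rx="10" ry="6" fill="%s" stroke="#333333"/>',
        svg_escape(p$ptm_node_id), num(p$x), num(p$y), p$color
      ))
      if (show_site_labels && nzchar(p$label)) {
        out <- c(out, sprintf(
          '<text id="sitelabel-%s" x="%s" y="%s" text-anchor="middle" font-size="7" font-family="sans-serif">%s</text>',
          svg_escape(p$ptm_node_id), num(p$x), num(p$y - 8),
          svg_escape(p$label)
        ))
      }
    }
  }

  if (NROW(graph$summary_nodes)) {
    for (r in seq_len(nrow(graph$summary_nodes))) {
      s <- graph$summary_nodes[r, ]
      out <- c(out, sprintf(
        '<circle id="%s" cx="%s" cy="%s" r="9" fill="%s" stroke="#333333"/>',
        svg_escape(s$summary_node_id), num(s$x), num(s$y), s$color
      ))
      out <- c(out, sprintf(
        '<text id="count-%s" x="%s" y="%s" text-anchor="middle" font-size="8" fill="#ffffff" font-family="sans-serif">%d</text>',
        svg_escape(s$summary_node_id), num(s$x), num(s$y + 3), s$count
      ))
    }
  }

  if (NROW(graph$highlights)) {
    ring <- c(up = "#d62728", down = "#1f77b4", unknown = "#7b2d8b")
    for (r in seq_len(nrow(graph$highlights))) {
      h <- graph$highlights[r, ]
      ctr <- endpoint_xy(skeleton, h$node_id)
      out <- c(out, sprintf(
        '<circle id="highlight-%s-%d" cx="%s" cy="%s" r="%d" fill="none" stroke="%s" stroke-width="3"/>',
        svg_escape(h$node_id), r, num(ctr[1]), num(ctr[2]), NODE_W %/% 2 + 4,
        ring[[h$direction]]
      ))
    }
  }

  out <- c(out, "</svg>")
  paste(out, collapse = "\n")
}

#' Write an SVG document to a file
#'
#' @param svg String produced by [render_svg()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  writeLines(svg, path, useBytes = TRUE)
  invisible(path)
}
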