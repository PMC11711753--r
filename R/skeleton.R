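# Unified pathway-skeleton data model shared by the KGML and GPML readers and
# by everything downstream (projection, layout, rendering, enrichment ranking).
#
# A skeleton is a mixed graph: typed nodes (with 2-D pixel coordinates, origin
# top-left, y growing downward), typed edges whose endpoints may be other
# edges, and group nodes defined purely by their member set.

SKELETON_FORMAT_VERSION <- 1L

NODE_TYPES <- c("gene_protein", "compound", "pathway", "misc", "group")
VISUAL_CLASSES <- c("activation", "inhibition", "binding_association",
                    "indirect", "other")
SOURCE_DBS <- c("kegg", "wikipathways", "custom")

#' Create a skeleton node
#'
#' Nodes carry a type from the unified vocabulary (`gene_protein`, `compound`,
#' `pathway`, `misc`, `group`), a display label, identifier annotations and,
#' for regular (non-group) nodes, cartesian pixel coordinates. Group nodes
#' have no coordinates of their own; they are defined solely by the set of
#' regular nodes they contain.
#'
#' Coordinates are stored at 2-decimal precision (the documented precision of
#' the JSON serialization).
#'
#' @param node_id Unique (per pathway) opaque string id.
#' @param node_type One of `r paste(NODE_TYPES, collapse = ", ")`.
#' @param label Display string; may be empty.
#' @param uniprot_accessions Character vector of UniProt accessions.
#' @param gene_names Character vector of gene symbols.
#' @param x,y Pixel coordinates (ignored and dropped for group nodes).
#' @param members For group nodes, character vector of member node ids.
#' @return A list of class `skeleton_node`.
#' @export
skeleton_node <- function(node_id, node_type, label = "",
                          uniprot_accessions = character(),
                          gene_names = character(),
                          x = NULL, y = NULL, members = NULL) {
  stopifnot(is_string(node_id), is_string(node_type))
  node <- list(
    node_id = node_id,
    node_type = node_type,
    label = as.character(label %||% ""),
    uniprot_accessions = as.character(uniprot_accessions %||% character()),
    gene_names = as.character(gene_names %||% character()),
    x = if (node_type != "group" && !is.null(x)) round(as.numeric(x), 2) else NULL,
    y = if (node_type != "group" && !is.null(y)) round(as.numeric(y), 2) else NULL,
    members = if (node_type == "group") as.character(members %||% character()) else NULL
  )
  class(node) <- "skeleton_node"
  node
}

#' Create a skeleton edge
#'
#' Edge endpoints are references by id and may point at a node *or at another
#' edge* (the unified representation of GPML anchors). The visual class is a
#' pure function of the relation-type set (see [visual_class_for()]) and is
#' recomputed here; a stored class is never trusted.
#'
#' @param edge_id Opaque string id, unique within the pathway (and disjoint
#'   from node ids so endpoint references are unambiguous).
#' @param source,target Endpoint references (node id or edge id).
#' @param relation_types Non-empty character vector of relation subtypes from
#'   the unified vocabulary.
#' @return A list of class `skeleton_edge`.
#' @export
skeleton_edge <- function(edge_id, source, target, relation_types) {
  stopifnot(is_string(edge_id), is_string(source), is_string(target))
  relation_types <- unique(as.character(relation_types))
  edge <- list(
    edge_id = edge_id,
    source = source,
    target = target,
    relation_types = relation_types,
    visual_class = visual_class_for(relation_types)
  )
  class(edge) <- "skeleton_edge"
  edge
}

#' Visual class of a relation-type set
#'
#' Maps a set of relation subtypes onto one of the four visually distinct
#' edge classes (`activation`, `inhibition`, `binding_association`,
#' `indirect`); every other subtype renders as `other`. Multi-type edges are
#' resolved by priority: inhibition > activation > indirect >
#' binding_association > other. The mapping is deterministic: the same set
#' always yields the same class.
#'
#' @param relation_types Character vector of relation subtypes.
#' @return A single string, one of the five visual classes.
#' @export
visual_class_for <- function(relation_types) {
  rt <- unique(as.character(relation_types))
  if (length(rt) == 0L) return("other")
  if ("inhibition" %in% rt) return("inhibition")
  if ("activation" %in% rt) return("activation")
  if ("indirect" %in% rt) return("indirect")
  if ("binding/association" %in% rt) return("binding_association")
  "other"
}

#' Create a pathway skeleton
#'
#' @param pathway_id Pathway identifier (e.g. `"hsa04150"`, `"WP51"`, or a
#'   user-defined id).
#' @param name Human-readable pathway name.
#' @param organism Organism code or name.
#' @param source_db One of `"kegg"`, `"wikipathways"`, `"custom"`.
#' @param nodes List of [skeleton_node()] objects.
#' @param edges List of [skeleton_edge()] objects.
#' @return A list of class `pathway_skeleton`.
#' @seealso [validate_skeleton()], [save_skeleton()], [load_skeleton()]
#' @export
pathway_skeleton <- function(pathway_id, name = pathway_id, organism = "",
                             source_db = "custom",
                             nodes = list(), edges = list()) {
  stopifnot(is_string(pathway_id))
  sk <- list(
    format_version = SKELETON_FORMAT_VERSION,
    pathway_id = pathway_id,
    name = as.character(name),
    organism = as.character(organism),
    source_db = source_db,
    nodes = unname(nodes),
    edges = unname(edges)
  )
  class(sk) <- "pathway_skeleton"
  sk
}

#' @export
print.pathway_skeleton <- function(x, ...) {
  types <- vapply(x$nodes, function(n) n$node_type, character(1))
  cat(sprintf("<pathway_skeleton> %s (%s, %s)\n", x$pathway_id,
              x$name, x$source_db))
  cat(sprintf("  %d nodes (%s), %d edges\n", length(x$nodes),
              paste(sprintf("%s: %d", names(table(types)), table(types)),
                    collapse = ", "),
              length(x$edges)))
  invisible(x)
}

node_ids <- function(skeleton) {
  vapply(skeleton$nodes, function(n) n$node_id, character(1))
}

edge_ids <- function(skeleton) {
  vapply(skeleton$edges, function(e) e$edge_id, character(1))
}

skeleton_node_by_id <- function(skeleton, id) {
  for (n in skeleton$nodes) if (n$node_id == id) return(n)
  NULL
}

#' Validate a pathway skeleton
#'
#' Checks every structural invariant of the skeleton model and reports all
#' violations. Validation is total (it never raises on bad content) and
#' idempotent.
#'
#' Rules checked: unique node and edge ids (disjoint namespaces); valid node
#' and relation types; group nodes have at least one member, no coordinates,
#' and only existing non-group members; regular nodes carry finite
#' coordinates; edge endpoints resolve to an existing node or edge; edges
#' carry a non-empty relation-type set and the visual class implied by it;
#' the skeleton contains at least one `gene_protein` node (pathways without
#' gene or gene-product nodes are not importable).
#'
#' @param skeleton A [pathway_skeleton()].
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_skeleton <- function(skeleton) {
  v <- character()
  if (!inherits(skeleton, "pathway_skeleton")) {
    return("not a pathway_skeleton object")
  }
  nids <- node_ids(skeleton)
  eids <- edge_ids(skeleton)
  if (anyDuplicated(nids)) {
    v <- c(v, sprintf("duplicate node id: %s",
                      unique(nids[duplicated(nids)])))
  }
  if (anyDuplicated(eids)) {
    v <- c(v, sprintf("duplicate edge id: %s",
                      unique(eids[duplicated(eids)])))
  }
  shared <- intersect(nids, eids)
  if (length(shared)) {
    v <- c(v, sprintf("id used by both a node and an edge: %s", shared))
  }
  group_ids <- nids[vapply(skeleton$nodes,
                           function(n) identical(n$node_type, "group"),
                           logical(1))]
  for (n in skeleton$nodes) {
    if (!n$node_type %in% NODE_TYPES) {
      v <- c(v, sprintf("node %s: unknown node_type '%s'", n$node_id,
                        n$node_type))
      next
    }
    if (n$node_type == "group") {
      if (length(n$members) < 1L) {
        v <- c(v, sprintf("group node %s: empty member set", n$node_id))
      }
      if (!is.null(n$x) || !is.null(n$y)) {
        v <- c(v, sprintf("group node %s: must not carry coordinates",
                          n$node_id))
      }
      missing <- setdiff(n$members, nids)
      for (m in missing) {
        v <- c(v, sprintf("group node %s: member '%s' does not exist",
                          n$node_id, m))
      }
      nested <- intersect(n$members, group_ids)
      for (m in nested) {
        v <- c(v, sprintf("group node %s: member '%s' is itself a group",
                          n$node_id, m))
      }
    } else {
      if (!is_number(n$x) || !is_number(n$y)) {
        v <- c(v, sprintf("node %s: missing or non-finite coordinates",
                          n$node_id))
      }
    }
  }
  endpoints <- c(nids, eids)
  for (e in skeleton$edges) {
    if (length(e$relation_types) == 0L) {
      v <- c(v, sprintf("edge %s: empty relation_types", e$edge_id))
    }
    if (!e$source %in% endpoints) {
      v <- c(v, sprintf("edge %s: source '%s' does not resolve", e$edge_id,
                        e$source))
    }
    if (!e$target %in% endpoints) {
      v <- c(v, sprintf("edge %s: target '%s' does not resolve", e$edge_id,
                        e$target))
    }
    expected <- visual_class_for(e$relation_types)
    if (!identical(e$visual_class, expected)) {
      v <- c(v, sprintf("edge %s: visual_class '%s' does not match '%s'",
                        e$edge_id, e$visual_class %||% "<missing>", expected))
    }
  }
  n_gene <- sum(vapply(skeleton$nodes,
                       function(n) identical(n$node_type, "gene_protein"),
                       logical(1)))
  if (n_gene == 0L) {
    v <- c(v, "no gene_protein node")
  }
  v
}

# --- JSON serialization ------------------------------------------------------

node_to_json <- function(n) {
  out <- list(
    nodeId = jsonlite::unbox(n$node_id),
    nodeType = jsonlite::unbox(n$node_type),
    label = jsonlite::unbox(n$label),
    uniprotAccessions = as.character(n$uniprot_accessions),
    geneNames = as.character(n$gene_names)
  )
  if (n$node_type == "group") {
    out$members <- as.character(n$members)
  } else {
    out$x <- jsonlite::unbox(n$x)
    out$y <- jsonlite::unbox(n$y)
  }
  out
}

edge_to_json <- function(e) {
  list(
    edgeId = jsonlite::unbox(e$edge_id),
    source = jsonlite::unbox(e$source),
    target = jsonlite::unbox(e$target),
    relationTypes = as.character(e$relation_types),
    visualClass = jsonlite::unbox(e$visual_class)
  )
}

#' Save a pathway skeleton as JSON
#'
#' Writes the documented, versioned JSON schema (top-level keys
#' `formatVersion`, `pathwayId`, `name`, `organism`, `sourceDb`, `nodes`,
#' `edges`; nodes and edges are arrays of flat objects). The skeleton is
#' validated first and saving is refused on any violation, so only
#' schema-conforming documents are ever produced. Coordinates are written at
#' the stored 2-decimal precision, which makes `load(save(x))` lossless.
#'
#' @param skeleton A valid [pathway_skeleton()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_skeleton <- function(skeleton, path) {
  violations <- validate_skeleton(skeleton)
  if (length(violations)) {
    stop("refusing to save invalid skeleton:\n  ",
         paste(violations, collapse = "\n  "))
  }
  doc <- list(
    formatVersion = jsonlite::unbox(skeleton$format_version),
    pathwayId = jsonlite::unbox(skeleton$pathway_id),
    name = jsonlite::unbox(skeleton$name),
    organism = jsonlite::unbox(skeleton$organism),
    sourceDb = jsonlite::unbox(skeleton$source_db),
    nodes = lapply(skeleton$nodes, node_to_json),
    edges = lapply(skeleton$edges, edge_to_json)
  )
  jsonlite::write_json(doc, path, digits = NA, pretty = TRUE)
  invisible(path)
}

require_field <- function(obj, field, where) {
  if (is.null(obj[[field]])) {
    stop(sprintf("skeleton JSON parse error at %s: missing field '%s'",
                 where, field))
  }
  obj[[field]]
}

#' Load a pathway skeleton from JSON
#'
#' Reads a document produced by [save_skeleton()] (or conforming to the same
#' schema). Schema violations raise a parse error naming the first offending
#' path.
#'
#' @param path Path to a skeleton JSON file.
#' @return A [pathway_skeleton()].
#' @export
load_skeleton <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("formatVersion", "pathwayId", "nodes", "edges")) {
    require_field(doc, f, "$")
  }
  nodes <- lapply(seq_along(doc$nodes), function(i) {
    nd <- doc$nodes[[i]]
    where <- sprintf("$.nodes[%d]", i)
    skeleton_node(
      node_id = require_field(nd, "nodeId", where),
      node_type = require_field(nd, "nodeType", where),
      label = nd$label %||% "",
      uniprot_accessions = unlist(nd$uniprotAccessions) %||% character(),
      gene_names = unlist(nd$geneNames) %||% character(),
      x = nd$x, y = nd$y,
      members = unlist(nd$members) %||% character()
    )
  })
  edges <- lapply(seq_along(doc$edges), function(i) {
    ed <- doc$edges[[i]]
    where <- sprintf("$.edges[%d]", i)
    skeleton_edge(
      edge_id = require_field(ed, "edgeId", where),
      source = require_field(ed, "source", where),
      target = require_field(ed, "target", where),
      relation_types = unlist(require_field(ed, "relationTypes", where))
    )
  })
  pathway_skeleton(
    pathway_id = doc$pathwayId,
    name = doc$name %||% doc$pathwayId,
    organism = doc$organism %||% "",
    source_db = doc$sourceDb %||% "custom",
    nodes = nodes,
    edges = edges
  )
}

#' Compare two skeletons field-for-field
#'
#' Order-insensitive over nodes and edges (both sides are sorted by id before
#' comparison). Used to state the round-trip identity `load(save(x)) == x`.
#'
#' @param a,b Two [pathway_skeleton()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
skeletons_equal <- function(a, b) {
  norm <- function(s) {
    s$nodes <- s$nodes[order(node_ids(s))]
    s$edges <- s$edges[order(edge_ids(s))]
    s$edges <- lapply(s$edges, function(e) {
      e$relation_types <- sort(e$relation_types)
      e
    })
    s
  }
  isTRUE(all.equal(norm(a), norm(b), tolerance = 0))
}

# Outcome used by the importers for pathways with no gene or gene-product
# node: reported as skipped, not raised as an error.
skipped_pathway <- function(pathway_id, reason) {
  structure(list(pathway_id = pathway_id, reason = reason),
            class = "skipped_pathway")
}

#' Test for a skipped-pathway outcome
#'
#' The KGML and GPML readers refuse to import pathways that contain zero
#' gene/gene-product nodes (they are not useful for signaling analysis);
#' such pathways yield a `skipped_pathway` object instead of a skeleton.
#'
#' @param x Any object.
#' @return `TRUE` if `x` is a skipped-pathway outcome.
#' @export
is_skipped_pathway <- function(x) inherits(x, "skipped_pathway")

#' @export
print.skipped_pathway <- function(x, ...) {
  cat(sprintf("<skipped pathway> %s: %s\n", x$pathway_id, x$reason))
  invisible(x)
}
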