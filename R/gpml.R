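# WikiPathways GPML reader. GPML pathways are community-curated and less
# standardized than KEGG: node kinds are mapped onto the four unified types
# (gene_protein, compound, pathway, misc), arrowhead edge types are partly
# mapped onto the KEGG-derived subtype vocabulary and partly retained
# verbatim, and "anchor" constructs (an interaction terminating on another
# interaction) are resolved into edges whose endpoint references are edge ids.

#' GPML node-kind table
#'
#' The shipped 13-entry vocabulary of GPML node kinds (DataNode `Type`
#' attribute values plus the `Label` and `Shape` elements) and their unified
#' node types. Kinds that carry no gene/compound/pathway semantics map to
#' `misc`.
#'
#' @return Data frame with columns `gpml` and `unified`.
#' @export
gpml_node_types <- function() {
  data.frame(
    gpml = c("GeneProduct", "Protein", "Rna", "Complex", "Metabolite",
             "Pathway", "Unknown", "Label", "Shape", "CellularComponent",
             "Event", "Organ", "Cell"),
    unified = c("gene_protein", "gene_protein", "gene_protein", "misc",
                "compound", "pathway", "misc", "misc", "misc", "misc",
                "misc", "misc", "misc"),
    stringsAsFactors = FALSE
  )
}

#' GPML edge-type table
#'
#' The shipped 24-entry vocabulary of GPML arrowhead edge types. Ten are
#' converted into KEGG-derived subtypes (`mapped = TRUE`); the other fourteen
#' are retained verbatim as additional subtypes.
#'
#' @return Data frame with columns `gpml`, `unified`, `mapped`.
#' @export
gpml_edge_types <- function() {
  mapped <- data.frame(
    gpml = c("Arrow", "mim-stimulation", "mim-necessary-stimulation",
             "mim-catalysis", "TBar", "mim-inhibition", "SBGN-Inhibition",
             "mim-binding", "mim-covalent-bond", "mim-transcription-translation"),
    unified = c("activation", "activation", "activation", "activation",
                "inhibition", "inhibition", "inhibition",
                "binding/association", "binding/association", "expression"),
    mapped = TRUE, stringsAsFactors = FALSE
  )
  retained <- data.frame(
    gpml = c("Line", "Receptor", "LigandSquare", "ReceptorSquare",
             "LigandRound", "ReceptorRound", "mim-conversion",
             "mim-modification", "mim-cleavage", "mim-branching-left",
             "mim-branching-right", "mim-gap", "mim-translocation",
             "SBGN-Catalysis"),
    unified = NA_character_, mapped = FALSE, stringsAsFactors = FALSE
  )
  retained$unified <- retained$gpml
  rbind(mapped, retained)
}

#' Map GPML node and edge types onto the unified vocabulary
#'
#' @param gpml_node_type GPML node kind, or `NULL`.
#' @param gpml_edge_type GPML arrowhead type, or `NULL`.
#' @return List with elements `node_type` and `edge_subtype`. Unknown node
#'   kinds map to `misc` and unknown edge types are retained verbatim, both
#'   with a warning.
#' @export
map_gpml_types <- function(gpml_node_type = NULL, gpml_edge_type = NULL) {
  node_type <- NULL
  if (!is.null(gpml_node_type)) {
    tab <- gpml_node_types()
    i <- match(gpml_node_type, tab$gpml)
    if (is.na(i)) {
      warning(sprintf("unknown GPML node kind '%s'; recorded as misc",
                      gpml_node_type), call. = FALSE)
      node_type <- "misc"
    } else {
      node_type <- tab$unified[i]
    }
  }
  edge_subtype <- NULL
  if (!is.null(gpml_edge_type)) {
    tab <- gpml_edge_types()
    i <- match(gpml_edge_type, tab$gpml)
    if (is.na(i)) {
      warning(sprintf("unknown GPML edge type '%s'; retained verbatim",
                      gpml_edge_type), call. = FALSE)
      edge_subtype <- gpml_edge_type
    } else {
      edge_subtype <- tab$unified[i]
    }
  }
  list(node_type = node_type, edge_subtype = edge_subtype)
}

#' Resolve GPML anchors into edge-on-edge endpoint references
#'
#' Each interaction may declare anchors (named points along its line) that
#' other interactions terminate on. Resolution replaces every anchor
#' reference by the id of the interaction carrying the anchor, so no anchor
#' constructs remain and the edge count is preserved.
#'
#' @param interactions List of interactions, each a list with fields
#'   `edge_id`, `source`, `target` (graph ids or anchor ids),
#'   `relation_types` (character), and `anchors` (character vector of anchor
#'   ids declared on this interaction).
#' @return List of [skeleton_edge()] objects.
#' @export
resolve_anchors <- function(interactions) {
  anchor_owner <- character()
  for (it in interactions) {
    for (a in it$anchors %||% character()) anchor_owner[[a]] <- it$edge_id
  }
  resolve <- function(ref, eid, role) {
    if (!is.null(ref) && ref %in% names(anchor_owner)) {
      return(anchor_owner[[ref]])
    }
    ref
  }
  lapply(interactions, function(it) {
    skeleton_edge(
      edge_id = it$edge_id,
      source = resolve(it$source, it$edge_id, "source"),
      target = resolve(it$target, it$edge_id, "target"),
      relation_types = it$relation_types
    )
  })
}

gpml_ns <- function(doc) {
  # GPML documents carry a default namespace (e.g. the 2013a schema); strip
  # it so XPath stays readable across schema versions.
  xml2::xml_ns_strip(doc)
  doc
}

#' Parse a GPML pathway file into a pathway skeleton
#'
#' DataNodes, Labels and Shapes become skeleton nodes via the node-kind
#' table; Groups become group nodes; Interactions become edges via the
#' edge-type table with anchors resolved to edge-on-edge references. Xrefs
#' are unified to UniProt accessions through the offline mapping table
#' (priority: a UniProt xref is used directly; otherwise Entrez, Ensembl and
#' HGNC xrefs are looked up). PTM state decorations are not imported.
#'
#' @param source Path to a GPML file, a GPML string, or an `xml2` document.
#' @param mapping An [id_mapping_table()] or `NULL`.
#' @return A [pathway_skeleton()], or a skipped-pathway outcome when the
#'   file contains no gene/gene-product nodes.
#' @export
parse_gpml <- function(source, mapping = NULL) {
  doc <- gpml_ns(xml2::read_xml(source))
  root <- xml2::xml_find_first(doc, "/Pathway")
  if (inherits(root, "xml_missing")) {
    stop("not a GPML document: missing <Pathway> root element")
  }
  name <- attr_or(root, "Name", "wikipathways")
  pathway_id <- attr_or(root, "ID", name)
  org <- attr_or(root, "Organism", "")

  nodes <- list()
  group_members <- list()  # GroupId -> character vector of node ids
  auto <- 0L
  next_id <- function(prefix) {
    auto <<- auto + 1L
    sprintf("%s%d", prefix, auto)
  }

  add_element <- function(el, kind) {
    gid <- attr_or(el, "GraphId", next_id("gn"))
    gfx <- xml2::xml_find_first(el, "Graphics")
    x <- as.numeric(attr_or(gfx, "CenterX", "0"))
    y <- as.numeric(attr_or(gfx, "CenterY", "0"))
    label <- attr_or(el, "TextLabel", "")
    accessions <- character()
    if (identical(kind, "datanode")) {
      node_kind <- attr_or(el, "Type", "Unknown")
      xref <- xml2::xml_find_first(el, "Xref")
      if (!inherits(xref, "xml_missing")) {
        db <- attr_or(xref, "Database", "")
        xid <- attr_or(xref, "ID", "")
        if (nzchar(db) && nzchar(xid)) {
          if (normalize_db(db) == "uniprot") {
            accessions <- xid
          } else {
            accessions <- map_to_uniprot(mapping, db, xid)
          }
        }
      }
    } else {
      node_kind <- kind  # "Label" or "Shape"
    }
    genes <- map_to_gene(mapping, accessions)
    node_type <- map_gpml_types(gpml_node_type = node_kind)$node_type
    node <- skeleton_node(
      node_id = gid, node_type = node_type, label = label,
      uniprot_accessions = accessions, gene_names = genes, x = x, y = y
    )
    nodes[[length(nodes) + 1L]] <<- node
    gref <- attr_or(el, "GroupRef", "")
    if (nzchar(gref)) {
      group_members[[gref]] <<- c(group_members[[gref]], gid)
    }
    gid
  }

  for (el in xml2::xml_find_all(doc, "/Pathway/DataNode")) {
    add_element(el, "datanode")
  }
  for (el in xml2::xml_find_all(doc, "/Pathway/Label")) add_element(el, "Label")
  for (el in xml2::xml_find_all(doc, "/Pathway/Shape")) add_element(el, "Shape")

  for (el in xml2::xml_find_all(doc, "/Pathway/Group")) {
    group_id <- attr_or(el, "GroupId", attr_or(el, "GraphId", next_id("grp")))
    members <- group_members[[group_id]] %||% character()
    nodes[[length(nodes) + 1L]] <- skeleton_node(
      node_id = paste0("group_", group_id), node_type = "group",
      members = members
    )
  }

  interactions <- list()
  for (el in xml2::xml_find_all(doc, "/Pathway/Interaction")) {
    eid <- attr_or(el, "GraphId", next_id("ie"))
    points <- xml2::xml_find_all(el, "Graphics/Point")
    if (length(points) < 2L) {
      stop(sprintf("interaction %s: needs start and end points", eid))
    }
    src <- attr_or(points[[1]], "GraphRef", "")
    tgt <- attr_or(points[[length(points)]], "GraphRef", "")
    if (!nzchar(src) || !nzchar(tgt)) {
      stop(sprintf("interaction %s: start or end reference missing", eid))
    }
    arrow <- ""
    for (p in rev(points)) {
      arrow <- attr_or(p, "ArrowHead", "")
      if (nzchar(arrow)) break
    }
    if (!nzchar(arrow)) arrow <- "Line"
    anchors <- vapply(xml2::xml_find_all(el, "Graphics/Anchor"),
                      function(a) attr_or(a, "GraphId", ""), character(1))
    interactions[[length(interactions) + 1L]] <- list(
      edge_id = eid, source = src, target = tgt,
      relation_types = map_gpml_types(gpml_edge_type = arrow)$edge_subtype,
      anchors = anchors[nzchar(anchors)]
    )
  }
  edges <- resolve_anchors(interactions)

  # Interactions may reference a group by its GroupId; retarget those to the
  # group node id used above.
  group_node_of <- character()
  for (el in xml2::xml_find_all(doc, "/Pathway/Group")) {
    gid <- attr_or(el, "GroupId", "")
    if (nzchar(gid)) group_node_of[[gid]] <- paste0("group_", gid)
    graphid <- attr_or(el, "GraphId", "")
    if (nzchar(graphid)) group_node_of[[graphid]] <- paste0("group_", gid)
  }
  edges <- lapply(edges, function(e) {
    if (e$source %in% names(group_node_of)) e$source <- group_node_of[[e$source]]
    if (e$target %in% names(group_node_of)) e$target <- group_node_of[[e$target]]
    e
  })

  n_gene <- sum(vapply(nodes, function(n) n$node_type == "gene_protein",
                       logical(1)))
  if (n_gene == 0L) {
    return(skipped_pathway(pathway_id, "no gene or gene-product nodes"))
  }
  pathway_skeleton(
    pathway_id = pathway_id, name = name, organism = org,
    source_db = "wikipathways", nodes = nodes, edges = edges
  )
}
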