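# KEGG KGML reader: parses the KGML XML dialect and normalizes it into the
# unified pathway skeleton.
#
# Normalization rules:
#   * node types: gene and ortholog collapse to gene_protein; map becomes
#     pathway; compound stays compound; anything unknown becomes misc (with a
#     warning).
#   * relation subtypes pass through except two merges: "indirect" and
#     "indirect effect" both become "indirect"; "inhibition" and "repression"
#     both become "inhibition".
#   * many-to-many reactions are expanded into one directed edge per
#     (substrate, product) pair; a reversible reaction is marked by a
#     "reversible" relation type rather than a duplicate back-edge.
#   * KEGG identifiers are mapped offline to UniProt accessions and gene
#     symbols via an id_mapping_table.
#   * pathways with zero gene_protein nodes are reported as skipped.

#' KGML relation-subtype table
#'
#' The shipped vocabulary of KEGG relation subtypes and their unified
#' equivalents: 19 KGML subtypes mapping onto 17 unified subtypes (the two
#' documented merges collapse "indirect effect" into "indirect" and
#' "repression" into "inhibition").
#'
#' @return Data frame with columns `kgml` and `unified`.
#' @export
kegg_relation_subtypes <- function() {
  data.frame(
    kgml = c("activation", "inhibition", "repression", "expression",
             "indirect", "indirect effect", "state change",
             "binding/association", "dissociation", "missing interaction",
             "phosphorylation", "dephosphorylation", "glycosylation",
             "ubiquitination", "methylation", "demethylation", "sumoylation",
             "compound", "hidden compound"),
    unified = c("activation", "inhibition", "inhibition", "expression",
                "indirect", "indirect", "state change",
                "binding/association", "dissociation", "missing interaction",
                "phosphorylation", "dephosphorylation", "glycosylation",
                "ubiquitination", "methylation", "demethylation",
                "sumoylation", "compound", "hidden compound"),
    stringsAsFactors = FALSE
  )
}

#' Map KGML node and relation types onto the unified vocabulary
#'
#' @param kegg_node_type KGML entry type (`gene`, `ortholog`, `compound`,
#'   `map`, `group`, ...), or `NULL`.
#' @param kegg_relation_subtype KGML relation subtype name, or `NULL`.
#' @return List with elements `node_type` and `edge_subtype` (each `NULL` if
#'   the corresponding input was `NULL`). Unknown node types map to `misc`
#'   and unknown relation subtypes are retained verbatim, both with a
#'   warning.
#' @export
map_kegg_types <- function(kegg_node_type = NULL,
                           kegg_relation_subtype = NULL) {
  node_type <- NULL
  if (!is.null(kegg_node_type)) {
    node_type <- switch(kegg_node_type,
      gene = "gene_protein",
      ortholog = "gene_protein",
      compound = "compound",
      map = "pathway",
      group = "group",
      {
        warning(sprintf("unknown KGML entry type '%s'; recorded as misc",
                        kegg_node_type), call. = FALSE)
        "misc"
      }
    )
  }
  edge_subtype <- NULL
  if (!is.null(kegg_relation_subtype)) {
    tab <- kegg_relation_subtypes()
    i <- match(kegg_relation_subtype, tab$kgml)
    if (is.na(i)) {
      warning(sprintf("unknown KGML relation subtype '%s'; retained verbatim",
                      kegg_relation_subtype), call. = FALSE)
      edge_subtype <- kegg_relation_subtype
    } else {
      edge_subtype <- tab$unified[i]
    }
  }
  list(node_type = node_type, edge_subtype = edge_subtype)
}

#' Expand a many-to-many KGML reaction into one-to-one edges
#'
#' Emits exactly one directed edge per (substrate, product) pair, i.e.
#' `|substrates| * |products|` edges. Reversibility is recorded as an extra
#' `"reversible"` relation type on each emitted edge; no back-edges are
#' duplicated.
#'
#' @param reaction List with fields `reaction_id`, `substrates` (character
#'   vector of node ids), `products` (ditto) and `reversible` (flag).
#' @param id_prefix Prefix for generated edge ids.
#' @return List of [skeleton_edge()] objects.
#' @export
expand_reaction <- function(reaction, id_prefix = reaction$reaction_id) {
  subs <- as.character(reaction$substrates)
  prods <- as.character(reaction$products)
  if (length(subs) == 0L || length(prods) == 0L) {
    stop(sprintf("reaction %s: empty substrate or product list",
                 reaction$reaction_id %||% "<unnamed>"))
  }
  types <- c("reaction", if (isTRUE(reaction$reversible)) "reversible")
  edges <- list()
  k <- 0L
  for (s in subs) {
    for (p in prods) {
      k <- k + 1L
      edges[[k]] <- skeleton_edge(
        edge_id = sprintf("%s_%d", id_prefix, k),
        source = s, target = p, relation_types = types
      )
    }
  }
  edges
}

kgml_label <- function(graphics_name, gene_names, kegg_ids) {
  if (length(gene_names)) return(gene_names[[1]])
  if (is_string(graphics_name) && nzchar(graphics_name)) {
    # KGML graphics names are comma-separated alias lists; keep the first,
    # dropping KEGG's trailing ellipsis marker.
    return(sub("\\.\\.\\.$", "", trimws(strsplit(graphics_name, ",")[[1]][1])))
  }
  if (length(kegg_ids)) return(kegg_ids[[1]])
  ""
}

#' Parse a KGML pathway file into a pathway skeleton
#'
#' @param source Path to a KGML file, a KGML string, or an `xml2` document.
#' @param mapping An [id_mapping_table()] (KEGG ids keyed under db `"KEGG"`),
#'   or `NULL` for no identifier mapping (labels then fall back to the KGML
#'   graphics names / KEGG ids and accession lists stay empty).
#' @return A [pathway_skeleton()], or a skipped-pathway outcome (see
#'   [is_skipped_pathway()]) when the file contains no gene or ortholog
#'   entries.
#' @export
parse_kgml <- function(source, mapping = NULL) {
  doc <- xml2::read_xml(source)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing")) {
    stop("not a KGML document: missing <pathway> root element")
  }
  pathway_id <- sub("^path:", "", attr_or(root, "name", "kegg"))
  title <- attr_or(root, "title", pathway_id)
  org <- attr_or(root, "org", "")

  entries <- xml2::xml_find_all(doc, "/pathway/entry")
  nodes <- list()
  entry_to_node <- character()  # KGML entry id -> skeleton node id
  for (en in entries) {
    eid <- xml2::xml_attr(en, "id")
    etype <- xml2::xml_attr(en, "type")
    gfx <- xml2::xml_find_first(en, "graphics")
    nid <- paste0("n", eid)
    entry_to_node[[eid]] <- nid
    if (identical(etype, "group")) {
      members <- xml2::xml_attr(xml2::xml_find_all(en, "component"), "id")
      nodes[[length(nodes) + 1L]] <- skeleton_node(
        node_id = nid, node_type = "group",
        members = paste0("n", members)
      )
      next
    }
    node_type <- map_kegg_types(kegg_node_type = etype)$node_type
    kegg_ids <- strsplit(attr_or(en, "name", ""), "\\s+")[[1]]
    kegg_ids <- kegg_ids[nzchar(kegg_ids) & kegg_ids != "undefined"]
    accessions <- unique(unlist(lapply(kegg_ids, function(k) {
      map_to_uniprot(mapping, "KEGG", k)
    }))) %||% character()
    genes <- map_to_gene(mapping, accessions)
    gname <- if (!inherits(gfx, "xml_missing")) {
      xml2::xml_attr(gfx, "name")
    }
    nodes[[length(nodes) + 1L]] <- skeleton_node(
      node_id = nid, node_type = node_type,
      label = kgml_label(gname, genes, kegg_ids),
      uniprot_accessions = accessions, gene_names = genes,
      x = if (!inherits(gfx, "xml_missing")) {
        as.numeric(xml2::xml_attr(gfx, "x"))
      } else 0,
      y = if (!inherits(gfx, "xml_missing")) {
        as.numeric(xml2::xml_attr(gfx, "y"))
      } else 0
    )
  }

  edges <- list()
  rels <- xml2::xml_find_all(doc, "/pathway/relation")
  for (i in seq_along(rels)) {
    rel <- rels[[i]]
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "subtype"), "name")
    if (length(subtypes) == 0L) subtypes <- xml2::xml_attr(rel, "type")
    unified <- vapply(subtypes, function(s) {
      map_kegg_types(kegg_relation_subtype = s)$edge_subtype
    }, character(1), USE.NAMES = FALSE)
    edges[[length(edges) + 1L]] <- skeleton_edge(
      edge_id = sprintf("rel%d", i),
      source = entry_to_node[[xml2::xml_attr(rel, "entry1")]],
      target = entry_to_node[[xml2::xml_attr(rel, "entry2")]],
      relation_types = unified
    )
  }

  reactions <- xml2::xml_find_all(doc, "/pathway/reaction")
  for (i in seq_along(reactions)) {
    rx <- reactions[[i]]
    subs <- xml2::xml_attr(xml2::xml_find_all(rx, "substrate"), "id")
    prods <- xml2::xml_attr(xml2::xml_find_all(rx, "product"), "id")
    expanded <- expand_reaction(
      list(reaction_id = sprintf("rxn%d", i),
           substrates = unname(entry_to_node[subs]),
           products = unname(entry_to_node[prods]),
           reversible = identical(xml2::xml_attr(rx, "type"), "reversible"))
    )
    edges <- c(edges, expanded)
  }

  skeleton <- pathway_skeleton(
    pathway_id = pathway_id, name = title, organism = org,
    source_db = "kegg", nodes = nodes, edges = edges
  )
  n_gene <- sum(vapply(nodes, function(n) n$node_type == "gene_protein",
                       logical(1)))
  if (n_gene == 0L) {
    return(skipped_pathway(pathway_id, "no gene or gene-product nodes"))
  }
  skeleton
}
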