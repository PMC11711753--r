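minimal_gpml <- function() {
  paste(
    '<?xml version="1.0"?>',
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="Mini" Organism="Homo sapiens" ID="WP9001">',
    '  <DataNode TextLabel="MTOR" GraphId="d1" Type="GeneProduct"><Graphics CenterX="100" CenterY="100"/><Xref Database="Entrez Gene" ID="2475"/></DataNode>',
    '  <DataNode TextLabel="AKT1" GraphId="d2" Type="GeneProduct"><Graphics CenterX="200" CenterY="100"/><Xref Database="Ensembl" ID="ENSG00000142208"/></DataNode>',
    '  <Label TextLabel="note" GraphId="l1"><Graphics CenterX="300" CenterY="50"/></Label>',
    '  <Interaction GraphId="i1"><Graphics><Point GraphRef="d1"/><Point GraphRef="d2" ArrowHead="Arrow"/></Graphics></Interaction>',
    '</Pathway>', sep = "\n")
}

gpml_mapping <- function() {
  id_mapping_table(
    to_uniprot = data.frame(
      db = c("Entrez Gene", "Ensembl"),
      id = c("2475", "ENSG00000142208"),
      uniprot = c("P42345", "P31749")),
    uniprot_to_gene = data.frame(uniprot = c("P42345", "P31749"),
                                 gene = c("MTOR", "AKT1"))
  )
}

test_that("node and edge tables have the documented shape (13 / 24, 10 mapped + 14 retained)", {
  ntab <- gpml_node_types()
  expect_identical(nrow(ntab), 13L)
  expect_setequal(unique(ntab$unified),
                  c("gene_protein", "compound", "pathway", "misc"))
  etab <- gpml_edge_types()
  expect_identical(nrow(etab), 24L)
  expect_identical(sum(etab$mapped), 10L)
  expect_identical(sum(!etab$mapped), 14L)
  # retained types keep their own name
  expect_identical(etab$unified[!etab$mapped], etab$gpml[!etab$mapped])
})

test_that("GPML kinds map onto the unified vocabulary", {
  expect_identical(map_gpml_types(gpml_node_type = "GeneProduct")$node_type,
                   "gene_protein")
  expect_identical(map_gpml_types(gpml_node_type = "Protein")$node_type,
                   "gene_protein")
  expect_identical(map_gpml_types(gpml_node_type = "Label")$node_type, "misc")
  expect_identical(map_gpml_types(gpml_node_type = "Metabolite")$node_type,
                   "compound")
  expect_identical(map_gpml_types(gpml_edge_type = "TBar")$edge_subtype,
                   "inhibition")
  expect_identical(map_gpml_types(gpml_edge_type = "Arrow")$edge_subtype,
                   "activation")
  expect_identical(map_gpml_types(gpml_edge_type = "mim-conversion")$edge_subtype,
                   "mim-conversion")  # retained verbatim
  expect_warning(out <- map_gpml_types(gpml_node_type = "Widget"), "unknown")
  expect_identical(out$node_type, "misc")
})

test_that("anchors resolve to edge-on-edge references", {
  interactions <- list(
    list(edge_id = "i1", source = "a", target = "b",
         relation_types = "activation", anchors = "anch1"),
    list(edge_id = "i2", source = "c", target = "anch1",
         relation_types = "inhibition", anchors = character())
  )
  edges <- resolve_anchors(interactions)
  expect_length(edges, 2L)
  expect_identical(edges[[2]]$target, "i1")

  # no anchors: identity modulo representation
  plain <- resolve_anchors(list(list(edge_id = "e", source = "a",
                                     target = "b",
                                     relation_types = "activation",
                                     anchors = character())))
  expect_identical(plain[[1]]$source, "a")
  expect_identical(plain[[1]]$target, "b")

  # chained anchors: anchor on an edge that itself ends on an edge
  chain <- resolve_anchors(list(
    list(edge_id = "i1", source = "a", target = "b",
         relation_types = "activation", anchors = "x1"),
    list(edge_id = "i2", source = "c", target = "x1",
         relation_types = "activation", anchors = "x2"),
    list(edge_id = "i3", source = "d", target = "x2",
         relation_types = "activation", anchors = character())
  ))
  expect_identical(chain[[2]]$target, "i1")
  expect_identical(chain[[3]]$target, "i2")
  # endpoint reference graph is acyclic: walking target refs terminates
  ref <- "i3"
  ids <- vapply(chain, function(e) e$edge_id, "")
  seen <- character()
  while (ref %in% ids) {
    expect_false(ref %in% seen)
    seen <- c(seen, ref)
    ref <- chain[[match(ref, ids)]]$target
  }
})

test_that("a minimal GPML file parses to the hand-counted skeleton", {
  sk <- parse_gpml(minimal_gpml(), gpml_mapping())
  types <- vapply(sk$nodes, function(n) n$node_type, "")
  expect_identical(sum(types == "gene_protein"), 2L)
  expect_identical(sum(types == "misc"), 1L)
  expect_length(sk$edges, 1L)
  expect_identical(validate_skeleton(sk), character(0))
  # Ensembl xref resolved through the offline table
  akt <- sk$nodes[[2]]
  expect_identical(akt$uniprot_accessions, "P31749")
  expect_identical(akt$gene_names, "AKT1")
})

test_that("interactions ending on an anchor become edges targeting edges", {
  xml <- paste(
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="A" ID="WP9002">',
    '  <DataNode TextLabel="G1" GraphId="d1" Type="GeneProduct"><Graphics CenterX="0" CenterY="0"/></DataNode>',
    '  <DataNode TextLabel="G2" GraphId="d2" Type="GeneProduct"><Graphics CenterX="10" CenterY="0"/></DataNode>',
    '  <DataNode TextLabel="G3" GraphId="d3" Type="GeneProduct"><Graphics CenterX="5" CenterY="10"/></DataNode>',
    '  <Interaction GraphId="i1"><Graphics><Point GraphRef="d1"/><Anchor Position="0.5" GraphId="a1"/><Point GraphRef="d2" ArrowHead="Arrow"/></Graphics></Interaction>',
    '  <Interaction GraphId="i2"><Graphics><Point GraphRef="d3"/><Point GraphRef="a1" ArrowHead="TBar"/></Graphics></Interaction>',
    '</Pathway>', sep = "\n")
  sk <- parse_gpml(xml)
  expect_length(sk$edges, 2L)
  expect_identical(sk$edges[[2]]$target, "i1")
  expect_identical(validate_skeleton(sk), character(0))
})

test_that("gene-free GPML pathways are skipped and parsing is deterministic", {
  no_gene <- paste(
    '<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="M" ID="WP9003">',
    '  <DataNode TextLabel="glucose" GraphId="d1" Type="Metabolite"><Graphics CenterX="0" CenterY="0"/></DataNode>',
    '</Pathway>', sep = "\n")
  expect_true(is_skipped_pathway(parse_gpml(no_gene)))

  fx <- make_fixture_pathway(synthetic_spec(seed = 11), "gpml")
  expect_true(skeletons_equal(parse_gpml(fx$xml, fx$id_map),
                              parse_gpml(fx$xml, fx$id_map)))
})
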