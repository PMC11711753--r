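proj_skeleton <- function() {
  pathway_skeleton(
    "proj", nodes = list(
      skeleton_node("n1", "gene_protein", label = "MTOR",
                    uniprot_accessions = "P42345", gene_names = "MTOR",
                    x = 100, y = 100),
      skeleton_node("n2", "gene_protein", label = "MTOR (cascade 2)",
                    uniprot_accessions = "P42345", gene_names = "MTOR",
                    x = 400, y = 300),
      skeleton_node("n3", "gene_protein", label = "RPS6KA1",
                    uniprot_accessions = "Q15418", gene_names = "RPS6KA1",
                    x = 250, y = 100),
      skeleton_node("n4", "gene_protein", label = "SOS1",
                    uniprot_accessions = "Q07889", gene_names = "SOS1",
                    x = 250, y = 250)
    ),
    edges = list(skeleton_edge("e1", "n1", "n3", "activation"))
  )
}

record <- function(gene = character(), acc = character(), site = "S1",
                   regulation = "up", fc = NA_real_, pec50 = NA_real_,
                   key = paste0(gene, "_", site)[1]) {
  ptm_dataset(experiment = "e1", peptide_key = key %||% "pep",
              uniprot_accessions = list(acc), gene_names = list(gene),
              sites = list(parse_site(site)), regulation = regulation,
              fold_change = fc, pec50 = pec50)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

test_that("a record matching a protein that appears twice yields two PTM nodes", {
  g <- project_dataset(record(gene = "MTOR", site = "S2448"),
                       proj_skeleton())
  expect_identical(nrow(g$ptm_nodes), 2L)
  expect_setequal(g$ptm_nodes$node_id, c("n1", "n2"))
  expect_identical(nrow(g$anchor_edges), 2L)
  expect_length(g$unmatched, 0L)
})

test_that("matching works by accession alone or gene name alone (union semantics)", {
  by_acc <- project_dataset(record(acc = "P42345-2", site = "S2448"),
                            proj_skeleton())
  expect_identical(nrow(by_acc$ptm_nodes), 2L)  # isoform suffix stripped
  by_gene <- project_dataset(record(gene = "mtor", site = "S2448"),
                             proj_skeleton())
  expect_identical(nrow(by_gene$ptm_nodes), 2L)  # case-insensitive
})

test_that("unmatched records are reported, not dropped silently", {
  g <- project_dataset(record(gene = "EGFR", site = "Y1068"),
                       proj_skeleton())
  expect_identical(nrow(g$ptm_nodes), 0L)
  expect_identical(g$unmatched, 1L)
})

test_that("collapse replaces PTM nodes by per-regulation summary nodes with counts", {
  ds <- ptm_dataset(
    experiment = "e1",
    peptide_key = sprintf("pep%d", 1:5),
    gene_names = rep(list("SOS1"), 5),
    sites = lapply(sprintf("S%d", 1131:1135), parse_site),
    regulation = c("up", "up", "up", "down", "down")
  )
  g <- project_dataset(ds, proj_skeleton(), collapse = TRUE)
  expect_identical(nrow(g$ptm_nodes), 0L)
  expect_identical(nrow(g$summary_nodes), 2L)
  counts <- setNames(g$summary_nodes$count, g$summary_nodes$regulation)
  expect_identical(counts[["up"]], 3L)
  expect_identical(counts[["down"]], 2L)
  # sum of summary counts equals the number of (record, node) matches
  g_full <- project_dataset(ds, proj_skeleton(), collapse = FALSE)
  expect_identical(sum(g$summary_nodes$count), nrow(g_full$ptm_nodes))
})

test_that("regulation colors use the fixed palette", {
  sc <- color_scale("regulation")
  expect_identical(make_color(list(regulation = "up"), sc), "#d62728")
  expect_identical(make_color(list(regulation = "down"), sc), "#1f77b4")
  expect_identical(make_color(list(regulation = "not"), sc), "#999999")
})

test_that("continuous colors hit the endpoint colors exactly at the domain edges", {
  ds <- ptm_dataset(
    experiment = "e1", peptide_key = c("a", "b", "c"),
    gene_names = rep(list("MTOR"), 3),
    sites = lapply(c("S1", "S2", "S3"), parse_site),
    regulation = c("down", "down", "down"),
    pec50 = c(6.37, 7.41, 7.0)
  )
  g <- project_dataset(ds, proj_skeleton(),
                       scale = color_scale("potency", low = "#1f77b4",
                                           high = "#d62728"))
  expect_equal(g$scale$domain_min, 6.37)
  expect_equal(g$scale$domain_max, 7.41)
  cols <- g$ptm_nodes$color[match(c(1, 2), g$ptm_nodes$record)]
  expect_identical(toupper(cols[1]), "#1F77B4")
  expect_identical(toupper(cols[2]), "#D62728")
})

test_that("degenerate domains give the midpoint color; missing values the no-value gray", {
  sc <- color_scale("fold_change", low = "#000000", high = "#FFFFFF")
  sc$domain_min <- 1; sc$domain_max <- 1
  mid <- make_color(list(regulation = "up", fold_change = 1), sc)
  expect_identical(toupper(mid),
                   toupper(grDevices::rgb(127.5, 127.5, 127.5,
                                          maxColorValue = 255)))
  expect_identical(make_color(list(regulation = "up",
                                   fold_change = NA_real_), sc),
                   sc$na_color)
})

test_that("kinase-substrate overlay edges require both endpoints present", {
  ds <- record(gene = "SOS1", site = "S1134", regulation = "down")
  g <- project_dataset(ds, proj_skeleton())

  hit <- overlay_kinase_edges(g, kinase_substrate_table("RPS6KA1", "SOS1",
                                                        "S1134"))
  expect_identical(nrow(hit$overlay_edges), 1L)
  expect_identical(hit$overlay_edges$source, "n3")

  miss_kin <- overlay_kinase_edges(g, kinase_substrate_table("PLK1", "SOS1",
                                                             "S1134"))
  expect_identical(nrow(miss_kin$overlay_edges), 0L)
  expect_identical(miss_kin$overlay_skipped, 1L)

  two_kin <- overlay_kinase_edges(g, kinase_substrate_table(
    c("RPS6KA1", "MTOR"), c("SOS1", "SOS1"), c("S1134", "S1134")))
  # MTOR appears twice in the skeleton -> 2 edges + 1 from RPS6KA1
  expect_identical(nrow(two_kin$overlay_edges), 3L)

  miss_site <- overlay_kinase_edges(g, kinase_substrate_table("RPS6KA1",
                                                              "SOS1", "S99"))
  expect_identical(nrow(miss_site$overlay_edges), 0L)
})

test_that("kinase highlighting applies inclusive score and exclusive FDR cuts", {
  g <- project_dataset(record(gene = "SOS1", site = "S1134"),
                       proj_skeleton())
  act <- function(score, fdr, kinase = "MTOR", direction = "down") {
    data.frame(kinase = kinase, score = score, fdr = fdr,
               direction = direction)
  }
  marked <- highlight_kinases(g, act(-1.2, 0.01))
  expect_identical(sort(marked$highlights$node_id), c("n1", "n2"))
  expect_identical(unique(marked$highlights$direction), "down")

  inside_cut <- highlight_kinases(g, act(-0.3, 0.01))
  expect_identical(nrow(inside_cut$highlights), 0L)

  not_in_skeleton <- highlight_kinases(g, act(-2, 0.001, kinase = "PLK1"))
  expect_identical(nrow(not_in_skeleton$highlights), 0L)
  expect_identical(not_in_skeleton$highlight_unmatched, "PLK1")
})
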