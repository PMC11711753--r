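# Deterministic synthetic fixtures: pathway XML in both dialects (with ground
# truth), identifier maps, kinase-substrate tables, PSSMs, signatures and PTM
# datasets with planted signal. Everything is reproducible from a seed, so
# the whole test surface of the package needs no downloaded data.

#' Specification for synthetic fixtures
#'
#' Pathway-side fields control the synthetic diagram; dataset-side fields
#' control the synthetic PTM dataset. Defaults describe a small but
#' structurally complete pathway and a phosphoproteomics screen with a
#' planted kinase inhibition: 500 peptides of which the planted kinase's
#' substrates are shifted by -1.5 log2 units over Gaussian noise with
#' standard deviation 0.3 (a strong but realistic drug effect over typical
#' biological/technical spread), and 5% up- / 5% down-regulated bystander
#' peptides.
#'
#' @param seed Integer seed; all fixture generation is deterministic in it.
#' @param n_nodes Number of regular (non-group) nodes in the pathway.
#' @param n_edges Number of relations / plain interactions.
#' @param n_groups Number of group nodes (2 members each).
#' @param n_reactions KGML only: number of many-to-many reactions.
#' @param n_anchors GPML only: number of interactions terminating on an
#'   anchor.
#' @param n_peptides Number of PTM records in the synthetic dataset.
#' @param fraction_up,fraction_down Fractions of bystander records labeled
#'   up/down (with a +/-2 log2 shift).
#' @param planted_kinase Name of the kinase whose substrates carry the
#'   planted effect.
#' @param effect_shift Log2 shift applied to the planted kinase's substrates.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_nodes = 12L, n_edges = 14L,
                           n_groups = 1L, n_reactions = 1L, n_anchors = 1L,
                           n_peptides = 500L, fraction_up = 0.05,
                           fraction_down = 0.05, planted_kinase = "KIN1",
                           effect_shift = -1.5, noise_sd = 0.3) {
  stopifnot(fraction_up >= 0, fraction_down >= 0,
            fraction_up + fraction_down <= 1, is.finite(effect_shift))
  sp <- list(seed = as.integer(seed), n_nodes = as.integer(n_nodes),
             n_edges = as.integer(n_edges), n_groups = as.integer(n_groups),
             n_reactions = as.integer(n_reactions),
             n_anchors = as.integer(n_anchors),
             n_peptides = as.integer(n_peptides),
             fraction_up = fraction_up, fraction_down = fraction_down,
             planted_kinase = planted_kinase, effect_shift = effect_shift,
             noise_sd = noise_sd)
  class(sp) <- "synthetic_spec"
  sp
}

#' Identifier map matching the synthetic fixtures
#'
#' Maps the fixture KEGG ids (`hsa:10<i>`) and Entrez xrefs (`10<i>`) to
#' accessions `P100<i>` and gene symbols `GENE<i>`.
#'
#' @param n Number of genes covered.
#' @return An [id_mapping_table()].
#' @export
fixture_id_map <- function(n = 50L) {
  i <- seq_len(n)
  id_mapping_table(
    to_uniprot = rbind(
      data.frame(db = "KEGG", id = sprintf("hsa:10%02d", i),
                 uniprot = sprintf("P100%02d", i), stringsAsFactors = FALSE),
      data.frame(db = "Entrez Gene", id = sprintf("10%02d", i),
                 uniprot = sprintf("P100%02d", i), stringsAsFactors = FALSE)
    ),
    uniprot_to_gene = data.frame(uniprot = sprintf("P100%02d", i),
                                 gene = sprintf("GENE%d", i),
                                 stringsAsFactors = FALSE)
  )
}

fixture_node_plan <- function(spec) {
  n <- spec$n_nodes
  n_compound <- if (spec$n_reactions > 0) max(2L, n %/% 5L) else
    if (n >= 4L) 1L else 0L
  n_map <- if (n >= 5L) 1L else 0L
  n_gene <- n - n_compound - n_map
  if (n_gene < 1L) stop("spec too small: needs at least one gene node")
  types <- c(rep("gene", n_gene), rep("compound", n_compound),
             rep("map", n_map))
  data.frame(
    idx = seq_len(n), kind = types,
    x = 80 + 90 * ((seq_len(n) - 1) %% 5),
    y = 80 + 70 * ((seq_len(n) - 1) %/% 5),
    stringsAsFactors = FALSE
  )
}

sample_edge_pairs <- function(n_nodes, n_edges) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    stop(sprintf("infeasible spec: %d edges exceed the %d-node complete graph",
                 n_edges, n_nodes))
  }
  all_pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  chosen <- all_pairs[sample.int(nrow(all_pairs), n_edges), , drop = FALSE]
  flip <- sample(c(TRUE, FALSE), n_edges, replace = TRUE)
  data.frame(from = ifelse(flip, chosen[, 2], chosen[, 1]),
             to = ifelse(flip, chosen[, 1], chosen[, 2]))
}

#' Generate a synthetic pathway file with ground truth
#'
#' Emits a pathway document in the requested XML dialect together with the
#' skeleton the corresponding reader is expected to produce. The generated
#' diagram contains gene, compound and pathway-link nodes, the requested
#' number of groups, and a many-to-many reaction (KGML) or anchored
#' interaction (GPML) when requested. Byte-identical output under the same
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dialect `"kgml"` or `"gpml"`.
#' @return List with elements `xml` (string), `skeleton` (ground truth
#'   [pathway_skeleton()]) and `id_map` (the matching [fixture_id_map()]).
#' @export
make_fixture_pathway <- function(spec, dialect = c("kgml", "gpml")) {
  dialect <- match.arg(dialect)
  with_seed(spec$seed, {
    if (dialect == "kgml") fixture_kgml(spec) else fixture_gpml(spec)
  })
}

fixture_kgml <- function(spec) {
  plan <- fixture_node_plan(spec)
  id_map <- fixture_id_map(max(50L, spec$n_nodes))
  pathway_id <- sprintf("syn%05d", spec$seed %% 100000L)

  entries <- character()
  nodes <- list()
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    if (p$kind == "gene") {
      kegg_id <- sprintf("hsa:10%02d", p$idx)
      gene <- sprintf("GENE%d", p$idx)
      acc <- sprintf("P100%02d", p$idx)
      entries <- c(entries, sprintf(
        '  <entry id="%d" name="%s" type="gene"><graphics name="%s" x="%d" y="%d" width="46" height="17"/></entry>',
        p$idx, kegg_id, gene, p$x, p$y))
      nodes[[i]] <- skeleton_node(sprintf("n%d", p$idx), "gene_protein",
                                  label = gene, uniprot_accessions = acc,
                                  gene_names = gene, x = p$x, y = p$y)
    } else if (p$kind == "compound") {
      cid <- sprintf("cpd:C%05d", p$idx)
      entries <- c(entries, sprintf(
        '  <entry id="%d" name="%s" type="compound"><graphics name="%s" x="%d" y="%d" width="8" height="8"/></entry>',
        p$idx, cid, cid, p$x, p$y))
      nodes[[i]] <- skeleton_node(sprintf("n%d", p$idx), "compound",
                                  label = cid, x = p$x, y = p$y)
    } else {
      mid <- sprintf("path:hsa%05d", p$idx)
      entries <- c(entries, sprintf(
        '  <entry id="%d" name="%s" type="map"><graphics name="Linked pathway" x="%d" y="%d" width="46" height="17"/></entry>',
        p$idx, mid, p$x, p$y))
      nodes[[i]] <- skeleton_node(sprintf("n%d", p$idx), "pathway",
                                  label = "Linked pathway", x = p$x, y = p$y)
    }
  }

  # groups over consecutive gene pairs
  gene_idx <- plan$idx[plan$kind == "gene"]
  if (spec$n_groups * 2 > length(gene_idx)) {
    stop("infeasible spec: not enough gene nodes for the requested groups")
  }
  for (g in seq_len(spec$n_groups)) {
    members <- gene_idx[(2 * g - 1):(2 * g)]
    gid <- nrow(plan) + g
    entries <- c(entries, sprintf(
      '  <entry id="%d" name="undefined" type="group">%s</entry>',
      gid, paste(sprintf('<component id="%d"/>', members), collapse = "")))
    nodes[[length(nodes) + 1L]] <- skeleton_node(
      sprintf("n%d", gid), "group", members = sprintf("n%d", members))
  }

  # relations
  rel_tab <- kegg_relation_subtypes()
  pairs <- sample_edge_pairs(spec$n_nodes, spec$n_edges)
  subtype <- sample(rel_tab$kgml, spec$n_edges, replace = TRUE)
  relations <- sprintf(
    '  <relation entry1="%d" entry2="%d" type="PPrel"><subtype name="%s" value=""/></relation>',
    pairs$from, pairs$to, subtype)
  edges <- lapply(seq_len(spec$n_edges), function(i) {
    skeleton_edge(sprintf("rel%d", i),
                  sprintf("n%d", pairs$from[i]), sprintf("n%d", pairs$to[i]),
                  rel_tab$unified[match(subtype[i], rel_tab$kgml)])
  })

  # reactions over compounds
  reactions <- character()
  comp_idx <- plan$idx[plan$kind == "compound"]
  for (r in seq_len(spec$n_reactions)) {
    n_s <- if (length(comp_idx) >= 4) 2L else 1L
    subs <- comp_idx[seq_len(n_s)]
    prods <- setdiff(comp_idx, subs)[1]
    reversible <- (r %% 2 == 0)
    reactions <- c(reactions, sprintf(
      '  <reaction id="%d" name="rn:R%05d" type="%s">%s%s</reaction>',
      1000 + r, r, if (reversible) "reversible" else "irreversible",
      paste(sprintf('<substrate id="%d" name="s"/>', subs), collapse = ""),
      paste(sprintf('<product id="%d" name="p"/>', prods), collapse = "")))
    expanded <- expand_reaction(list(
      reaction_id = sprintf("rxn%d", r),
      substrates = sprintf("n%d", subs), products = sprintf("n%d", prods),
      reversible = reversible))
    edges <- c(edges, expanded)
  }

  xml <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<pathway name="path:%s" org="syn" title="Synthetic pathway %s">',
            pathway_id, pathway_id),
    entries, relations, reactions, "</pathway>"), collapse = "\n")

  skeleton <- pathway_skeleton(pathway_id,
                               name = sprintf("Synthetic pathway %s",
                                              pathway_id),
                               organism = "syn", source_db = "kegg",
                               nodes = nodes, edges = edges)
  list(xml = xml, skeleton = skeleton, id_map = id_map)
}

fixture_gpml <- function(spec) {
  plan <- fixture_node_plan(spec)
  id_map <- fixture_id_map(max(50L, spec$n_nodes))
  pathway_id <- sprintf("SYNWP%d", spec$seed %% 100000L)

  elements <- character()
  nodes <- list()
  gene_idx <- plan$idx[plan$kind == "gene"]
  group_of <- rep(NA_integer_, nrow(plan))
  if (spec$n_groups * 2 > length(gene_idx)) {
    stop("infeasible spec: not enough gene nodes for the requested groups")
  }
  for (g in seq_len(spec$n_groups)) {
    group_of[gene_idx[(2 * g - 1):(2 * g)]] <- g
  }

  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    gid <- sprintf("d%d", p$idx)
    gref <- if (!is.na(group_of[i])) sprintf(' GroupRef="g%d"', group_of[i])
            else ""
    if (p$kind == "gene") {
      gene <- sprintf("GENE%d", p$idx)
      acc <- sprintf("P100%02d", p$idx)
      elements <- c(elements, sprintf(
        '  <DataNode TextLabel="%s" GraphId="%s" Type="GeneProduct"%s><Graphics CenterX="%d" CenterY="%d"/><Xref Database="Entrez Gene" ID="10%02d"/></DataNode>',
        gene, gid, gref, p$x, p$y, p$idx))
      nodes[[i]] <- skeleton_node(gid, "gene_protein", label = gene,
                                  uniprot_accessions = acc, gene_names = gene,
                                  x = p$x, y = p$y)
    } else if (p$kind == "compound") {
      lbl <- sprintf("Metabolite%d", p$idx)
      elements <- c(elements, sprintf(
        '  <DataNode TextLabel="%s" GraphId="%s" Type="Metabolite"%s><Graphics CenterX="%d" CenterY="%d"/><Xref Database="ChEBI" ID="CHEBI:%d"/></DataNode>',
        lbl, gid, gref, p$x, p$y, p$idx))
      nodes[[i]] <- skeleton_node(gid, "compound", label = lbl,
                                  x = p$x, y = p$y)
    } else {
      lbl <- "Linked pathway"
      elements <- c(elements, sprintf(
        '  <DataNode TextLabel="%s" GraphId="%s" Type="Pathway"%s><Graphics CenterX="%d" CenterY="%d"/></DataNode>',
        lbl, gid, gref, p$x, p$y))
      nodes[[i]] <- skeleton_node(gid, "pathway", label = lbl,
                                  x = p$x, y = p$y)
    }
  }

  # one free-text label node (misc)
  elements <- c(elements,
    '  <Label TextLabel="annotation" GraphId="lab1"><Graphics CenterX="420" CenterY="40"/></Label>')
  nodes[[length(nodes) + 1L]] <- skeleton_node("lab1", "misc",
                                               label = "annotation",
                                               x = 420, y = 40)

  for (g in seq_len(spec$n_groups)) {
    members <- sprintf("d%d", gene_idx[(2 * g - 1):(2 * g)])
    nodes[[length(nodes) + 1L]] <- skeleton_node(sprintf("group_g%d", g),
                                                 "group", members = members)
  }

  edge_tab <- gpml_edge_types()
  pairs <- sample_edge_pairs(spec$n_nodes, spec$n_edges)
  arrows <- sample(edge_tab$gpml, spec$n_edges, replace = TRUE)
  interactions <- character()
  edges <- list()
  for (i in seq_len(spec$n_edges)) {
    anchor <- if (i == 1L && spec$n_anchors > 0L) {
      '<Anchor Position="0.5" GraphId="anch1"/>'
    } else ""
    interactions <- c(interactions, sprintf(
      '  <Interaction GraphId="i%d"><Graphics><Point GraphRef="d%d"/>%s<Point GraphRef="d%d" ArrowHead="%s"/></Graphics></Interaction>',
      i, pairs$from[i], anchor, pairs$to[i], arrows[i]))
    edges[[i]] <- skeleton_edge(
      sprintf("i%d", i), sprintf("d%d", pairs$from[i]),
      sprintf("d%d", pairs$to[i]),
      edge_tab$unified[match(arrows[i], edge_tab$gpml)])
  }
  for (a in seq_len(spec$n_anchors)) {
    src <- sprintf("d%d", gene_idx[(a - 1L) %% length(gene_idx) + 1L])
    eid <- sprintf("ia%d", a)
    interactions <- c(interactions, sprintf(
      '  <Interaction GraphId="%s"><Graphics><Point GraphRef="%s"/><Point GraphRef="anch1" ArrowHead="TBar"/></Graphics></Interaction>',
      eid, src))
    edges[[length(edges) + 1L]] <- skeleton_edge(eid, src, "i1", "inhibition")
  }

  groups_xml <- sprintf('  <Group GroupId="g%d"/>', seq_len(spec$n_groups))
  xml <- paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="Synthetic pathway %s" Organism="Homo sapiens" ID="%s">',
            pathway_id, pathway_id),
    elements, interactions, groups_xml, "</Pathway>"), collapse = "\n")

  skeleton <- pathway_skeleton(pathway_id,
                               name = sprintf("Synthetic pathway %s",
                                              pathway_id),
                               organism = "Homo sapiens",
                               source_db = "wikipathways",
                               nodes = nodes, edges = edges)
  list(xml = xml, skeleton = skeleton, id_map = id_map)
}

#' Synthetic kinase-substrate table
#'
#' Kinases `KIN1..KINn`, each annotated with substrates drawn from the
#' fixture gene symbols, at sites unique across the whole table.
#'
#' @param spec A [synthetic_spec()].
#' @param n_kinases Number of kinases.
#' @param substrates_per_kinase Substrates annotated per kinase.
#' @return A [kinase_substrate_table()].
#' @export
make_fixture_ks_table <- function(spec, n_kinases = 20L,
                                  substrates_per_kinase = 10L) {
  with_seed(spec$seed + 1L, {
    rows <- n_kinases * substrates_per_kinase
    kin <- rep(sprintf("KIN%d", seq_len(n_kinases)),
               each = substrates_per_kinase)
    sub <- sprintf("GENE%d", sample.int(max(50L, spec$n_nodes), rows,
                                        replace = TRUE))
    kinase_substrate_table(kin, sub, sprintf("S%d", 100 + seq_len(rows)))
  })
}

#' Synthetic PTM dataset with planted kinase signal
#'
#' Generates one record per kinase-substrate annotation plus filler records
#' up to `n_peptides`. Substrates of the planted kinase get fold changes
#' shifted by `effect_shift` over Gaussian noise of sd `noise_sd` and are
#' labeled by the shift's direction; `fraction_up` / `fraction_down` of the
#' filler records are labeled as regulated bystanders with a +/-2 log2
#' shift; all other records are unregulated noise. In potency mode the
#' regulated records additionally receive pEC50 values spanning exactly the
#' band `potency_band` (emulating a drug acting within roughly one order of
#' magnitude of concentration).
#'
#' @param spec A [synthetic_spec()].
#' @param skeleton Optional [pathway_skeleton()]; when given, substrate gene
#'   symbols that also occur in the skeleton make the records projectable.
#' @param ks_table A [kinase_substrate_table()] containing
#'   `spec$planted_kinase`.
#' @param potency Assign pEC50 values to regulated records.
#' @param potency_band Two-element potency band (pEC50).
#' @return A [ptm_dataset()] with attribute `planted` (list with the kinase
#'   and its substrate site keys).
#' @export
make_synthetic_dataset <- function(spec, skeleton = NULL, ks_table,
                                   potency = FALSE,
                                   potency_band = c(6.4, 7.4)) {
  if (!spec$planted_kinase %in% ks_table$kinase) {
    stop(sprintf("planted kinase %s absent from the kinase-substrate table",
                 spec$planted_kinase))
  }
  with_seed(spec$seed + 2L, {
    n_annot <- nrow(ks_table)
    n_fill <- max(0L, spec$n_peptides - n_annot)
    planted <- ks_table$kinase == spec$planted_kinase

    gene <- c(ks_table$substrate, sprintf("FILLER%d", seq_len(n_fill)))
    site <- c(ks_table$site, sprintf("S%d", 10000 + seq_len(n_fill)))
    n <- length(gene)
    fc <- stats::rnorm(n, 0, spec$noise_sd)
    fc[planted] <- fc[planted] + spec$effect_shift
    regulation <- rep("not", n)
    if (spec$effect_shift < 0) regulation[planted] <- "down"
    if (spec$effect_shift > 0) regulation[planted] <- "up"

    fill_idx <- n_annot + seq_len(n_fill)
    n_up <- round(spec$fraction_up * n_fill)
    n_down <- round(spec$fraction_down * n_fill)
    shuffled <- sample(fill_idx)
    up_idx <- shuffled[seq_len(n_up)]
    down_idx <- shuffled[n_up + seq_len(n_down)]
    fc[up_idx] <- fc[up_idx] + 2
    fc[down_idx] <- fc[down_idx] - 2
    regulation[up_idx] <- "up"
    regulation[down_idx] <- "down"

    pec50 <- rep(NA_real_, n)
    if (potency) {
      reg_idx <- which(regulation != "not")
      if (length(reg_idx) == 1L) {
        pec50[reg_idx] <- mean(potency_band)
      } else if (length(reg_idx) > 1L) {
        pec50[reg_idx] <- seq(potency_band[1], potency_band[2],
                              length.out = length(reg_idx))
      }
    }

    ds <- ptm_dataset(
      experiment = "synthetic",
      peptide_key = sprintf("%s_%s", gene, site),
      uniprot_accessions = rep(list(character()), n),
      gene_names = lapply(gene, identity),
      sites = lapply(site, parse_site),
      regulation = regulation,
      fold_change = fc,
      pec50 = pec50
    )
    attr(ds, "planted") <- list(
      kinase = spec$planted_kinase,
      sites = sprintf("%s_%s", ks_table$substrate[planted],
                      ks_table$site[planted])
    )
    ds
  })
}

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic kinase PSSMs
#'
#' One PSSM per kinase over the window -5..+4; each kinase strongly prefers
#' a distinct residue at each flank position (weight `strength` vs 1 for the
#' rest), giving well-separated motifs.
#'
#' @param spec A [synthetic_spec()].
#' @param n_kinases Number of kinases (named `KIN1..`).
#' @param strength Preference weight of the favored residue.
#' @return Named list of [pssm()] objects.
#' @export
make_fixture_pssms <- function(spec, n_kinases = 10L, strength = 8) {
  with_seed(spec$seed + 3L, {
    out <- lapply(seq_len(n_kinases), function(k) {
      m <- matrix(1, 10, length(AMINO_ACIDS),
                  dimnames = list(NULL, AMINO_ACIDS))
      fav <- sample(AMINO_ACIDS, 10, replace = TRUE)
      for (i in 1:10) m[i, fav[i]] <- strength
      m[6, ] <- 1; m[6, c("S", "T", "Y")] <- strength  # phospho-acceptor
      pssm(sprintf("KIN%d", k), m, -5:4)
    })
    names(out) <- vapply(out, function(m) m$kinase, character(1))
    out
  })
}

#' Sample flanking sequences from a PSSM
#'
#' Draws residues position-wise with probability proportional to the PSSM
#' weights (center forced to S).
#'
#' @param mat A [pssm()].
#' @param n Number of sequences.
#' @return Character vector of flanking sequences.
#' @export
sample_pssm_peptides <- function(mat, n) {
  vapply(seq_len(n), function(i) {
    aa <- vapply(seq_along(mat$positions), function(p) {
      w <- mat$matrix[p, ]
      sample(colnames(mat$matrix), 1, prob = w / sum(w))
    }, character(1))
    aa[mat$positions == 0] <- "S"
    paste(aa, collapse = "")
  }, character(1))
}

#' Random flanking sequences
#'
#' Uniform residues, center forced to S.
#' @param n Number of sequences.
#' @param width Window width.
#' @return Character vector.
#' @export
random_flanks <- function(n, width = 10L) {
  center <- width %/% 2 + 1L
  vapply(seq_len(n), function(i) {
    aa <- sample(AMINO_ACIDS, width, replace = TRUE)
    aa[center] <- "S"
    paste(aa, collapse = "")
  }, character(1))
}

#' Synthetic gene-set signature database
#'
#' One signature per requested set: random gene symbols from the fixture
#' vocabulary, plus (optionally) a signature equal to a skeleton's gene set.
#'
#' @param spec A [synthetic_spec()].
#' @param n_signatures Number of random signatures.
#' @param size Members per signature.
#' @param skeleton Optional skeleton whose gene symbols become an extra
#'   signature named after the pathway.
#' @return List of [signature_set()] objects.
#' @export
make_fixture_signatures <- function(spec, n_signatures = 10L, size = 8L,
                                    skeleton = NULL) {
  with_seed(spec$seed + 4L, {
    sigs <- lapply(seq_len(n_signatures), function(i) {
      signature_set(sprintf("SIG%d", i),
                    sprintf("GENE%d", sample.int(50L, size)))
    })
    if (!is.null(skeleton)) {
      genes <- unique(unlist(lapply(skeleton$nodes, function(n) n$gene_names)))
      genes <- genes[nzchar(genes)]
      if (length(genes)) {
        sigs <- c(sigs, list(signature_set(skeleton$pathway_id, genes)))
      }
    }
    sigs
  })
}

#' Random well-formed skeleton
#'
#' Random typed nodes, edges (including, optionally, an edge terminating on
#' another edge) and one group; always contains gene_protein nodes, so it
#' passes validation. Used for serialization round-trip testing.
#'
#' @param seed Integer seed.
#' @param n_nodes,n_edges Graph size.
#' @param edge_on_edge Include an edge whose target is another edge.
#' @return A [pathway_skeleton()].
#' @export
random_skeleton <- function(seed = 1L, n_nodes = 8L, n_edges = 10L,
                            edge_on_edge = TRUE) {
  with_seed(seed, {
    types <- sample(c("gene_protein", "compound", "pathway", "misc"),
                    n_nodes, replace = TRUE,
                    prob = c(0.6, 0.2, 0.1, 0.1))
    types[1] <- "gene_protein"
    nodes <- lapply(seq_len(n_nodes), function(i) {
      skeleton_node(sprintf("n%d", i), types[i],
                    label = sprintf("N%d", i),
                    uniprot_accessions = if (types[i] == "gene_protein") {
                      sprintf("P%05d", i)
                    } else character(),
                    gene_names = if (types[i] == "gene_protein") {
                      sprintf("GENE%d", i)
                    } else character(),
                    x = round(stats::runif(1, 0, 500), 2),
                    y = round(stats::runif(1, 0, 500), 2))
    })
    nodes[[n_nodes + 1L]] <- skeleton_node("grp1", "group",
                                           members = c("n1", "n2"))
    subtypes <- kegg_relation_subtypes()$unified
    edges <- lapply(seq_len(n_edges), function(i) {
      skeleton_edge(sprintf("e%d", i),
                    sprintf("n%d", sample.int(n_nodes, 1)),
                    sprintf("n%d", sample.int(n_nodes, 1)),
                    sample(subtypes, sample.int(2, 1)))
    })
    if (edge_on_edge && n_edges >= 2L) {
      edges[[n_edges]] <- skeleton_edge(sprintf("e%d", n_edges),
                                        "n1", "e1", "activation")
    }
    pathway_skeleton(sprintf("RSK%d", seed), organism = "syn",
                     source_db = "custom", nodes = nodes, edges = edges)
  })
}
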