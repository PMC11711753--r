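# Projection of a PTM regulation dataset onto a pathway skeleton: identifier
# matching, generation of PTM / summary nodes and their invisible anchor
# edges, color resolution, kinase-substrate overlay edges, and threshold-based
# highlighting of perturbed kinases.

REGULATION_LEVELS <- c("up", "down", "not")

#' Construct a PTM dataset
#'
#' One row per regulated modified peptide per experiment. Identifier columns
#' are list columns so a record can carry several accessions / gene symbols /
#' modified sites.
#'
#' @param experiment Character vector of experiment labels.
#' @param peptide_key Modified-peptide or site identifiers.
#' @param uniprot_accessions List of character vectors (one per record).
#' @param gene_names List of character vectors.
#' @param sites List of data frames with columns `residue` (one-letter code)
#'   and `position` (1-based integer); may be empty per record.
#' @param regulation One of `"up"`, `"down"`, `"not"` per record
#'   (case-insensitive).
#' @param fold_change Signed log2 fold change (optional, `NA` allowed).
#' @param p_adj Adjusted p-value in `[0, 1]` (optional).
#' @param pec50 Potency as -log10 molar EC50 (optional).
#' @param details List of named lists with free-form annotations.
#' @return A data frame of class `ptm_dataset`.
#' @export
ptm_dataset <- function(experiment, peptide_key, uniprot_accessions = NULL,
                        gene_names = NULL, sites = NULL, regulation,
                        fold_change = NA_real_, p_adj = NA_real_,
                        pec50 = NA_real_, details = NULL) {
  n <- length(peptide_key)
  regulation <- tolower(as.character(regulation))
  bad <- !regulation %in% REGULATION_LEVELS
  if (any(bad)) {
    stop(sprintf("invalid regulation value(s): %s",
                 paste(unique(regulation[bad]), collapse = ", ")))
  }
  empty_sites <- data.frame(residue = character(), position = integer(),
                            stringsAsFactors = FALSE)
  sites <- sites %||% rep(list(empty_sites), n)
  for (s in sites) {
    if (nrow(s) && any(s$position < 1L)) stop("site positions must be >= 1")
  }
  ds <- data.frame(
    experiment = rep_len(as.character(experiment), n),
    peptide_key = as.character(peptide_key),
    regulation = regulation,
    fold_change = rep_len(as.numeric(fold_change), n),
    p_adj = rep_len(as.numeric(p_adj), n),
    pec50 = rep_len(as.numeric(pec50), n),
    stringsAsFactors = FALSE
  )
  ds$uniprot_accessions <- uniprot_accessions %||% rep(list(character()), n)
  ds$gene_names <- gene_names %||% rep(list(character()), n)
  ds$sites <- sites
  ds$details <- details %||% rep(list(list()), n)
  class(ds) <- c("ptm_dataset", class(ds))
  ds
}

# --- color scales -------------------------------------------------------------

#' Define a PTM node color scale
#'
#' Three modes mirror the three coloring schemes of the renderer: `regulation`
#' uses a fixed categorical palette (up = red, down = blue, not = gray);
#' `fold_change` and `potency` interpolate linearly between two endpoint
#' colors over the range of values observed among the *matched* records (the
#' domain is determined after projection).
#'
#' @param mode `"regulation"`, `"fold_change"` or `"potency"`.
#' @param low,high Endpoint colors for the continuous modes.
#' @param palette Named colors for regulation mode.
#' @param na_color Color used when a continuous-mode record lacks the value.
#' @return An object of class `color_scale`.
#' @export
color_scale <- function(mode = c("regulation", "fold_change", "potency"),
                        low = "#1f77b4", high = "#d62728",
                        palette = c(up = "#d62728", down = "#1f77b4",
                                    not = "#999999"),
                        na_color = "#cccccc") {
  mode <- match.arg(mode)
  sc <- list(mode = mode, low = low, high = high, palette = palette,
             na_color = na_color, domain_min = NA_real_,
             domain_max = NA_real_)
  class(sc) <- "color_scale"
  sc
}

scale_value_of <- function(record, scale) {
  switch(scale$mode,
         regulation = NA_real_,
         fold_change = record$fold_change,
         potency = record$pec50)
}

# Fix the continuous domain from the values of the matched records only.
resolve_scale_domain <- function(scale, values) {
  if (scale$mode == "regulation") return(scale)
  values <- values[is.finite(values)]
  if (length(values)) {
    scale$domain_min <- min(values)
    scale$domain_max <- max(values)
  }
  scale
}

interp_color <- function(low, high, t) {
  ramp <- grDevices::colorRamp(c(low, high))
  rgb <- ramp(max(0, min(1, t)))
  grDevices::rgb(rgb[1], rgb[2], rgb[3], maxColorValue = 255)
}

#' Color of a single PTM record under a scale
#'
#' Regulation mode returns the fixed palette color. Continuous modes
#' interpolate between the endpoint colors over `[domain_min, domain_max]`;
#' the domain endpoints map exactly onto the endpoint colors. A degenerate
#' domain (all matched records share one value) yields the midpoint color; a
#' record without the relevant value gets the designated no-value color.
#'
#' @param record A single-row slice of a [ptm_dataset()] (or a list with the
#'   same fields).
#' @param scale A [color_scale()] with a resolved domain (as stored on a
#'   projected graph; see [project_dataset()]).
#' @return A hex color string.
#' @export
make_color <- function(record, scale) {
  if (scale$mode == "regulation") {
    return(unname(scale$palette[[record$regulation]]))
  }
  v <- scale_value_of(record, scale)
  if (!length(v) || !is.finite(v)) return(scale$na_color)
  if (!is.finite(scale$domain_min) || !is.finite(scale$domain_max)) {
    return(scale$na_color)
  }
  width <- scale$domain_max - scale$domain_min
  t <- if (width == 0) 0.5 else (v - scale$domain_min) / width
  interp_color(scale$low, scale$high, t)
}

# --- matching -----------------------------------------------------------------

# A record matches a node if any stripped accession matches (exact) or any
# gene name matches case-insensitively ("and/or" union semantics).
record_matches_node <- function(record, node) {
  rec_acc <- strip_isoform(record$uniprot_accessions[[1]])
  node_acc <- strip_isoform(node$uniprot_accessions)
  if (length(rec_acc) && length(node_acc) &&
      length(intersect(rec_acc, node_acc))) {
    return(TRUE)
  }
  rec_gene <- tolower(record$gene_names[[1]])
  node_gene <- tolower(c(node$gene_names, node$label))
  length(rec_gene) > 0L && length(intersect(rec_gene, node_gene)) > 0L
}

#' Project a PTM dataset onto a pathway skeleton
#'
#' Each record is compared against every skeleton node by UniProt accession
#' (exact, isoform suffixes stripped) and/or gene name (case-insensitive); a
#' record matching several nodes yields one PTM node per match (proteins can
#' legitimately appear twice in one diagram). Matched records get an
#' invisible anchor edge to their reference node and a color from the scale,
#' whose continuous domain is fixed over the matched records only. With
#' `collapse = TRUE` the per-record nodes are replaced by one summary node
#' per (skeleton node, regulation type) carrying the count of collapsed
#' records.
#'
#' @param dataset A [ptm_dataset()].
#' @param skeleton A [pathway_skeleton()].
#' @param scale A [color_scale()].
#' @param collapse Collapse per-record PTM nodes into summary nodes.
#' @return An object of class `projected_graph` with fields `base`,
#'   `ptm_nodes`, `anchor_edges`, `summary_nodes`, `overlay_edges`,
#'   `highlights`, `unmatched` (record indices that matched no node) and
#'   `scale` (domain-resolved).
#' @export
project_dataset <- function(dataset, skeleton, scale = color_scale(),
                            collapse = FALSE) {
  stopifnot(inherits(skeleton, "pathway_skeleton"))
  matchable <- Filter(function(n) n$node_type != "group", skeleton$nodes)
  pairs_rec <- integer(); pairs_node <- character()
  for (i in seq_len(nrow(dataset))) {
    rec <- dataset[i, ]
    for (n in matchable) {
      if (record_matches_node(rec, n)) {
        pairs_rec <- c(pairs_rec, i)
        pairs_node <- c(pairs_node, n$node_id)
      }
    }
  }
  unmatched <- setdiff(seq_len(nrow(dataset)), unique(pairs_rec))

  scale <- resolve_scale_domain(
    scale,
    vapply(unique(pairs_rec), function(i) {
      v <- scale_value_of(dataset[i, ], scale)
      if (length(v)) v else NA_real_
    }, numeric(1))
  )

  ptm_nodes <- data.frame(
    ptm_node_id = character(), record = integer(), node_id = character(),
    regulation = character(), color = character(), label = character(),
    x = numeric(), y = numeric(), stringsAsFactors = FALSE
  )
  summary_nodes <- data.frame(
    summary_node_id = character(), node_id = character(),
    regulation = character(), count = integer(), color = character(),
    x = numeric(), y = numeric(), stringsAsFactors = FALSE
  )
  anchor_edges <- data.frame(edge_id = character(), source = character(),
                             target = character(), stringsAsFactors = FALSE)

  if (length(pairs_rec)) {
    if (collapse) {
      key <- paste(pairs_node, dataset$regulation[pairs_rec], sep = "\r")
      tab <- table(key)
      parts <- strsplit(names(tab), "\r", fixed = TRUE)
      reg_palette <- color_scale("regulation")$palette
      summary_nodes <- data.frame(
        summary_node_id = sprintf("summary_%s_%s",
                                  vapply(parts, `[`, "", 1),
                                  vapply(parts, `[`, "", 2)),
        node_id = vapply(parts, `[`, "", 1),
        regulation = vapply(parts, `[`, "", 2),
        count = as.integer(tab),
        color = unname(reg_palette[vapply(parts, `[`, "", 2)]),
        x = NA_real_, y = NA_real_, stringsAsFactors = FALSE
      )
      anchor_edges <- data.frame(
        edge_id = paste0("anchor_", summary_nodes$summary_node_id),
        source = summary_nodes$summary_node_id,
        target = summary_nodes$node_id, stringsAsFactors = FALSE
      )
    } else {
      site_label <- vapply(pairs_rec, function(i) {
        s <- dataset$sites[[i]]
        if (nrow(s)) paste(paste0(s$residue, s$position), collapse = "/")
        else ""
      }, character(1))
      ptm_nodes <- data.frame(
        ptm_node_id = sprintf("ptm_%d_%s", pairs_rec, pairs_node),
        record = pairs_rec,
        node_id = pairs_node,
        regulation = dataset$regulation[pairs_rec],
        color = vapply(seq_along(pairs_rec), function(k) {
          make_color(dataset[pairs_rec[k], ], scale)
        }, character(1)),
        label = site_label,
        x = NA_real_, y = NA_real_, stringsAsFactors = FALSE
      )
      anchor_edges <- data.frame(
        edge_id = paste0("anchor_", ptm_nodes$ptm_node_id),
        source = ptm_nodes$ptm_node_id,
        target = ptm_nodes$node_id, stringsAsFactors = FALSE
      )
    }
  }

  graph <- list(
    base = skeleton,
    dataset = dataset,
    ptm_nodes = ptm_nodes,
    summary_nodes = summary_nodes,
    anchor_edges = anchor_edges,
    overlay_edges = data.frame(edge_id = character(), source = character(),
                               target = character(), kinase = character(),
                               stringsAsFactors = FALSE),
    highlights = data.frame(node_id = character(), direction = character(),
                            stringsAsFactors = FALSE),
    unmatched = unmatched,
    scale = scale,
    collapse = collapse,
    laid_out = FALSE
  )
  class(graph) <- "projected_graph"
  graph
}

#' @export
print.projected_graph <- function(x, ...) {
  cat(sprintf("<projected_graph> on %s\n", x$base$pathway_id))
  cat(sprintf("  %d PTM nodes, %d summary nodes, %d anchor edges, %d overlay edges, %d highlights, %d unmatched records\n",
              nrow(x$ptm_nodes), nrow(x$summary_nodes), nrow(x$anchor_edges),
              nrow(x$overlay_edges), nrow(x$highlights), length(x$unmatched)))
  invisible(x)
}

#' Construct a kinase-substrate annotation table
#'
#' @param kinase Kinase gene symbols.
#' @param substrate Substrate identifiers (UniProt accession or gene symbol).
#' @param site Site strings, residue letter followed by 1-based position
#'   (e.g. `"S1134"`).
#' @return Data frame of class `kinase_substrate_table`.
#' @export
kinase_substrate_table <- function(kinase, substrate, site) {
  ok <- grepl("^[A-Za-z][0-9]+$", site)
  if (!all(ok)) {
    stop(sprintf("malformed site string(s): %s",
                 paste(unique(site[!ok]), collapse = ", ")))
  }
  tab <- data.frame(kinase = as.character(kinase),
                    substrate = as.character(substrate),
                    site = as.character(site), stringsAsFactors = FALSE)
  class(tab) <- c("kinase_substrate_table", class(tab))
  tab
}

#' Read a kinase-substrate table from TSV
#'
#' Expects columns `kinase`, `substrate`, `site`.
#' @param path Path to the TSV file.
#' @return A [kinase_substrate_table()].
#' @export
read_kinase_substrate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  kinase_substrate_table(df$kinase, df$substrate, df$site)
}

node_gene_keys <- function(node) {
  tolower(c(node$gene_names, node$label))
}

#' Overlay kinase-substrate edges on a projected graph
#'
#' For every annotation row whose kinase matches a `gene_protein` skeleton
#' node (by gene symbol, case-insensitive) and whose substrate site matches a
#' projected PTM node (substrate identifier against the record's accessions
#' or gene names; site against any of the record's modified sites), one
#' overlay edge kinase-node -> PTM-node is added. Rows without a match are
#' counted in `overlay_skipped`.
#'
#' @param graph A [project_dataset()] result (not collapsed).
#' @param table A [kinase_substrate_table()].
#' @return The graph with `overlay_edges` filled in.
#' @export
overlay_kinase_edges <- function(graph, table) {
  stopifnot(inherits(graph, "projected_graph"))
  kin_nodes <- Filter(function(n) n$node_type == "gene_protein",
                      graph$base$nodes)
  edges <- graph$overlay_edges
  skipped <- 0L
  for (r in seq_len(nrow(table))) {
    kin <- tolower(table$kinase[r])
    sub_id <- tolower(table$substrate[r])
    res <- substr(table$site[r], 1, 1)
    pos <- as.integer(substring(table$site[r], 2))
    kin_ids <- vapply(Filter(function(n) kin %in% node_gene_keys(n),
                             kin_nodes),
                      function(n) n$node_id, character(1))
    ptm_hits <- character()
    for (k in seq_len(nrow(graph$ptm_nodes))) {
      rec <- graph$dataset[graph$ptm_nodes$record[k], ]
      ids <- tolower(c(strip_isoform(rec$uniprot_accessions[[1]]),
                       rec$gene_names[[1]]))
      if (!sub_id %in% ids) next
      s <- rec$sites[[1]]
      if (nrow(s) && any(toupper(s$residue) == toupper(res) &
                         s$position == pos)) {
        ptm_hits <- c(ptm_hits, graph$ptm_nodes$ptm_node_id[k])
      }
    }
    if (length(kin_ids) == 0L || length(ptm_hits) == 0L) {
      skipped <- skipped + 1L
      next
    }
    for (kn in kin_ids) {
      for (ph in ptm_hits) {
        edges <- rbind(edges, data.frame(
          edge_id = sprintf("overlay_%d_%s_%s", r, kn, ph),
          source = kn, target = ph, kinase = table$kinase[r],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  graph$overlay_edges <- edges
  graph$overlay_skipped <- skipped
  graph
}

#' Highlight perturbed kinases on a projected graph
#'
#' Flags `gene_protein` nodes whose kinase passes the activity thresholds:
#' `|score| >= score_cut` (inclusive) and `fdr < fdr_cut` (exclusive). The
#' defaults correspond to flagging kinases at |score| >= 0.5 and FDR < 0.1.
#' Marks are colored by direction (`up` = red, `down` = blue, `unknown` =
#' purple).
#'
#' @param graph A [project_dataset()] result.
#' @param activities Data frame with columns `kinase`, `score`, `fdr`,
#'   `direction` (one of `"up"`, `"down"`, `"unknown"`).
#' @param score_cut Minimum absolute score (inclusive). Default 0.5.
#' @param fdr_cut FDR bound (exclusive). Default 0.1.
#' @return The graph with `highlights` filled in; kinases passing the cuts
#'   but absent from the skeleton are reported in `highlight_unmatched`.
#' @export
highlight_kinases <- function(graph, activities, score_cut = 0.5,
                              fdr_cut = 0.1) {
  stopifnot(inherits(graph, "projected_graph"))
  pass <- abs(activities$score) >= score_cut & activities$fdr < fdr_cut
  kin_nodes <- Filter(function(n) n$node_type == "gene_protein",
                      graph$base$nodes)
  hl <- graph$highlights
  unmatched <- character()
  for (r in which(pass)) {
    kin <- tolower(activities$kinase[r])
    hits <- Filter(function(n) kin %in% node_gene_keys(n), kin_nodes)
    if (length(hits) == 0L) {
      unmatched <- c(unmatched, activities$kinase[r])
      next
    }
    for (n in hits) {
      hl <- rbind(hl, data.frame(node_id = n$node_id,
                                 direction = activities$direction[r],
                                 stringsAsFactors = FALSE))
    }
  }
  graph$highlights <- unique(hl)
  graph$highlight_unmatched <- unmatched
  graph
}
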