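# Offline identifier mapping. Pathway files label nodes with database-specific
# identifiers (KEGG gene ids, Entrez/Ensembl xrefs, ...); these are unified to
# UniProt accessions and then to gene symbols through plain lookup tables so
# that imports are hermetic (no network access, ever). Lookups are total:
# a missing key yields an empty result, never an error.

#' Create an offline identifier-mapping table
#'
#' @param to_uniprot Data frame with columns `db`, `id`, `uniprot`: maps a
#'   (database, identifier) pair to a UniProt accession. The database name
#'   for KEGG gene identifiers is `"KEGG"`; GPML xref database names (e.g.
#'   `"Entrez Gene"`, `"Ensembl"`, `"HGNC"`, `"Uniprot-TrEMBL"`) are
#'   normalized case-insensitively.
#' @param uniprot_to_gene Data frame with columns `uniprot`, `gene`.
#' @return An object of class `id_mapping_table`.
#' @export
id_mapping_table <- function(to_uniprot = NULL, uniprot_to_gene = NULL) {
  empty1 <- data.frame(db = character(), id = character(),
                       uniprot = character(), stringsAsFactors = FALSE)
  empty2 <- data.frame(uniprot = character(), gene = character(),
                       stringsAsFactors = FALSE)
  tu <- if (is.null(to_uniprot)) empty1 else to_uniprot
  ug <- if (is.null(uniprot_to_gene)) empty2 else uniprot_to_gene
  stopifnot(all(c("db", "id", "uniprot") %in% names(tu)),
            all(c("uniprot", "gene") %in% names(ug)))
  tab <- list(
    to_uniprot = data.frame(db = normalize_db(tu$db), id = as.character(tu$id),
                            uniprot = as.character(tu$uniprot),
                            stringsAsFactors = FALSE),
    uniprot_to_gene = data.frame(uniprot = as.character(ug$uniprot),
                                 gene = as.character(ug$gene),
                                 stringsAsFactors = FALSE)
  )
  class(tab) <- "id_mapping_table"
  tab
}

normalize_db <- function(db) {
  db <- tolower(as.character(db))
  db[db %in% c("uniprot", "uniprot-trembl", "uniprot-swissprot",
               "uniprotkb")] <- "uniprot"
  db[db %in% c("entrez gene", "entrez", "ncbi gene")] <- "entrez"
  db[grepl("^ensembl", db)] <- "ensembl"
  db[db %in% c("hgnc", "hgnc accession number", "gene symbol")] <- "hgnc"
  db[db == "kegg genes"] <- "kegg"
  db
}

#' Read an identifier-mapping table from TSV files
#'
#' @param to_uniprot_tsv Path to a 3-column TSV (`db`, `id`, `uniprot`), with
#'   header.
#' @param uniprot_to_gene_tsv Path to a 2-column TSV (`uniprot`, `gene`),
#'   with header.
#' @return An [id_mapping_table()].
#' @export
read_id_mapping <- function(to_uniprot_tsv, uniprot_to_gene_tsv) {
  tu <- utils::read.delim(to_uniprot_tsv, stringsAsFactors = FALSE)
  ug <- utils::read.delim(uniprot_to_gene_tsv, stringsAsFactors = FALSE)
  id_mapping_table(tu, ug)
}

#' Map a database identifier to UniProt accessions
#'
#' @param mapping An [id_mapping_table()] (or `NULL` for the empty table).
#' @param db Database name (e.g. `"KEGG"`, `"Entrez Gene"`, `"Ensembl"`).
#' @param id Identifier string.
#' @return Character vector of accessions (possibly empty).
#' @export
map_to_uniprot <- function(mapping, db, id) {
  if (is.null(mapping)) return(character())
  hit <- mapping$to_uniprot$db == normalize_db(db) &
    mapping$to_uniprot$id == as.character(id)
  unique(mapping$to_uniprot$uniprot[hit])
}

#' Map UniProt accessions to gene symbols
#'
#' @param mapping An [id_mapping_table()] (or `NULL`).
#' @param accessions Character vector of accessions.
#' @return Character vector of gene symbols (possibly empty), in accession
#'   order, deduplicated.
#' @export
map_to_gene <- function(mapping, accessions) {
  if (is.null(mapping) || length(accessions) == 0L) return(character())
  idx <- match(strip_isoform(accessions), mapping$uniprot_to_gene$uniprot)
  unique(mapping$uniprot_to_gene$gene[idx[!is.na(idx)]])
}
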