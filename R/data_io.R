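# Readers for user-supplied PTM regulation tables (CSV) and dose-response
# outputs (CurveCurator-style curves.txt + TOML parameter file), plus the
# dose-pair deduplication rules for two-dose screens.

#' Default CSV column map
#'
#' Maps the logical fields of a PTM record onto the default header names.
#' Any entry can be overridden; only `peptide_key`, `regulation` and at least
#' one of `accessions` / `genes` are required to be resolvable.
#'
#' @return Named character vector.
#' @export
ptm_csv_columns <- function() {
  c(peptide_key = "Peptide", accessions = "Uniprot", genes = "Gene Names",
    site = "Site", regulation = "Regulation", fold_change = "Fold Change",
    p_adj = "Adjusted p-value", pec50 = "pEC50", experiment = "Experiment")
}

#' Parse a site string into residue and position
#'
#' Accepts one or more `";"`- or `"/"`-separated site tokens of the form
#' residue letter + 1-based position (e.g. `"S1134"`, `"T246;S250"`).
#'
#' @param site Site string (may be empty).
#' @return Data frame with columns `residue`, `position`; zero rows on empty
#'   input, `NULL` on a malformed token.
#' @export
parse_site <- function(site) {
  empty <- data.frame(residue = character(), position = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(site) || !nzchar(trimws(site))) return(empty)
  tokens <- trimws(strsplit(site, "[;/&]")[[1]])
  tokens <- tokens[nzchar(tokens)]
  if (!all(grepl("^[A-Za-z][0-9]+$", tokens))) return(NULL)
  data.frame(residue = toupper(substr(tokens, 1, 1)),
             position = as.integer(substring(tokens, 2)),
             stringsAsFactors = FALSE)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  counts <- c("," = lengths(regmatches(header, gregexpr(",", header, fixed = TRUE))),
              "\t" = lengths(regmatches(header, gregexpr("\t", header, fixed = TRUE))),
              ";" = lengths(regmatches(header, gregexpr(";", header, fixed = TRUE))))
  names(counts)[which.max(counts)]
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  v <- trimws(strsplit(x, "[;,]")[[1]])
  v[nzchar(v)]
}

#' Read a PTM regulation table from CSV
#'
#' The delimiter is sniffed among comma, tab and semicolon; the decimal
#' separator is `"."`. Regulation values are normalized case-insensitively
#' and must be one of up/down/not; site strings are split into residue and
#' 1-based position. Malformed rows are collected (with their line numbers)
#' into the `errors` attribute of the result rather than aborting the read;
#' a missing required column is a hard error naming the column.
#'
#' @param path Path to the CSV/TSV file.
#' @param column_map Named character vector overriding [ptm_csv_columns()].
#' @return A [ptm_dataset()] with attribute `errors` (data frame with
#'   columns `line`, `message`).
#' @export
read_ptm_csv <- function(path, column_map = ptm_csv_columns()) {
  cmap <- ptm_csv_columns()
  cmap[names(column_map)] <- column_map
  delim <- sniff_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "", dec = ".")
  need <- c("peptide_key", "regulation")
  for (f in need) {
    if (!cmap[[f]] %in% names(raw)) {
      stop(sprintf("required column '%s' (field %s) not found", cmap[[f]], f))
    }
  }
  if (!cmap[["accessions"]] %in% names(raw) &&
      !cmap[["genes"]] %in% names(raw)) {
    stop(sprintf("need at least one identifier column: '%s' or '%s'",
                 cmap[["accessions"]], cmap[["genes"]]))
  }
  col <- function(f, default = NA) {
    nm <- cmap[[f]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  errors <- data.frame(line = integer(), message = character(),
                       stringsAsFactors = FALSE)
  keep <- logical(nrow(raw))
  regulation <- tolower(trimws(as.character(col("regulation"))))
  sites <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    line <- i + 1L  # header is line 1
    if (!regulation[i] %in% REGULATION_LEVELS) {
      errors <- rbind(errors, data.frame(
        line = line,
        message = sprintf("invalid regulation '%s'", regulation[i]),
        stringsAsFactors = FALSE))
      next
    }
    s <- parse_site(as.character(col("site"))[i])
    if (is.null(s)) {
      errors <- rbind(errors, data.frame(
        line = line,
        message = sprintf("malformed site '%s'", as.character(col("site"))[i]),
        stringsAsFactors = FALSE))
      next
    }
    sites[[i]] <- s
    keep[i] <- TRUE
  }
  idx <- which(keep)
  ds <- ptm_dataset(
    experiment = as.character(col("experiment", "default"))[idx],
    peptide_key = as.character(col("peptide_key"))[idx],
    uniprot_accessions = lapply(as.character(col("accessions", ""))[idx],
                                split_multi),
    gene_names = lapply(as.character(col("genes", ""))[idx], split_multi),
    sites = sites[idx],
    regulation = regulation[idx],
    fold_change = suppressWarnings(as.numeric(col("fold_change"))[idx]),
    p_adj = suppressWarnings(as.numeric(col("p_adj"))[idx]),
    pec50 = suppressWarnings(as.numeric(col("pec50"))[idx])
  )
  attr(ds, "errors") <- errors
  ds
}

#' Write a PTM dataset to CSV
#'
#' Inverse of [read_ptm_csv()] for the documented columns (multi-valued
#' fields are `";"`-joined), so `read(write(x))` is lossless.
#'
#' @param dataset A [ptm_dataset()].
#' @param path Destination path.
#' @param column_map Named character vector overriding [ptm_csv_columns()].
#' @return `path`, invisibly.
#' @export
write_ptm_csv <- function(dataset, path, column_map = ptm_csv_columns()) {
  cmap <- ptm_csv_columns()
  cmap[names(column_map)] <- column_map
  df <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
    a = dataset$peptide_key,
    b = vapply(dataset$uniprot_accessions, paste, "", collapse = ";"),
    c = vapply(dataset$gene_names, paste, "", collapse = ";"),
    d = vapply(dataset$sites, function(s) {
      paste(paste0(s$residue, s$position), collapse = ";")
    }, ""),
    e = dataset$regulation,
    f = dataset$fold_change,
    g = dataset$p_adj,
    h = dataset$pec50,
    i = dataset$experiment
  )
  names(df) <- unname(cmap[c("peptide_key", "accessions", "genes", "site",
                             "regulation", "fold_change", "p_adj", "pec50",
                             "experiment")])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# --- TOML ---------------------------------------------------------------------

toml_scalar <- function(tok) {
  tok <- trimws(tok)
  if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
  if (grepl("^'.*'$", tok)) return(gsub("^'|'$", "", tok))
  if (tok %in% c("true", "false")) return(tok == "true")
  num <- suppressWarnings(as.numeric(tok))
  if (!is.na(num)) return(num)
  tok
}

#' Read a TOML parameter file (subset)
#'
#' Minimal reader covering the flat structure of dose-response experiment
#' parameter files: `[section]` headers, `key = value` pairs with string,
#' number, boolean or one-level array values, `#` comments. Nested tables,
#' multi-line strings and datetimes are not supported.
#'
#' @param path Path to the TOML file.
#' @return Nested named list (top level keys, plus one list per section).
#' @export
read_toml <- function(path) {
  lines <- readLines(path)
  out <- list()
  section <- NULL
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      out[[section]] <- out[[section]] %||% list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed TOML line: %s", raw))
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substring(line, eq + 1))
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      inner <- gsub("^\\[|\\]$", "", val)
      items <- trimws(strsplit(inner, ",")[[1]])
      items <- items[nzchar(items)]
      vals <- lapply(items, toml_scalar)
      if (all(vapply(vals, is.numeric, logical(1)))) {
        unlist(vals)
      } else {
        unlist(lapply(vals, as.character))
      }
    } else {
      toml_scalar(val)
    }
    if (is.null(section)) out[[key]] <- parsed
    else out[[section]][[key]] <- parsed
  }
  out
}

#' Default curves-file column map
#' @return Named character vector.
#' @export
curves_columns <- function() {
  c(peptide_key = "Name", genes = "Genes", proteins = "Proteins",
    regulation = "Curve Regulation", pec50 = "pEC50",
    fold_change = "Curve Fold Change", site = "Site")
}

#' Read dose-response curve output with its parameter file
#'
#' Reads a curves table (TSV; one fitted dose-response curve per modified
#' peptide) together with the TOML file holding the experimental parameters
#' (drug name and dose series). Curves classified as regulated become
#' up/down records carrying potency (pEC50) and curve fold change;
#' unclassified curves become `not` records without potency. pEC50 values
#' outside the window implied by the dose range are flagged in the record
#' details (`out_of_range`). A drug-name mismatch between a drug column in
#' the curves file and the TOML is a hard error.
#'
#' @param curves_path Path to the curves TSV.
#' @param toml_path Path to the TOML parameter file. Recognized keys (top
#'   level or in any section): `drug` (string) and `doses` (numeric vector,
#'   nM).
#' @param column_map Named character vector overriding [curves_columns()].
#' @return A [ptm_dataset()]; the pEC50 window is stored in attribute
#'   `pec50_window` as c(high, low) potency bounds.
#' @export
read_curvecurator <- function(curves_path, toml_path,
                              column_map = curves_columns()) {
  cmap <- curves_columns()
  cmap[names(column_map)] <- column_map
  params <- read_toml(toml_path)
  find_param <- function(key) {
    if (!is.null(params[[key]])) return(params[[key]])
    for (s in params) {
      if (is.list(s) && !is.null(s[[key]])) return(s[[key]])
    }
    NULL
  }
  drug <- find_param("drug")
  doses <- find_param("doses")
  window <- if (!is.null(doses)) {
    # doses in nM; pEC50 = -log10(molar)
    rev(range(-log10(doses * 1e-9)))  # c(high potency, low potency)
  } else {
    c(NA_real_, NA_real_)
  }

  raw <- utils::read.delim(curves_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (f in c("peptide_key", "regulation")) {
    if (!cmap[[f]] %in% names(raw)) {
      stop(sprintf("required curves column '%s' not found", cmap[[f]]))
    }
  }
  if ("Drug" %in% names(raw) && !is.null(drug)) {
    mism <- unique(raw$Drug[!is.na(raw$Drug) & raw$Drug != drug])
    if (length(mism)) {
      stop(sprintf("drug name mismatch: curves say %s, parameters say %s",
                   paste(mism, collapse = ","), drug))
    }
  }
  col <- function(f, default = NA) {
    nm <- cmap[[f]]
    if (nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  reg_raw <- tolower(trimws(as.character(col("regulation"))))
  regulation <- ifelse(reg_raw %in% c("up", "down"), reg_raw, "not")
  pec50 <- suppressWarnings(as.numeric(col("pec50")))
  pec50[regulation == "not"] <- NA_real_
  fold_change <- suppressWarnings(as.numeric(col("fold_change")))
  fold_change[regulation == "not"] <- NA_real_
  sites <- lapply(as.character(col("site", "")), function(s) {
    parsed <- parse_site(s)
    if (is.null(parsed)) parse_site("") else parsed
  })
  details <- lapply(seq_len(nrow(raw)), function(i) {
    d <- list(drug = drug %||% "")
    if (is.finite(pec50[i]) && all(is.finite(window))) {
      d$out_of_range <- pec50[i] > window[1] || pec50[i] < window[2]
    }
    d
  })
  ds <- ptm_dataset(
    experiment = rep(drug %||% "curves", nrow(raw)),
    peptide_key = as.character(col("peptide_key")),
    uniprot_accessions = lapply(as.character(col("proteins", "")),
                                split_multi),
    gene_names = lapply(as.character(col("genes", "")), split_multi),
    sites = sites,
    regulation = regulation,
    fold_change = fold_change,
    pec50 = pec50,
    details = details
  )
  attr(ds, "pec50_window") <- window
  ds
}

# --- dose-pair deduplication --------------------------------------------------

#' Deduplicate two-dose screening records
#'
#' Reduces per-compound records measured at a low and a high dose to exactly
#' one entry per peptide. First, within-experiment duplicates (multiply
#' phosphorylated peptides) are resolved by keeping the most significant
#' entry, i.e. the lowest adjusted p-value (rule I). Then, per peptide:
#' \itemize{
#'   \item rule III: if the high-dose entry is significant, keep it;
#'   \item rule IV: if only the low-dose entry is significant, keep it;
#'   \item rule II: if neither is significant, keep the high-dose entry.
#' }
#' Rules II-IV are mutually exclusive and exhaustive over the four
#' significance patterns. A peptide observed at a single dose keeps that
#' entry (`rule = "single"`).
#'
#' @param records Data frame with columns `peptide_key`, `dose` (`"low"` or
#'   `"high"`), `significant` (logical), `p_adj`, and any payload columns.
#' @return One row per peptide, with an added `rule` column recording which
#'   rule fired.
#' @export
dedup_dose_pairs <- function(records) {
  stopifnot(all(c("peptide_key", "dose", "significant", "p_adj") %in%
                  names(records)),
            all(records$dose %in% c("low", "high")))
  # rule I: within (peptide, dose) keep lowest adjusted p
  key <- paste(records$peptide_key, records$dose, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    idx[which.min(records$p_adj[idx])]
  }), use.names = FALSE)
  records <- records[sort(keep), , drop = FALSE]

  out <- lapply(split(records, records$peptide_key), function(d) {
    low <- d[d$dose == "low", , drop = FALSE]
    high <- d[d$dose == "high", , drop = FALSE]
    if (nrow(high) == 0L || nrow(low) == 0L) {
      row <- d[1, , drop = FALSE]
      row$rule <- "single"
      return(row)
    }
    if (high$significant) {
      high$rule <- "III"
      high
    } else if (low$significant) {
      low$rule <- "IV"
      low
    } else {
      high$rule <- "II"
      high
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
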