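# Enrichment battery: single-sample set enrichment with an ECDF-difference
# statistic (gene-centric and gene-centric-redundant flavors, and PTM-site
# signatures with signed membership), permutation p-values, kinase-substrate
# enrichment analysis (KSEA, mean-fold-change z statistic), and PSSM-based
# kinase motif enrichment with Fisher tests. All p-value families are
# corrected with Benjamini-Hochberg.

#' Build a ranked profile
#'
#' A profile is an ordered list of (key, value) pairs for one experiment,
#' sorted by value in descending order with ties broken by input order
#' (stable). Two duplicate policies are supported: `collapse_max_abs` keeps,
#' for each key, the single entry with the maximum absolute value (the
#' site-level and gene-centric convention), while `keep_all` retains every
#' entry so a gene contributes once per regulated peptide (the gene-centric
#' redundant convention).
#'
#' @param keys Character vector of profile keys (gene symbols or site keys).
#' @param values Numeric values (e.g. log2 fold changes).
#' @param duplicate_policy `"collapse_max_abs"` or `"keep_all"`.
#' @return Data frame of class `ranked_profile` with columns `key`, `value`,
#'   sorted descending.
#' @export
ranked_profile <- function(keys, values,
                           duplicate_policy = c("collapse_max_abs",
                                                "keep_all")) {
  duplicate_policy <- match.arg(duplicate_policy)
  stopifnot(length(keys) == length(values))
  df <- data.frame(key = as.character(keys), value = as.numeric(values),
                   stringsAsFactors = FALSE)
  if (duplicate_policy == "collapse_max_abs") {
    keep <- logical(nrow(df))
    for (k in unique(df$key)) {
      idx <- which(df$key == k)
      keep[idx[which.max(abs(df$value[idx]))]] <- TRUE
    }
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(-df$value), , drop = FALSE]  # stable radix/merge order
  rownames(df) <- NULL
  attr(df, "duplicate_policy") <- duplicate_policy
  class(df) <- c("ranked_profile", class(df))
  df
}

#' Define a signature
#'
#' A named set of member keys: gene symbols for gene-centric signatures or
#' site keys for PTM signatures. PTM signatures may carry a direction sign
#' per member (+1 / -1); a -1-signed member contributes with its profile
#' value negated before ranking.
#'
#' @param signature_id Signature name.
#' @param members Character vector of member keys (non-empty).
#' @param signs Optional numeric vector of +1/-1, same length as `members`.
#' @return List of class `signature_set`.
#' @export
signature_set <- function(signature_id, members, signs = NULL) {
  members <- as.character(members)
  if (length(members) == 0L) stop("signature must have at least one member")
  if (!is.null(signs)) {
    stopifnot(length(signs) == length(members), all(signs %in% c(-1, 1)))
  }
  sig <- list(signature_id = signature_id, members = members, signs = signs)
  class(sig) <- "signature_set"
  sig
}

#' Read signatures from a GMT-like file
#'
#' One signature per line: id, description, then tab-separated member keys.
#' A member may carry a direction suffix `";+1"` or `";-1"` (PTM-signature
#' convention); unsuffixed members default to +1 when any member is signed.
#'
#' @param path Path to the GMT file.
#' @return List of [signature_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop(sprintf("malformed GMT line (needs id, description, members): %s",
                   substr(ln, 1, 40)))
    }
    raw <- parts[-(1:2)]
    has_sign <- grepl(";[+-]1$", raw)
    members <- sub(";[+-]1$", "", raw)
    signs <- if (any(has_sign)) {
      ifelse(grepl(";-1$", raw), -1, 1)
    } else NULL
    signature_set(parts[1], members, signs)
  })
}

#' ECDF-difference enrichment score
#'
#' The test statistic is the normalized integrated difference between the
#' empirical cumulative distribution function of the signature members'
#' positions in the ranked profile and the ECDF of the remaining entries'
#' positions:
#' \deqn{score = \frac{1}{N} \sum_{i=1}^{N} \left[ F_{sig}(i) - F_{rest}(i) \right]}
#' A positive score means the members concentrate at high ranks (top of the
#' profile), a negative score at low ranks. For signed signatures, the
#' profile values of -1-signed members are negated before re-ranking. With
#' `statistic = "ks"` the maximum absolute deviation between the two ECDFs
#' (signed at its argmax) is returned instead of the integrated form.
#'
#' Under the `keep_all` duplicate policy every profile row matching a member
#' key contributes individually, so a gene is counted once per regulated
#' peptide (redundant counting).
#'
#' @param profile A [ranked_profile()].
#' @param signature A [signature_set()].
#' @param statistic `"area"` (integrated difference, default) or `"ks"`.
#' @return List with `score` (NA with a `diagnostic` attribute when the
#'   overlap is zero or the signature covers the whole profile) and `overlap`
#'   (number of distinct member keys present in the profile).
#' @export
enrichment_score <- function(profile, signature,
                             statistic = c("area", "ks")) {
  statistic <- match.arg(statistic)
  keys <- profile$key
  values <- profile$value
  if (!is.null(signature$signs)) {
    neg <- signature$members[signature$signs == -1]
    flip <- keys %in% neg
    values[flip] <- -values[flip]
    ord <- order(-values)   # stable
    keys <- keys[ord]
    values <- values[ord]
  }
  member <- keys %in% signature$members
  overlap <- length(intersect(signature$members, keys))
  n_sig <- sum(member)
  n <- length(keys)
  if (n_sig == 0L) {
    score <- NA_real_
    attr(score, "diagnostic") <- "zero overlap"
    return(list(score = score, overlap = 0L))
  }
  if (n_sig == n) {
    score <- NA_real_
    attr(score, "diagnostic") <- "signature covers the entire profile"
    return(list(score = score, overlap = overlap))
  }
  f_sig <- cumsum(member) / n_sig
  f_rest <- cumsum(!member) / (n - n_sig)
  diff <- f_sig - f_rest
  score <- if (statistic == "area") {
    sum(diff) / n
  } else {
    diff[which.max(abs(diff))]
  }
  list(score = score, overlap = overlap)
}

#' Permutation p-values for set enrichment
#'
#' For each signature the observed score is compared against the scores of
#' size-matched random member sets drawn (without replacement) from the
#' profile rows: `p = (1 + #{|score_perm| >= |score_obs|}) / (1 + n_perm)`.
#' p-values are Benjamini-Hochberg adjusted across the signatures of the
#' profile (one experiment = one family); NA-scored signatures are excluded
#' from the BH family. Deterministic under a fixed seed.
#'
#' @param profile A [ranked_profile()].
#' @param signatures List of [signature_set()] objects.
#' @param n_perm Number of permutations (>= 100). Default 1000.
#' @param seed Integer seed.
#' @param statistic Passed to [enrichment_score()].
#' @return Data frame with columns `signature_id`, `overlap`, `score`, `p`,
#'   `p_adj`.
#' @export
permutation_pvalues <- function(profile, signatures, n_perm = 1000,
                                seed = 1L, statistic = "area") {
  stopifnot(n_perm >= 100)
  n <- nrow(profile)
  res <- data.frame(
    signature_id = vapply(signatures, function(s) s$signature_id,
                          character(1)),
    overlap = 0L, score = NA_real_, p = NA_real_, p_adj = NA_real_,
    stringsAsFactors = FALSE
  )
  with_seed(seed, {
    for (i in seq_along(signatures)) {
      obs <- enrichment_score(profile, signatures[[i]],
                              statistic = statistic)
      res$overlap[i] <- obs$overlap
      res$score[i] <- obs$score
      if (is.na(obs$score)) next
      n_sig <- sum(profile$key %in% signatures[[i]]$members)
      null_scores <- vapply(seq_len(n_perm), function(p) {
        member <- logical(n)
        member[sample.int(n, n_sig)] <- TRUE
        f_sig <- cumsum(member) / n_sig
        f_rest <- cumsum(!member) / (n - n_sig)
        d <- f_sig - f_rest
        if (statistic == "area") sum(d) / n else d[which.max(abs(d))]
      }, numeric(1))
      res$p[i] <- (1 + sum(abs(null_scores) >= abs(obs$score))) / (1 + n_perm)
    }
  })
  ok <- !is.na(res$p)
  res$p_adj[ok] <- bh_adjust(res$p[ok])
  res
}

#' Kinase-substrate enrichment analysis (KSEA)
#'
#' Mean-fold-change statistic: for a kinase with `m` annotated substrates
#' present in the (deduplicated) site profile,
#' \deqn{z = (\bar{x}_{substrates} - \bar{x}_{all}) \cdot \sqrt{m} / s_{all}}
#' where the mean and standard deviation of all sites define the expected
#' value and spread under the null. Two-sided p-values come from the standard
#' normal; BH adjustment is applied across kinases. Kinases with fewer than
#' `min_substrates` matched substrates are omitted.
#'
#' @param fold_changes Data frame with columns `id` (substrate accession or
#'   gene symbol), `site` (e.g. `"S1134"`), `value` (log2 fold change).
#'   Duplicate (id, site) entries are collapsed to the maximum absolute
#'   value.
#' @param table A [kinase_substrate_table()].
#' @param min_substrates Minimum substrate count (default 3).
#' @return Data frame with columns `kinase`, `z_score`, `p`, `p_adj`,
#'   `n_substrates`, sorted by p ascending (stable).
#' @export
ksea <- function(fold_changes, table, min_substrates = 3L) {
  stopifnot(all(c("id", "site", "value") %in% names(fold_changes)))
  key <- paste(tolower(fold_changes$id), toupper(fold_changes$site))
  prof <- ranked_profile(key, fold_changes$value,
                         duplicate_policy = "collapse_max_abs")
  mean_all <- mean(prof$value)
  sd_all <- stats::sd(prof$value)
  if (!is.finite(sd_all) || sd_all == 0) {
    stop("KSEA undefined: zero variance across all site fold changes")
  }
  kinases <- unique(table$kinase)
  rows <- lapply(kinases, function(k) {
    sub <- table[table$kinase == k, , drop = FALSE]
    sub_key <- paste(tolower(sub$substrate), toupper(sub$site))
    vals <- prof$value[prof$key %in% sub_key]
    m <- length(vals)
    if (m < min_substrates) return(NULL)
    z <- (mean(vals) - mean_all) * sqrt(m) / sd_all
    data.frame(kinase = k, z_score = z,
               p = 2 * stats::pnorm(-abs(z)),
               n_substrates = m, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(kinase = character(), z_score = numeric(),
                      p = numeric(), p_adj = numeric(),
                      n_substrates = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("kinase", "z_score", "p", "p_adj", "n_substrates")]
}

# --- motif enrichment ---------------------------------------------------------

#' Create a kinase position-specific scoring matrix
#'
#' @param kinase Kinase name.
#' @param matrix Numeric matrix of positive preference weights, rows =
#'   positions (default -5..+4 around the phospho-acceptor), columns = amino
#'   acids (one-letter codes).
#' @param positions Integer vector of positions (must be contiguous and
#'   match `nrow(matrix)`).
#' @return List of class `pssm`.
#' @export
pssm <- function(kinase, matrix, positions = -5:4) {
  stopifnot(nrow(matrix) == length(positions),
            all(diff(positions) == 1L),
            all(matrix > 0))
  if (is.null(colnames(matrix))) stop("PSSM needs amino-acid column names")
  m <- list(kinase = kinase, matrix = matrix, positions = positions)
  class(m) <- "pssm"
  m
}

#' Read PSSMs from a TSV file
#'
#' Long format with columns `kinase`, `position`, then one column per amino
#' acid.
#' @param path Path to the TSV.
#' @return List of [pssm()] objects.
#' @export
read_pssms <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lapply(split(df, df$kinase), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    m <- as.matrix(d[, setdiff(names(d), c("kinase", "position")),
                     drop = FALSE])
    pssm(d$kinase[1], m, d$position)
  })
}

#' Score flanking sequences against a PSSM
#'
#' The score of a peptide is the sum over positions of the log2 preference
#' weight of the residue observed at that position. Sequences must be
#' centered on the phospho-acceptor with width equal to the PSSM window;
#' padding characters (`_` or residues absent from the matrix) are skipped.
#'
#' @param sequences Character vector of flanking sequences.
#' @param mat A [pssm()].
#' @return Numeric vector of scores.
#' @export
score_flanks <- function(sequences, mat) {
  width <- length(mat$positions)
  widths <- nchar(sequences)
  if (any(widths != width)) {
    stop(sprintf("flanking sequence of wrong width at index %d (expected %d)",
                 which(widths != width)[1], width))
  }
  lw <- log2(mat$matrix)
  vapply(sequences, function(s) {
    aa <- strsplit(s, "")[[1]]
    sc <- 0
    for (i in seq_len(width)) {
      j <- match(aa[i], colnames(lw))
      if (!is.na(j)) sc <- sc + lw[i, j]
    }
    sc
  }, numeric(1), USE.NAMES = FALSE)
}

# Two-sided Fisher exact p for a 2x2 table (a,b / c,d).
fisher_exact_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), nrow = 2))$p.value
}

#' Kinase motif enrichment
#'
#' Every peptide is scored against every kinase PSSM; scores are converted to
#' percentiles of the kinase's background score distribution (fraction of
#' background scores <= score). For each site the `top_k` kinases by
#' percentile are kept (default 15, stable tie-break by kinase order). Each
#' kinase appearing in any top-k list is then tested per regulation direction
#' for overrepresentation with a two-sided Fisher exact test on the 2x2 table
#' (regulated in that direction vs not) x (kinase in the site's top-k vs
#' not), with BH adjustment across kinases within the direction.
#'
#' @param peptides Data frame with columns `sequence` (flanking sequence
#'   centered on the phospho-residue) and `regulation` (`up`/`down`/`not`).
#' @param pssms List of [pssm()] objects.
#' @param background Named list (by kinase) of numeric background score
#'   distributions (non-empty each).
#' @param top_k Number of top kinases kept per site. Default 15.
#' @return Data frame with columns `kinase`, `direction`, `n_top_regulated`,
#'   `n_top_other`, `n_rest_regulated`, `n_rest_other`, `p`, `p_adj`.
#' @export
motif_enrichment <- function(peptides, pssms, background, top_k = 15L) {
  kin_names <- vapply(pssms, function(m) m$kinase, character(1))
  for (k in kin_names) {
    if (is.null(background[[k]]) || length(background[[k]]) == 0L) {
      stop(sprintf("empty background score distribution for kinase %s", k))
    }
  }
  n_pep <- nrow(peptides)
  pct <- matrix(0, n_pep, length(pssms),
                dimnames = list(NULL, kin_names))
  for (j in seq_along(pssms)) {
    sc <- score_flanks(peptides$sequence, pssms[[j]])
    bg <- background[[kin_names[j]]]
    pct[, j] <- vapply(sc, function(x) mean(bg <= x), numeric(1))
  }
  top_k <- min(top_k, length(pssms))
  in_top <- matrix(FALSE, n_pep, length(pssms),
                   dimnames = list(NULL, kin_names))
  for (i in seq_len(n_pep)) {
    ord <- order(-pct[i, ])  # stable: ties keep kinase order
    in_top[i, ord[seq_len(top_k)]] <- TRUE
  }
  out <- list()
  for (direction in c("up", "down")) {
    reg <- peptides$regulation == direction
    if (!any(reg)) next
    rows <- lapply(kin_names, function(k) {
      top <- in_top[, k]
      a <- sum(reg & top); b <- sum(!reg & top)
      c_ <- sum(reg & !top); d <- sum(!reg & !top)
      data.frame(kinase = k, direction = direction,
                 n_top_regulated = a, n_top_other = b,
                 n_rest_regulated = c_, n_rest_other = d,
                 p = fisher_exact_p(a, b, c_, d),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    res$p_adj <- bh_adjust(res$p)
    out[[direction]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control with monotonicity
#' enforcement; adjusted values never fall below the raw p-values and the
#' procedure is idempotent on already-adjusted monotone inputs.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Rank pathways by enrichment score
#'
#' Pathway signatures are ordered by decreasing absolute enrichment score
#' (the gene-centric-redundant score is the conventional sort key for
#' presenting candidate pathways); NA-scored pathways sort last; ties keep
#' input order (stable).
#'
#' @param results Data frame with columns `signature_id` and `score` (one row
#'   per pathway signature).
#' @return The input rows, reordered.
#' @export
rank_pathways <- function(results) {
  key <- abs(results$score)
  ord <- order(is.na(key), -ifelse(is.na(key), -Inf, key))
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
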