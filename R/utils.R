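# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so callers are unaffected.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic pseudo-uniform in [0, 1) from integer inputs; used where
# bit-identical output across runs is part of the contract (layout) and the
# global RNG must not be touched.
hash_unit <- function(seed, i) {
  x <- (as.numeric(seed) * 9301 + as.numeric(i) * 49297) %% 233280
  x / 233280
}

# Strip UniProt isoform suffixes ("P42345-2" -> "P42345").
strip_isoform <- function(acc) sub("-[0-9]+$", "", acc)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# xml_attr() returns NA for a missing attribute; fall back to a default.
attr_or <- function(node, attr, default = "") {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
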