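# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (explicit loops, closed forms, exhaustive enumeration)
# and share no code with the package implementation.

# Brute-force two-ECDF enrichment score: sort the profile by value
# (descending, stable), then accumulate the ECDF difference position by
# position with explicit counting loops.
oracle_ecdf_score <- function(keys, values, members) {
  ord <- order(-values)
  keys <- keys[ord]
  n <- length(keys)
  in_sig <- keys %in% members
  n_sig <- sum(in_sig)
  n_rest <- n - n_sig
  if (n_sig == 0L || n_rest == 0L) return(NA_real_)
  total <- 0
  for (i in seq_len(n)) {
    c_sig <- 0
    c_rest <- 0
    for (j in seq_len(i)) {
      if (in_sig[j]) c_sig <- c_sig + 1 else c_rest <- c_rest + 1
    }
    total <- total + (c_sig / n_sig - c_rest / n_rest)
  }
  total / n
}

# Exact two-sided Fisher p for a 2x2 table via hypergeometric enumeration:
# sum the probabilities of all tables with the same margins whose probability
# does not exceed the observed one (within a relative tolerance, matching the
# conventional definition).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Convex hull vertex set by exhaustive triangle containment: a point is a
# hull vertex iff it lies strictly inside no triangle formed by three other
# points and on no segment between two other points.
oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  if (n <= 3L) return(pts)  # generic-position points: all are vertices
  cross2 <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  inside <- logical(n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    p <- pts[i, ]
    for (tri in utils::combn(others, 3, simplify = FALSE)) {
      a <- pts[tri[1], ]; b <- pts[tri[2], ]; c <- pts[tri[3], ]
      s1 <- cross2(a, b, p); s2 <- cross2(b, c, p); s3 <- cross2(c, a, p)
      if ((s1 >= 0 && s2 >= 0 && s3 >= 0) ||
          (s1 <= 0 && s2 <= 0 && s3 <= 0)) {
        inside[i] <- TRUE
        break
      }
    }
  }
  pts[!inside, , drop = FALSE]
}

sort_points <- function(pts) {
  pts <- round(pts, 9)
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

# Truth table for the dose-pair rules (given rule-I-resolved input).
oracle_dedup_rule <- function(low_sig, high_sig) {
  if (high_sig) "III" else if (low_sig) "IV" else "II"
}
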