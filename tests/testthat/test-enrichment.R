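test_that("top/bottom signatures give symmetric scores of opposite sign", {
  prof <- ranked_profile(c("A", "B", "C", "D"), c(4, 3, 2, 1))
  top <- enrichment_score(prof, signature_set("top", c("A", "B")))
  bottom <- enrichment_score(prof, signature_set("bottom", c("C", "D")))
  expect_gt(top$score, 0)
  expect_lt(bottom$score, 0)
  expect_equal(abs(top$score), abs(bottom$score))
})

test_that("enrichment score equals the brute-force two-ECDF oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    keys <- sprintf("G%d", seq_len(n))
    values <- stats::rnorm(n)
    prof <- ranked_profile(keys, values)
    members <- sample(keys, sample(1:(n - 1), 1))
    got <- enrichment_score(prof, signature_set("s", members))
    expect_equal(got$score, oracle_ecdf_score(keys, values, members),
                 tolerance = 1e-12)
  }
})

test_that("keep_all profiles count duplicate keys once per occurrence", {
  keys <- c("A", "B", "A", "C", "A", "D")
  values <- c(6, 5, 4, 3, 2, 1)
  prof <- ranked_profile(keys, values, duplicate_policy = "keep_all")
  expect_identical(nrow(prof), 6L)
  got <- enrichment_score(prof, signature_set("s", "A"))
  expect_equal(got$score, oracle_ecdf_score(keys, values, "A"),
               tolerance = 1e-12)
  # hand value: member positions 1, 3, 5 of 6 -> mean ECDF difference 1/6
  expect_equal(got$score, 1 / 6, tolerance = 1e-12)
  # the collapsed profile keeps only A's strongest entry and scores
  # differently (0.5): redundant occurrences really do contribute
  collapsed <- ranked_profile(keys, values,
                              duplicate_policy = "collapse_max_abs")
  expect_identical(nrow(collapsed), 4L)
  got_gc <- enrichment_score(collapsed, signature_set("s", "A"))
  expect_equal(got_gc$score, 0.5, tolerance = 1e-12)
})

test_that("gene-centric and redundant scoring coincide without duplicate keys", {
  set.seed(7)
  keys <- sprintf("G%d", 1:12)
  values <- stats::rnorm(12)
  sig <- signature_set("s", sample(keys, 4))
  a <- enrichment_score(ranked_profile(keys, values, "collapse_max_abs"), sig)
  b <- enrichment_score(ranked_profile(keys, values, "keep_all"), sig)
  expect_identical(a, b)
})

test_that("degenerate overlaps yield NA scores with diagnostics, not errors", {
  prof <- ranked_profile(c("A", "B"), c(2, 1))
  none <- enrichment_score(prof, signature_set("s", "Z"))
  expect_identical(none$overlap, 0L)
  expect_true(is.na(none$score))
  all_of_it <- enrichment_score(prof, signature_set("s", c("A", "B")))
  expect_true(is.na(all_of_it$score))
  expect_match(attr(all_of_it$score, "diagnostic"), "entire profile")
})

test_that("signed members contribute with negated values", {
  prof <- ranked_profile(c("A", "B", "C", "D"), c(4, 3, 2, 1))
  unsigned <- enrichment_score(prof, signature_set("s", c("A", "B")))
  # sign -1 on B: its value flips from 3 to -3, moving it to the bottom
  signed <- enrichment_score(prof, signature_set("s", c("A", "B"),
                                                 signs = c(1, -1)))
  expect_false(isTRUE(all.equal(signed$score, unsigned$score)))
  expect_equal(signed$score,
               oracle_ecdf_score(c("A", "B", "C", "D"), c(4, -3, 2, 1),
                                 c("A", "B")),
               tolerance = 1e-12)
  expect_identical(signed$overlap, 2L)
})

test_that("permutation p-values are calibrated at the extremes and reproducible", {
  # maximal achievable |score| for its size: on a 200-item profile no random
  # 2-subset reaches it, so p attains its lower bound 1/(1+n_perm)
  prof <- ranked_profile(sprintf("G%d", 1:200), 200:1)
  top_sig <- signature_set("top", c("G1", "G2"))
  res <- permutation_pvalues(prof, list(top_sig), n_perm = 500, seed = 3)
  expect_equal(res$p, 1 / 501, tolerance = 1e-12)

  prof <- ranked_profile(sprintf("G%d", 1:12), 12:1)
  sigs <- list(signature_set("a", c("G2", "G9")),
               signature_set("b", c("G4", "G5", "G11")))
  r1 <- permutation_pvalues(prof, sigs, n_perm = 300, seed = 11)
  r2 <- permutation_pvalues(prof, sigs, n_perm = 300, seed = 11)
  expect_identical(r1, r2)
  expect_true(all(r1$p_adj >= r1$p))
})

test_that("KSEA matches its closed form on a hand-computed example", {
  # background: mean 0, sd 1 over sites s1..s8; substrates of K: -2, -1, -3
  fc <- data.frame(
    id = sprintf("g%d", 1:8),
    site = rep("S1", 8),
    value = c(-2, -1, -3, 2, 1, 3, 0.5, -0.5)
  )
  # choose the background so mean 0 and sd exactly 1 is not required; compute
  # the expected z from the same closed form with base R
  tab <- kinase_substrate_table(rep("K", 3), sprintf("g%d", 1:3),
                                rep("S1", 3))
  res <- ksea(fc, tab, min_substrates = 3)
  m_all <- mean(fc$value); s_all <- stats::sd(fc$value)
  z_expected <- (mean(c(-2, -1, -3)) - m_all) * sqrt(3) / s_all
  expect_equal(res$z_score, z_expected, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pnorm(-abs(z_expected)), tolerance = 1e-12)
})

test_that("KSEA of the full background against itself is zero", {
  set.seed(5)
  fc <- data.frame(id = sprintf("g%d", 1:50), site = "S1",
                   value = stats::rnorm(50))
  tab <- kinase_substrate_table(rep("ALL", 50), fc$id, fc$site)
  res <- ksea(fc, tab)
  expect_equal(res$z_score, 0, tolerance = 1e-12)
})

test_that("KSEA honors the minimum substrate count and zero-variance guard", {
  fc <- data.frame(id = c("a", "b", "c"), site = "S1", value = c(1, 2, 3))
  tab <- kinase_substrate_table(c("K1", "K1", "K2"), c("a", "b", "c"),
                                rep("S1", 3))
  res <- ksea(fc, tab, min_substrates = 2)
  expect_identical(res$kinase, "K1")  # K2 has one substrate -> omitted
  flat <- data.frame(id = c("a", "b", "c"), site = "S1", value = c(1, 1, 1))
  expect_error(ksea(flat, tab, min_substrates = 2), "zero variance")
})

test_that("planted kinase inhibition is recovered at rank one", {
  spec <- synthetic_spec(seed = 33)
  ks <- make_fixture_ks_table(spec)
  ds <- make_synthetic_dataset(spec, ks_table = ks)
  fc <- data.frame(
    id = vapply(ds$gene_names, `[`, "", 1),
    site = vapply(ds$sites, function(s) paste0(s$residue[1], s$position[1]),
                  ""),
    value = ds$fold_change
  )
  res <- ksea(fc, ks)
  expect_identical(res$kinase[1], spec$planted_kinase)
  expect_lt(res$p_adj[1], 0.1)
})

test_that("peptides matching a PSSM argmax score maximally (percentile 1)", {
  spec <- synthetic_spec(seed = 4)
  pssms <- make_fixture_pssms(spec, n_kinases = 3)
  m <- pssms[[1]]
  best <- paste(colnames(m$matrix)[apply(m$matrix, 1, which.max)],
                collapse = "")
  sc <- score_flanks(best, m)
  expect_equal(sc, sum(log2(apply(m$matrix, 1, max))), tolerance = 1e-12)
  bg <- score_flanks(random_flanks(100), m)
  expect_equal(mean(bg <= sc), 1)
})

test_that("sequences of the wrong width are rejected with their index", {
  spec <- synthetic_spec(seed = 4)
  m <- make_fixture_pssms(spec, n_kinases = 1)[[1]]
  expect_error(score_flanks(c("SSSSSSSSSS", "SHORT"), m), "index 2")
})

test_that("padding characters are skipped in motif scoring", {
  spec <- synthetic_spec(seed = 4)
  m <- make_fixture_pssms(spec, n_kinases = 1)[[1]]
  padded <- paste0("__", substr(random_flanks(1), 3, 10))
  expect_true(is.finite(score_flanks(padded, m)))
})

test_that("the Fisher test used by motif enrichment equals the hypergeometric tail", {
  p_impl <- ptmpath:::fisher_exact_p(5, 5, 5, 85)
  expect_equal(p_impl, oracle_fisher_p(5, 5, 5, 85), tolerance = 1e-9)
  set.seed(12)
  for (i in 1:25) {
    tab <- sample(0:12, 4, replace = TRUE)
    expect_equal(ptmpath:::fisher_exact_p(tab[1], tab[2], tab[3], tab[4]),
                 oracle_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
  }
})

test_that("a planted motif gets the smallest adjusted p among kinases", {
  spec <- synthetic_spec(seed = 21)
  pssms <- make_fixture_pssms(spec, n_kinases = 20)
  bg <- lapply(pssms, function(m) {
    score_flanks(ptmpath:::with_seed(99, random_flanks(300)), m)
  })
  planted_seq <- ptmpath:::with_seed(100, sample_pssm_peptides(pssms[["KIN1"]], 30))
  other_up <- ptmpath:::with_seed(101, random_flanks(10))
  nulls <- ptmpath:::with_seed(102, random_flanks(60))
  peptides <- data.frame(
    sequence = c(planted_seq, other_up, nulls),
    regulation = c(rep("up", 40), rep("not", 60))
  )
  res <- motif_enrichment(peptides, pssms, bg, top_k = 5)
  up <- res[res$direction == "up", ]
  expect_identical(up$kinase[which.min(up$p_adj)], "KIN1")
})

test_that("BH adjustment follows the step-up closed form and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  set.seed(3)
  p <- stats::runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # idempotent where the step-up minimum binds into a constant plateau
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  # order-preservation under permutation of the input
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pathway ranking sorts by absolute score with NAs last, stably", {
  res <- data.frame(signature_id = c("A", "B", "C"),
                    score = c(2.1, -3.0, NA))
  expect_identical(rank_pathways(res)$signature_id, c("B", "A", "C"))

  all_na <- data.frame(signature_id = c("x", "y", "z"), score = NA_real_)
  expect_identical(rank_pathways(all_na)$signature_id, c("x", "y", "z"))

  ties <- data.frame(signature_id = c("p", "q", "r"),
                     score = c(1.5, -1.5, 1.5))
  expect_identical(rank_pathways(ties)$signature_id, c("p", "q", "r"))
})

test_that("GMT files round-trip signatures with signed members", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "SIG1\tdesc\tGENE1\tGENE2\tGENE3",
    "SIG2\tptm sig\tP1_S10;+1\tP2_S20;-1"
  ), path)
  sigs <- read_gmt(path)
  expect_length(sigs, 2L)
  expect_identical(sigs[[1]]$members, c("GENE1", "GENE2", "GENE3"))
  expect_null(sigs[[1]]$signs)
  expect_identical(sigs[[2]]$members, c("P1_S10", "P2_S20"))
  expect_identical(sigs[[2]]$signs, c(1, -1))
})
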