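sample_dataset <- function() {
  ptm_dataset(
    experiment = c("e1", "e1", "e2"),
    peptide_key = c("PEP1", "PEP2", "PEP3"),
    uniprot_accessions = list("P42345", c("P31749", "P31750"), character()),
    gene_names = list("MTOR", c("AKT1", "AKT2"), "SOS1"),
    sites = list(parse_site("S2448"), parse_site("T308;S473"),
                 parse_site("S1134")),
    regulation = c("up", "down", "not"),
    fold_change = c(1.5, -2.25, NA),
    p_adj = c(0.01, 0.002, NA),
    pec50 = c(NA, 6.4, NA)
  )
}

test_that("site strings split into residue and 1-based position", {
  s <- parse_site("S1134")
  expect_identical(s$residue, "S")
  expect_identical(s$position, 1134L)
  multi <- parse_site("T246;S250")
  expect_identical(nrow(multi), 2L)
  expect_identical(parse_site(""), parse_site(NA))
  expect_null(parse_site("position12"))
})

test_that("CSV reading normalizes case, parses sites and collects bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Peptide,Uniprot,Gene Names,Site,Regulation,Fold Change",
    "PEP1,P42345,MTOR,S2448,Up,1.5",
    "PEP2,,SOS1,S1134,down,-2.0",
    "PEP3,,EGFR,Y1068,increased,0.1",
    "PEP4,,EGFR,badsite,down,0.1"
  ), path)
  ds <- read_ptm_csv(path)
  expect_identical(nrow(ds), 2L)
  expect_identical(ds$regulation, c("up", "down"))
  expect_identical(ds$sites[[2]]$position, 1134L)
  errs <- attr(ds, "errors")
  expect_identical(errs$line, c(4L, 5L))
  expect_match(errs$message[1], "increased")
})

test_that("missing required columns are hard errors naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Peptide,Gene Names,Site", "PEP1,MTOR,S1"), path)
  expect_error(read_ptm_csv(path), "Regulation")
  writeLines(c("Peptide,Regulation,Site", "PEP1,up,S1"), path)
  expect_error(read_ptm_csv(path), "identifier column")
})

test_that("tab and semicolon delimiters are sniffed", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Peptide\tUniprot\tGene Names\tSite\tRegulation",
               "PEP1\tP42345\tMTOR\tS2448\tup"), path)
  expect_identical(nrow(read_ptm_csv(path)), 1L)
})

test_that("CSV write/read round-trips all documented columns", {
  ds <- sample_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ptm_csv(ds, path)
  back <- read_ptm_csv(path)
  expect_identical(back$peptide_key, ds$peptide_key)
  expect_identical(back$regulation, ds$regulation)
  expect_identical(back$sites, ds$sites)
  expect_identical(back$uniprot_accessions, ds$uniprot_accessions)
  expect_identical(back$gene_names, ds$gene_names)
  expect_equal(back$fold_change, ds$fold_change)
  expect_equal(back$p_adj, ds$p_adj)
  expect_equal(back$pec50, ds$pec50)
  expect_identical(back$experiment, ds$experiment)
})

test_that("the TOML subset reader handles sections, scalars and arrays", {
  path <- withr::local_tempfile(fileext = ".toml")
  writeLines(c(
    'title = "experiment"   # comment',
    "[Experiment]",
    'drug = "Lapatinib"',
    "doses = [1, 3, 10, 30, 100, 300, 1000, 3000, 10000]",
    "control = true",
    "dose_scale = 1e-9"
  ), path)
  tl <- read_toml(path)
  expect_identical(tl$title, "experiment")
  expect_identical(tl$Experiment$drug, "Lapatinib")
  expect_length(tl$Experiment$doses, 9L)
  expect_true(tl$Experiment$control)
  expect_equal(tl$Experiment$dose_scale, 1e-9)
})

curves_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  toml <- file.path(dir, "params.toml")
  writeLines(c("[Experiment]", 'drug = "Lapatinib"',
               "doses = [1, 3, 10, 30, 100, 300, 1000, 3000, 10000, 10000]"),
             toml)
  curves <- file.path(dir, "curves.txt")
  writeLines(c(
    paste("Name", "Genes", "Proteins", "Curve Regulation", "pEC50",
          "Curve Fold Change", "Site", sep = "\t"),
    paste("PEP1", "EGFR", "P00533", "down", "7.41", "-2.2", "Y1068",
          sep = "\t"),
    paste("PEP2", "GRB2", "P62993", "not", "", "", "S86", sep = "\t"),
    paste("PEP3", "SOS1", "Q07889", "up", "4.2", "1.1", "S1134", sep = "\t")
  ), curves)
  list(toml = toml, curves = curves)
}

test_that("curve outputs become records with potency only when regulated", {
  fx <- curves_fixture()
  ds <- read_curvecurator(fx$curves, fx$toml)
  expect_identical(ds$regulation, c("down", "not", "up"))
  expect_equal(ds$pec50, c(7.41, NA, 4.2))
  expect_true(is.na(ds$fold_change[2]))
  expect_identical(unique(ds$experiment), "Lapatinib")
  # 1 nM..10 uM -> pEC50 window [9, 5]
  expect_equal(attr(ds, "pec50_window"), c(9, 5))
  flags <- vapply(ds$details, function(d) isTRUE(d$out_of_range), logical(1))
  expect_identical(flags, c(FALSE, FALSE, TRUE))
})

test_that("a drug-name mismatch between curves and parameters is fatal", {
  dir <- withr::local_tempdir()
  fx <- curves_fixture(dir)
  curves2 <- file.path(dir, "curves2.txt")
  writeLines(c(
    paste("Name", "Curve Regulation", "Drug", sep = "\t"),
    paste("PEP1", "down", "Dasatinib", sep = "\t")
  ), curves2)
  expect_error(read_curvecurator(curves2, fx$toml), "mismatch")
})

test_that("dose-pair deduplication applies rules I-IV", {
  rec <- data.frame(
    peptide_key = c("A", "A", "B", "B", "C", "C", "D", "D", "E", "E"),
    dose = rep(c("low", "high"), 5),
    significant = c(FALSE, FALSE,   # B? see keys below
                    TRUE, TRUE,
                    TRUE, FALSE,
                    FALSE, TRUE,
                    FALSE, FALSE),
    p_adj = c(0.5, 0.3, 0.01, 0.02, 0.04, 0.6, 0.7, 0.03, 0.8, 0.9)
  )
  out <- dedup_dose_pairs(rec)
  expect_identical(nrow(out), 5L)
  get <- function(k) out[out$peptide_key == k, ]
  expect_identical(get("A")$rule, "II")    # neither -> high dose
  expect_identical(get("A")$dose, "high")
  expect_identical(get("B")$rule, "III")   # high significant -> high
  expect_identical(get("C")$rule, "IV")    # only low significant -> low
  expect_identical(get("C")$dose, "low")
  expect_identical(get("D")$rule, "III")
})

test_that("within-experiment duplicates keep the most significant entry first", {
  rec <- data.frame(
    peptide_key = c("A", "A", "A"),
    dose = c("high", "high", "low"),
    significant = c(TRUE, TRUE, FALSE),
    p_adj = c(0.2, 0.04, 0.5)
  )
  out <- dedup_dose_pairs(rec)
  expect_identical(nrow(out), 1L)
  expect_identical(out$p_adj, 0.04)  # rule I kept the lower p before III
  expect_identical(out$rule, "III")
})

test_that("single-dose peptides keep their only entry", {
  rec <- data.frame(peptide_key = "X", dose = "low", significant = FALSE,
                    p_adj = 0.4)
  out <- dedup_dose_pairs(rec)
  expect_identical(out$rule, "single")
})
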