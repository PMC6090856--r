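test_that("the built-in scorer is deterministic and allele-specific", {
  pep <- "VGACGVGKSALTIQL"
  a <- toy_pssm_score(pep, "DRB1*01:01")
  expect_identical(a, toy_pssm_score(pep, "DRB1*01:01"))
  expect_false(isTRUE(all.equal(a, toy_pssm_score(pep, "DRB1*12:01"))))
  # determinism survives RNG state changes around the call
  set.seed(123); runif(5)
  expect_identical(a, toy_pssm_score(pep, "DRB1*01:01"))
  # scoring is invariant to input ordering
  set.seed(2)
  peps <- replicate(30, random_protein(15))
  fwd <- score_peptides(peps, "DRB1*07:01")
  rev <- score_peptides(rev(peps), "DRB1*07:01")
  expect_equal(fwd, rev(rev))
  expect_error(score_peptides("ACDEFGli", "DRB1*01:01"), "alphabet")
  expect_error(score_peptides("ACDEFG", "DRB1*01:01"), "length")
})

test_that("the score-to-IC50 transform is strictly decreasing with fixed anchors", {
  # ic50 = 50000^(1 - s): s = 1 -> 1 nM, s = 0 -> 50000 nM
  expect_equal(50000^(1 - 1), 1)
  expect_equal(50000^(1 - 0), 50000)
  # raising the raw score via bias can only lower the IC50
  set.seed(3)
  peps <- replicate(50, random_protein(15))
  base <- score_peptides(peps, "DRB1*01:01")
  biased <- score_peptides(peps, "DRB1*01:01", bias = 1.5)
  expect_true(all(biased <= base))
  expect_true(any(biased < base))
})

test_that("IC50 categories are exhaustive, exclusive and strict at the cuts", {
  expect_equal(categorize(c(49.9, 50, 214.21, 499.9, 500, 1e5)),
               c("strong", "weak", "weak", "weak", "non_binder", "non_binder"))
  set.seed(4)
  x <- exp(runif(200, 0, log(50000)))
  cats <- categorize(x)
  expect_true(all(cats %in% c("strong", "weak", "non_binder")))
  expect_equal(sum(cats == "strong") + sum(cats == "weak") +
                 sum(cats == "non_binder"), 200L)
  expect_error(categorize(0), "positive")
})

test_that("typed mode scores only each patient's alleles; panel mode scores all", {
  cand <- data.frame(patient_id = c("P01", "P02"), gene = "G1",
                     protein_change = "p.G12C", mhc_class = "II", length = 15L,
                     sequence = c("VGACGVGKSALTIQL", "KLVVVGADGVGKSAL"),
                     mutant_positions = "4", wt_sequence = NA_character_,
                     stringsAsFactors = FALSE)
  samples <- make_samples(2, hla_class2_alleles = c("DRB1*01:01;DRB1*01:01",
                                                    "DRB1*07:01;DRB1*12:01"))
  panel <- c("DRB1*01:01", "DRB1*07:01", "DRB1*12:01")
  typed <- score_candidates(cand, panel, samples = samples, mode = "typed")
  expect_equal(sort(unique(typed$allele[typed$patient_id == "P01"])), "DRB1*01:01")
  expect_equal(sort(unique(typed$allele[typed$patient_id == "P02"])),
               c("DRB1*07:01", "DRB1*12:01"))
  pan <- score_candidates(cand, panel, mode = "panel")
  expect_equal(nrow(pan), 2L * 3L)
  expect_true(all(pan$predictor_name == "toy-pssm"))
  expect_true(all(pan$allele_mode == "panel"))
})

test_that("the external predictor adapter parses fixtures and refuses absent executables", {
  fix <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\tic50_nm",
               "VGACGVGKSALTIQL\tDRB1*01:01\t214.21",
               "KLVVVGADGVGKSAL\tDRB1*11:03\t280.09"), fix)
  calls <- parse_predictor_output(fix)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$category, c("weak", "weak"))

  writeLines(c("peptide\tallele\tic50_nm",
               "VGACGVGKSALTIQL\tDRB1*01:01\tstrong"), fix)
  expect_error(parse_predictor_output(fix), "line 2")

  cand <- data.frame(sequence = "VGACGVGKSALTIQL", length = 15L,
                     stringsAsFactors = FALSE)
  expect_error(
    run_external_predictor(cand, "DRB1*01:01",
                           list(executable = "/nonexistent/netmhciipan")),
    "not installed")
})
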