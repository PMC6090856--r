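test_that("expression gate uses the 3-read floor with absent genes as zero", {
  expr <- data.frame(patient_id = c("P1", "P1", "P2"),
                     gene = c("G1", "G2", "G1"),
                     read_count = c(3L, 2L, 50L), stringsAsFactors = FALSE)
  expect_true(is_expressed("G1", "P1", expr))
  expect_false(is_expressed("G2", "P1", expr))
  expect_false(is_expressed("G3", "P1", expr))
  expect_false(is_expressed("G2", "P2", expr))
})

test_that("the HGVS-p parser covers the dialects in the mutation tables", {
  expect_equal(parse_protein_change("p.G12C"),
               list(type = "substitution", wt = "G", pos = 12L, alt = "C"))
  expect_equal(parse_protein_change("p.G12 V")$alt, "V")  # stray spaces ignored
  expect_equal(parse_protein_change("p.L100L")$type, "silent")
  expect_equal(parse_protein_change("p.E100*")$type, "nonsense")
  expect_equal(parse_protein_change("p.A69fs"),
               list(type = "frameshift", wt = "A", pos = 69L))
  expect_equal(parse_protein_change("p.ELR746del"),
               list(type = "del", wt = "ELR", pos = 746L))
  expect_equal(parse_protein_change("p.773_774insH"),
               list(type = "ins", pos = 773L, end = 774L, alt = "H"))
  expect_equal(parse_protein_change("p.709_710ET>D"),
               list(type = "delins", pos = 709L, end = 710L, wt = "ET", alt = "D"))
  expect_error(parse_protein_change("c.35G>T"), "unsupported")
  expect_error(parse_protein_change("p.G12del_oops"), "unsupported")
})

test_that("substitutions and in-frame indels edit the protein with span tracking", {
  k <- kras_fixture()
  wt <- k$proteome[["TX_KRAS"]]
  res <- apply_protein_change(wt, "p.G12C")
  expect_equal(substr(res$protein, 12, 12), "C")
  expect_equal(res$span, c(12L, 12L))
  expect_equal(nchar(res$protein), nchar(wt))
  expect_error(apply_protein_change(wt, "p.A12C"), "mismatch")

  # deletion: EGFR-style residue run; junction span
  prot <- "MAAAELRKKK"
  res <- apply_protein_change(prot, "p.ELR5del")
  expect_equal(res$protein, "MAAAKKK")
  expect_equal(res$span, c(4L, 5L))

  # insertion between adjacent residues
  res <- apply_protein_change("MAKW", "p.2_3insHH")
  expect_equal(res$protein, "MAHHKW")
  expect_equal(res$span, c(3L, 4L))

  # range replacement
  res <- apply_protein_change("MAETKW", "p.3_4ET>D")
  expect_equal(res$protein, "MADKW")
  expect_equal(res$span, c(2L, 4L))
})

test_that("frameshifts re-translate the shifted frame to the new stop", {
  # ATG AAA GAT TGG TGT TAA = MKDWC; deleting the first base of codon 2
  # shifts the frame: ATG AAG ATT GGT GTT AA -> MKIGV (hand translation),
  # novel residues from position 3 to the new C-terminus
  res <- apply_protein_change("MKDWC", "p.K2fs", cds = "ATGAAAGATTGGTGTTAA")
  expect_equal(res$protein, "MKIGV")
  expect_equal(res$span, c(3L, 5L))
  expect_false(res$no_peptide)

  # an explicit CDS edit overrides the default single-base-deletion
  # convention; here the shifted frame happens to re-encode the same
  # residues (AAA GGG TTT -> AAG GGT TTT), so there is no novelty
  res <- apply_protein_change("MKGF", "p.K2fs", cds = "ATGAAAGGGTTTTAA",
                              fs_edit = list(pos = 5L, ref = "A", alt = ""))
  expect_true(res$no_peptide)

  # immediate stop in the shifted frame -> flagged, no peptide:
  # ATG CTA AAA TAA = MLK; deleting base 4 gives ATG TAA ... = M-stop
  res <- apply_protein_change("MLK", "p.L2fs", cds = "ATGCTAAAATAA")
  expect_true(res$no_peptide)

  expect_error(apply_protein_change("MKGF", "p.K2fs"), "requires the coding")
  expect_error(apply_protein_change("MKGF", "p.K2fs", cds = "ATGAAATTTTAA"),
               "does not translate")
})

test_that("silent and nonsense variants yield no peptide windows", {
  res <- apply_protein_change("MKGF", "p.G3G")
  expect_true(res$no_peptide)
  res <- apply_protein_change("MKGF", "p.G3*")
  expect_true(res$no_peptide)
  expect_equal(res$protein, "MK")
  expect_equal(nrow(enumerate_windows(res$protein, res$span, 15)), 0L)
})

test_that("windows stay inside the protein and always cover the mutation", {
  set.seed(13)
  for (i in 1:40) {
    len <- sample(16:90, 1)
    prot <- random_protein(len)
    pos <- sample(len, 1)
    w <- enumerate_windows(prot, c(pos, pos), c(8, 11, 15))
    if (nrow(w) == 0L) next
    expect_true(all(w$start >= 1))
    expect_true(all(w$start + w$length - 1 <= len))
    # every window covers the mutant position
    expect_true(all(w$start <= pos & w$start + w$length - 1 >= pos))
    # the reported mutant positions index the mutated residue
    idx <- as.integer(w$mutant_positions)
    expect_true(all(substr(w$sequence, idx, idx) == substr(prot, pos, pos)))
  }
  expect_warning(w <- enumerate_windows("MKGF", c(2L, 2L), 15), "shorter")
  expect_equal(nrow(w), 0L)
})

test_that("missense candidates always differ from the wild-type window", {
  set.seed(5)
  proteome <- c(TX01 = random_protein(120))
  muts <- make_mutations(1, patient_id = "P01", transcript_id = "TX01",
                         protein_change = sprintf("p.%s60W",
                                                  substr(proteome[["TX01"]], 60, 60)))
  if (substr(proteome[["TX01"]], 60, 60) == "W") {
    muts$protein_change <- sprintf("p.%s60Y", "W")
  }
  cand <- build_candidates(muts, proteome, class2_length = 15L,
                           class1_lengths = 8:11)
  expect_true(nrow(cand) > 0)
  expect_true(all(cand$sequence != cand$wt_sequence))
  expect_true(all(nchar(cand$sequence) == cand$length))
  expect_equal(sort(unique(cand$mhc_class)), c("I", "II"))
})
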