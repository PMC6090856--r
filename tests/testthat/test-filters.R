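test_that("filter boundaries follow the strict printed semantics", {
  muts <- make_mutations(6,
    pon_frequency = c(0.011, 0.01, 0, 0, 0, 0),
    in_dbsnp = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    in_1000g = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    alt_count = c(20L, 5L, 20L, 20L, 4L, 5L),
    ref_count = c(20L, 5L, 20L, 20L, 5L, 5L))
  rep <- filter_mutations(muts)
  # removed: PoN 1.1%, dbSNP, 1000G, depth 9; kept: PoN exactly 1% @ depth 10, depth 10
  expect_equal(sort(rep$kept$patient_id), c("P02", "P06"))
  expect_equal(unname(rep$removed_by), c(1L, 1L, 1L, 1L))
})

test_that("each removal is attributed to the first failing filter", {
  # a record failing everything counts only against the PoN filter
  muts <- make_mutations(1, pon_frequency = 0.5, in_dbsnp = TRUE,
                         in_1000g = TRUE, alt_count = 1L, ref_count = 1L)
  rep <- filter_mutations(muts)
  expect_equal(unname(rep$removed_by["pon"]), 1L)
  expect_equal(sum(rep$removed_by), 1L)
})

test_that("filtering conserves and is order-invariant over random fixtures", {
  set.seed(41)
  for (rep_i in 1:20) {
    n <- sample(5:60, 1)
    muts <- make_mutations(n,
      patient_id = sprintf("P%02d", sample(5, n, replace = TRUE)),
      pon_frequency = round(runif(n, 0, 0.03), 4),
      in_dbsnp = runif(n) < 0.2, in_1000g = runif(n) < 0.2,
      alt_count = as.integer(rpois(n, 8)), ref_count = as.integer(rpois(n, 8)))
    muts$pos <- seq_len(n) * 10L  # unique identity
    rep1 <- filter_mutations(muts)
    expect_equal(nrow(rep1$kept) + sum(rep1$removed_by), nrow(muts))
    shuffled <- muts[sample(n), , drop = FALSE]
    rep2 <- filter_mutations(shuffled)
    expect_equal(sort(rep1$kept$pos), sort(rep2$kept$pos))
    expect_equal(rep1$removed_by, rep2$removed_by)
  }
})

test_that("category counts cover all seven classes and sum to input size", {
  expect_equal(sum(count_by_category(make_mutations(0)[0, ])), 0L)
  expect_length(count_by_category(make_mutations(0)[0, ]), 7L)

  muts <- make_mutations(3, classification = c("missense", "missense", "frameshift_indel"),
                         ref_allele = c("A", "A", "GA"), alt_allele = c("T", "T", "G"))
  cnt <- count_by_category(muts)
  expect_equal(unname(cnt["missense"]), 2L)
  expect_equal(unname(cnt["frameshift_indel"]), 1L)
  expect_equal(sum(cnt), 3L)
})

test_that("the lung adenocarcinoma category tally reproduces the cohort total", {
  printed <- c(missense = 26296L, silent = 8965L, nonsense = 2061L,
               splice_site = 911L, nonstop_readthrough = 98L,
               frameshift_indel = 1735L, inframe_indel = 163L)
  muts <- data.frame(classification = rep(names(printed), printed),
                     stringsAsFactors = FALSE)
  cnt <- count_by_category(muts)
  expect_equal(cnt[names(printed)], printed)
  expect_equal(sum(cnt), 40229L)
})
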