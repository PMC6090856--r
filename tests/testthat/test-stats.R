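test_that("the one-sided Mann-Whitney U matches hand-derived cases", {
  res <- mann_whitney_one_sided(c(3, 4, 5), c(1, 2))
  expect_equal(res$u, 6)
  expect_equal(res$p, 0.1)   # only 1 of C(5,2)=10 rank splits attains U=6
  # identical samples carry no evidence for "greater"
  x <- c(1, 2, 2, 5)
  expect_gte(mann_whitney_one_sided(x, x)$p, 0.5)
  expect_error(mann_whitney_one_sided(numeric(0), 1), "non-empty")
})

test_that("the tied large-sample path matches the longhand normal approximation", {
  set.seed(21)
  for (i in 1:10) {
    x <- rpois(40, 5); y <- rpois(150, 4)
    got <- mann_whitney_one_sided(x, y)
    n <- length(x); m <- length(y); N <- n + m
    r <- rank(c(x, y))
    u <- sum(r[1:n]) - n * (n + 1) / 2
    ties <- table(c(x, y))
    sigma <- sqrt(n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    p_ref <- pnorm((u - n * m / 2 - 0.5) / sigma, lower.tail = FALSE)
    expect_equal(got$u, u)
    expect_equal(got$p, p_ref, tolerance = 1e-6)
  }
})

test_that("BH adjustment reproduces the step-up by hand", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  # monotone in sorted-p order
  set.seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("patient burden deduplicates at the mutation level with best category", {
  calls <- make_calls(rep("P01", 3), "DRB1*01:01",
                      c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC", "DDDDDDDDDDDDDDD"),
                      c("weak", "weak", "strong"))
  muts <- make_mutations(2, patient_id = c("P01", "P02"), gene = "G01")
  burden <- per_patient_burden(calls, muts)
  p1 <- burden[burden$patient_id == "P01", ]
  expect_equal(p1$n_strong, 1L)  # one mutation, strongest call wins
  expect_equal(p1$n_weak, 0L)
  # zero-burden patients still emitted, ordering by total burden
  expect_equal(burden$patient_id, c("P01", "P02"))
  expect_equal(burden$n_strong[2] + burden$n_weak[2], 0L)
})

test_that("gene frequency counts binders per patient fraction", {
  calls <- rbind(
    make_calls(c("P01", "P02", "P03"), "DRB1*01:01",
               c("AAAAAAAAAAAAAAA", "CCCCCCCCCCCCCCC", "DDDDDDDDDDDDDDD"),
               c("weak", "weak", "strong"), gene = "G01"),
    make_calls("P04", "DRB1*01:01", "EEEEEEEEEEEEEEE", "non_binder", gene = "G02"))
  muts <- make_mutations(4, patient_id = sprintf("P%02d", 1:4),
                         gene = c("G01", "G01", "G01", "G02"))
  pg <- per_gene_frequency(calls, muts, n_patients = 10)
  g1 <- pg[pg$gene == "G01", ]
  expect_equal(g1$freq_of_patients, 0.3)
  expect_equal(g1$n_strong, 1L)
  expect_equal(g1$n_weak, 2L)
  g2 <- pg[pg$gene == "G02", ]
  expect_equal(g2$freq_of_patients, 0)
  expect_equal(g2$n_other, 1L)
  expect_equal(nrow(per_gene_frequency(calls[0, ], muts[0, ], 1)), 0L)
})

test_that("allele enrichment is symmetric and flags unevaluated alleles", {
  patients <- sprintf("P%02d", 1:6)
  calls <- rbind(
    make_calls(rep(patients, each = 2), "A*01:01",
               paste0(rep(patients, each = 2), "PEPTIDEAAAA", 1:2), "weak"),
    make_calls(rep(patients, each = 2), "B*01:01",
               paste0(rep(patients, each = 2), "PEPTIDEAAAA", 1:2), "weak"))
  enr <- allele_enrichment(calls, patients, c("A*01:01", "B*01:01", "C*01:01"))
  pa <- enr$p_value[enr$allele == "A*01:01"]
  pb <- enr$p_value[enr$allele == "B*01:01"]
  expect_equal(pa, pb)   # identical call sets -> identical p
  un <- enr[enr$allele == "C*01:01", ]
  expect_false(un$evaluated)
  expect_equal(un$p_value, 1)
  expect_error(allele_enrichment(calls, patients, "A*01:01"), "at least 2")
})

test_that("typed-mode totals agree across patient and allele breakdowns", {
  set.seed(31)
  cfg <- synth_config(n_patients = 10, n_genes = 30,
                      mean_mutations_per_patient = 15,
                      allele_panel = drb1_panel()[1:5], seed = 17)
  co <- generate_cohort(cfg)
  res <- suppressWarnings(run_pipeline(
    co, config = run_config(allele_mode = "typed",
                            allele_panel = cfg$allele_panel), quiet = TRUE))
  cs <- res$tables$cohort
  dd_total <- cs$totals$strong_peptides + cs$totals$weak_peptides
  expect_equal(sum(cs$per_allele$total), dd_total)
  expect_equal(cs$totals$neo_mutations,
               sum(cs$per_patient$n_strong + cs$per_patient$n_weak))
})
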