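test_that("expected VAF follows the purity/copy-number scaling", {
  expect_equal(expected_vaf(1, 1, 2), 0.5)
  expect_equal(expected_vaf(1, 0.5, 2), 0.25)
  expect_equal(expected_vaf(0, 0.7, 3), 0)
  expect_equal(expected_vaf(0.5, 0.8, 4), 0.5 * 0.8 / (2 * 0.2 + 0.8 * 4))
  # monotone in ccf
  v <- expected_vaf(seq(0, 1, 0.1), 0.6, 3)
  expect_true(all(diff(v) > 0))
  expect_error(expected_vaf(1, 0.5, 0), "deleted")
  expect_error(expected_vaf(1, 1.2, 2), "purity")
})

test_that("posterior mode tracks the VAF-implied CCF and normalizes", {
  p <- ccf_posterior(50, 50, 1, 2)     # VAF 0.5 -> CCF 1
  expect_equal(p$mode, 1.0)
  p <- ccf_posterior(10, 30, 1, 2)     # VAF 0.25 -> CCF 0.5
  expect_equal(p$mode, 0.5, tolerance = 0.011)
  for (q in list(c(5, 5), c(40, 80), c(3, 200))) {
    p <- ccf_posterior(q[1], q[2], 0.7, 2)
    expect_equal(sum(p$density) * 0.01, 1, tolerance = 1e-6)
    expect_true(all(p$density >= 0))
    expect_true(p$ci95[1] <= p$ci95[2])
  }
  expect_error(ccf_posterior(0, 0, 1, 2), "alt \\+ ref")
})

test_that("increasing purity never raises the posterior CCF mode", {
  set.seed(7)
  for (i in 1:25) {
    alt <- sample(1:80, 1); ref <- sample(1:120, 1); cn <- sample(1:4, 1)
    modes <- vapply(c(0.3, 0.5, 0.7, 0.9),
                    function(a) ccf_posterior(alt, ref, a, cn)$mode, numeric(1))
    expect_true(all(diff(modes) <= 1e-9))
  }
})

test_that("clonal calls come from the credible interval reaching near 1", {
  expect_true(classify_clonal(ccf_posterior(200, 200, 1, 2)))
  expect_false(classify_clonal(ccf_posterior(30, 170, 1, 2)))
  # a two-read mutation is uninformative: the wide CI reaches the clonal region
  expect_true(classify_clonal(ccf_posterior(1, 1, 1, 2)))
  # threshold is configurable
  p <- ccf_posterior(30, 170, 1, 2)
  expect_true(classify_clonal(p, clonal_ccf_min = p$ci95[2]))
})

test_that("clonality annotation joins purity and falls back to diploid", {
  muts <- make_mutations(2, patient_id = c("P01", "P01"),
                         alt_count = c(30L, 10L), ref_count = c(30L, 50L),
                         pos = c(150L, 9999L))
  samples <- make_samples(1, purity = 1)
  segments <- data.frame(patient_id = "P01", chrom = "1", start = 1L,
                         end = 1000L, total_cn = 2L)
  expect_warning(ann <- annotate_clonality(muts, samples, segments),
                 "without a covering")
  expect_equal(ann$local_cn, c(2L, 2L))
  expect_true(ann$is_clonal[1])
  expect_false(ann$is_clonal[2])
  expect_error(annotate_clonality(make_mutations(1, patient_id = "PX"),
                                  samples, segments), "absent")
})

test_that("purity estimation warns on tiny input and errors on empty", {
  m <- make_mutations(1, alt_count = 30L, ref_count = 30L)
  m$local_cn <- 2L
  expect_warning(res <- estimate_purity(m), "low-confidence")
  expect_true(res$purity_hat >= 0.05 && res$purity_hat <= 1)
  expect_error(estimate_purity(m[0, ]), "at least one")
})
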