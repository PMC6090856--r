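test_that("the generator is deterministic and extending the cohort is stable", {
  cfg <- synth_config(n_patients = 6, n_genes = 25,
                      mean_mutations_per_patient = 20, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$samples, b$samples)
  expect_identical(a$proteome, b$proteome)
  # adding patients must not perturb earlier patients' draws
  cfg2 <- synth_config(n_patients = 8, n_genes = 25,
                       mean_mutations_per_patient = 20, seed = 42)
  c8 <- generate_cohort(cfg2)
  expect_identical(a$mutations,
                   c8$mutations[c8$mutations$patient_id %in% a$samples$patient_id, ])
  # and the written bundle is byte-stable
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(a, d1); write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generated bundles pass all readers with zero schema errors", {
  cfg <- synth_config(n_patients = 4, n_genes = 20,
                      mean_mutations_per_patient = 15, seed = 7)
  co <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  muts <- read_mutations(file.path(d, "mutations.tsv"), dialect = "tsv")
  expect_equal(nrow(muts), nrow(co$mutations))
  expect_equal(nrow(read_samples(file.path(d, "samples.tsv"))), 4L)
  expect_gt(nrow(read_segments(file.path(d, "segments.tsv"))), 0L)
  expect_gt(nrow(read_expression(file.path(d, "expression.tsv"))), 0L)
  expect_length(read_fasta(file.path(d, "proteome.fasta")), 20L)
  # truth manifest aligns with the mutation table one-to-one
  expect_equal(nrow(co$truth$mutations), nrow(co$mutations))
  expect_false(anyDuplicated(co$truth$mutations$mut_id) > 0)
  # clonal bookkeeping matches the labels
  expect_equal(sum(co$truth$mutations$clonal),
               sum(co$truth$mutations$true_ccf == 1))
})

test_that("every generated coding HGVS-p applies cleanly to the proteome", {
  cfg <- synth_config(n_patients = 6, n_genes = 25,
                      mean_mutations_per_patient = 40, seed = 3)
  co <- generate_cohort(cfg)
  coding <- co$mutations[co$mutations$classification %in%
                           c("missense", "silent", "nonsense",
                             "frameshift_indel", "inframe_indel"), ]
  for (i in seq_len(nrow(coding))) {
    tx <- coding$transcript_id[i]
    expect_no_error(apply_protein_change(co$proteome[[tx]],
                                         coding$protein_change[i],
                                         cds = co$cds[[tx]]))
  }
})

test_that("simulated clonal VAFs concentrate at purity/2 on diploid segments", {
  cfg <- synth_config(n_patients = 12, n_genes = 40,
                      mean_mutations_per_patient = 120,
                      purity_range = c(0.6, 0.6), clonal_fraction = 1,
                      mean_depth = 200, depth_dispersion = 1e6, seed = 5)
  co <- generate_cohort(cfg)
  tm <- co$truth$mutations
  diploid <- tm$local_cn == 2
  expect_gt(sum(diploid), 1000L)
  m <- co$mutations[diploid, ]
  vaf <- m$alt_count / (m$alt_count + m$ref_count)
  se <- sd(vaf) / sqrt(length(vaf))
  expect_lt(abs(mean(vaf) - 0.3), 2 * se + 1e-3)
})

test_that("the KRAS hotspot fixture reproduces the published neo-peptides", {
  k <- kras_fixture()
  expect_equal(nrow(k$mutations), 6L)
  expect_setequal(k$mutations$protein_change,
                  paste0("p.G12", c("C", "V", "A", "D", "R", "S")))
  g12c <- apply_protein_change(k$proteome[["TX_KRAS"]], "p.G12C")
  expect_equal(substr(g12c$protein, 9, 23), "VGACGVGKSALTIQL")
  # fixture round-trips through the io module
  d <- withr::local_tempdir()
  write_mutations(k$mutations, file.path(d, "m.tsv"))
  write_fasta(k$proteome, file.path(d, "p.fasta"))
  expect_equal(nrow(read_mutations(file.path(d, "m.tsv"), "tsv")), 6L)
  expect_equal(read_fasta(file.path(d, "p.fasta"))[["TX_KRAS"]],
               k$proteome[["TX_KRAS"]])
})
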