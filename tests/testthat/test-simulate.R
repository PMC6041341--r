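test_that("generators are pure functions of their seed", {
  a <- simulate_family_matrix(n_orthogroups = 150, seed = 3)
  b <- simulate_family_matrix(n_orthogroups = 150, seed = 3)
  expect_identical(a, b)
  expect_false(identical(a$counts, simulate_family_matrix(n_orthogroups = 150, seed = 4)$counts))

  expect_identical(simulate_expression(n_genes = 50, seed = 3),
                   simulate_expression(n_genes = 50, seed = 3))
  expect_identical(simulate_cds_pairs(n_pairs = 5, seed = 3),
                   simulate_cds_pairs(n_pairs = 5, seed = 3))
  expect_identical(simulate_kmer_histogram(genome_size = 1e4, seed = 3),
                   simulate_kmer_histogram(genome_size = 1e4, seed = 3))
})

test_that("simulated count matrices satisfy the rule they plant and honor zero loss rates", {
  sim <- simulate_family_matrix(n_orthogroups = 400, seed = 8)
  tr <- sim$truth
  # planted conserved rows are exactly the rows the rule selects
  cons <- conserved_orthogroups(sim$counts, tr$reference, tr$panel, tr$min_present)
  expect_setequal(cons$orthogroup, tr$conserved)
  # the planted partition is internally consistent
  expect_length(intersect(tr$specific_a, tr$specific_b), 0)
  expect_setequal(tr$lost_a, c(tr$joint, tr$specific_a))
  expect_setequal(tr$lost_b, c(tr$joint, tr$specific_b))

  none <- simulate_family_matrix(n_orthogroups = 200, loss_rate_a = 0,
                                 loss_rate_b = 0, joint_rate = 0, seed = 9)
  expect_length(none$truth$lost_a, 0)
  expect_length(none$truth$lost_b, 0)
  m <- as.matrix(none$counts[none$counts$orthogroup %in% none$truth$conserved,
                             none$truth$targets])
  expect_true(all(m >= 1))

  expect_error(simulate_family_matrix(100, loss_rate_a = 1.2, seed = 1), "\\[0, 1\\]")
  expect_error(simulate_family_matrix(100, joint_rate = 0.2, loss_rate_a = 0.1, seed = 1),
               "joint_rate")
})

test_that("noiseless expression planting is recovered exactly; pet_fraction 0 yields none", {
  sim <- simulate_expression(n_genes = 300, pet_fraction = 0.25, fold = 10,
                             noise_cv = 0, seed = 21)
  pets <- principal_tissues(sim$expression)
  truth <- sim$truth[!is.na(sim$truth$pet_tissue), ]
  expect_setequal(paste(pets$gene, pets$tissue),
                  paste(truth$gene, truth$pet_tissue))

  empty <- simulate_expression(n_genes = 100, pet_fraction = 0, noise_cv = 0, seed = 22)
  expect_equal(nrow(principal_tissues(empty$expression)), 0)
})

test_that("noisy planted PETs are recovered with high sensitivity", {
  # bound established by Monte-Carlo over these 5 fixed seeds
  sens <- vapply(1:5, function(s) {
    sim <- simulate_expression(n_genes = 500, fold = 3, noise_cv = 0.2, seed = s)
    pets <- principal_tissues(sim$expression)
    truth <- sim$truth[!is.na(sim$truth$pet_tissue), ]
    mean(paste(truth$gene, truth$pet_tissue) %in% paste(pets$gene, pets$tissue))
  }, 1)
  expect_gte(mean(sens), 0.95)
})

test_that("planted CDS lesions drive the expected scan outcomes", {
  one <- simulate_cds_pairs(n_pairs = 20,
                            lesion_mix = c(frameshift = 1, premature_stop = 0, intact = 0),
                            background_sub_rate = 0, seed = 25)
  scan <- scan_pseudogenes(one$pairs)
  expect_true(all(scan$pairs$n_frameshift == 1))

  clean <- simulate_cds_pairs(n_pairs = 20,
                              lesion_mix = c(frameshift = 0, premature_stop = 0, intact = 1),
                              background_sub_rate = 0.01, seed = 26)
  expect_false(any(scan_pseudogenes(clean$pairs)$pairs$is_pseudogene))
})

test_that("simulated references are intact ORFs and candidates differ only as planted", {
  sim <- simulate_cds_pairs(n_pairs = 10, seed = 27)
  for (ref in sim$pairs$reference) {
    expect_equal(nchar(ref) %% 3, 0)
    expect_equal(substr(ref, 1, 3), "ATG")
    cods <- substring(ref, seq(1, nchar(ref) - 2, 3), seq(3, nchar(ref), 3))
    expect_true(cods[length(cods)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(cods[-length(cods)] %in% c("TAA", "TAG", "TGA")))
  }
  # intact pairs have equal length; frameshift pairs differ by 1-2 nt
  joined <- dplyr::inner_join(sim$pairs, sim$truth$pairs, by = "pair_id")
  dlen <- abs(nchar(joined$candidate) - nchar(joined$reference))
  expect_true(all(dlen[joined$planted != "frameshift"] == 0))
  expect_true(all(dlen[joined$planted == "frameshift"] %in% 1:2))
})

test_that("simulated k-mer histograms carry the planted coverage peak", {
  sim <- simulate_kmer_histogram(genome_size = 2e5, coverage = 42,
                                 repeat_fraction = 0, error_rate = 0, seed = 29)
  peak <- sim$histogram$depth[which.max(sim$histogram$count)]
  expect_lte(abs(peak - 42), 1)
  expect_error(simulate_kmer_histogram(coverage = -1, seed = 1), "positive")
  expect_error(simulate_kmer_histogram(repeat_fraction = 2, seed = 1), "\\[0, 1\\]")
})
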