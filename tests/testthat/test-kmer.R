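test_that("k-mer histograms read back and malformed files are rejected", {
  tf <- withr::local_tempfile(fileext = ".histo")
  writeLines(c("1 100", "2 50", "42 9000"), tf)
  h <- read_kmer_histogram(tf)
  expect_equal(h$depth, c(1L, 2L, 42L))
  expect_equal(h$count, c(100, 50, 9000))

  writeLines(c("0 5", "1 10"), tf)
  expect_error(read_kmer_histogram(tf), "positive integer")
  writeLines(character(0), tf)
  expect_error(read_kmer_histogram(tf), "empty")
  writeLines(c("2 5", "1 10"), tf)
  expect_error(read_kmer_histogram(tf), "sorted")
  writeLines(c("1 5", "1 10"), tf)
  expect_error(read_kmer_histogram(tf), "sorted")
})

test_that("valley/peak detection finds the error threshold and ties break to the smaller depth", {
  # error spike at 1-2, valley at 5, bump peaking at 42
  depths <- 1:60
  counts <- c(50000, 9000, 2000, 600, 200, # error spike, bottom at depth 5
              210 + round(5000 * exp(-(6:60 - 42)^2 / 200))) # coverage bump at 42
  h <- tibble::tibble(depth = depths, count = counts)
  fp <- find_peak(h)
  expect_equal(fp$error_threshold, 5L)
  expect_equal(fp$peak_depth, 42L)

  # unimodal bump rising from depth 1: no valley
  h2 <- tibble::tibble(depth = 1:10, count = c(1, 2, 5, 9, 12, 11, 8, 4, 2, 1))
  expect_error(find_peak(h2), "valley")
  # monotone decreasing: no valley either
  h3 <- tibble::tibble(depth = 1:10, count = 10:1)
  expect_error(find_peak(h3), "valley")

  # two equal maxima above the threshold: the smaller depth wins
  h4 <- tibble::tibble(depth = 1:10, count = c(100, 10, 2, 30, 50, 50, 30, 10, 5, 2))
  expect_equal(find_peak(h4)$peak_depth, 5L)
})

test_that("genome size is mass over peak depth and responds predictably to the histogram", {
  # all k-mers at depth 42, total mass 4200 -> G = 100
  h <- tibble::tibble(depth = 42L, count = 100)
  est <- estimate_genome_size(h, error_threshold = 1, peak_depth = 42)
  expect_equal(est$genome_size, 100)
  expect_equal(est$kmer_count, 4200)

  base <- tibble::tibble(depth = c(1L, 2L, 5L, 40L, 42L, 44L),
                         count = c(1000, 300, 10, 50, 80, 50))
  e1 <- estimate_genome_size(base, error_threshold = 5, peak_depth = 42)
  # doubling every count doubles K and G, peak unchanged
  e2 <- estimate_genome_size(dplyr::mutate(base, count = count * 2),
                             error_threshold = 5, peak_depth = 42)
  expect_equal(e2$genome_size, 2 * e1$genome_size)
  expect_equal(e2$peak_depth, e1$peak_depth)
  # extra mass strictly below the threshold changes nothing
  e3 <- estimate_genome_size(dplyr::mutate(base, count = count + c(9e6, 9e6, 0, 0, 0, 0)),
                             error_threshold = 5, peak_depth = 42)
  expect_equal(e3$genome_size, e1$genome_size)
  # the naive estimate does include it
  expect_gt(e3$genome_size_naive, e1$genome_size_naive)

  expect_error(estimate_genome_size(base, error_threshold = 50, peak_depth = 42), "exceed")
  expect_error(estimate_genome_size(tibble::tibble(depth = c(1L, 2L, 3L), count = c(1, 1, 0)),
                                    error_threshold = 3, peak_depth = 5),
               "above the error threshold")
})

test_that("the published-scale quotient reproduces the naive division", {
  # 11,700,637,064 17-mers at a 42x peak: naive quotient ~278.59 Mb
  h <- tibble::tibble(depth = 42L, count = 11700637064 / 42)
  est <- estimate_genome_size(h, error_threshold = 1, peak_depth = 42)
  expect_equal(est$genome_size, 11700637064 / 42)
  expect_equal(round(est$genome_size / 1e6, 2), 278.59)
})

test_that("simulated histograms recover genome size, peak and repeat fraction", {
  sim <- simulate_kmer_histogram(genome_size = 1e6, coverage = 50,
                                 repeat_fraction = 0.2, repeat_copy = 2,
                                 error_rate = 0.01, seed = 17)
  est <- estimate_genome_size(sim$histogram, repeat_multiplier = 1.5)
  expect_lt(abs(est$genome_size - 1e6) / 1e6, 0.05)
  expect_lte(abs(est$peak_depth - 50), 1)
  # cutoff midway between the single-copy and two-copy bumps separates them
  expect_lt(abs(est$repeat_fraction - 0.2), 0.05)

  # sampled k-mer mass is conserved: ~ coverage x genome size (no errors)
  clean <- simulate_kmer_histogram(genome_size = 1e6, coverage = 50,
                                   repeat_fraction = 0, error_rate = 0, seed = 19)
  mass <- sum(clean$histogram$depth * clean$histogram$count)
  expect_lt(abs(mass - 50 * 1e6) / (50 * 1e6), 0.02)
})
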