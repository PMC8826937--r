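# small raw dataset: 4 genes x (7 fractions x 2 replicates)
make_fc <- function(counts, reps = 2) {
  meta <- expand.grid(fraction = LETTERS[1:7], replicate = seq_len(reps),
                      stringsAsFactors = FALSE)
  meta$library_id <- paste0(meta$fraction, meta$replicate)
  meta$ribodepleted_ng <- 10
  meta$total_rna_ug <- 5
  fraction_counts(counts, meta)
}

test_that("low-count exclusion requires every replicate below threshold", {
  counts <- matrix(1, 3, 14, dimnames = list(c("g9", "g10", "gBig"), NULL))
  counts["g9", ] <- c(rep(9 / 7, 7), rep(9 / 7, 7))      # 9 reads per replicate
  counts["g10", ] <- c(rep(10 / 7, 7), rep(0, 7))        # 10 in one replicate
  counts["gBig", ] <- 100
  fc <- make_fc(counts)
  flt <- filter_low_counts(fc, threshold = 10)
  expect_identical(sort(flt$retained), c("g10", "gBig"))
  expect_identical(flt$excluded$gene, "g9")
  # threshold 0 retains everything
  expect_length(filter_low_counts(fc, threshold = 0)$retained, 3)
  expect_error(filter_low_counts(fc, threshold = -1), ">= 0")
})

test_that("median-of-ratios size factors match hand values and the literal oracle", {
  # two libraries, counts [[2,4],[8,16]]: factors 1/sqrt(2) and sqrt(2)
  m <- cbind(c(2, 8), c(4, 16))
  expect_equal(unname(size_factors_median_of_ratios(m)),
               c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(size_factors_median_of_ratios(cbind(c(5, 7), c(5, 7)))),
               c(1, 1))
  set.seed(20)
  for (i in 1:10) {
    m <- matrix(rpois(120, 30) + rbinom(120, 1, 0.9), 20, 6)
    expect_equal(unname(size_factors_median_of_ratios(m)),
                 unname(sf_oracle(m)), tolerance = 1e-12)
  }
  expect_error(size_factors_median_of_ratios(cbind(c(0, 3), c(2, 0))),
               "size factors undefined")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  # odd gene count: the median is a single order statistic, so the
  # ratio-space median here coincides with DESeq2's log-space median
  set.seed(4)
  m <- matrix(rnbinom(21 * 6, mu = 60, size = 3) + 1, 21, 6)
  expect_equal(unname(size_factors_median_of_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("scaling one library's counts multiplies its factor and leaves others' normalized counts stable", {
  set.seed(21)
  m <- matrix(rpois(120, 40) + 1, 20, 6)
  s0 <- sf_oracle(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  s1 <- sf_oracle(m2)
  # geometric means absorb 4^(1/6); the scaled library's factor rises by the rest
  expect_equal(s1[3] / s0[3], 4 / 4^(1 / 6), tolerance = 1e-12)
  expect_equal(s1[-3] / s0[-3], rep(4^(-1 / 6), 5), tolerance = 1e-12)
  norm0 <- sweep(m, 2, size_factors_median_of_ratios(m), "/")
  norm1 <- sweep(m2, 2, size_factors_median_of_ratios(m2), "/")
  expect_equal(sweep(norm1, 2, norm1[1, ] / norm0[1, ], "/"), norm0,
               tolerance = 1e-12)
})

test_that("the yield rescalings follow the aliquot formulas and commute", {
  expect_equal(ribodepletion_scale(100, 10), 100)   # 10 ng aliquot: unchanged
  expect_equal(ribodepletion_scale(100, 25), 250)
  expect_equal(total_rna_scale(40, 5), 40)          # 5 ug aliquot: unchanged
  expect_equal(total_rna_scale(40, 7.5), 60)
  # linearity and commutativity of the scalar chain
  expect_equal(ribodepletion_scale(3, 12) + ribodepletion_scale(4, 12),
               ribodepletion_scale(7, 12))
  expect_equal(total_rna_scale(ribodepletion_scale(11, 8), 9),
               ribodepletion_scale(total_rna_scale(11, 9), 8))
  expect_error(ribodepletion_scale(10, 0), "> 0")
  expect_error(total_rna_scale(10, -2), "> 0")
})

test_that("proportions are percentages summing to 100 per gene and replicate", {
  counts <- matrix(0, 3, 7, dimnames = list(c("eq", "inA", "steps"), NULL))
  counts["eq", ] <- 70
  counts["inA", ] <- c(100, 0, 0, 0, 0, 0, 0)
  counts["steps", ] <- c(1, 2, 3, 4, 0, 0, 0)
  fc <- make_fc(cbind(counts, counts))  # 2 identical replicates
  fc$norm <- fc$counts
  pp <- compute_proportions(fc)
  expect_equal(unname(pp$mean["eq", ]), rep(100 / 7, 7))
  expect_equal(unname(pp$mean["inA", ]), c(100, 0, 0, 0, 0, 0, 0))
  expect_equal(unname(pp$mean["steps", ]), c(10, 20, 30, 40, 0, 0, 0))
  sums <- apply(pp$proportions, c(1, 3), sum)
  expect_equal(unname(sums), matrix(100, 3, 2), tolerance = 1e-9)
})

test_that("zero-total replicates are dropped and empty genes excluded with a report", {
  counts <- cbind(matrix(c(10, 10), 2, 7), matrix(c(10, 0), 2, 7))
  rownames(counts) <- c("ok", "half")
  fc <- make_fc(counts)
  fc$norm <- fc$counts
  expect_warning(pp <- compute_proportions(fc), "zero total")
  expect_true(all(is.na(pp$proportions["half", , 2])))
  expect_false(anyNA(pp$proportions["half", , 1]))
  counts2 <- counts
  counts2["half", ] <- 0
  fc2 <- make_fc(counts2)
  fc2$norm <- fc2$counts
  expect_warning(pp2 <- compute_proportions(fc2), "excluded")
  expect_identical(pp2$excluded, "half")
  expect_identical(rownames(pp2$proportions), "ok")
})

test_that("proportions are invariant to coherent library distortions", {
  set.seed(12)
  profs <- t(sapply(1:15, function(i)
    simulate_fraction_profile(runif(1, 30, 95), sample(LETTERS[2:7], 1), 1)))
  sim <- simulate_counts(profs, depth = 2e4, noise_conc = Inf, n_reps = 2,
                         seed = 13, sampling = "expected")
  base <- compute_proportions(normalize_counts(sim$counts))
  # scaling one library's raw counts: absorbed entirely by the size factors
  fc_scaled <- sim$counts
  fc_scaled$counts[, 5] <- fc_scaled$counts[, 5] * 7
  scaled <- compute_proportions(normalize_counts(fc_scaled))
  expect_equal(scaled$proportions, base$proportions, tolerance = 1e-9)
  # moving quantity between the two metadata columns coherently
  fc_meta <- sim$counts
  fc_meta$meta$ribodepleted_ng[5] <- fc_meta$meta$ribodepleted_ng[5] * 3
  fc_meta$meta$total_rna_ug[5] <- fc_meta$meta$total_rna_ug[5] / 3
  shifted <- compute_proportions(normalize_counts(fc_meta))
  expect_equal(shifted$proportions, base$proportions, tolerance = 1e-9)
})

test_that("the full chain recovers true proportions exactly on noiseless data", {
  set.seed(14)
  profs <- t(sapply(1:25, function(i)
    simulate_fraction_profile(runif(1, 30, 95), sample(LETTERS[2:7], 1), 1)))
  rownames(profs) <- sprintf("g%02d", 1:25)
  dist <- exp(stats::runif(21, -0.7, 0.7))
  sim <- simulate_counts(profs, depth = 5e4, noise_conc = Inf, n_reps = 3,
                         seed = 15, sampling = "expected",
                         lib_distortion = dist)
  pp <- compute_proportions(normalize_counts(sim$counts))
  expect_lt(max(abs(sweep(pp$proportions, c(1, 2), profs))), 1e-8)
})

test_that("count tables round-trip through the HTSeq and matrix readers", {
  dir <- withr::local_tempdir()
  counts <- matrix(rpois(5 * 14, 40), 5,
                   dimnames = list(paste0("g", 1:5), NULL))
  meta <- expand.grid(fraction = LETTERS[1:7], replicate = 1:2,
                      stringsAsFactors = FALSE)
  meta$library_id <- paste0(meta$fraction, meta$replicate)
  meta$ribodepleted_ng <- 12
  meta$total_rna_ug <- 6
  files <- file.path(dir, paste0(meta$library_id, ".tsv"))
  for (l in seq_along(files))
    write.table(cbind(c(paste0("g", 1:5), "__no_feature"),
                      c(counts[, l], 99)),
                files[l], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  fc <- read_htseq_counts(setNames(files, meta$library_id), meta)
  expect_equal(unname(fc$counts), unname(counts))
  expect_identical(rownames(fc$counts), paste0("g", 1:5))

  mfile <- file.path(dir, "matrix.tsv")
  write.table(data.frame(gene = rownames(counts),
                         setNames(as.data.frame(counts), meta$library_id),
                         check.names = FALSE),
              mfile, sep = "\t", quote = FALSE, row.names = FALSE)
  fc2 <- read_count_matrix(mfile, meta)
  expect_equal(fc2$counts, fc$counts)
})
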