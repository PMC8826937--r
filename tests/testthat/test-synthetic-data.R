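test_that("fraction profiles put 100 - RO in fraction A and a unimodal kernel over B..G", {
  # zero occupancy: everything free
  expect_equal(unname(simulate_fraction_profile(0, "D", 1)),
               c(100, 0, 0, 0, 0, 0, 0))
  # degenerate kernel: all translated mass in the peak
  expect_equal(unname(simulate_fraction_profile(100, "B", 0)),
               c(0, 100, 0, 0, 0, 0, 0))
  # spread = 1 is the plain binomial kernel with mode at the peak
  p <- simulate_fraction_profile(80, "E", 1)
  expect_equal(unname(p),
               c(20, 80 * dbinom(0:5, 5, 3.5 / 6)))
  expect_equal(sum(p), 100)
  # peak label respected for every peak and sub-unit spread
  for (pk in LETTERS[2:7]) {
    for (sp in c(0.3, 0.7, 1)) {
      prof <- simulate_fraction_profile(70, pk, sp)
      expect_equal(sum(prof), 100, tolerance = 1e-12)
      expect_identical(names(which.max(prof[2:7])), pk)
    }
  }
  expect_error(simulate_fraction_profile(50, "A", 1), "translated")
  expect_error(simulate_fraction_profile(50, "C", -1), "spread")
  expect_error(simulate_fraction_profile(120, "C", 1), "ro_true")
})

test_that("simulated counts are seeded-deterministic and converge to the true proportions", {
  profs <- rbind(simulate_fraction_profile(80, "D", 1),
                 simulate_fraction_profile(60, "F", 0.5),
                 simulate_fraction_profile(95, "B", 1))
  rownames(profs) <- c("gA", "gB", "gC")
  s1 <- simulate_counts(profs, depth = 2e4, n_reps = 2, seed = 42)
  s2 <- simulate_counts(profs, depth = 2e4, n_reps = 2, seed = 42)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$counts$meta, s2$counts$meta)

  # noiseless limit: empirical library compositions match the true profiles
  s3 <- simulate_counts(profs, depth = 1e6, noise_conc = Inf, n_reps = 1,
                        seed = 7, gene_abundance = rep(1, 3))
  recovered <- compute_proportions(normalize_counts(s3$counts))
  expect_lt(max(abs(sweep(recovered$proportions, c(1, 2), profs))), 0.5)

  expect_error(simulate_counts(profs, depth = 1e3, n_reps = 2, seed = 1,
                               lib_distortion = rep(-1, 14)), "> 0")
})

test_that("sampled proportion error at working depth is bounded by a high-depth oracle", {
  set.seed(31)
  profs <- t(sapply(1:100, function(i)
    simulate_fraction_profile(runif(1, 40, 95), sample(LETTERS[2:7], 1), 1)))
  err_at <- function(depth, seed) {
    s <- simulate_counts(profs, depth = depth, noise_conc = Inf, n_reps = 3,
                         seed = seed, gene_abundance = rep(1, 100))
    p <- compute_proportions(normalize_counts(s$counts))
    mean(abs(sweep(p$proportions, c(1, 2), profs)))
  }
  e_work <- err_at(5e4, 1)
  e_high <- err_at(5e6, 2)  # 100x depth: sampling error ~10x smaller
  expect_lt(e_high, e_work)
  expect_lt(e_work, 10 * 1.5 * e_high)  # sqrt(100) scaling with slack
})

test_that("covariate studies have the declared linear structure", {
  # noiseless single-coefficient study: OLS recovers it exactly, R^2 = 1
  s0 <- simulate_covariate_study(300, c(mrna_conc = 0.3), sigma = 0, seed = 5)
  fit <- suppressWarnings(
    fit_translation_model(s0$metrics, s0$covariates, "RO", select = "none"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  est <- fit$coefficients
  expect_equal(est$estimate[est$predictor == "mrna_conc"], 10 * 0.3,
               tolerance = 1e-6)
  # all betas zero: response variance is the residual variance (10 sigma)^2
  v <- vapply(1:10, function(i) {
    s <- simulate_covariate_study(500, c(mrna_conc = 0), sigma = 0.5,
                                  seed = 100 + i)
    stats::var(s$truth$ro_true)
  }, numeric(1))
  expect_equal(mean(v), (10 * 0.5)^2, tolerance = 0.1)
  # positive mRNA effect gives a positive Spearman correlation at large n
  s1 <- simulate_covariate_study(2000, c(mrna_conc = 0.4), sigma = 0.5,
                                 seed = 9)
  rho <- cor(log(s1$covariates$mrna_conc), s1$truth$ro_true,
             method = "spearman")
  expect_gt(rho, 0.3)
  expect_error(simulate_covariate_study(5, c(mrna_conc = 0.3), 1, seed = 1),
               "design columns")
  expect_error(simulate_covariate_study(100, c(not_a_cov = 1), 1, seed = 1),
               "unknown predictor")
})

test_that("induction pairs shift mass as instructed and reject invalid rules", {
  base <- c(A = 66, B = 10, C = 6, D = 6, E = 6, F = 3, G = 3)
  # identity shift: same profiles in both conditions
  s_id <- simulate_induction_pair(base, mrna_fold = 10, shift = identity,
                                  seed = 3, sampling = "expected",
                                  noise_conc = Inf)
  expect_equal(s_id$truth$profiles_low, s_id$truth$profiles_high)
  # halving A into E..G: hand-computed target profile
  s <- simulate_induction_pair(base, mrna_fold = 10,
                               shift = shift_from_a(0.5, c("E", "F", "G")),
                               seed = 3, sampling = "expected",
                               noise_conc = Inf)
  expect_equal(unname(s$truth$profiles_high[1, ]),
               c(33, 10, 6, 6, 17, 14, 14))
  # moving all of A into G empties fraction A entirely: RO hits 100
  # (fraction A carries no reads, so the raw compositions already show it)
  s2 <- simulate_induction_pair(base, mrna_fold = 5,
                                shift = shift_from_a(1, "G"), seed = 4,
                                sampling = "expected", noise_conc = Inf)
  props_high <- compute_proportions(s2$high$counts, use = "counts")
  expect_equal(unname(ribosome_occupancy(props_high)$ro_mean), 100)
  # a rule creating negative proportions is rejected
  bad_shift <- function(p) { p["A"] <- p["A"] - 200; p["G"] <- p["G"] + 200; p }
  expect_error(simulate_induction_pair(base, 2, bad_shift, seed = 1),
               "negative")
  expect_error(simulate_induction_pair(base, 1, identity, seed = 1),
               "mrna_fold")
})

test_that("qPCR simulation encodes abundances in Ct values", {
  # abundance 1 -> target Ct equals the spike Ct; abundance 2 -> one cycle less
  ct <- simulate_qpcr(c(x = 1, y = 2), spike_ct = 20, noise_sd = 0, seed = 1)
  expect_equal(ct$ct_target[ct$gene == "x"], 20)
  expect_equal(ct$ct_target[ct$gene == "y"], 19)
  # determinism
  a <- simulate_qpcr(c(x = 3), noise_sd = 0.4, seed = 8, n_primer_pairs = 5)
  b <- simulate_qpcr(c(x = 3), noise_sd = 0.4, seed = 8, n_primer_pairs = 5)
  expect_identical(a, b)
  expect_error(simulate_qpcr(c(x = -1), seed = 1), "> 0")
  expect_error(simulate_qpcr(c(x = 1), efficiency = 0.9, seed = 1),
               "efficiency")
})
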