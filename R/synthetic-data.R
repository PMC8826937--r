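#' Simulate a per-gene gradient fraction profile
#'
#' Builds the true percentage profile of one gene over the fractions
#' A..G. Fraction A receives `100 - ro_true` (the untranslated mRNA);
#' the translated mass `ro_true` is spread over B..G with a discretized
#' unimodal binomial kernel: bin weights are
#' `dbinom(j, 5, (m + 0.5)/6)^(1/spread^2)` (m the 0-based peak index),
#' renormalized. `spread = 1` gives the plain binomial with mode at the
#' peak; `spread -> 0` concentrates all translated mass in the peak
#' fraction; larger values flatten the profile.
#'
#' @param ro_true true ribosome occupancy, percent in [0, 100].
#' @param peak peak fraction label in B..G (never A).
#' @param spread non-negative kernel width; see Details above.
#' @param n_fractions number of fractions (default 7: A plus 6 translated).
#' @return Numeric proportion vector over the fractions, summing to 100.
#' @examples
#' simulate_fraction_profile(80, "E", 1)
#' @export
simulate_fraction_profile <- function(ro_true, peak, spread = 1,
                                      n_fractions = 7) {
  if (ro_true < 0 || ro_true > 100) stop("'ro_true' must be in [0, 100]")
  trans_labels <- LETTERS[2:n_fractions]
  if (!peak %in% trans_labels)
    stop("'peak' must be a translated fraction (",
         paste(range(trans_labels), collapse = ".."),
         "); fraction A holds untranslated mRNA")
  if (spread < 0) stop("'spread' must be >= 0")
  bins <- n_fractions - 1L
  m <- match(peak, trans_labels) - 1L
  if (spread == 0) {
    w <- as.numeric(seq_len(bins) == m + 1L)
  } else {
    lw <- stats::dbinom(0:(bins - 1L), bins - 1L, (m + 0.5) / bins,
                        log = TRUE) / spread^2
    w <- exp(lw - max(lw))
    w <- w / sum(w)
  }
  stats::setNames(c(100 - ro_true, ro_true * w), LETTERS[1:n_fractions])
}

#' Simulate gradient read-count libraries from true fraction profiles
#'
#' Emulates the sampling chain of a polysome-profiling RNA-seq experiment.
#' Per replicate, each gene's true profile is perturbed by a Dirichlet
#' draw (concentration `noise_conc * profile/100`; `Inf` disables the
#' noise). Each library (fraction, replicate) is then sequenced by a
#' multinomial draw over genes with probabilities proportional to gene
#' abundance times the gene's perturbed proportion in that fraction, at a
#' depth of `depth` reads scaled by the library's distortion factor.
#'
#' The per-library metadata (ribodepleted yield in ng, total extracted RNA
#' in ug) is emitted consistently with the simulated mRNA masses and the
#' library compositions, so that the three-stage normalization chain
#' recovers the perturbed true proportions (exactly with
#' `sampling = "expected"`, in expectation under multinomial sampling).
#' Library depth distortions are left for the size factors to absorb.
#'
#' @param true_profiles genes x 7 matrix of true percentage profiles (rows
#'   summing to 100), or a single profile vector.
#' @param depth target reads per library before distortion.
#' @param noise_conc Dirichlet concentration of the replicate noise
#'   (default 200; `Inf` = noiseless).
#' @param lib_distortion per-library depth distortion factors (> 0):
#'   vector of length 7 x n_reps (fraction-major), a 7 x n_reps matrix, or
#'   NULL for none.
#' @param n_reps number of biological replicates (default 3).
#' @param seed integer seed; required for reproducibility.
#' @param gene_abundance positive per-gene total mRNA abundances
#'   (arbitrary units); default log-normal(0, 1).
#' @param sampling `"multinomial"` (default) or `"expected"` (no read
#'   sampling: libraries carry exact expected counts).
#' @param phase phase label for the dataset.
#' @return List of class `sim_gradient`: `counts` (a [fraction_counts()]
#'   object) and `truth` (list with `profiles`, `noised` [genes x 7 x reps
#'   array of the Dirichlet-perturbed profiles the chain can recover],
#'   `abundance`, `depths`).
#' @export
simulate_counts <- function(true_profiles, depth = 5e4, noise_conc = 200,
                            lib_distortion = NULL, n_reps = 3, seed = NULL,
                            gene_abundance = NULL,
                            sampling = c("multinomial", "expected"),
                            phase = "custom") {
  sampling <- match.arg(sampling)
  if (is.null(dim(true_profiles)))
    true_profiles <- matrix(true_profiles, nrow = 1,
                            dimnames = list("gene1", names(true_profiles)))
  true_profiles <- as.matrix(true_profiles)
  stopifnot(ncol(true_profiles) == length(FRACTIONS))
  if (max(abs(rowSums(true_profiles) - 100)) > 1e-6)
    stop("each true profile must sum to 100")
  if (depth < 1) stop("'depth' must be >= 1")
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_genes <- nrow(true_profiles)
  if (is.null(rownames(true_profiles)))
    rownames(true_profiles) <- sprintf("gene%03d", seq_len(n_genes))
  colnames(true_profiles) <- FRACTIONS
  n_lib <- length(FRACTIONS) * n_reps
  if (is.null(lib_distortion)) lib_distortion <- rep(1, n_lib)
  lib_distortion <- as.numeric(lib_distortion)
  if (length(lib_distortion) != n_lib)
    stop("'lib_distortion' must supply one factor per library (", n_lib, ")")
  if (any(lib_distortion <= 0)) stop("distortion factors must be > 0")
  if (is.null(gene_abundance))
    gene_abundance <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  if (any(gene_abundance <= 0)) stop("gene abundances must be > 0")

  # replicate-level Dirichlet perturbation of the profiles
  noised <- array(NA_real_, c(n_genes, length(FRACTIONS), n_reps),
                  dimnames = list(rownames(true_profiles), FRACTIONS,
                                  paste0("rep", seq_len(n_reps))))
  for (k in seq_len(n_reps)) {
    if (is.infinite(noise_conc)) {
      noised[, , k] <- true_profiles
    } else {
      g <- matrix(stats::rgamma(n_genes * length(FRACTIONS),
                                shape = noise_conc * true_profiles / 100),
                  n_genes, length(FRACTIONS))
      noised[, , k] <- g / rowSums(g) * 100
    }
  }

  meta <- expand.grid(fraction = FRACTIONS, replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$library_id <- paste0(meta$fraction, meta$replicate)

  # per-library gene mRNA masses and read-sampling compositions
  mass <- matrix(NA_real_, n_genes, n_lib)
  for (l in seq_len(n_lib))
    mass[, l] <- gene_abundance *
      noised[, meta$fraction[l], meta$replicate[l]] / 100
  m_lib <- colSums(mass)                 # total mRNA mass per library
  q <- sweep(mass, 2, m_lib, "/")        # library read composition
  q[, m_lib == 0] <- 0                   # fraction without any mRNA

  depths <- round(depth * lib_distortion)
  counts <- matrix(0, n_genes, n_lib,
                   dimnames = list(rownames(true_profiles), meta$library_id))
  for (l in seq_len(n_lib))
    counts[, l] <- if (sampling == "multinomial")
      stats::rmultinom(1, depths[l], q[, l]) else depths[l] * q[, l]

  # metadata consistent with the normalization model: the ribodepletion
  # yield tracks each library's total mRNA mass per unit of total RNA,
  # times the library-construction efficiency that the median-of-ratios
  # size factors estimate on these counts (their composition term), so
  # that size factors + metadata jointly restore per-fraction mRNA masses
  filled <- m_lib > 0
  sigma <- rep(NA_real_, n_lib)
  sigma[filled] <- size_factors_median_of_ratios(
    counts[, filled, drop = FALSE]) / depths[filled]
  total_base <- c(A = 60, B = 45, C = 40, D = 35, E = 30, F = 25, G = 20)
  meta$total_rna_ug <- unname(total_base[meta$fraction])
  ribo_raw <- ifelse(filled, m_lib * sigma / meta$total_rna_ug, NA)
  meta$ribodepleted_ng <- 50 * ribo_raw / mean(ribo_raw, na.rm = TRUE)
  # an mRNA-free fraction still yields a trace ribodepletion amount
  meta$ribodepleted_ng[!filled] <- 1e-9
  meta$phase <- phase

  fc <- fraction_counts(counts, meta[c("library_id", "fraction", "replicate",
                                       "ribodepleted_ng", "total_rna_ug",
                                       "phase")])
  structure(list(counts = fc,
                 truth = list(profiles = true_profiles, noised = noised,
                              abundance = gene_abundance, depths = depths)),
            class = "sim_gradient")
}

#' @export
print.sim_gradient <- function(x, ...) {
  cat("sim_gradient: ", nrow(x$counts$counts), " genes, ",
      ncol(x$counts$counts), " libraries; truth attached\n", sep = "")
  invisible(x)
}

#' Simulate a full gradient study with known RO/RD ground truth
#'
#' Convenience generator for end-to-end validation: draws per-gene true
#' occupancies (normal, mean 90, sd 7, clipped to [15, 100], emulating the
#' high occupancies typical of exponentially growing bacteria), peak
#' fractions uniform over B..G, ORF lengths log-normal around 900 nt, and
#' runs [simulate_fraction_profile()] + [simulate_counts()].
#'
#' @param n_genes number of genes (default 300).
#' @param spread kernel width of the fraction profiles (default 1).
#' @param map [build_ribosome_map()] used for the true RD.
#' @inheritParams simulate_counts
#' @return List of class `sim_gradient` with the elements of
#'   [simulate_counts()] plus `truth$table`: data.frame gene, ro_true,
#'   peak_true, rd_true, orf_length.
#' @export
simulate_gradient_study <- function(n_genes = 300, depth = 5e4,
                                    noise_conc = 200, n_reps = 3,
                                    spread = 1, seed = NULL,
                                    lib_distortion = NULL,
                                    map = build_ribosome_map(),
                                    sampling = "multinomial",
                                    phase = "custom") {
  if (!is.null(seed)) set.seed(seed)
  ro_true <- pmin(100, pmax(15, stats::rnorm(n_genes, 90, 7)))
  peak_true <- sample(TRANSLATED_FRACTIONS, n_genes, replace = TRUE)
  orf_length <- pmax(150, round(stats::rlnorm(n_genes, log(900), 0.45)))
  profiles <- t(mapply(simulate_fraction_profile, ro_true, peak_true,
                       MoreArgs = list(spread = spread)))
  rownames(profiles) <- sprintf("gene%03d", seq_len(n_genes))
  sim <- simulate_counts(profiles, depth = depth, noise_conc = noise_conc,
                         lib_distortion = lib_distortion, n_reps = n_reps,
                         sampling = sampling, phase = phase)
  sim$truth$table <- data.frame(
    gene = rownames(profiles), ro_true = ro_true, peak_true = peak_true,
    rd_true = unclass(map)[peak_true] / orf_length * 100,
    orf_length = orf_length, row.names = NULL)
  sim
}

#' Simulate a gene covariate study with linear ground truth
#'
#' Draws the 17 gene covariates from realistic marginal distributions
#' (log-normal mRNA concentrations and ORF lengths, uniform GC contents,
#' normal GRAVY and TIR folding energies, multinomial categorical
#' covariates), builds the standardized design exactly as
#' [transform_covariates()] would, and generates responses with known
#' standardized coefficients:
#' `RO = clip(60 + 10 (X beta + eps), 15, 100)` and
#' `log10 RD = log10(0.45) + 0.3 (X beta + eps)` with
#' `eps ~ Normal(0, sigma)`. For a qualitative predictor the coefficient
#' applies to its first deviation-coded contrast column.
#'
#' @param n_genes number of genes.
#' @param beta_true named numeric vector of standardized coefficients;
#'   names must be covariate names (see [quantitative_covariates()],
#'   [qualitative_covariates()]).
#' @param sigma residual standard deviation of the linear predictor.
#' @param seed integer seed.
#' @return List: `covariates` (data.frame with `gene` column),
#'   `truth` (list with `beta_true`, `ro_true`, `rd_true`, `eta`,
#'   `sigma`), and `metrics` (data.frame gene, ro_mean, rd — the true
#'   values formatted as a metrics table for direct regression).
#' @export
simulate_covariate_study <- function(n_genes, beta_true = NULL, sigma = 1,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta_true))
    beta_true <- c(mrna_conc = 0.3, orf_gc = -0.2, cai = 0.2)
  all_cov <- c(quantitative_covariates(), qualitative_covariates())
  if (!all(names(beta_true) %in% all_cov))
    stop("unknown predictor(s) in beta_true: ",
         paste(setdiff(names(beta_true), all_cov), collapse = ", "))
  cov <- data.frame(
    gene = sprintf("gene%04d", seq_len(n_genes)),
    mrna_conc = stats::rlnorm(n_genes, 1, 1),
    orf_length = pmax(50, round(stats::rlnorm(n_genes, log(900), 0.45))),
    orf_gc = stats::runif(n_genes, 35, 65),
    cai = stats::runif(n_genes, 0.15, 0.85),
    chrom_location = stats::runif(n_genes, 0, 2.3e6),
    hydrophobicity = stats::rnorm(n_genes, -0.2, 0.35),
    utr5_gc = stats::runif(n_genes, 20, 60),
    utr5_length = round(stats::runif(n_genes, 10, 300)),
    dg_tir = stats::rnorm(n_genes, -7, 3),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    essentiality = stats::rbinom(n_genes, 1, 0.1) == 1,
    signal_peptide = stats::rbinom(n_genes, 1, 0.1) == 1,
    inner_membrane = stats::rbinom(n_genes, 1, 0.2) == 1,
    cell_location = sample(c("cytoplasm", "inner_membrane", "periplasm",
                             "envelope"), n_genes, replace = TRUE,
                           prob = c(0.55, 0.25, 0.1, 0.1)),
    cog = sample(c("metabolism", "information", "cellular", "poorly_char"),
                 n_genes, replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15)),
    csra_target = stats::rbinom(n_genes, 1, 0.15) == 1,
    second_utr_nt = sample(c("purine", "pyrimidine"), n_genes,
                           replace = TRUE, prob = c(0.6, 0.4))
  )
  # full design: intercept + 9 quantitative + 13 deviation-coded columns
  if (n_genes < 23)
    stop("n_genes (", n_genes, ") below the number of design columns (23)")
  design <- transform_covariates(cov)
  mm <- stats::model.matrix(
    ~ ., data = design,
    contrasts.arg = lapply(Filter(is.factor, design), function(f) "contr.sum"))
  # map each named beta to its design column (first contrast for factors)
  eta <- rep(0, n_genes)
  for (v in names(beta_true)) {
    col <- if (v %in% quantitative_covariates()) v else paste0(v, "1")
    if (!col %in% colnames(mm))
      stop("design column not found for predictor '", v, "'")
    eta <- eta + beta_true[[v]] * mm[, col]
  }
  eps_ro <- stats::rnorm(n_genes, 0, sigma)
  eps_rd <- stats::rnorm(n_genes, 0, sigma)
  ro_true <- pmin(100, pmax(15, 60 + 10 * (eta + eps_ro)))
  rd_true <- 10^(log10(0.45) + 0.3 * (eta + eps_rd))
  list(covariates = cov,
       truth = list(beta_true = beta_true, ro_true = ro_true,
                    rd_true = rd_true, eta = eta, sigma = sigma),
       metrics = data.frame(gene = cov$gene, ro_mean = ro_true,
                            rd = rd_true))
}

#' Shift rule moving untranslated mRNA into heavy fractions
#'
#' Returns a function on percentage profiles that moves `move_frac` of
#' fraction A's proportion equally into the target fractions, emulating
#' the profile change seen when transcription induction raises the mRNA
#' concentration and the ribosome load.
#'
#' @param move_frac fraction of A's mass to move, in [0, 1].
#' @param to target fraction labels (default E, F, G).
#' @return Function: proportion vector over A..G -> shifted vector.
#' @export
shift_from_a <- function(move_frac = 0.5, to = c("E", "F", "G")) {
  stopifnot(move_frac >= 0, move_frac <= 1,
            all(to %in% TRANSLATED_FRACTIONS))
  function(profile) {
    moved <- profile["A"] * move_frac
    profile["A"] <- profile["A"] - moved
    profile[to] <- profile[to] + moved / length(to)
    profile
  }
}

#' Simulate a paired low/high mRNA-concentration experiment
#'
#' Generates two count datasets for the same genes: the low condition uses
#' the base profiles; in the high condition total mRNA abundance is
#' multiplied by `mrna_fold` and each profile is transformed by the shift
#' rule (typically moving mass out of fraction A into heavy fractions; see
#' [shift_from_a()]).
#'
#' @param base_profile percentage profile vector over A..G, or a genes x 7
#'   matrix.
#' @param mrna_fold fold increase in mRNA abundance upon induction (> 1).
#' @param shift function mapping a profile vector to the induced profile;
#'   must preserve non-negativity and the sum of 100. `identity` is
#'   allowed.
#' @inheritParams simulate_counts
#' @return List of class `sim_induction`: `low` and `high`
#'   (`sim_gradient` objects) and `truth` (list with `profiles_low`,
#'   `profiles_high`, `mrna_fold`).
#' @export
simulate_induction_pair <- function(base_profile, mrna_fold = 20,
                                    shift = shift_from_a(), seed = NULL,
                                    depth = 5e4, noise_conc = 200,
                                    n_reps = 3, sampling = "multinomial") {
  if (mrna_fold <= 1) stop("'mrna_fold' must be > 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(base_profile)))
    base_profile <- matrix(base_profile, nrow = 1,
                           dimnames = list("gene1", names(base_profile)))
  base_profile <- as.matrix(base_profile)
  colnames(base_profile) <- FRACTIONS
  high_profile <- t(apply(base_profile, 1, function(p) {
    out <- shift(stats::setNames(p, FRACTIONS))
    if (any(out < 0))
      stop("shift rule produced negative proportions")
    if (abs(sum(out) - 100) > 1e-6)
      stop("shift rule must preserve the total of 100")
    out
  }))
  abundance <- stats::rlnorm(nrow(base_profile), 0, 0.5)
  low <- simulate_counts(base_profile, depth = depth,
                         noise_conc = noise_conc, n_reps = n_reps,
                         gene_abundance = abundance, sampling = sampling)
  high <- simulate_counts(high_profile, depth = depth,
                          noise_conc = noise_conc, n_reps = n_reps,
                          gene_abundance = abundance * mrna_fold,
                          sampling = sampling)
  structure(list(low = low, high = high,
                 truth = list(profiles_low = base_profile,
                              profiles_high = high_profile,
                              mrna_fold = mrna_fold)),
            class = "sim_induction")
}

#' Simulate qPCR Ct values against a constant spike-in
#'
#' Each target's Ct is the spike-in Ct minus the log (base `efficiency`)
#' of its relative abundance, plus normal measurement noise:
#' `Ct_target = spike_ct - log_eff(abundance) + Normal(0, noise_sd)`.
#'
#' @param rel_abundances named positive vector of relative abundances (one
#'   per gene), each measured with `n_primer_pairs` primer pairs.
#' @param spike_ct Ct of the ERCC spike-in (cycles).
#' @param efficiency amplification efficiency, fold per cycle (> 1).
#' @param noise_sd standard deviation of Ct measurement noise (cycles).
#' @param seed integer seed.
#' @param n_primer_pairs primer pairs per gene.
#' @return data.frame: gene, primer_pair, ct_target, ct_spike.
#' @export
simulate_qpcr <- function(rel_abundances, spike_ct = 20, efficiency = 2,
                          noise_sd = 0, seed = NULL, n_primer_pairs = 1) {
  if (efficiency <= 1) stop("'efficiency' must be > 1")
  if (any(rel_abundances <= 0)) stop("abundances must be > 0")
  if (!is.null(seed)) set.seed(seed)
  genes <- names(rel_abundances)
  if (is.null(genes)) genes <- paste0("gene", seq_along(rel_abundances))
  out <- expand.grid(primer_pair = seq_len(n_primer_pairs), gene = genes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ab <- rel_abundances[match(out$gene, genes)]
  out$ct_target <- spike_ct - log(ab, base = efficiency) +
    stats::rnorm(nrow(out), 0, noise_sd)
  out$ct_spike <- spike_ct
  out[c("gene", "primer_pair", "ct_target", "ct_spike")]
}

#' Deterministic example table of 24 gradient subfractions
#'
#' A synthetic Bioanalyzer-style subfraction table: two leading
#' subfractions of free RNA and ribosomal subunits (23S/16S ratio 0.3)
#' followed by six rRNA-abundance peaks at the whole-ribosome ratio of
#' 1.8, each wide enough to survive the window-3 smoothing of
#' [classify_subfractions()], for demonstrating and testing the pooling
#' step.
#'
#' @return data.frame with columns subfraction_id, rrna16s_qty,
#'   rrna23s_qty, total_rna_ug, ribodepleted_ng.
#' @export
synthetic_subfraction_table <- function() {
  # peaks span (shoulder, top, shoulder) with deep valleys in between; the
  # last peak is truncated by the end of the gradient
  h <- c(100, 85, 70, 55, 40, 28)
  shape <- c(unlist(lapply(h[1:5], function(x) c(0.35 * x, x, 0.35 * x, 4))),
             0.35 * h[6], h[6])
  total <- c(90, 40, shape)
  ratio <- c(rep(0.3, 2), rep(1.8, 22))
  rrna16 <- total / (1 + ratio)
  data.frame(subfraction_id = 1:24,
             rrna16s_qty = rrna16,
             rrna23s_qty = total - rrna16,
             total_rna_ug = pmax(total / 10, 0.5),
             ribodepleted_ng = pmax(total / 2, 1))
}
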