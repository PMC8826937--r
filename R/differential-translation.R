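#' Per-fraction log ratios between two conditions
#'
#' Log ratio, per fraction, of the mean mRNA proportion at the high mRNA
#' concentration over the low one. A ratio below 0 means the proportion of
#' mRNA copies in that fraction is lower at the high concentration. A
#' small pseudo-proportion guards fractions with zero proportion.
#'
#' @param mean_high,mean_low mean proportion vectors over A..G (percent,
#'   each summing to 100).
#' @param base logarithm base (default 2).
#' @param pseudo pseudo-proportion in percentage points added to both
#'   numerator and denominator (default 0.1; 0 allowed when all fractions
#'   are positive).
#' @return Named numeric vector of per-fraction log ratios.
#' @export
fraction_log_ratios <- function(mean_high, mean_low, base = 2, pseudo = 0.1) {
  if (any(mean_high < 0) || any(mean_low < 0))
    stop("proportions must be non-negative")
  if (pseudo < 0) stop("'pseudo' must be >= 0")
  if (pseudo == 0 && any(mean_high == 0 | mean_low == 0))
    stop("zero proportions present; use a positive 'pseudo'")
  r <- log((mean_high + pseudo) / (mean_low + pseudo), base = base)
  if (is.null(names(r)) && length(r) == length(FRACTIONS)) names(r) <- FRACTIONS
  r
}

#' Relative ribosome-occupancy change upon induction
#'
#' Percent increase of RO between the low and high mRNA-concentration
#' conditions: `(ro_high - ro_low) / ro_low * 100`.
#'
#' @param ro_low,ro_high RO values in percent; `ro_low` must be > 0.
#' @return Percent increase (negative when RO decreased).
#' @export
ro_change <- function(ro_low, ro_high) {
  if (any(ro_low <= 0)) stop("'ro_low' must be > 0 (relative change undefined)")
  (ro_high - ro_low) / ro_low * 100
}

#' Relative RNA abundance from spike-in normalized qPCR Ct values
#'
#' Fold-change delta-Ct quantification against ERCC spike-ins added at
#' constant quantity: per primer pair the abundance relative to the spike
#' is `efficiency^(ct_spike - ct_target)`; a gene measured with several
#' primer pairs is summarized by the geometric mean across pairs.
#'
#' @param measurements data.frame with columns `ct_target` and `ct_spike`
#'   (cycles), one row per primer pair for one gene.
#' @param efficiency amplification efficiency, fold per cycle (default 2,
#'   perfect doubling); must be > 1.
#' @return Relative abundance (dimensionless, > 0).
#' @examples
#' delta_ct_abundance(data.frame(ct_target = 19, ct_spike = 20))  # 2
#' @export
delta_ct_abundance <- function(measurements, efficiency = 2) {
  if (efficiency <= 1) stop("'efficiency' must be > 1 fold per cycle")
  if (nrow(measurements) < 1) stop("at least one primer pair is required")
  if (anyNA(measurements$ct_spike) || is.null(measurements$ct_spike))
    stop("missing spike-in Ct value")
  per_pair <- efficiency^(measurements$ct_spike - measurements$ct_target)
  exp(mean(log(per_pair)))
}

#' Correct per-fraction qPCR abundances for total RNA extracted
#'
#' Only a fixed aliquot (default 5 ug) of each fraction's total RNA enters
#' the qPCR experiment, so spike-relative abundances are rescaled by the
#' total amount extracted in the fraction over the aliquot. The corrected
#' abundances feed the same proportion/RO computations as sequencing
#' counts.
#'
#' @param rel_abundance spike-relative abundance per fraction.
#' @param total_rna_qty total RNA extracted per fraction, ug.
#' @param aliquot_ug aliquot used in the qPCR experiment, ug.
#' @return Corrected abundances.
#' @export
qpcr_fraction_normalize <- function(rel_abundance, total_rna_qty,
                                    aliquot_ug = 5) {
  if (any(total_rna_qty <= 0)) stop("'total_rna_qty' must be > 0")
  rel_abundance * total_rna_qty / aliquot_ug
}

#' Compare translation profiles between low and high mRNA concentrations
#'
#' For each gene present in both conditions, computes the per-fraction log
#' ratios of mean proportions (high over low), the RO under each condition
#' and the relative RO increase.
#'
#' @param profile_low,profile_high [compute_proportions()] results for the
#'   no-induction and induction datasets.
#' @inheritParams fraction_log_ratios
#' @return data.frame of class `induction_comparison`: gene, `log_ratio_A`
#'   .. `log_ratio_G`, `ro_low`, `ro_high`, `ro_percent_increase`.
#'   Attribute `log_base` records the base used.
#' @export
compare_induction <- function(profile_low, profile_high, base = 2,
                              pseudo = 0.1) {
  stopifnot(inherits(profile_low, "proportion_profile"),
            inherits(profile_high, "proportion_profile"))
  genes <- intersect(rownames(profile_low$mean), rownames(profile_high$mean))
  if (!length(genes)) stop("no genes shared between the two conditions")
  lr <- t(vapply(genes, function(g)
    fraction_log_ratios(profile_high$mean[g, ], profile_low$mean[g, ],
                        base = base, pseudo = pseudo),
    numeric(length(FRACTIONS))))
  colnames(lr) <- paste0("log_ratio_", FRACTIONS)
  ro_low <- 100 - profile_low$mean[genes, "A"]
  ro_high <- 100 - profile_high$mean[genes, "A"]
  out <- data.frame(gene = genes, lr, ro_low = ro_low, ro_high = ro_high,
                    ro_percent_increase = ro_change(ro_low, ro_high),
                    row.names = NULL)
  attr(out, "log_base") <- base
  class(out) <- c("induction_comparison", "data.frame")
  out
}

#' @export
print.induction_comparison <- function(x, ...) {
  cat("induction_comparison: ", nrow(x), " gene(s), log base ",
      attr(x, "log_base"), "\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}
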