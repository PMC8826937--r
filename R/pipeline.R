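#' Run the full polysome-profiling quantification pipeline
#'
#' Chains the analysis stages on raw fraction counts: low-count filtering,
#' the three-stage normalization, per-gene fraction proportions, and the
#' translation metrics (RO, bootstrap peak fraction, RD with outlier
#' exclusion).
#'
#' @param fc a [fraction_counts()] object with raw counts.
#' @param orf_lengths named numeric vector of ORF lengths in nt (optional;
#'   without it no RD is computed).
#' @param threshold low-count exclusion threshold (reads).
#' @param map a [build_ribosome_map()].
#' @param rd_cutoff outlier RD cutoff (strict), default the maximum
#'   theoretical density.
#' @inheritParams bootstrap_peak_fraction
#' @return Object of class `polysome_profile`: list with `counts`
#'   (normalized [fraction_counts()]), `proportions`
#'   ([compute_proportions()] result), `metrics`
#'   ([translation_metrics()] table after RD outlier exclusion),
#'   `excluded` (list: `low_counts`, `no_profile`, `outlier_rd`).
#' @examples
#' sim <- simulate_gradient_study(n_genes = 40, depth = 5000, seed = 7)
#' pp <- polysome_profile(sim$counts,
#'                        orf_lengths = with(sim$truth$table,
#'                                           setNames(orf_length, gene)),
#'                        n_boot = 200, seed = 7)
#' pp
#' @export
polysome_profile <- function(fc, orf_lengths = NULL, threshold = 10,
                             map = build_ribosome_map(), n_boot = 1000,
                             conf = 0.95, rd_cutoff = max_theoretical_density(),
                             seed = NULL) {
  flt <- filter_low_counts(fc, threshold = threshold)
  norm <- normalize_counts(flt$counts)
  props <- compute_proportions(norm)
  metrics <- translation_metrics(props, orf_lengths = orf_lengths, map = map,
                                 n_boot = n_boot, conf = conf, seed = seed)
  rd_flt <- filter_outlier_rd(metrics, cutoff = rd_cutoff)
  structure(list(counts = norm, proportions = props,
                 metrics = rd_flt$retained,
                 excluded = list(low_counts = flt$excluded,
                                 no_profile = props$excluded,
                                 outlier_rd = rd_flt$excluded)),
            class = "polysome_profile")
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat("polysome_profile pipeline result\n")
  print(x$counts)
  m <- x$metrics
  cat(nrow(m), " genes quantified; mean RO ",
      round(mean(m$ro_mean, na.rm = TRUE), 1), "% (sd ",
      round(stats::sd(m$ro_mean, na.rm = TRUE), 1), "); ",
      sum(m$confined), " genes with confined peak; mean RD ",
      signif(mean(m$rd, na.rm = TRUE), 2), " ribosomes/100 nt\n",
      "excluded: ", nrow(x$excluded$low_counts), " low-count, ",
      length(x$excluded$no_profile), " empty-profile, ",
      nrow(x$excluded$outlier_rd), " outlier-RD gene(s)\n", sep = "")
  invisible(x)
}

#' @export
summary.polysome_profile <- function(object, ...) {
  print(object)
  cat("\nRO distribution (percent):\n")
  print(summary(object$metrics$ro_mean))
  cat("\nPeak fractions among confined genes:\n")
  print(table(object$metrics$peak_fraction[object$metrics$confined]))
  invisible(object)
}

#' @export
plot.polysome_profile <- function(x, genes = NULL, ...) {
  mp <- x$proportions$mean
  if (is.null(genes)) genes <- utils::head(rownames(mp), 12)
  graphics::matplot(seq_along(FRACTIONS), t(mp[genes, , drop = FALSE]),
                    type = "b", pch = 16, lty = 1, xaxt = "n",
                    xlab = "fraction", ylab = "mean mRNA proportion (%)", ...)
  graphics::axis(1, at = seq_along(FRACTIONS), labels = FRACTIONS)
  invisible(x)
}
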