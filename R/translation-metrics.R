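#' Ribosome occupancy per gene
#'
#' RO is the percentage of a gene's mRNA copies bound by at least one
#' ribosome: the summed proportions in the translated fractions B..G,
#' i.e. 100 minus the proportion in fraction A. Computed per replicate,
#' then averaged; the sample standard deviation across replicates is
#' reported.
#'
#' @param profile a [compute_proportions()] result (`proportion_profile`).
#' @return data.frame: gene, one `ro_rep*` column per replicate (percent),
#'   `ro_mean`, `ro_sd`.
#' @export
ribosome_occupancy <- function(profile) {
  stopifnot(inherits(profile, "proportion_profile"))
  ro <- 100 - profile$proportions[, "A", , drop = TRUE]
  if (is.null(dim(ro))) ro <- matrix(ro, ncol = dim(profile$proportions)[3])
  out <- data.frame(gene = rownames(profile$proportions), ro,
                    row.names = NULL, check.names = FALSE)
  names(out)[-1] <- paste0("ro_", dimnames(profile$proportions)[[3]])
  out$ro_mean <- rowMeans(ro, na.rm = TRUE)
  out$ro_sd <- apply(ro, 1, stats::sd, na.rm = TRUE)
  out
}

#' Bootstrap-on-residuals peak fraction for one gene
#'
#' The peak fraction is the translated fraction (B..G) with the highest
#' mean mRNA proportion, validated by a residual bootstrap: residuals of
#' each replicate proportion from the fraction mean are pooled across all
#' seven fractions and replicates, and each bootstrap profile adds one
#' randomly drawn residual (with replacement) to the mean proportion of
#' each fraction. The peak is recorded in each of `n_boot` bootstrap
#' profiles; the modal peak's relative frequency measures its stability
#' and the gene is called confined when that frequency reaches `conf`.
#'
#' Bootstrap profiles are used only through their argmax over B..G, so
#' they are neither renormalized to 100 nor clipped at 0; argmax ties are
#' broken toward the lighter fraction.
#'
#' @param profiles replicate x fraction (A..G) matrix of proportions
#'   (percent) for a single gene; at least two replicates.
#' @param n_boot number of bootstrap profiles (default 1000).
#' @param conf confinement threshold on the modal relative frequency
#'   (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return List: `peak_fraction` (label in B..G, or NA when undetermined),
#'   `peak_frequency`, `confined`, `frequencies` (named frequencies over
#'   B..G).
#' @export
bootstrap_peak_fraction <- function(profiles, n_boot = 1000, conf = 0.95,
                                    seed = NULL) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2)
    stop("bootstrap on residuals needs at least 2 replicates")
  if (ncol(profiles) != length(FRACTIONS))
    stop("expected ", length(FRACTIONS), " fraction columns")
  colnames(profiles) <- FRACTIONS
  if (!is.null(seed)) set.seed(seed)
  mean_prof <- colMeans(profiles)
  res <- as.vector(sweep(profiles, 2, mean_prof))
  trans <- mean_prof[TRANSLATED_FRACTIONS]
  if (all(trans == 0) && all(res == 0))
    return(list(peak_fraction = NA_character_, peak_frequency = NA_real_,
                confined = FALSE,
                frequencies = stats::setNames(rep(NA_real_, 6),
                                              TRANSLATED_FRACTIONS)))
  # one residual drawn per fraction A..G; only B..G enter the argmax
  draws <- matrix(sample(res, 7L * n_boot, replace = TRUE), n_boot, 7L)
  boot <- sweep(draws[, 2:7, drop = FALSE], 2, trans, "+")
  # ties.method = "first" breaks argmax ties toward the lighter fraction
  peaks <- max.col(boot, ties.method = "first")
  freq <- tabulate(peaks, nbins = 6L) / n_boot
  names(freq) <- TRANSLATED_FRACTIONS
  modal <- which.max(freq)
  list(peak_fraction = TRANSLATED_FRACTIONS[modal],
       peak_frequency = unname(freq[modal]),
       confined = unname(freq[modal] >= conf),
       frequencies = freq)
}

#' Ribosome density from the peak fraction
#'
#' RD is the number of ribosomes attributed to the gene's peak fraction,
#' per 100 nt of open reading frame.
#'
#' @param peak fraction label in B..G.
#' @param map a [build_ribosome_map()].
#' @param orf_length ORF length in nt (> 0).
#' @return Ribosomes per 100 nt.
#' @examples
#' ribosome_density("E", build_ribosome_map(), 400)  # 4/400*100 = 1
#' @export
ribosome_density <- function(peak, map = build_ribosome_map(), orf_length) {
  if (any(!peak %in% TRANSLATED_FRACTIONS))
    stop("peak fraction must be one of B..G (fraction A is not translated)")
  if (any(orf_length <= 0)) stop("'orf_length' must be > 0")
  if (any(!peak %in% names(map))) stop("ribosome map lacks an entry for the peak")
  unname(unclass(map)[peak] / orf_length * 100)
}

#' Maximum theoretical ribosome density
#'
#' Ribosomes per 100 nt when the ORF is fully packed with ribosomes of the
#' given footprint (about 30 nt for a bacterial ribosome), i.e.
#' `100 / footprint_nt`.
#'
#' @param footprint_nt nucleotides covered by one ribosome (default 30).
#' @return Ribosomes per 100 nt.
#' @export
max_theoretical_density <- function(footprint_nt = 30) {
  if (footprint_nt <= 0) stop("'footprint_nt' must be > 0")
  100 / footprint_nt
}

#' Exclude genes with outlier ribosome densities
#'
#' Genes whose RD strictly exceeds the cutoff (by default the maximum
#' theoretical density for a 30-nt footprint, 3.33 ribosomes/100 nt) are
#' physically implausible and removed.
#'
#' @param metrics data.frame with columns `gene` and `rd` (see
#'   [translation_metrics()]); rows with NA rd are kept.
#' @param cutoff RD cutoff; strict inequality.
#' @return List: `retained` (filtered data.frame), `excluded` (data.frame
#'   gene, rd).
#' @export
filter_outlier_rd <- function(metrics, cutoff = max_theoretical_density()) {
  out <- !is.na(metrics$rd) & metrics$rd > cutoff
  list(retained = metrics[!out, , drop = FALSE],
       excluded = metrics[out, c("gene", "rd"), drop = FALSE])
}

#' Per-gene translation metrics: RO, peak fraction and RD
#'
#' Combines [ribosome_occupancy()], [bootstrap_peak_fraction()] (run per
#' gene) and [ribosome_density()] into the per-gene metrics table. RD is
#' reported only for genes whose peak is confined to a single fraction.
#'
#' @param profile a [compute_proportions()] result.
#' @param orf_lengths named numeric vector of ORF lengths (nt) covering
#'   the profiled genes; genes without a length get NA rd.
#' @param map a [build_ribosome_map()].
#' @inheritParams bootstrap_peak_fraction
#' @return data.frame of class `translation_metrics`: gene, per-replicate
#'   RO, ro_mean, ro_sd, peak_fraction, peak_frequency, confined, rd. The
#'   ribosome map used is attached as attribute `ribosome_map`.
#' @export
translation_metrics <- function(profile, orf_lengths = NULL,
                                map = build_ribosome_map(),
                                n_boot = 1000, conf = 0.95, seed = NULL) {
  stopifnot(inherits(profile, "proportion_profile"))
  if (!is.null(seed)) set.seed(seed)
  ro <- ribosome_occupancy(profile)
  genes <- rownames(profile$proportions)
  boot <- lapply(genes, function(g) {
    prof <- t(profile$proportions[g, , ])
    prof <- prof[stats::complete.cases(prof), , drop = FALSE]
    if (nrow(prof) < 2)
      return(list(peak_fraction = NA_character_, peak_frequency = NA_real_,
                  confined = FALSE))
    bootstrap_peak_fraction(prof, n_boot = n_boot, conf = conf)
  })
  ro$peak_fraction <- vapply(boot, `[[`, character(1), "peak_fraction")
  ro$peak_frequency <- vapply(boot, `[[`, numeric(1), "peak_frequency")
  ro$confined <- vapply(boot, `[[`, logical(1), "confined")
  ro$rd <- NA_real_
  if (!is.null(orf_lengths)) {
    idx <- ro$confined & !is.na(ro$peak_fraction) &
      ro$gene %in% names(orf_lengths)
    ro$rd[idx] <- ribosome_density(ro$peak_fraction[idx], map,
                                   orf_lengths[ro$gene[idx]])
  }
  attr(ro, "ribosome_map") <- map
  class(ro) <- c("translation_metrics", "data.frame")
  ro
}

#' @export
print.translation_metrics <- function(x, ...) {
  cat("translation_metrics: ", nrow(x), " genes; mean RO ",
      round(mean(x$ro_mean, na.rm = TRUE), 1), "%; ",
      sum(x$confined), " confined peak(s); mean RD ",
      signif(mean(x$rd, na.rm = TRUE), 2), " ribosomes/100 nt\n", sep = "")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more genes)\n", sep = "")
  invisible(x)
}
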