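#' Exclude low-count transcripts
#'
#' A transcript is excluded when its read count summed over the seven
#' fractions falls below `threshold` in every replicate; a single replicate
#' reaching the threshold retains the gene. With `scope = "library"` the
#' rule is applied to individual libraries instead (excluded only when
#' every single library is below the threshold).
#'
#' @param fc a [fraction_counts()] object with raw counts.
#' @param threshold minimum read count (default 10).
#' @param scope `"replicate"` (default: per-replicate fraction totals) or
#'   `"library"`.
#' @return A list with the filtered `fraction_counts` (element `counts`),
#'   the retained gene ids (`retained`) and an exclusion report data.frame
#'   (`excluded`: gene, phase, max_total).
#' @export
filter_low_counts <- function(fc, threshold = 10,
                              scope = c("replicate", "library")) {
  scope <- match.arg(scope)
  stopifnot(inherits(fc, "fraction_counts"))
  if (threshold < 0) stop("'threshold' must be >= 0")
  if (scope == "replicate") {
    reps <- unique(fc$meta$replicate)
    totals <- vapply(reps, function(k) {
      rowSums(fc$counts[, fc$meta$replicate == k, drop = FALSE])
    }, numeric(nrow(fc$counts)))
    keep <- apply(totals >= threshold, 1, any)
    max_stat <- apply(totals, 1, max)
  } else {
    keep <- apply(fc$counts >= threshold, 1, any)
    max_stat <- apply(fc$counts, 1, max)
  }
  excluded <- data.frame(
    gene = rownames(fc$counts)[!keep],
    phase = rep(fc$meta$phase[1], sum(!keep)),
    max_total = max_stat[!keep],
    row.names = NULL
  )
  fc$counts <- fc$counts[keep, , drop = FALSE]
  list(counts = fc, retained = rownames(fc$counts), excluded = excluded)
}

#' Median-of-ratios library size factors
#'
#' For library l the size factor is the median, over genes with a positive
#' geometric mean across libraries, of the ratio of the gene's count in l
#' to its across-library geometric mean. Dividing each library by its size
#' factor puts all libraries on a common scale.
#'
#' @param counts numeric genes x libraries matrix of raw counts.
#' @return Numeric vector of positive size factors, one per library.
#' @examples
#' size_factors_median_of_ratios(cbind(c(2, 8), c(4, 16)))  # 1/sqrt(2), sqrt(2)
#' @export
size_factors_median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has a nonzero count in every library; size factors undefined")
  geomean <- exp(loggeo[use])
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnts)
    stats::median(cnts / geomean))
  stats::setNames(sf, colnames(counts))
}

#' Rescale normalized counts by ribodepleted RNA yield
#'
#' Library construction consumes a fixed aliquot (default 10 ng) of the
#' ribodepleted RNA of each fraction; multiplying by the actual yield over
#' the aliquot restores per-fraction mRNA quantities.
#'
#' @param n_deseq size-factor normalized count(s).
#' @param ribodepleted_qty ribodepleted RNA yield of the library, ng.
#' @param aliquot_ng aliquot used for library construction, ng.
#' @return Rescaled count(s): `n_deseq * ribodepleted_qty / aliquot_ng`.
#' @export
ribodepletion_scale <- function(n_deseq, ribodepleted_qty, aliquot_ng = 10) {
  if (any(ribodepleted_qty <= 0)) stop("'ribodepleted_qty' must be > 0")
  n_deseq * ribodepleted_qty / aliquot_ng
}

#' Rescale counts by the total RNA extracted in the fraction
#'
#' A constant aliquot (default 5 ug) of each fraction's total RNA enters
#' ribodepletion; multiplying by the extracted amount over the aliquot
#' yields the final normalized count proportional to the fraction's mRNA
#' content.
#'
#' @param n_ribo ribodepletion-scaled count(s).
#' @param total_rna_qty total RNA extracted in the fraction, ug.
#' @param aliquot_ug aliquot used for ribodepletion, ug.
#' @return Final normalized count(s): `n_ribo * total_rna_qty / aliquot_ug`.
#' @export
total_rna_scale <- function(n_ribo, total_rna_qty, aliquot_ug = 5) {
  if (any(total_rna_qty <= 0)) stop("'total_rna_qty' must be > 0")
  n_ribo * total_rna_qty / aliquot_ug
}

#' Run the three-stage normalization chain
#'
#' Applies, in order: median-of-ratios size factors (library-size
#' correction), the ribodepletion-yield rescaling and the total-RNA
#' rescaling. The result is stored in the object (`$norm`,
#' `$size_factors`).
#'
#' @inheritParams filter_low_counts
#' @param aliquot_ng,aliquot_ug aliquots used at library construction (ng)
#'   and ribodepletion (ug).
#' @return The `fraction_counts` object with elements `norm` (final
#'   normalized matrix) and `size_factors` added.
#' @export
normalize_counts <- function(fc, aliquot_ng = 10, aliquot_ug = 5) {
  stopifnot(inherits(fc, "fraction_counts"))
  sf <- size_factors_median_of_ratios(fc$counts)
  n_deseq <- sweep(fc$counts, 2, sf, "/")
  n_ribo <- sweep(n_deseq, 2, fc$meta$ribodepleted_ng / aliquot_ng, "*")
  fc$norm <- sweep(n_ribo, 2, fc$meta$total_rna_ug / aliquot_ug, "*")
  fc$size_factors <- sf
  fc
}

#' Per-gene mRNA proportions across gradient fractions
#'
#' For each gene and replicate, the percentage of the gene's normalized
#' counts found in each fraction A..G. Genes with a zero total in a
#' replicate have no defined profile there and are dropped from that
#' replicate (with a warning); genes with no profile in any replicate are
#' excluded and reported.
#'
#' @param fc a normalized [fraction_counts()] object (see
#'   [normalize_counts()]), or one carrying already-final counts in
#'   `$counts` when `use = "counts"`.
#' @param use which matrix to use: `"norm"` (default) or `"counts"`.
#' @return An object of class `proportion_profile`: list with `proportions`
#'   (genes x 7 fractions x replicates array, percent; NA where a replicate
#'   was dropped), `mean` (genes x 7 matrix, percent) and `excluded`
#'   (character vector of genes with no profile anywhere).
#' @export
compute_proportions <- function(fc, use = c("norm", "counts")) {
  use <- match.arg(use)
  stopifnot(inherits(fc, "fraction_counts"))
  mat <- if (use == "norm") fc$norm else fc$counts
  if (is.null(mat)) stop("no normalized counts; run normalize_counts() first")
  arr <- .library_array(mat, fc$meta)
  totals <- apply(arr, c(1, 3), sum)
  empty <- totals <= 0 | is.na(totals)
  props <- sweep(arr, c(1, 3), totals, "/") * 100
  if (any(empty)) {
    for (k in seq_len(ncol(totals))) props[empty[, k], , k] <- NA_real_
    n_drop <- sum(empty & !apply(empty, 1, all))
    if (n_drop > 0)
      warning(n_drop, " gene-replicate profile(s) with zero total dropped")
  }
  excluded <- rownames(mat)[apply(empty, 1, all)]
  if (length(excluded)) {
    warning(length(excluded), " gene(s) with no profile in any replicate excluded")
    props <- props[!rownames(mat) %in% excluded, , , drop = FALSE]
  }
  mean_props <- apply(props, c(1, 2), mean, na.rm = TRUE)
  structure(list(proportions = props, mean = mean_props, excluded = excluded),
            class = "proportion_profile")
}

#' @export
print.proportion_profile <- function(x, ...) {
  d <- dim(x$proportions)
  cat("proportion_profile: ", d[1], " genes x ", d[2], " fractions x ",
      d[3], " replicates (percent of mRNA copies)\n", sep = "")
  invisible(x)
}
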