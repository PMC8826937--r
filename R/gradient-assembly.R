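#' Assign gradient subfractions to the analysis fractions A--G
#'
#' A sucrose gradient is collected as 24 subfractions (top first). The
#' leading subfractions containing free RNAs and free 30S/50S subunits —
#' recognized by a 23S/16S rRNA ratio away from the ~1.8 of whole
#' ribosomes — form fraction A. The remaining subfractions are partitioned
#' contiguously at the local minima of total rRNA abundance (16S + 23S,
#' smoothed with a running mean of window 3) separating successive
#' gradient peaks: the first four peaks become fractions B (monosome),
#' C, D and E, and the remaining polysomal peaks are pooled into F and G
#' (a single unresolved heavy tail is split at its midpoint).
#'
#' @param table data.frame with columns `subfraction_id` (1..24, unique),
#'   `rrna16s_qty`, `rrna23s_qty` (arbitrary units), and optionally
#'   `total_rna_ug`, `ribodepleted_ng`.
#' @param ratio_window numeric length-2 interval of 23S/16S ratios accepted
#'   as whole ribosomes (default `c(1.5, 2.1)` around the nominal 1.8).
#' @return Named character vector: fraction label (A..G) per subfraction,
#'   in subfraction order.
#' @export
classify_subfractions <- function(table, ratio_window = c(1.5, 2.1)) {
  required <- c("subfraction_id", "rrna16s_qty", "rrna23s_qty")
  if (!all(required %in% names(table)))
    stop("subfraction table needs columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(table$subfraction_id)) stop("duplicated subfraction ids")
  table <- table[order(table$subfraction_id), , drop = FALSE]
  n <- nrow(table)
  if (n != 24) stop("expected 24 subfractions, got ", n)
  total <- table$rrna16s_qty + table$rrna23s_qty
  if (sum(total > 0) < 7) stop("fewer than 7 subfractions with rRNA signal")
  ratio <- ifelse(table$rrna16s_qty > 0,
                  table$rrna23s_qty / table$rrna16s_qty, NA_real_)
  ribosomal <- !is.na(ratio) & ratio >= ratio_window[1] & ratio <= ratio_window[2]
  # fraction A: leading contiguous run of non-ribosomal subfractions
  first_rib <- match(TRUE, ribosomal)
  if (is.na(first_rib) || first_rib == 1)
    stop("no leading free-subunit block found: cannot delimit fraction A")
  a_block <- seq_len(first_rib - 1)
  rest <- seq.int(first_rib, n)

  # peak boundaries: local minima of the smoothed total rRNA trace
  sm <- .running_mean3(total[rest])
  m <- length(sm)
  is_min <- vapply(seq_len(m), function(i) {
    i > 1 && i < m && sm[i] < sm[i - 1] && sm[i] <= sm[i + 1]
  }, logical(1))
  cuts <- which(is_min)  # minimum belongs to the left block
  blocks <- findInterval(seq_len(m), cuts + 1L) + 1L
  n_blocks <- max(blocks)
  if (n_blocks < 4)
    stop("unresolvable subfraction profile: only ", n_blocks,
         " peak block(s) found after the free-subunit block; at least the ",
         "monosome and the 2-4-ribosome peaks must be resolvable")
  if (n_blocks == 4)
    stop("unresolvable subfraction profile: 4 peak blocks delimit B..E ",
         "but leave no polysomal material for fractions F and G")
  labels_rest <- character(m)
  labels_rest[blocks <= 4] <- FRACTIONS[blocks[blocks <= 4] + 1L]
  if (n_blocks == 5) {
    # a single unresolved heavy-polysome tail: split it at its midpoint
    tail_idx <- which(blocks == 5)
    half <- tail_idx[seq_len(ceiling(length(tail_idx) / 2))]
    labels_rest[half] <- "F"
    labels_rest[setdiff(tail_idx, half)] <- "G"
    if (!any(labels_rest == "G"))
      stop("heavy-polysome tail too short to split into fractions F and G")
  } else {
    # remaining peak blocks split between F and G
    rem <- n_blocks - 4L
    f_blocks <- 4L + seq_len(floor(rem / 2))
    labels_rest[blocks %in% f_blocks] <- "F"
    labels_rest[blocks > max(f_blocks)] <- "G"
  }
  out <- c(rep("A", length(a_block)), labels_rest)
  stats::setNames(out, table$subfraction_id)
}

.running_mean3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  xp <- c(x[1], x, x[n])  # repeat endpoints
  (xp[1:n] + xp[2:(n + 1)] + xp[3:(n + 2)]) / 3
}

#' Pool subfraction counts and RNA quantities into fractions
#'
#' Read counts, and where present the per-subfraction RNA quantity
#' metadata, are summed within each fraction label. The grand total of
#' reads is conserved exactly.
#'
#' @param subfraction_counts genes x subfractions numeric matrix; column
#'   names identify subfractions.
#' @param labels named character vector mapping subfraction id to fraction
#'   label, as returned by [classify_subfractions()].
#' @param quantities optional data.frame with `subfraction_id`,
#'   `ribodepleted_ng`, `total_rna_ug` to be summed per fraction.
#' @return List with `counts` (genes x pooled-fractions matrix, columns in
#'   A..G order) and, when quantities are given, `quantities` (data.frame
#'   fraction, ribodepleted_ng, total_rna_ug).
#' @export
pool_counts <- function(subfraction_counts, labels, quantities = NULL) {
  subfraction_counts <- as.matrix(subfraction_counts)
  ids <- colnames(subfraction_counts)
  if (is.null(ids)) ids <- as.character(seq_len(ncol(subfraction_counts)))
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab))
    stop("no fraction label for subfraction(s): ",
         paste(missing_lab, collapse = ", "))
  lab <- factor(labels[ids], levels = FRACTIONS)
  present <- levels(lab)[tabulate(lab, nbins = nlevels(lab)) > 0]
  pooled <- matrix(NA_real_, nrow(subfraction_counts), length(present),
                   dimnames = list(rownames(subfraction_counts), present))
  for (f in present)
    pooled[, f] <- rowSums(subfraction_counts[, lab == f, drop = FALSE])
  out <- list(counts = pooled)
  if (!is.null(quantities)) {
    qlab <- labels[as.character(quantities$subfraction_id)]
    out$quantities <- data.frame(
      fraction = names(tapply(quantities$ribodepleted_ng, qlab, sum)),
      ribodepleted_ng = as.numeric(tapply(quantities$ribodepleted_ng, qlab, sum)),
      total_rna_ug = as.numeric(tapply(quantities$total_rna_ug, qlab, sum)),
      row.names = NULL
    )
  }
  out
}

#' Ribosome numbers attributed to fractions A--G
#'
#' Fraction A holds untranslated mRNA (0 ribosomes); the first four
#' gradient peaks are the monosome and the 2-, 3- and 4-ribosome
#' polysomes. The pooled heavy fractions F and G are assigned extrapolated
#' ribosome numbers, user-overridable since they depend on the gradient.
#'
#' @param f_count,g_count ribosome numbers for fractions F and G; must
#'   satisfy 4 < f_count < g_count.
#' @return Named integer vector over A..G (class `ribosome_map`).
#' @examples
#' build_ribosome_map()        # A:0 B:1 C:2 D:3 E:4 F:6 G:9
#' @export
build_ribosome_map <- function(f_count = 6, g_count = 9) {
  f_count <- as.integer(f_count); g_count <- as.integer(g_count)
  if (!(4 < f_count && f_count < g_count))
    stop("ribosome map must be monotone: need 4 < f_count < g_count, got F=",
         f_count, ", G=", g_count)
  structure(stats::setNames(c(0L, 1L, 2L, 3L, 4L, f_count, g_count), FRACTIONS),
            class = "ribosome_map")
}

#' @export
print.ribosome_map <- function(x, ...) {
  cat("ribosome_map:", paste(names(x), unclass(x), sep = ":", collapse = " "), "\n")
  invisible(x)
}
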