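#' Fraction count matrix with per-library RNA-quantity metadata
#'
#' Container for polysome-profiling read counts: a genes x libraries matrix
#' where each library is one (fraction, replicate) pair, together with the
#' per-library metadata the normalization chain consumes (ribodepleted RNA
#' yield in ng, total extracted RNA in ug).
#'
#' @param counts numeric matrix, genes in rows, libraries in columns;
#'   non-negative. Column names, if present, must match
#'   `meta$library_id`.
#' @param meta data.frame with one row per library and columns
#'   `library_id`, `fraction` (one of A..G), `replicate` (integer),
#'   `ribodepleted_ng` (> 0), `total_rna_ug` (> 0). An optional `phase`
#'   column is carried along.
#' @param phase growth-phase label attached to the dataset when `meta` has
#'   no `phase` column ("exponential", "stationary" or "custom").
#'
#' @return An object of class `fraction_counts`: a list with elements
#'   `counts` and `meta`.
#' @examples
#' fc <- simulate_counts(simulate_fraction_profile(80, "D", 1),
#'                       depth = 1000, n_reps = 2, seed = 1)$counts
#' fc
#' @export
fraction_counts <- function(counts, meta, phase = "custom") {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts))
    stop("'counts' must be a non-negative numeric matrix without NAs")
  required <- c("library_id", "fraction", "replicate",
                "ribodepleted_ng", "total_rna_ug")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(meta) != ncol(counts))
    stop("metadata has ", nrow(meta), " rows but 'counts' has ",
         ncol(counts), " libraries")
  meta$library_id <- as.character(meta$library_id)
  meta$fraction <- as.character(meta$fraction)
  if (!all(meta$fraction %in% FRACTIONS))
    stop("fraction labels must be in ", paste(FRACTIONS, collapse = ""))
  if (anyDuplicated(meta[c("fraction", "replicate")]))
    stop("duplicated (fraction, replicate) pairs in metadata")
  if (any(meta$ribodepleted_ng <= 0) || any(meta$total_rna_ug <= 0))
    stop("RNA quantities must be strictly positive")
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), meta$library_id))
      stop("column names of 'counts' do not match meta$library_id")
    meta <- meta[match(colnames(counts), meta$library_id), , drop = FALSE]
  } else {
    colnames(counts) <- meta$library_id
  }
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(meta$phase)) meta$phase <- phase
  rownames(meta) <- meta$library_id
  structure(list(counts = counts, meta = meta), class = "fraction_counts")
}

#' @export
print.fraction_counts <- function(x, ...) {
  cat("fraction_counts: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " libraries (", length(unique(x$meta$fraction)), " fractions x ",
      length(unique(x$meta$replicate)), " replicates), phase: ",
      paste(unique(x$meta$phase), collapse = "/"), "\n", sep = "")
  if (!is.null(x$norm))
    cat("normalized counts present (size factors ",
        paste(signif(x$size_factors, 3), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' @export
dim.fraction_counts <- function(x) dim(x$counts)

#' Read HTSeq-count style count files into a fraction count matrix
#'
#' Each per-library file is a two-column TAB-separated table
#' (gene_id, count), the format written by `htseq-count`. Special counter
#' rows (`__no_feature`, `__ambiguous`, ...) are dropped.
#'
#' @param files named character vector of file paths; names (or basenames)
#'   must match `library_id` in the metadata.
#' @param meta library metadata data.frame (see [fraction_counts()]) or the
#'   path of a TAB-separated metadata file with those columns.
#' @return A [fraction_counts()] object.
#' @export
read_htseq_counts <- function(files, meta) {
  if (is.character(meta) && length(meta) == 1)
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  if (is.null(names(files)))
    names(files) <- sub("\\.(tsv|txt|counts)$", "", basename(files))
  tabs <- lapply(files, function(f) {
    x <- utils::read.delim(f, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("gene_id", "count"))
    x[!startsWith(x$gene_id, "__"), ]
  })
  genes <- tabs[[1]]$gene_id
  counts <- vapply(tabs, function(x) {
    if (!identical(x$gene_id, genes))
      x <- x[match(genes, x$gene_id), ]
    as.numeric(x$count)
  }, numeric(length(genes)))
  rownames(counts) <- genes
  fraction_counts(counts, meta)
}

#' Read a genes x libraries count matrix from a TSV file
#'
#' @param file TAB-separated file, first column gene ids, remaining columns
#'   one per library, header row of library ids.
#' @inheritParams read_htseq_counts
#' @return A [fraction_counts()] object.
#' @export
read_count_matrix <- function(file, meta) {
  if (is.character(meta) && length(meta) == 1)
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  x <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  counts <- as.matrix(x[, -1, drop = FALSE])
  rownames(counts) <- x[[1]]
  fraction_counts(counts, meta)
}

# Reshape one matrix (genes x libraries) into genes x fraction x replicate.
.library_array <- function(mat, meta) {
  reps <- sort(unique(meta$replicate))
  arr <- array(NA_real_, dim = c(nrow(mat), length(FRACTIONS), length(reps)),
               dimnames = list(rownames(mat), FRACTIONS, paste0("rep", reps)))
  for (l in seq_len(nrow(meta)))
    arr[, meta$fraction[l], match(meta$replicate[l], reps)] <- mat[, l]
  arr
}
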