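#' @name covariates
#' @title Gene covariates of the translation regression models
#'
#' @description The regression models explain RO (percent) or log RD with
#' nine quantitative gene covariates — mRNA concentration, ORF length and
#' GC%, codon adaptation index (CAI), chromosomal distance from OriC,
#' protein hydrophobicity (GRAVY), 5'UTR GC% and length, and the folding
#' energy of the translation initiation region (-30..+24 nt) — and eight
#' qualitative ones: strand, essentiality, presence of a signal peptide,
#' inner-membrane protein, cellular location, COG category, CsrA target,
#' and the purine/pyrimidine class of the second 5'UTR nucleotide.
#'
#' `quantitative_covariates()`, `qualitative_covariates()` and
#' `default_log_flags()` return the canonical column names and the
#' covariates log-transformed by default (mRNA concentration, ORF length,
#' CAI and 5'UTR length; the RD response is itself log-transformed).
NULL

#' @rdname covariates
#' @export
quantitative_covariates <- function() {
  c("mrna_conc", "orf_length", "orf_gc", "cai", "chrom_location",
    "hydrophobicity", "utr5_gc", "utr5_length", "dg_tir")
}

#' @rdname covariates
#' @export
qualitative_covariates <- function() {
  c("strand", "essentiality", "signal_peptide", "inner_membrane",
    "cell_location", "cog", "csra_target", "second_utr_nt")
}

#' @rdname covariates
#' @export
default_log_flags <- function() c("mrna_conc", "orf_length", "cai", "utr5_length")

#' Transform and standardize a covariate table for regression
#'
#' Log-flagged quantitative covariates are log10-transformed (the base is
#' immaterial to standardized coefficients since every quantitative column
#' is subsequently z-scored to mean 0, sd 1). Qualitative covariates are
#' converted to factors. Genes with any missing value are dropped listwise
#' and counted.
#'
#' @param covariates data.frame with (a subset of) the covariate columns
#'   (see [quantitative_covariates()]); extra columns are ignored. A
#'   `gene` column, if present, becomes row names.
#' @param log_flags quantitative covariates to log-transform; must be
#'   strictly positive.
#' @param drop covariates to exclude from the design (e.g. `orf_length`
#'   for the RD model).
#' @return data.frame (the design table) with scaled numeric columns and
#'   factor columns; attribute `n_dropped` counts genes removed for
#'   missing values.
#' @export
transform_covariates <- function(covariates, log_flags = default_log_flags(),
                                 drop = character()) {
  covariates <- as.data.frame(covariates)
  if ("gene" %in% names(covariates)) {
    rownames(covariates) <- covariates$gene
    covariates$gene <- NULL
  }
  keep <- setdiff(intersect(names(covariates),
                            c(quantitative_covariates(),
                              qualitative_covariates())),
                  drop)
  x <- covariates[, keep, drop = FALSE]
  cc <- stats::complete.cases(x)
  x <- x[cc, , drop = FALSE]
  unknown <- setdiff(log_flags, quantitative_covariates())
  if (length(unknown))
    stop("log flag(s) not quantitative covariates: ",
         paste(unknown, collapse = ", "))
  for (v in intersect(names(x), quantitative_covariates())) {
    col <- as.numeric(x[[v]])
    if (v %in% log_flags) {
      if (any(col <= 0))
        stop("covariate '", v, "' has nonpositive values; cannot log-transform")
      col <- log10(col)
    }
    s <- stats::sd(col)
    if (!is.finite(s) || s == 0)
      stop("covariate '", v, "' has zero variance; cannot standardize")
    x[[v]] <- (col - mean(col)) / s
  }
  for (v in intersect(names(x), qualitative_covariates()))
    x[[v]] <- factor(x[[v]])
  attr(x, "n_dropped") <- sum(!cc)
  x
}

#' Deviation (sum-to-zero) coding of a qualitative covariate
#'
#' Returns the k-1 deviation-coded design columns for a factor with k
#' observed levels. Under this coding a level's coefficient is its
#' deviation from the mean over all levels, and the full set of k level
#' coefficients sums to zero (the omitted level's coefficient is minus the
#' sum of the others).
#'
#' @param levels factor (or vector coerced to factor) with at least 2
#'   observed levels.
#' @return Numeric matrix with one row per observation and k-1 columns
#'   named `<level>` for the first k-1 levels.
#' @export
encode_qualitative <- function(levels) {
  f <- droplevels(factor(levels))
  k <- nlevels(f)
  if (k < 2) stop("qualitative covariate has a single observed level")
  m <- stats::contr.sum(k)[f, , drop = FALSE]
  colnames(m) <- levels(f)[seq_len(k - 1)]
  rownames(m) <- NULL
  m
}

# expand lm coefficients into a per-(predictor, level) table; deviation-coded
# factor levels are completed with the implied last level (minus the sum).
.coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]; pv <- sm[, "Pr(>|t|)"]
  asg <- attr(stats::model.matrix(fit), "assign")
  terms_lab <- c("(Intercept)", attr(stats::terms(fit), "term.labels"))
  xl <- fit$xlevels
  rows <- list()
  for (t in unique(asg)) {
    lab <- terms_lab[t + 1]
    idx <- which(asg == t)
    if (!is.null(xl[[lab]])) {
      lev <- xl[[lab]]
      e <- c(est[idx], -sum(est[idx]))
      rows[[lab]] <- data.frame(predictor = lab, level = lev,
                                estimate = unname(e),
                                p_value = c(unname(pv[idx]), NA_real_))
    } else {
      rows[[lab]] <- data.frame(predictor = lab, level = NA_character_,
                                estimate = unname(est[idx]),
                                p_value = unname(pv[idx]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares fit of a translation metric on gene covariates
#'
#' Fits the linear model by least squares with deviation (sum-to-zero)
#' contrasts for factor covariates, and reports per-coefficient two-sided
#' t-test p-values, R-squared and AIC. Rank-deficient designs are
#' rejected with the collinear columns named.
#'
#' @param design data.frame of predictors (numeric columns standardized,
#'   factors for qualitative covariates; see [transform_covariates()]), or
#'   a numeric matrix.
#' @param response numeric response vector (RO in percent, or log RD).
#' @return Object of class `translation_lm`; see
#'   [fit_translation_model()] for the fields.
#' @export
fit_ols <- function(design, response) {
  design <- as.data.frame(design)
  if (nrow(design) != length(response))
    stop("design and response lengths differ")
  if (nrow(design) <= ncol(design) + 1)
    stop("more design columns than observations")
  dat <- cbind(.response = response, .set_sum_contrasts(design))
  fit <- stats::lm(.response ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  .as_translation_lm(fit, included = attr(stats::terms(fit), "term.labels"))
}

# deviation coding attached per column so models refitted on predictor
# subsets (stepwise search) keep the same contrasts without warnings
.set_sum_contrasts <- function(design) {
  for (v in names(design)) {
    if (is.factor(design[[v]]))
      stats::contrasts(design[[v]]) <- stats::contr.sum(nlevels(design[[v]]))
  }
  design
}

.as_translation_lm <- function(fit, included, response_name = "response") {
  sm <- summary(fit)
  structure(list(
    fit = fit,
    response = response_name,
    coefficients = .coef_table(fit),
    r_squared = sm$r.squared,
    aic = stats::AIC(fit),
    n_genes = stats::nobs(fit),
    included_predictors = included
  ), class = "translation_lm")
}

#' Stepwise model selection by AIC
#'
#' Starting from the full model (or from the intercept for forward
#' selection), whole predictors — a qualitative covariate's deviation-coded
#' columns move as one block — are added or removed while the AIC strictly
#' decreases. The search is deterministic given the column order of the
#' design.
#'
#' @inheritParams fit_ols
#' @param direction `"both"` (default), `"backward"` or `"forward"`.
#' @return A `translation_lm` for the selected model.
#' @export
stepwise_aic <- function(design, response,
                         direction = c("both", "backward", "forward")) {
  direction <- match.arg(direction)
  design <- as.data.frame(design)
  dat <- cbind(.response = response, .set_sum_contrasts(design))
  full <- stats::lm(.response ~ ., data = dat)
  if (anyNA(stats::coef(full))) {
    bad <- names(stats::coef(full))[is.na(stats::coef(full))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  scope <- list(lower = ~1, upper = stats::formula(full))
  start <- if (direction == "forward")
    stats::lm(.response ~ 1, data = dat) else full
  sel <- stats::step(start, scope = scope, direction = direction, trace = 0)
  .as_translation_lm(sel, included = attr(stats::terms(sel), "term.labels"))
}

#' Fit the RO or RD regression model from metrics and covariates
#'
#' Joins a [translation_metrics()] table with a gene covariate table,
#' applies the transforms ([transform_covariates()]; for the RD model the
#' response is log10 RD and ORF length is removed from the design because
#' RD is inversely proportional to it by construction), and fits the
#' multiple linear regression, optionally followed by stepwise AIC
#' selection.
#'
#' @param metrics a [translation_metrics()] data.frame (needs `gene`,
#'   `ro_mean` and, for the RD model, `rd`).
#' @param covariates data.frame with a `gene` column and covariate columns.
#' @param response `"RO"` or `"RD"`.
#' @param log_flags covariates to log-transform (see
#'   [transform_covariates()]).
#' @param select stepwise direction passed to [stepwise_aic()], or
#'   `"none"` for the full model.
#' @return Object of class `translation_lm`: list with the underlying
#'   `lm` fit (`fit`), `response`, `coefficients` (predictor, level,
#'   estimate, p_value; factor levels completed so each set sums to 0),
#'   `r_squared`, `aic`, `n_genes`, `included_predictors`.
#' @export
fit_translation_model <- function(metrics, covariates,
                                  response = c("RO", "RD"),
                                  log_flags = default_log_flags(),
                                  select = c("both", "none", "backward",
                                             "forward")) {
  response <- match.arg(response)
  select <- match.arg(select)
  stopifnot(is.data.frame(metrics), "gene" %in% names(metrics))
  if (response == "RO") {
    y <- stats::setNames(metrics$ro_mean, metrics$gene)
    drop <- character()
  } else {
    ok <- !is.na(metrics$rd) & metrics$rd > 0
    y <- stats::setNames(log10(metrics$rd[ok]), metrics$gene[ok])
    drop <- "orf_length"
  }
  design <- transform_covariates(covariates, log_flags = log_flags, drop = drop)
  genes <- intersect(names(y), rownames(design))
  if (length(genes) < 2) stop("too few genes shared by metrics and covariates")
  design <- design[genes, , drop = FALSE]
  design <- droplevels(design)
  y <- y[genes]
  res <- if (select == "none") fit_ols(design, y)
         else stepwise_aic(design, y, direction = select)
  res$response <- if (response == "RO") "RO" else "logRD"
  res
}

#' @export
print.translation_lm <- function(x, ...) {
  cat("translation_lm: ", x$response, " ~ ",
      paste(x$included_predictors, collapse = " + "), "\n",
      "n = ", x$n_genes, ", R-squared = ", signif(x$r_squared, 3),
      ", AIC = ", round(x$aic, 1), "\n", sep = "")
  invisible(x)
}

#' @export
summary.translation_lm <- function(object, ...) {
  print(object)
  cat("\nStandardized coefficients (factor levels deviation-coded, sum 0):\n")
  tab <- object$coefficients
  tab$estimate <- signif(tab$estimate, 3)
  tab$p_value <- signif(tab$p_value, 2)
  print.data.frame(tab, row.names = FALSE)
  invisible(object)
}

#' @export
coef.translation_lm <- function(object, expanded = FALSE, ...) {
  if (expanded) object$coefficients else stats::coef(object$fit)
}

#' @export
predict.translation_lm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  stats::predict(object$fit, newdata = as.data.frame(newdata), ...)
}

#' @export
residuals.translation_lm <- function(object, ...) stats::residuals(object$fit)

#' @export
simulate.translation_lm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}

#' @export
plot.translation_lm <- function(x, ...) {
  tab <- x$coefficients
  tab <- tab[tab$predictor != "(Intercept)", ]
  lab <- ifelse(is.na(tab$level), tab$predictor,
                paste0(tab$predictor, ":", tab$level))
  graphics::dotchart(tab$estimate, labels = lab,
                     xlab = "standardized coefficient",
                     main = paste("Model for", x$response), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Spearman correlation screen with Benjamini-Hochberg correction
#'
#' Spearman rank correlation (average ranks on ties) of a translation
#' metric against each covariate column, with p-values adjusted across the
#' covariate family by the Benjamini-Hochberg step-up procedure. Constant
#' columns have no defined correlation and are reported as NA.
#'
#' @param metric numeric vector (one value per gene).
#' @param covariates numeric data.frame or matrix, one column per
#'   covariate, rows aligned with `metric`.
#' @return data.frame: covariate, n, rho, p_value, p_adj.
#' @export
spearman_bh <- function(metric, covariates) {
  covariates <- as.data.frame(covariates)
  res <- lapply(names(covariates), function(v) {
    ok <- stats::complete.cases(metric, covariates[[v]])
    n <- sum(ok)
    if (n < 3 || stats::sd(covariates[[v]][ok]) == 0 ||
        stats::sd(metric[ok]) == 0)
      return(data.frame(covariate = v, n = n, rho = NA_real_,
                        p_value = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(metric[ok], covariates[[v]][ok],
                      method = "spearman", exact = FALSE))
    data.frame(covariate = v, n = n, rho = unname(ct$estimate),
               p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p_value)
  out$p_adj[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out
}
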