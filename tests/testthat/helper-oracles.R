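# Independent oracles used to validate the package implementations.

# literal median-of-ratios definition: per-library median over genes (with a
# positive geometric mean) of count / across-library geometric mean
sf_oracle <- function(m) {
  gm <- apply(m, 1, function(r) exp(mean(log(r))))
  ok <- is.finite(gm) & gm > 0
  apply(m, 2, function(cnts) stats::median(cnts[ok] / gm[ok]))
}

# plain-loop residual bootstrap of the peak fraction (7 residual draws per
# bootstrap profile, argmax over B..G, ties to the lighter fraction)
boot_peak_oracle <- function(profiles, n_boot) {
  mp <- colMeans(profiles)
  res <- as.vector(sweep(profiles, 2, mp))
  peaks <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    prof <- mp + sample(res, 7, replace = TRUE)
    v <- prof[2:7]
    peaks[b] <- which(v == max(v))[1]
  }
  tabulate(peaks, nbins = 6) / n_boot
}

# exact two-fraction peak probability by enumeration over the residual pool:
# P(first fraction wins), ties awarded to the first (lighter) fraction
tie_peak_exact <- function(pool) {
  mean(outer(pool, pool, ">="))
}

# closed-form least squares via the normal equations
ols_oracle <- function(X, y) {
  X1 <- cbind(1, as.matrix(X))
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# replicate x fraction proportion matrices wrapped as a proportion_profile
make_profile <- function(..., genes = NULL) {
  mats <- list(...)
  n_rep <- nrow(mats[[1]])
  arr <- array(NA_real_, c(length(mats), 7, n_rep),
               dimnames = list(genes %||% paste0("g", seq_along(mats)),
                               LETTERS[1:7], paste0("rep", seq_len(n_rep))))
  for (i in seq_along(mats)) arr[i, , ] <- t(mats[[i]])
  structure(list(proportions = arr, mean = apply(arr, c(1, 2), mean),
                 excluded = character()),
            class = "proportion_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
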