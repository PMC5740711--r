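#' Global (per-sample mean) normalization
#'
#' Subtracts each sample's mean expression from that sample, i.e. uses the
#' per-sample mean as a universal housekeeping reference. Optionally the
#' grand mean of the input is added back to every entry so values stay on
#' the original scale; this constant shift does not affect any downstream
#' differential statistic.
#'
#' @param x Expression matrix (genes x samples), log2 units.
#' @param recentre If `TRUE`, add the grand mean of `x` back to all entries.
#' @return The normalized matrix; every column has mean 0 (or the grand
#'   mean, if `recentre`).
#' @export
normalize_global <- function(x, recentre = FALSE) {
  validate_expression_matrix(x)
  out <- sweep(x, 2L, colMeans(x), "-")
  if (isTRUE(recentre)) out <- out + mean(x)
  out
}

#' Median-IQR normalization
#'
#' A robust location-scale transformation: each sample's median is
#' subtracted, values are rescaled by `IQR_0 / IQR_j`, and the median of the
#' sample medians (`Med_0`) is added back. After normalization every column
#' has median `Med_0` and IQR `IQR_0`, where `Med_0` and `IQR_0` are the
#' medians of the per-sample medians and IQRs. IQRs use linear interpolation
#' between order statistics (quantile type 7), the same convention as
#' [iqr_filter()].
#'
#' @param x Expression matrix (genes x samples) with at least 2 samples;
#'   every column must have positive IQR.
#' @return The normalized matrix.
#' @export
normalize_median_iqr <- function(x) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  med_j <- apply(x, 2L, stats::median)
  iqr_j <- apply(x, 2L, stats::IQR, type = 7L)
  if (any(iqr_j <= 0)) {
    stop("zero IQR in sample(s): ",
         paste(colnames(x)[iqr_j <= 0], collapse = ", "),
         "; cannot rescale a degenerate sample", call. = FALSE)
  }
  med_0 <- stats::median(med_j)
  iqr_0 <- stats::median(iqr_j)
  sweep(sweep(x, 2L, med_j, "-"), 2L, iqr_0 / iqr_j, "*") + med_0
}

#' Quantile normalization
#'
#' Maps every sample onto a common reference distribution: the reference is
#' the mean of the r-th order statistics across all samples (both groups
#' pooled), and each value is replaced by the reference entry at its
#' within-column rank. Tied values receive the mean of the reference entries
#' over their tied rank range. After normalization all columns share the
#' same multiset of values.
#'
#' Delegates to [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param x Expression matrix (genes x samples) with at least 2 samples.
#' @return The normalized matrix.
#' @export
normalize_quantile <- function(x) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Cyclic loess normalization
#'
#' MA-space local-regression normalization between arrays, via
#' [limma::normalizeCyclicLoess()]. In `pairwise` mode each ordered pair of
#' columns is normalized against each other (the fitted M-vs-A trend is
#' split half-and-half between the two columns), cycling `iterations` times;
#' in `fast` mode each column is normalized against the column-mean
#' reference array instead of all pairs. Deterministic for fixed inputs.
#'
#' @param x Expression matrix (genes x samples) with at least 2 samples.
#' @param span Loess span in (0, 1]; fraction of points used per local fit.
#' @param iterations Number of cycles over the data.
#' @param mode `"fast"` (default; against the mean array) or `"pairwise"`
#'   (all ordered pairs).
#' @return The normalized matrix.
#' @export
normalize_cyclic_loess <- function(x, span = 0.7, iterations = 3L,
                                   mode = c("fast", "pairwise")) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1) {
    stop("span must be in (0, 1]", call. = FALSE)
  }
  mode <- match.arg(mode)
  method <- if (mode == "fast") "fast" else "pairs"
  out <- limma::normalizeCyclicLoess(x, span = span,
                                     iterations = as.integer(iterations),
                                     method = method)
  dimnames(out) <- dimnames(x)
  out
}

#' Apply a named between-array normalization
#'
#' Convenience dispatcher used by the benchmark harness and the command-line
#' wrapper.
#'
#' @param x Expression matrix.
#' @param method One of `"global"`, `"mediqr"`, `"quantile"`, `"loess"`.
#' @param ... Passed on to the specific method.
#' @return The normalized matrix.
#' @export
normalize_matrix <- function(x,
                             method = c("global", "mediqr", "quantile",
                                        "loess"),
                             ...) {
  method <- match.arg(method)
  switch(method,
         global = normalize_global(x, ...),
         mediqr = normalize_median_iqr(x),
         quantile = normalize_quantile(x),
         loess = normalize_cyclic_loess(x, ...))
}
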