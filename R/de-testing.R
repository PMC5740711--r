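#' Per-gene two-sample t-tests
#'
#' Vectorized two-sample t-tests for every row of an expression matrix,
#' comparing groups A and B. The pooled variant uses a common variance
#' estimate on N - 2 degrees of freedom; the Welch variant uses unpooled
#' group variances with Satterthwaite degrees of freedom. Genes with zero
#' variance in both groups get `NA` statistics (their count is attached as
#' attribute `"n_degenerate"`).
#'
#' @param x Expression matrix (genes x samples).
#' @param design A [group_design()].
#' @param variant `"pooled"` or `"welch"`.
#' @return A data.frame with columns gene_id, statistic, df, p_raw.
#' @export
two_sample_t <- function(x, design, variant = c("pooled", "welch")) {
  validate_expression_matrix(x)
  variant <- match.arg(variant)
  idx <- design_indices(design, x)
  n_A <- length(idx$A); n_B <- length(idx$B)
  if (n_A < 2L || n_B < 2L) stop("both groups need >= 2 samples",
                                 call. = FALSE)
  xA <- x[, idx$A, drop = FALSE]
  xB <- x[, idx$B, drop = FALSE]
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  vA <- rowSums((xA - mA)^2) / (n_A - 1)
  vB <- rowSums((xB - mB)^2) / (n_B - 1)
  degenerate <- (vA + vB) == 0

  if (variant == "pooled") {
    sp2 <- ((n_A - 1) * vA + (n_B - 1) * vB) / (n_A + n_B - 2)
    stat <- (mA - mB) / sqrt(sp2 * (1 / n_A + 1 / n_B))
    df <- rep(n_A + n_B - 2, nrow(x))
  } else {
    seA <- vA / n_A; seB <- vB / n_B
    stat <- (mA - mB) / sqrt(seA + seB)
    df <- (seA + seB)^2 / (seA^2 / (n_A - 1) + seB^2 / (n_B - 1))
  }
  stat[degenerate] <- NA_real_
  df[degenerate] <- NA_real_
  p <- 2 * stats::pt(-abs(stat), df = df)
  out <- data.frame(gene_id = rownames(x), statistic = unname(stat),
                    df = unname(df), p_raw = unname(p),
                    stringsAsFactors = FALSE)
  attr(out, "n_degenerate") <- sum(degenerate)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; `NA` entries are excluded from the family size
#' and returned as `NA`. Adjusted values are monotone in the ranks of the
#' input and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return Vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric", call. = FALSE)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p_values))
  out[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  out
}

#' Flag differentially expressed genes
#'
#' A gene is called DE when its adjusted p-value is below `alpha` AND its
#' absolute fold change exceeds `fc_threshold`, i.e.
#' `|log2_fc| > log2(fc_threshold)`.
#'
#' @param p_adj Vector of adjusted p-values.
#' @param log2_fc Vector of log2 fold changes (mean A - mean B).
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @param fc_threshold Fold-change threshold >= 1; default 1.25. Use 1 to
#'   disable the fold-change gate.
#' @return Logical vector (`NA` p-values are never called), with attribute
#'   `"n_selected"`.
#' @export
select_degs <- function(p_adj, log2_fc, alpha = 0.05, fc_threshold = 1.25) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  if (fc_threshold < 1) stop("fc_threshold must be >= 1", call. = FALSE)
  if (length(p_adj) != length(log2_fc)) {
    stop("p_adj and log2_fc lengths differ", call. = FALSE)
  }
  is_de <- !is.na(p_adj) & p_adj < alpha &
    abs(log2_fc) > log2(fc_threshold)
  attr(is_de, "n_selected") <- sum(is_de)
  is_de
}

#' Oracle test on noise-free expression data
#'
#' The pooled two-sample t-test applied to the hypothetical expression
#' matrix free of per-sample technical noise (the `x` component of the
#' simulation model). It is the benchmark upper bound that normalization
#' methods try to approach: no real pipeline can run it, since per-sample
#' noise is never observed separately.
#'
#' @param noise_free_matrix The oracle (alpha-free) expression matrix.
#' @param design A [group_design()].
#' @return As [two_sample_t()] with `variant = "pooled"`.
#' @export
oracle_test <- function(noise_free_matrix, design) {
  two_sample_t(noise_free_matrix, design, variant = "pooled")
}

#' Classical normalize-then-test pipeline
#'
#' The standard competitor pipeline: between-array normalization, a per-gene
#' two-sample t-test, BH adjustment, and the DE calling rule.
#'
#' @param x Expression matrix (genes x samples), log2 units.
#' @param design A [group_design()].
#' @param normalization One of `"global"`, `"mediqr"`, `"quantile"`,
#'   `"loess"`, or `"none"`.
#' @param test `"welch"` (default, as used for real-data analyses) or
#'   `"pooled"`.
#' @param alpha BH-adjusted significance threshold.
#' @param fc_threshold Fold-change threshold; 1 disables the gate.
#' @param ... Extra arguments for the normalization method (e.g. `span`,
#'   `mode` for loess).
#' @return A data.frame with columns gene_id, statistic, df, p_raw, p_adj,
#'   log2_fc, is_de.
#' @export
classic_de_test <- function(x, design,
                            normalization = c("quantile", "global",
                                              "mediqr", "loess", "none"),
                            test = c("welch", "pooled"),
                            alpha = 0.05, fc_threshold = 1.25, ...) {
  normalization <- match.arg(normalization)
  test <- match.arg(test)
  xn <- if (normalization == "none") x else
    normalize_matrix(x, method = normalization, ...)
  res <- two_sample_t(xn, design, variant = test)
  idx <- design_indices(design, xn)
  res$p_adj <- bh_adjust(res$p_raw)
  res$log2_fc <- unname(rowMeans(xn[, idx$A, drop = FALSE]) -
                          rowMeans(xn[, idx$B, drop = FALSE]))
  res$is_de <- as.logical(select_degs(res$p_adj, res$log2_fc,
                                      alpha = alpha,
                                      fc_threshold = fc_threshold))
  res
}
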