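# Internal RNG helpers -------------------------------------------------------

# Evaluate code under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seed < 2^31 derived from a master seed and a label;
# every independent source of randomness (effects, noise, baseline choice,
# pairing tie-breaks, replicates) draws from its own named substream so that
# all methods see identical data within a replicate.
substream_seed <- function(master, label, index = 0L) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483647
  s <- ((as.double(master) %% 2147483647) * 69621 + h + as.double(index) *
          7919) %% 2147483647
  as.integer(s) + 1L
}

# Configuration ---------------------------------------------------------------

#' Configuration for a super-delta run
#'
#' @param summarizer How the vector of pairwise t-statistics for a gene is
#'   condensed into one representative statistic: `"mftm"` (median fold trim
#'   median: drop the `trim_proportion` fraction deviating most from the
#'   median, then sqrt(2) times the median of the rest), `"median"` (untrimmed
#'   median), or `"mean"` (untrimmed mean; no pairing gene is defined).
#' @param trim_proportion Fraction of pairwise statistics removed by the MFTM
#'   trim, in \[0, 0.5). The trim count is `floor(trim_proportion * L)` where
#'   `L` is the number of defined pairwise statistics, so the trim never
#'   removes more than intended.
#' @param n_baseline Number of baseline genes to draw (uniformly, without
#'   replacement) as the shared normalization panel, or `"all"` to use every
#'   gene. Around 1000 baselines give results practically indistinguishable
#'   from using all genes at a fraction of the cost.
#' @param df_rule Degrees of freedom for p-values: `"pooled"` (N - 2, the
#'   pooled two-sample form used by the pairwise statistics) or `"welch"`
#'   (each pairwise statistic uses unpooled variances with Satterthwaite df,
#'   and per-gene df is summarized by the same trimmed median).
#' @param seed Integer seed controlling baseline sampling and pairing-gene
#'   tie-breaks.
#' @return An object of class `superdelta_config`.
#' @export
superdelta_config <- function(summarizer = c("mftm", "median", "mean"),
                              trim_proportion = 0.20,
                              n_baseline = 1000L,
                              df_rule = c("pooled", "welch"),
                              seed = 1L) {
  summarizer <- match.arg(summarizer)
  df_rule <- match.arg(df_rule)
  if (!is.numeric(trim_proportion) || length(trim_proportion) != 1L ||
      trim_proportion < 0 || trim_proportion >= 0.5) {
    stop("trim_proportion must be in [0, 0.5)", call. = FALSE)
  }
  if (!identical(n_baseline, "all")) {
    n_baseline <- as.integer(n_baseline)
    if (is.na(n_baseline) || n_baseline < 10L) {
      stop("n_baseline must be 'all' or an integer >= 10", call. = FALSE)
    }
  }
  structure(list(summarizer = summarizer,
                 trim_proportion = trim_proportion,
                 n_baseline = n_baseline,
                 df_rule = df_rule,
                 seed = as.integer(seed)),
            class = "superdelta_config")
}

#' Select baseline genes
#'
#' Draws `k` distinct gene IDs uniformly without replacement, reproducibly
#' for a fixed seed; `"all"` returns every gene. The same baseline panel is
#' shared by all target genes (a gene is excluded from its own panel at test
#' time).
#'
#' @param x Expression matrix (genes x samples).
#' @param k Number of baselines, or `"all"`.
#' @param seed Integer seed.
#' @return Character vector of gene IDs.
#' @export
select_baseline_genes <- function(x, k = "all", seed = 1L) {
  validate_expression_matrix(x)
  gene_ids <- rownames(x)
  if (identical(k, "all")) return(gene_ids)
  k <- as.integer(k)
  if (k > length(gene_ids)) {
    stop("k (", k, ") exceeds the number of genes (", length(gene_ids), ")",
         call. = FALSE)
  }
  with_seed(seed, sample(gene_ids, k))
}

# Pairwise t-statistics -------------------------------------------------------

#' Two-sample t-statistics on all pairwise gene differences
#'
#' For a target gene i and baseline gene i', the per-sample difference
#' `delta_{ii',j} = y_{ij} - y_{i'j}` cancels any noise shared by all genes
#' of sample j; the two-sample t-statistic comparing groups A and B on these
#' differences is the building block of super-delta. Statistics are computed
#' from per-group sufficient statistics (means, sums of squares, and
#' gene-by-gene cross-products), which is algebraically identical to the
#' naive loop over pairs.
#'
#' Entries where target and baseline are the same gene, and entries whose
#' pooled variance is (numerically) zero, are returned as `NA` and counted
#' in the `"n_undefined"` attribute.
#'
#' @param x Expression matrix (genes x samples).
#' @param design A [group_design()] covering the matrix samples; both groups
#'   must have at least 2 samples.
#' @param targets Character vector of target gene IDs (default: all genes).
#' @param baselines Character vector of baseline gene IDs (default: all).
#' @param variant `"pooled"` (pooled sd, N - 2 df) or `"welch"` (unpooled,
#'   Satterthwaite df; the df matrix is attached as attribute `"df"`).
#' @return A targets x baselines numeric matrix of t-statistics with
#'   attributes `"df"` (scalar for pooled, matrix for welch) and
#'   `"n_undefined"`.
#' @export
pairwise_t_stats <- function(x, design, targets = rownames(x),
                             baselines = rownames(x),
                             variant = c("pooled", "welch")) {
  validate_expression_matrix(x)
  variant <- match.arg(variant)
  idx <- design_indices(design, x)
  n_A <- length(idx$A); n_B <- length(idx$B)
  if (n_A < 2L || n_B < 2L) stop("both groups need >= 2 samples",
                                 call. = FALSE)
  bad <- setdiff(c(targets, baselines), rownames(x))
  if (length(bad)) stop("unknown gene IDs: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  N <- n_A + n_B

  suff <- function(cols) {
    Yt <- x[targets, cols, drop = FALSE]
    Yb <- x[baselines, cols, drop = FALSE]
    mt <- rowMeans(Yt); mb <- rowMeans(Yb)
    Zt <- Yt - mt; Zb <- Yb - mb
    list(mt = mt, mb = mb,
         sst = rowSums(Zt^2), ssb = rowSums(Zb^2),
         cross = Zt %*% t(Zb))
  }
  A <- suff(idx$A)
  B <- suff(idx$B)

  # SS of delta within a group: SS(y_i) + SS(y_i') - 2 * crossprod
  ss_A <- outer(A$sst, A$ssb, "+") - 2 * A$cross
  ss_B <- outer(B$sst, B$ssb, "+") - 2 * B$cross
  ss_A[ss_A < 0] <- 0
  ss_B[ss_B < 0] <- 0
  mean_diff <- outer(A$mt - B$mt, A$mb - B$mb, "-")

  # numerical floor: treat pooled variance as zero when it is vanishing
  # relative to the magnitude of the component sums of squares
  degenerate <- (ss_A + ss_B) <=
    1e-12 * (outer(A$sst + B$sst, A$ssb + B$ssb, "+") + 1e-300)

  if (variant == "pooled") {
    sp <- sqrt((ss_A + ss_B) / (N - 2))
    tt <- mean_diff / (sp * sqrt(1 / n_A + 1 / n_B))
    df <- N - 2
  } else {
    vA <- ss_A / (n_A - 1)
    vB <- ss_B / (n_B - 1)
    seA <- vA / n_A; seB <- vB / n_B
    se2 <- seA + seB
    tt <- mean_diff / sqrt(se2)
    df <- se2^2 / (seA^2 / (n_A - 1) + seB^2 / (n_B - 1))
    df[degenerate] <- NA_real_
  }
  n_degen <- sum(degenerate)
  tt[degenerate] <- NA_real_
  # blank the target == baseline cells without materializing an m x k
  # comparison matrix
  pos <- match(baselines, targets)
  hit <- which(!is.na(pos))
  if (length(hit)) {
    cells <- cbind(pos[hit], hit)
    n_degen <- n_degen - sum(degenerate[cells])
    tt[cells] <- NA_real_
  }
  dimnames(tt) <- list(targets, baselines)
  attr(tt, "df") <- df
  attr(tt, "n_undefined") <- n_degen
  tt
}

# Summarizers -----------------------------------------------------------------

# Core of the MFTM / median / mean summary for one row of pairwise
# statistics. Assumes the RNG is already seeded by the caller. Returns the
# survivor positions so callers can summarize companion quantities (effect
# estimates, Welch dfs) over the same trim set.
summarize_row <- function(t_row, summarizer, trim_proportion) {
  defined <- which(!is.na(t_row))
  L <- length(defined)
  if (L < 3L) {
    stop("fewer than 3 defined pairwise statistics; baseline panel too small",
         call. = FALSE)
  }
  if (summarizer == "mean") {
    return(list(statistic = sqrt(2) * mean(t_row[defined]),
                pairing_index = NA_integer_,
                survivors = defined, defined = defined))
  }
  trim <- if (summarizer == "median") 0 else trim_proportion
  n_trim <- floor(trim * L)
  vals <- t_row[defined]
  if (n_trim > 0L) {
    # fold the sample at its median and drop the largest deviations:
    # ascending |t - Med|, ties broken toward keeping the earlier index
    dev <- abs(vals - stats::median(vals))
    ord <- order(dev, seq_len(L))
    keep <- ord[seq_len(L - n_trim)]
  } else {
    keep <- seq_len(L)
  }
  surv <- defined[keep]
  sv <- t_row[surv]
  stat <- sqrt(2) * stats::median(sv)
  L2 <- length(sv)
  o <- order(sv)
  if (L2 %% 2L == 1L) {
    pairing <- surv[o[(L2 + 1L) %/% 2L]]
  } else {
    cands <- surv[o[c(L2 %/% 2L, L2 %/% 2L + 1L)]]
    pairing <- cands[sample.int(2L, 1L)]
  }
  list(statistic = stat, pairing_index = pairing,
       survivors = surv, defined = defined)
}

#' Summarize a vector of pairwise t-statistics into one statistic
#'
#' Implements the MFTM (median fold trim median) summary: the sample is
#' folded at its median and the `floor(trim_proportion * L)` entries with
#' the largest absolute deviation from that median are removed (L = number
#' of defined entries; ties at the trim boundary keep the earlier index);
#' the statistic is sqrt(2) times the median of the survivors. Centring the
#' trim on the median keeps the summary unbiased for the oracle statistic:
#' it discards the pairwise statistics that disagree most with the
#' consensus — typically those formed against a truly DE baseline gene —
#' without shrinking large statistics toward zero. The pairing index is the position whose value attains the
#' median; when the survivor count is even, the statistic is the usual
#' midpoint of the two central order statistics and the pairing label is
#' drawn at random between the two central entries. `"median"` is MFTM with
#' no trim; `"mean"` is sqrt(2) times the mean of all defined entries, with
#' no pairing index.
#'
#' @param t_row Numeric vector of pairwise t-statistics (`NA` = undefined).
#' @param summarizer `"mftm"`, `"median"` or `"mean"`.
#' @param trim_proportion Trim fraction in \[0, 0.5) (MFTM only).
#' @param seed Optional seed for the pairing tie-break; the caller's RNG
#'   state is preserved.
#' @return A list with `statistic` and `pairing_index` (`NA` for `"mean"`).
#' @export
summarize_statistics <- function(t_row,
                                 summarizer = c("mftm", "median", "mean"),
                                 trim_proportion = 0.20, seed = NULL) {
  summarizer <- match.arg(summarizer)
  res <- with_seed(seed, summarize_row(t_row, summarizer, trim_proportion))
  res[c("statistic", "pairing_index")]
}

# Main entry point ------------------------------------------------------------

#' Super-delta differential expression test
#'
#' Runs the full pipeline on a log2 expression matrix: (1) draw a shared
#' baseline panel; (2) for every gene, compute two-sample t-statistics on
#' its per-sample differences against each baseline gene (its own row
#' excludes itself); (3) condense each gene's statistics with the configured
#' summarizer (MFTM by default); (4) convert to two-sided p-values under a t
#' distribution and adjust with Benjamini-Hochberg. Because the difference
#' step cancels per-sample noise exactly, the whole result is invariant to
#' adding an arbitrary constant to each sample.
#'
#' The effect estimate reported per gene is the same robust summary applied
#' to the raw group-difference of the pairwise deltas (no sqrt(2) factor):
#' for MFTM/median, the median over the surviving baselines of
#' `mean_A(delta) - mean_B(delta)`; for the mean summarizer, the mean over
#' all defined baselines.
#'
#' @param x Expression matrix (genes x samples), log2 units.
#' @param design A [group_design()].
#' @param config A [superdelta_config()].
#' @return An object of class `superdelta_result`: a list with `table` (a
#'   data.frame with columns gene_id, statistic, pairing_gene, effect_log2,
#'   p_raw, p_adj), `baseline_gene_ids`, `config`, `df`, and counts of
#'   undefined pairs/genes. Genes with fewer than 3 defined pairwise
#'   statistics get `NA` results and are excluded from the BH family.
#' @export
superdelta_test <- function(x, design, config = superdelta_config()) {
  validate_expression_matrix(x)
  if (!inherits(config, "superdelta_config")) {
    stop("config must be a superdelta_config object", call. = FALSE)
  }
  gene_ids <- rownames(x)
  m <- length(gene_ids)
  if (!identical(config$n_baseline, "all") && config$n_baseline + 1L > m) {
    stop("n_baseline + 1 exceeds the number of genes", call. = FALSE)
  }
  baselines <- select_baseline_genes(x, config$n_baseline, config$seed)
  tmat <- pairwise_t_stats(x, design, targets = gene_ids,
                           baselines = baselines,
                           variant = config$df_rule)
  df_attr <- attr(tmat, "df")
  idx <- design_indices(design, x)
  mdiff_t <- rowMeans(x[, idx$A, drop = FALSE]) -
    rowMeans(x[, idx$B, drop = FALSE])
  mdiff_b <- mdiff_t[baselines]
  N <- design$N

  stat <- rep(NA_real_, m)
  pairing <- rep(NA_character_, m)
  effect <- rep(NA_real_, m)
  df_out <- rep(NA_real_, m)
  n_failed <- 0L

  tmat_t <- t(tmat)  # column access is contiguous in the per-gene loop
  with_seed(substream_seed(config$seed, "pairing"), {
    for (i in seq_len(m)) {
      row <- tmat_t[, i]
      if (sum(!is.na(row)) < 3L) {
        n_failed <- n_failed + 1L
        next
      }
      s <- summarize_row(row, config$summarizer, config$trim_proportion)
      stat[i] <- s$statistic
      if (!is.na(s$pairing_index)) pairing[i] <- baselines[s$pairing_index]
      eff_pool <- if (config$summarizer == "mean") s$defined else s$survivors
      eff_vals <- mdiff_t[i] - mdiff_b[eff_pool]
      effect[i] <- if (config$summarizer == "mean") mean(eff_vals)
                   else stats::median(eff_vals)
      df_out[i] <- if (config$df_rule == "pooled") N - 2
                   else stats::median(df_attr[i, s$survivors])
    }
  })

  p_raw <- 2 * stats::pt(-abs(stat), df = df_out)
  p_adj <- bh_adjust(p_raw)
  structure(list(
    table = data.frame(gene_id = gene_ids, statistic = stat,
                       pairing_gene = pairing, effect_log2 = effect,
                       p_raw = p_raw, p_adj = p_adj,
                       stringsAsFactors = FALSE),
    baseline_gene_ids = baselines,
    config = config,
    df = if (config$df_rule == "pooled") N - 2 else df_out,
    n_undefined_pairs = attr(tmat, "n_undefined"),
    n_failed_genes = n_failed),
    class = "superdelta_result")
}

#' @export
print.superdelta_result <- function(x, ...) {
  cat("Super-delta result:", nrow(x$table), "genes,",
      length(x$baseline_gene_ids), "baseline genes, summarizer",
      sQuote(x$config$summarizer), "\n")
  n_sig <- sum(x$table$p_adj < 0.05, na.rm = TRUE)
  cat("  genes with BH-adjusted p < 0.05:", n_sig, "\n")
  if (x$n_failed_genes > 0L) {
    cat("  genes without enough defined pairwise statistics:",
        x$n_failed_genes, "(excluded from BH)\n")
  }
  invisible(x)
}
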