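#' Rank differences between two per-gene statistic lists
#'
#' Both result lists are ranked by descending absolute statistic (rank 1 =
#' most significant; ties broken lexicographically by gene ID for
#' determinism). For each gene in the reference list's top `top_k`, the
#' report gives its rank in both lists and the difference
#' `rank_other - rank_ref`; a large positive difference marks a gene the
#' other method considers much less significant.
#'
#' @param statistics_ref,statistics_other Named numeric vectors of per-gene
#'   statistics (names = gene IDs); both must cover the same gene universe.
#' @param top_k Size of the reference top list.
#' @param reference Label recording which method is the reference.
#' @return A data.frame (class `rank_diff_report`) with columns gene_id,
#'   rank_ref, rank_other, rank_difference, sorted by descending
#'   rank_difference; attribute `"reference"` records the direction.
#' @export
rank_difference <- function(statistics_ref, statistics_other, top_k,
                            reference = "reference") {
  if (is.null(names(statistics_ref)) || is.null(names(statistics_other))) {
    stop("statistic vectors must be named by gene ID", call. = FALSE)
  }
  if (!setequal(names(statistics_ref), names(statistics_other))) {
    stop("the two results cover different gene universes", call. = FALSE)
  }
  if (top_k > length(statistics_ref)) {
    stop("top_k exceeds the number of genes", call. = FALSE)
  }
  rank_by_abs <- function(stats_vec) {
    ids <- names(stats_vec)
    ord <- order(-abs(stats_vec), ids)
    stats::setNames(seq_along(ord), ids[ord])
  }
  r_ref <- rank_by_abs(statistics_ref)
  r_other <- rank_by_abs(statistics_other)
  top_ids <- names(r_ref)[seq_len(top_k)]
  out <- data.frame(gene_id = top_ids,
                    rank_ref = unname(r_ref[top_ids]),
                    rank_other = unname(r_other[top_ids]),
                    stringsAsFactors = FALSE)
  out$rank_difference <- out$rank_other - out$rank_ref
  out <- out[order(-out$rank_difference, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- reference
  class(out) <- c("rank_diff_report", "data.frame")
  out
}

#' Pairing-gene frequency table
#'
#' Counts how often each baseline gene was chosen as a pairing gene (the
#' empirical housekeeping gene of a target). Genes paired strictly more
#' than `min_times` times are reported ("candidate housekeeping genes"),
#' together with a histogram of times-paired versus number of genes.
#'
#' @param result A `superdelta_result` from the `mftm` or `median`
#'   summarizer (the `mean` summarizer defines no pairing genes).
#' @param min_times Report genes paired strictly more than this many times.
#' @return A list of class `pairing_frequency_table` with `counts` (a
#'   data.frame gene_id / times_paired, filtered and sorted descending) and
#'   `histogram` (data.frame times_paired / n_genes over all pairing genes).
#' @export
pairing_frequency <- function(result, min_times = 5L) {
  stopifnot(inherits(result, "superdelta_result"))
  if (result$config$summarizer == "mean") {
    stop("pairing frequencies are undefined for the mean summarizer",
         call. = FALSE)
  }
  paired <- result$table$pairing_gene
  paired <- paired[!is.na(paired)]
  tab <- table(paired)
  counts <- data.frame(gene_id = names(tab),
                       times_paired = as.integer(tab),
                       stringsAsFactors = FALSE)
  hist_tab <- table(counts$times_paired)
  histogram <- data.frame(times_paired = as.integer(names(hist_tab)),
                          n_genes = as.integer(hist_tab))
  keep <- counts$times_paired > min_times
  counts <- counts[keep, , drop = FALSE]
  counts <- counts[order(-counts$times_paired, counts$gene_id), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  structure(list(counts = counts, histogram = histogram,
                 n_paired_targets = length(paired),
                 min_times = min_times),
            class = "pairing_frequency_table")
}
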