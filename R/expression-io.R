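#' Read a gene expression matrix from delimited text
#'
#' Expression matrices are plain numeric matrices oriented genes x samples:
#' rownames are gene IDs, colnames are sample IDs, and values are log2
#' expression units. The expected file layout is a header row of sample IDs
#' and a first column of gene IDs (the header may or may not carry a label
#' for the gene-ID column).
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter; defaults to tab.
#' @return A validated numeric matrix (genes x samples) with row and column
#'   order preserved from the file.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) {
    stop("expression file must have a header row and at least one gene row",
         call. = FALSE)
  }
  header <- strsplit(lines[[1L]], delimiter, fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], delimiter, fixed = TRUE)
  n_fields <- lengths(body)
  if (length(unique(n_fields)) != 1L) {
    stop("ragged rows in expression file (unequal field counts)",
         call. = FALSE)
  }
  n_col <- n_fields[[1L]] - 1L
  # header may include a leading label for the gene-ID column
  sample_ids <- if (length(header) == n_col + 1L) header[-1L] else header
  if (length(sample_ids) != n_col) {
    stop("header does not match body width", call. = FALSE)
  }
  gene_ids <- vapply(body, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = n_col,
                 dimnames = list(gene_ids, sample_ids))
  for (r in seq_along(body)) {
    cells <- body[[r]][-1L]
    num <- suppressWarnings(as.numeric(cells))
    bad <- which(is.na(num) & !(cells %in% c("NA", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   cells[bad[1L]], gene_ids[r], sample_ids[bad[1L]]),
           call. = FALSE)
    }
    vals[r, ] <- num
  }
  validate_expression_matrix(vals)
  vals
}

#' Write a gene expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]; values are written with 10
#' significant digits so a write/read round trip is lossless at that
#' precision.
#'
#' @param x Numeric matrix, genes x samples, with dimnames.
#' @param path Output file path.
#' @param delimiter Field delimiter; defaults to tab.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path, delimiter = "\t") {
  validate_expression_matrix(x)
  header <- paste(c("gene_id", colnames(x)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(x)), function(r) {
    paste(c(rownames(x)[r], formatC(x[r, ], format = "g", digits = 10)),
          collapse = delimiter)
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Validate an expression matrix
#'
#' Checks the invariants every downstream function assumes: a numeric matrix
#' with unique, non-empty gene and sample IDs and no non-finite values.
#' Missing values are rejected rather than imputed.
#'
#' @param x Object to validate.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression data must be a numeric matrix (genes x samples)",
         call. = FALSE)
  }
  gene_ids <- rownames(x)
  sample_ids <- colnames(x)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene IDs: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]),
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a two-group sample design
#'
#' @param assignment Named character vector (or factor) mapping sample IDs to
#'   group labels `"A"` / `"B"`.
#' @return An object of class `group_design`: a list with elements
#'   `assignment` (named character), `n_A`, `n_B` and `N`.
#' @export
group_design <- function(assignment) {
  assignment <- vapply(assignment, as.character, character(1L))
  if (is.null(names(assignment)) || any(!nzchar(names(assignment)))) {
    stop("assignment must be named by sample ID", call. = FALSE)
  }
  if (anyDuplicated(names(assignment))) {
    stop("duplicate sample IDs in design", call. = FALSE)
  }
  if (!all(assignment %in% c("A", "B"))) {
    stop("group labels must be 'A' or 'B'; got: ",
         paste(setdiff(unique(assignment), c("A", "B")), collapse = ", "),
         call. = FALSE)
  }
  n_A <- sum(assignment == "A")
  n_B <- sum(assignment == "B")
  if (n_A < 2L || n_B < 2L) {
    stop("each group needs at least 2 samples (got n_A=", n_A,
         ", n_B=", n_B, ")", call. = FALSE)
  }
  structure(list(assignment = assignment, n_A = n_A, n_B = n_B,
                 N = n_A + n_B),
            class = "group_design")
}

#' Read a two-group design file
#'
#' The design file is two-column delimited text: sample ID, then group label
#' (`A` or `B`). The design must cover exactly the samples of the companion
#' expression matrix.
#'
#' @param path Path to the design file.
#' @param matrix Companion expression matrix (for sample-ID validation).
#' @param delimiter Field delimiter; defaults to tab.
#' @return A [group_design()] object.
#' @export
read_group_design <- function(path, matrix, delimiter = "\t") {
  validate_expression_matrix(matrix)
  tab <- utils::read.table(path, sep = delimiter, header = FALSE,
                           colClasses = "character",
                           col.names = c("sample_id", "group"))
  assignment <- stats::setNames(tab$group, tab$sample_id)
  missing <- setdiff(colnames(matrix), names(assignment))
  if (length(missing)) {
    stop("design is missing samples: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(assignment), colnames(matrix))
  if (length(unknown)) {
    stop("design lists unknown samples: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  group_design(assignment[colnames(matrix)])
}

# Column indices for each group, in matrix column order.
design_indices <- function(design, x) {
  if (!inherits(design, "group_design")) {
    stop("design must be a group_design object", call. = FALSE)
  }
  if (!setequal(names(design$assignment), colnames(x))) {
    stop("design samples do not match matrix samples", call. = FALSE)
  }
  grp <- design$assignment[colnames(x)]
  list(A = which(grp == "A"), B = which(grp == "B"))
}

# Per-row IQR under the declared quantile convention (type 7, linear
# interpolation between order statistics); used by iqr_filter and
# median-IQR normalization alike.
row_iqrs <- function(x) {
  apply(x, 1L, stats::IQR, type = 7L)
}

#' Filter genes by inter-quartile range
#'
#' Non-specific filtering: keeps the `ceil(keep_fraction * m)` genes with the
#' largest per-gene IQR across all samples. Original gene order is preserved
#' among survivors; ties at the cutoff are broken by original row order
#' (earlier rows kept first).
#'
#' @param x Expression matrix (genes x samples).
#' @param keep_fraction Fraction of genes to keep, in (0, 1].
#' @return The filtered expression matrix.
#' @export
iqr_filter <- function(x, keep_fraction) {
  validate_expression_matrix(x)
  if (ncol(x) < 2L) stop("need at least 2 samples to compute IQRs",
                         call. = FALSE)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1L ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stop("keep_fraction must be a single value in (0, 1]", call. = FALSE)
  }
  m <- nrow(x)
  n_keep <- as.integer(ceiling(keep_fraction * m))
  iqrs <- row_iqrs(x)
  # stable: among tied IQRs the earlier row wins
  keep <- sort(order(-iqrs, seq_len(m))[seq_len(n_keep)])
  x[keep, , drop = FALSE]
}
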