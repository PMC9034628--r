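#' Construct an expression dataset
#'
#' The core container of the package: a genes-by-samples matrix of (by
#' convention log2-scale) expression values, with unique gene and sample
#' identifiers and, optionally, a per-sample CMS label.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   column.
#' @param labels Optional character vector of per-sample CMS labels
#'   (`"CMS1"`..`"CMS4"`), aligned with `sample_ids`.
#' @param log_scale Logical; `TRUE` declares that `values` are already on the
#'   log2 scale. If `FALSE` the values are transformed by `log2(x + 1)` at
#'   construction, so a stored dataset is always log2-scale.
#'
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `labels` (possibly `NULL`).
#' @export
expression_dataset <- function(values, gene_ids, sample_ids, labels = NULL,
                               log_scale = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene_ids length (", length(gene_ids),
         ") does not match row count (", nrow(values), ")")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length (", length(sample_ids),
         ") does not match column count (", ncol(values), ")")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (!isTRUE(log_scale)) {
    if (any(values < 0))
      stop("negative values are incompatible with log_scale = FALSE")
    values <- log2(values + 1)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != length(sample_ids))
      stop("labels length does not match number of samples")
    bad <- setdiff(unique(labels), cms_levels())
    if (length(bad))
      stop("labels must be one of ", paste(cms_levels(), collapse = "/"),
           "; found: ", paste(bad, collapse = ", "))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         labels = labels),
    class = "ExpressionDataset"
  )
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$labels)) {
    tab <- table(factor(x$labels, levels = cms_levels()))
    cat("labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  } else {
    cat("labels: none\n")
  }
  invisible(x)
}

#' Subset an expression dataset by sample
#'
#' @param ds An `ExpressionDataset`.
#' @param idx Integer or logical index, or character sample ids.
#' @return An `ExpressionDataset` restricted to the selected samples.
#' @export
subset_samples <- function(ds, idx) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.character(idx)) idx <- match(idx, ds$sample_ids)
  expression_dataset(
    ds$values[, idx, drop = FALSE],
    ds$gene_ids,
    ds$sample_ids[idx],
    labels = if (is.null(ds$labels)) NULL else ds$labels[idx]
  )
}

#' Subset an expression dataset by gene
#'
#' @param ds An `ExpressionDataset`.
#' @param idx Integer or logical index, or character gene ids.
#' @return An `ExpressionDataset` restricted to the selected genes.
#' @export
subset_genes <- function(ds, idx) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.character(idx)) {
    miss <- setdiff(idx, ds$gene_ids)
    if (length(miss))
      stop("gene id(s) not in dataset: ", paste(miss, collapse = ", "))
    idx <- match(idx, ds$gene_ids)
  }
  expression_dataset(
    ds$values[idx, , drop = FALSE],
    ds$gene_ids[idx],
    ds$sample_ids,
    labels = ds$labels
  )
}

#' Read an expression matrix (and labels) from delimited text
#'
#' The matrix file follows the GEO series-matrix convention: a header row of
#' sample ids and a first column of gene ids, genes in rows. The optional
#' label file is two-column delimited text with a header
#' (`sample_id`, `label`) mapping each sample id to its CMS label; labels are
#' aligned to the matrix columns by id, never by file order.
#'
#' @param matrix_path Path to the expression matrix file.
#' @param label_path Optional path to the label file.
#' @param delimiter Field delimiter, default tab.
#' @param log_scale Logical; `FALSE` applies `log2(x + 1)` on load.
#' @param transpose Logical; set `TRUE` if the file stores samples in rows.
#' @param na_action `"error"` (default) rejects a matrix with non-finite
#'   entries; `"drop"` removes the offending gene rows with a warning.
#' @return An `ExpressionDataset`.
#' @export
read_expression <- function(matrix_path, label_path = NULL, delimiter = "\t",
                            log_scale = TRUE, transpose = FALSE,
                            na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  tab <- utils::read.table(matrix_path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2L) stop("matrix file must have gene ids plus >=1 sample")
  gene_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  sample_ids <- colnames(tab)[-1L]
  if (transpose) {
    values <- t(values)
    tmp <- gene_ids; gene_ids <- sample_ids; sample_ids <- tmp
  }
  if (!all(is.finite(values))) {
    if (na_action == "drop") {
      bad <- !apply(is.finite(values), 1L, all)
      warning("dropping ", sum(bad), " gene row(s) with non-finite values")
      values <- values[!bad, , drop = FALSE]
      gene_ids <- gene_ids[!bad]
    } else {
      stop("expression matrix contains non-finite values ",
           "(use na_action = \"drop\" to remove the rows)")
    }
  }
  labels <- NULL
  if (!is.null(label_path)) {
    lab <- utils::read.table(label_path, header = TRUE, sep = delimiter,
                             stringsAsFactors = FALSE, comment.char = "",
                             quote = "\"")
    if (ncol(lab) < 2L) stop("label file must have two columns")
    lab_ids <- as.character(lab[[1L]])
    if (anyDuplicated(lab_ids))
      stop("duplicate sample id(s) in label file: ",
           paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "))
    unknown <- setdiff(lab_ids, sample_ids)
    if (length(unknown))
      stop("label file refers to unknown sample id(s): ",
           paste(unknown, collapse = ", "))
    m <- match(sample_ids, lab_ids)
    if (anyNA(m))
      stop("sample(s) missing a label: ",
           paste(sample_ids[is.na(m)], collapse = ", "))
    labels <- as.character(lab[[2L]])[m]
  }
  expression_dataset(values, gene_ids, sample_ids, labels = labels,
                     log_scale = log_scale)
}

#' Write an expression dataset to delimited text
#'
#' @param ds An `ExpressionDataset`.
#' @param matrix_path Output path for the matrix.
#' @param label_path Optional output path for a two-column label file.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, `ds`.
#' @export
write_expression <- function(ds, matrix_path, label_path = NULL,
                             delimiter = "\t") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  out <- data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, matrix_path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  if (!is.null(label_path)) {
    if (is.null(ds$labels)) stop("dataset has no labels to write")
    utils::write.table(
      data.frame(sample_id = ds$sample_ids, label = ds$labels),
      label_path, sep = delimiter, quote = FALSE, row.names = FALSE
    )
  }
  invisible(ds)
}

#' Construct a gene set with per-pair provenance
#'
#' A `GeneSet` records which pairwise subtype comparison contributed each
#' gene. The flattened `gene_ids` ordering is deterministic: genes are sorted
#' lexicographically within each pair's contribution, pairs are visited in the
#' fixed order of [cms_pairs()], and a gene is kept at its first occurrence.
#'
#' @param provenance Named list mapping a pair label (e.g. `"CMS1_vs_CMS2"`)
#'   to the character vector of genes that comparison contributed.
#' @return An object of class `GeneSet` with elements `gene_ids` and
#'   `provenance`.
#' @export
gene_set <- function(provenance) {
  stopifnot(is.list(provenance))
  canonical <- vapply(cms_pairs(), pair_label, character(1))
  extra <- setdiff(names(provenance), canonical)
  if (length(extra))
    stop("unknown pair label(s): ", paste(extra, collapse = ", "))
  ordered_prov <- lapply(canonical, function(lb) {
    g <- provenance[[lb]]
    if (is.null(g)) character(0) else sort(unique(as.character(g)),
                                           method = "radix")
  })
  names(ordered_prov) <- canonical
  ids <- unique(unlist(ordered_prov, use.names = FALSE))
  structure(list(gene_ids = ids, provenance = ordered_prov),
            class = "GeneSet")
}

#' @export
print.GeneSet <- function(x, ...) {
  cat("GeneSet with", length(x$gene_ids), "genes\n")
  for (lb in names(x$provenance))
    cat(" ", lb, ":", length(x$provenance[[lb]]), "\n")
  invisible(x)
}

as_gene_ids <- function(genes) {
  if (inherits(genes, "GeneSet")) genes$gene_ids else as.character(genes)
}

#' Reorder a dataset's rows to a gene set
#'
#' Returns a dataset whose rows are exactly the gene set, in its order. Genes
#' absent from the input are handled according to `missing_policy`:
#' `"error"` aborts listing the missing genes, `"fill_zero"` inserts all-zero
#' rows, and `"fill_mean"` inserts each gene's training-set mean (which must
#' be supplied via `gene_means`, e.g. from a trained model bundle).
#'
#' @param ds An `ExpressionDataset`.
#' @param genes A `GeneSet` or character vector of gene ids (non-empty).
#' @param missing_policy One of `"error"`, `"fill_zero"`, `"fill_mean"`.
#' @param gene_means Named numeric vector of per-gene means used by
#'   `"fill_mean"`.
#' @return An `ExpressionDataset` with rows `genes` in order.
#' @export
align_to_genes <- function(ds, genes,
                           missing_policy = c("error", "fill_zero",
                                              "fill_mean"),
                           gene_means = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  missing_policy <- match.arg(missing_policy)
  ids <- as_gene_ids(genes)
  if (!length(ids)) stop("gene set is empty")
  m <- match(ids, ds$gene_ids)
  missing <- ids[is.na(m)]
  if (length(missing) && missing_policy == "error")
    stop("gene(s) absent from dataset: ", paste(missing, collapse = ", "))
  vals <- matrix(0, nrow = length(ids), ncol = ncol(ds$values))
  present <- !is.na(m)
  vals[present, ] <- ds$values[m[present], , drop = FALSE]
  if (length(missing) && missing_policy == "fill_mean") {
    if (is.null(gene_means))
      stop("missing_policy = \"fill_mean\" requires gene_means")
    mm <- gene_means[missing]
    if (anyNA(mm))
      stop("gene_means lacks entries for: ",
           paste(missing[is.na(mm)], collapse = ", "))
    vals[!present, ] <- matrix(mm, nrow = length(missing),
                               ncol = ncol(vals))
  }
  expression_dataset(vals, ids, ds$sample_ids, labels = ds$labels)
}
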