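#' Expression matrix container
#'
#' A gene-by-sample expression matrix carrying its current scale. Matrices are
#' read as TPM (`transform = "tpm"`) and must be moved to the canonical
#' analysis scale log2(TPM+1) with [log_transform()] before any downstream
#' step; all analysis functions refuse raw TPM so the two scales can never be
#' mixed silently.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene identifiers) and colnames (sample identifiers).
#' @param transform `"tpm"` or `"log2p1"`.
#' @return An object of class `expr_matrix`: the matrix with a `transform`
#'   attribute. Gene and sample identifiers are opaque case-sensitive strings.
#' @export
expr_matrix <- function(values, transform = c("tpm", "log2p1")) {
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (transform == "tpm" && any(values < 0))
    stop("TPM values must be non-negative")
  structure(values, transform = transform, class = c("expr_matrix", "matrix"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "transform")))
  invisible(x)
}

#' Current scale of an expression matrix
#' @param m an `expr_matrix`.
#' @return `"tpm"` or `"log2p1"`.
#' @export
expr_transform <- function(m) attr(m, "transform")

# Internal guard used by every analysis entry point.
stopifnot_log2p1 <- function(m) {
  if (!inherits(m, "expr_matrix"))
    stop("expected an expr_matrix")
  if (!identical(attr(m, "transform"), "log2p1"))
    stop("expression must be on the log2(TPM+1) scale; call log_transform() first")
  invisible(m)
}

#' Read a delimited expression matrix
#'
#' Expects one header row of sample identifiers and one leading column of gene
#' identifiers. Duplicate gene rows are collapsed to their per-cell maximum
#' with a warning. The result is on the TPM scale.
#'
#' @param path file path.
#' @param delimiter field delimiter, default tab.
#' @param orientation `"genes_by_samples"` (default) or `"samples_by_genes"`
#'   for a transposed file; the returned object is always genes x samples.
#' @return An [expr_matrix()] with `transform = "tpm"`.
#' @export
read_expression <- function(path, delimiter = "\t",
                            orientation = c("genes_by_samples",
                                            "samples_by_genes")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, row.names = NULL,
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L) stop("empty expression matrix: ", path)
  ids <- df[[1L]]
  num <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(num) <- "double")
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1L]], colnames(num)[bad[2L]], path))
  }
  rownames(num) <- ids
  if (orientation == "samples_by_genes") num <- t(num)
  if (anyDuplicated(rownames(num))) {
    dups <- unique(rownames(num)[duplicated(rownames(num))])
    warning("collapsing ", length(dups),
            " duplicated gene row(s) by per-cell maximum: ",
            paste(utils::head(dups, 5L), collapse = ", "))
    num <- do.call(rbind, lapply(split(seq_len(nrow(num)), rownames(num)),
                                 function(i) {
                                   apply(num[i, , drop = FALSE], 2L, max)
                                 }))
    # split() sorts by name; keep first-appearance order of the input file
    num <- num[unique(ids[ids %in% rownames(num)]), , drop = FALSE]
  }
  expr_matrix(num, transform = "tpm")
}

#' Write an expression matrix as TSV
#' @param m an `expr_matrix`.
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transform TPM to log2(TPM+1)
#'
#' The canonical analysis scale. Applying it twice is an error so a matrix can
#' never be silently double-transformed.
#'
#' @param m an `expr_matrix` with `transform = "tpm"`.
#' @return An `expr_matrix` with `transform = "log2p1"`.
#' @export
log_transform <- function(m) {
  if (!inherits(m, "expr_matrix")) stop("expected an expr_matrix")
  if (identical(attr(m, "transform"), "log2p1"))
    stop("matrix is already log2(TPM+1)-transformed")
  expr_matrix(log2(unclass(m) + 1), transform = "log2p1")
}
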