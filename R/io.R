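#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-delimited `name<TAB>description<TAB>`
#' genes... The description column is ignored. Set order follows the file.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene identifiers
#'   (class `gene_set_collection`). Set names are unique; sets are non-empty.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 gene",
                   i, length(fields)))
    nms[i] <- fields[1L]
    sets[[i]] <- fields[-(1:2)][nzchar(fields[-(1:2)])]
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets named list of gene identifier vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

# canonical pyrimidine-strand substitution classes and 96 trinucleotide
# contexts, ordered substitution-major then 5' base then 3' base
SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context labels
#'
#' Labels of the form `A[C>T]G`: pyrimidine-strand substitution flanked by the
#' 5' and 3' reference bases. Ordering is substitution-major
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' base, then 3' base, each A,C,G,T.
#'
#' @return Character vector of length 96.
#' @export
context_labels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(SUBSTITUTION_CLASSES, function(s) {
    as.vector(t(outer(bases, bases, function(p5, p3)
      paste0(p5, "[", s, "]", p3))))
  }))
}

#' Read a MAF-like somatic mutation table
#'
#' Tab-delimited with columns `sample`, `gene`, `vaf`, `ref`, `alt` and
#' optionally `context` (a 96-category label such as `A[C>T]G`). Rows failing
#' validation (VAF outside (0,1], malformed context) are dropped with a
#' per-row reason in the `rejected` attribute.
#'
#' @param path file path.
#' @return data.frame of class `mutation_catalog` with columns sample, gene,
#'   vaf, ref, alt, substitution, context, is_coding.
#' @export
read_mutations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "gene", "vaf", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         "; expected schema: sample, gene, vaf, ref, alt[, context, is_coding]")
  if (!"context" %in% names(df)) df$context <- NA_character_
  if (!"is_coding" %in% names(df)) df$is_coding <- 1L
  df$vaf <- suppressWarnings(as.numeric(df$vaf))
  reasons <- rep(NA_character_, nrow(df))
  bad_vaf <- is.na(df$vaf) | df$vaf <= 0 | df$vaf > 1
  reasons[bad_vaf] <- "vaf out of range"
  known <- context_labels()
  has_ctx <- !is.na(df$context) & nzchar(df$context)
  bad_ctx <- has_ctx & !(df$context %in% known) & is.na(reasons)
  reasons[bad_ctx] <- "unrecognized trinucleotide context"
  keep <- is.na(reasons)
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep])
  if (nrow(rejected))
    warning(nrow(rejected), " mutation row(s) rejected; see attr(x, 'rejected')")
  out <- df[keep, , drop = FALSE]
  out$substitution <- ifelse(!is.na(out$context) & nzchar(out$context),
                             substr(out$context, 3L, 5L), NA_character_)
  rownames(out) <- NULL
  structure(out, rejected = rejected,
            class = c("mutation_catalog", "data.frame"))
}

#' Read a clinical table
#'
#' Tab-delimited per-sample outcomes and covariates. A schema maps file
#' columns to the canonical names `sample`, `os_time`, `os_event`, `rfs_time`,
#' `rfs_event`, `response`; unmapped columns are kept as covariates. The
#' derived `responder` column is 1 for CR/PR, 0 for SD/PD, NA when response is
#' missing. Missing values stay `NA` and are never imputed; analyses drop
#' incomplete cases for the variables they use.
#'
#' @param path file path.
#' @param schema named character vector `canonical = file_column`; by default
#'   columns are assumed to already carry canonical names.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path, schema = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps '", canon, "' to missing column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  if (!"sample" %in% names(df))
    stop("clinical table missing mandatory column 'sample'")
  as_clinical(df)
}

#' Validate and type a clinical data.frame
#' @param df data.frame with a `sample` column and any of the canonical
#'   outcome columns.
#' @return data.frame of class `clinical_table`.
#' @export
as_clinical <- function(df) {
  if (anyDuplicated(df$sample))
    stop("duplicate sample identifiers in clinical table")
  for (tm in intersect(c("os_time", "rfs_time"), names(df))) {
    df[[tm]] <- as.numeric(df[[tm]])
    if (any(df[[tm]] < 0, na.rm = TRUE)) stop(tm, " contains negative times")
  }
  for (ev in intersect(c("os_event", "rfs_event"), names(df))) {
    df[[ev]] <- as.integer(df[[ev]])
    if (!all(df[[ev]] %in% c(0L, 1L, NA_integer_)))
      stop(ev, " must be 0/1")
  }
  if ("response" %in% names(df)) {
    ok <- df$response %in% c("CR", "PR", "SD", "PD") | is.na(df$response)
    if (!all(ok))
      stop("unrecognized response value(s): ",
           paste(unique(df$response[!ok]), collapse = ", "))
    df$responder <- ifelse(is.na(df$response), NA_integer_,
                           as.integer(df$response %in% c("CR", "PR")))
  }
  structure(df, class = c("clinical_table", "data.frame"))
}

#' Read a clonotype count table
#'
#' Tab-delimited with columns `sample`, `receptor` (BCR or TCR), `clonotype`,
#' `count`. Rows with non-positive or non-integer counts are rejected with a
#' reason in the `rejected` attribute.
#'
#' @param path file path.
#' @return data.frame of class `clonotype_table`.
#' @export
read_clonotypes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "receptor", "clonotype", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clonotype table missing column(s): ", paste(miss, collapse = ", "),
         "; expected schema: sample, receptor, clonotype, count")
  df$count <- suppressWarnings(as.numeric(df$count))
  reasons <- rep(NA_character_, nrow(df))
  bad <- is.na(df$count) | df$count < 1 | df$count != round(df$count)
  reasons[bad] <- "count must be a positive integer"
  bad_r <- !df$receptor %in% c("BCR", "TCR") & is.na(reasons)
  reasons[bad_r] <- "receptor must be BCR or TCR"
  keep <- is.na(reasons)
  rejected <- data.frame(row = which(!keep), reason = reasons[!keep])
  if (nrow(rejected))
    warning(nrow(rejected), " clonotype row(s) rejected; see attr(x, 'rejected')")
  out <- df[keep, , drop = FALSE]
  out$count <- as.integer(out$count)
  rownames(out) <- NULL
  structure(out, rejected = rejected,
            class = c("clonotype_table", "data.frame"))
}
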