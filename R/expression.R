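#' Expression matrix with condition labels
#'
#' Container for a normalized log2 expression matrix (probes x samples)
#' together with a sample-to-condition assignment and an optional
#' probe-to-gene-symbol map. All downstream computation is probe-level;
#' gene symbols are annotations.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). No missing values allowed.
#' @param conditions named character vector mapping every sample id to a
#'   condition label.
#' @param gene_symbols optional named character vector mapping probe ids to
#'   gene symbols (many probes may share a symbol).
#' @return An object of class `bake_expr` with elements `values`,
#'   `conditions`, `gene_symbols`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(x, setNames(c("A", "A", "B", "B"), colnames(x)))
#' @export
expression_matrix <- function(values, conditions, gene_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  probes <- rownames(values)
  samples <- colnames(values)
  if (is.null(probes) || is.null(samples))
    stop("`values` must have probe rownames and sample colnames")
  if (anyDuplicated(probes))
    stop("duplicate probe id(s): ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values; ",
         "missing values are rejected, not imputed")
  conditions <- vapply(conditions, as.character, character(1))
  missing_annot <- setdiff(samples, names(conditions))
  if (length(missing_annot))
    stop("sample(s) missing from condition annotation: ",
         paste(missing_annot, collapse = ", "))
  conditions <- conditions[samples]
  if (!is.null(gene_symbols)) {
    gene_symbols <- vapply(gene_symbols, as.character, character(1))
    gene_symbols <- gene_symbols[intersect(names(gene_symbols), probes)]
  }
  structure(list(values = values, conditions = conditions,
                 gene_symbols = gene_symbols),
            class = "bake_expr")
}

#' @export
print.bake_expr <- function(x, ...) {
  cat(sprintf("bake_expr: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$conditions)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.bake_expr <- function(x) dim(x$values)

#' Probe ids of an expression matrix
#' @param m a [expression_matrix()] object.
#' @return character vector of probe ids.
#' @export
probes <- function(m) rownames(m$values)

#' Sample ids of one or more conditions
#' @param m a [expression_matrix()] object.
#' @param conditions condition labels; default all.
#' @return character vector of sample ids.
#' @export
samples_of <- function(m, conditions = NULL) {
  if (is.null(conditions)) return(colnames(m$values))
  unknown <- setdiff(conditions, unique(m$conditions))
  if (length(unknown))
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  colnames(m$values)[m$conditions %in% conditions]
}

#' Read an expression matrix and its sample annotation from delimited text
#'
#' The matrix file is TSV with probe ids in the first column and sample ids
#' in the header; the GCT dialect (two extra header lines, `Description`
#' column) is detected and accepted. The annotation file is TSV with columns
#' `sample` and `condition` (header optional when exactly two columns).
#'
#' @param path path to the expression TSV/GCT file.
#' @param annotation path to the sample-annotation TSV.
#' @param gene_symbols optional named character vector (probe -> symbol) or
#'   path to a two-column TSV (probe, symbol).
#' @return a [expression_matrix()] object; probe order is preserved.
#' @export
read_expression <- function(path, annotation, gene_symbols = NULL) {
  lines <- readLines(path)
  skip <- 0L
  gct <- length(lines) >= 1 && startsWith(lines[[1]], "#1.2")
  if (gct) skip <- 2L
  df <- read.delim(path, header = TRUE, sep = "\t", skip = skip,
                   check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression file needs a probe column and >=1 sample")
  probe_ids <- df[[1]]
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id(s) in ", path, ": ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  data_cols <- 2:ncol(df)
  if (gct && tolower(names(df)[2]) == "description") data_cols <- data_cols[-1]
  vals <- as.matrix(df[, data_cols, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at probe '%s', sample '%s' (row %d, column %d)",
                 probe_ids[bad[1]], colnames(vals)[bad[2]], bad[1], bad[2]))
  }
  dimnames(num) <- list(probe_ids, colnames(vals))
  ann <- read.delim(annotation, header = TRUE, sep = "\t",
                    check.names = FALSE, colClasses = "character")
  if (!all(c("sample", "condition") %in% names(ann))) {
    if (ncol(ann) == 2) names(ann) <- c("sample", "condition")
    else stop("annotation file must have columns 'sample' and 'condition'")
  }
  cond <- setNames(ann$condition, ann$sample)
  missing_annot <- setdiff(colnames(num), names(cond))
  if (length(missing_annot))
    stop("sample(s) in matrix missing from annotation: ",
         paste(missing_annot, collapse = ", "))
  if (is.character(gene_symbols) && length(gene_symbols) == 1 &&
      file.exists(gene_symbols)) {
    gm <- read.delim(gene_symbols, header = FALSE, sep = "\t",
                     colClasses = "character")
    gene_symbols <- setNames(gm[[2]], gm[[1]])
  }
  expression_matrix(num, cond, gene_symbols)
}

#' Write an expression matrix (and optionally its annotation) as TSV
#'
#' @param m a [expression_matrix()] object.
#' @param path output path for the matrix TSV.
#' @param annotation optional output path for the sample/condition TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, annotation = NULL) {
  df <- data.frame(probe = rownames(m$values), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    ann <- data.frame(sample = colnames(m$values),
                      condition = unname(m$conditions))
    write.table(ann, annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Quantile-normalize the sample columns of an expression matrix
#'
#' Makes the empirical distribution of every sample identical (each column's
#' sorted values become the row-wise mean of all sorted columns); tied values
#' receive the average of the tied quantile values. Delegates to
#' [limma::normalizeQuantiles()]. Idempotent to numerical precision.
#'
#' @param m a [expression_matrix()] object with at least two samples.
#' @return a quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(m) {
  if (ncol(m$values) < 2)
    stop("quantile normalization needs at least 2 samples")
  v <- limma::normalizeQuantiles(m$values, ties = TRUE)
  dimnames(v) <- dimnames(m$values)
  expression_matrix(v, m$conditions, m$gene_symbols)
}
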