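#' Expression matrix container
#'
#' A light container for a non-negative feature-by-sample expression matrix
#' with an explicit unit tag, so downstream stages can refuse input on the
#' wrong scale (e.g. the CPM filter requires raw counts).
#'
#' @param values numeric matrix, rows = features, columns = samples. Row and
#'   column names are required and must be unique; all entries must be
#'   non-negative and finite.
#' @param unit one of `"counts"`, `"cpm"`, `"normalized"`, `"log2rpm"`.
#' @return an object of class `ExpressionMatrix`: the matrix with a `unit`
#'   attribute.
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- expression_matrix(m, "counts")
#' em_unit(em)
#' @export
expression_matrix <- function(values,
                              unit = c("counts", "cpm", "normalized", "log2rpm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must carry feature (row) and sample (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (any(!is.finite(values)))
    stop("non-finite values in expression matrix")
  # log-scale data may be negative; linear-scale data may not
  if (unit != "log2rpm" && any(values < 0))
    stop("negative values not allowed for unit '", unit, "'")
  structure(values, unit = unit, class = c("ExpressionMatrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
em_unit <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  attr(x, "unit")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [unit: %s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  k <- min(5L, nrow(x)); j <- min(5L, ncol(x))
  print(unclass(x)[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(x) > k || ncol(x) > j) cat("...\n")
  invisible(x)
}

# internal: rebuild with same class/unit after a matrix operation
em_like <- function(values, template, unit = attr(template, "unit")) {
  expression_matrix(values, unit)
}

#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose header row names the samples and whose
#' first column holds feature ids. Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param unit unit tag to attach (see [expression_matrix()]).
#' @return an `ExpressionMatrix`.
#' @export
read_expression_matrix <- function(path, unit = "counts") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a feature-id column plus >= 1 sample column: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric entries in ", path)
  rownames(vals) <- ids
  expression_matrix(vals, unit)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]; full double precision is kept
#' (values are written with 15 significant digits) so that a write/read
#' round-trip reproduces the matrix up to float formatting.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @param id_column name for the feature-id column in the header.
#' @export
write_expression_matrix <- function(x, path, id_column = "feature_id") {
  stopifnot(inherits(x, "ExpressionMatrix"))
  df <- data.frame(id = rownames(x), format(unclass(x), digits = 15, trim = TRUE,
                                            scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample-to-condition assignment
#'
#' @param x a named character vector or factor (names = sample ids, values =
#'   condition labels), or a two-column data.frame (sample_id, condition).
#' @param reference optional label to use as the reference condition; by
#'   default the first level in sort order.
#' @return a named factor with exactly two levels, reference first. Each
#'   condition must contain at least two samples (within-condition sample
#'   pairs are needed for the empirical noise distribution).
#' @export
sample_groups <- function(x, reference = NULL) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) stop("expected columns sample_id, condition")
    v <- as.character(x[[2]]); names(v) <- as.character(x[[1]]); x <- v
  }
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sample ids must be unique and named")
  labs <- sort(unique(as.character(x)))
  if (length(labs) != 2)
    stop("exactly two condition labels required, got: ", paste(labs, collapse = ", "))
  if (!is.null(reference)) {
    if (!reference %in% labs) stop("reference label not present: ", reference)
    labs <- c(reference, setdiff(labs, reference))
  }
  f <- factor(as.character(x), levels = labs)
  names(f) <- names(x)
  n <- table(f)
  if (any(n < 2))
    stop("each condition needs >= 2 samples; got ",
         paste(sprintf("%s=%d", names(n), n), collapse = ", "))
  f
}

#' Read a sample metadata table
#'
#' TSV with columns `sample_id` and `condition` (extra columns ignored).
#'
#' @inheritParams read_expression_matrix
#' @inheritParams sample_groups
#' @export
read_sample_groups <- function(path, reference = NULL) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  sample_groups(df[, need], reference = reference)
}
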