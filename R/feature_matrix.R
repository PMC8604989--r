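#' Construct a per-cell feature matrix
#'
#' A `feature_matrix` is a plain numeric matrix with cells as rows and
#' features as columns, carrying unique cell identifiers (rownames), unique
#' feature names (colnames) and a modality tag. It is the basic container
#' for both views of a Patch-seq style experiment. Note that the matrix is
#' stored cells-by-features; methods papers often write the transpose
#' (features-by-cells) -- the orientation here follows single-cell file
#' conventions.
#'
#' @param values numeric matrix, cells in rows and features in columns.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   existing rownames.
#' @param feature_names character vector of unique feature names; defaults to
#'   existing colnames.
#' @param modality one of `"electrophysiology"`, `"expression"`, `"latent"`.
#' @return a `feature_matrix` object (a numeric matrix with attributes).
#' @examples
#' m <- feature_matrix(matrix(1:6, 3, 2), paste0("c", 1:3), c("g1", "g2"),
#'                     "expression")
#' dim(m)
#' @export
feature_matrix <- function(values, cell_ids = rownames(values),
                           feature_names = colnames(values),
                           modality = c("expression", "electrophysiology",
                                        "latent")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(cell_ids)) stop("cell_ids are required")
  if (is.null(feature_names)) stop("feature_names are required")
  cell_ids <- as.character(cell_ids)
  feature_names <- as.character(feature_names)
  if (nrow(values) != length(cell_ids))
    stop("number of rows does not match length of cell_ids")
  if (ncol(values) != length(feature_names))
    stop("number of columns does not match length of feature_names")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  dimnames(values) <- list(cell_ids, feature_names)
  structure(values, modality = modality, class = c("feature_matrix", "matrix",
                                                   "array"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d cells x %d features\n",
              attr(x, "modality"), nrow(x), ncol(x)))
  if (anyNA(x)) cat(sprintf("  %d missing values\n", sum(is.na(x))))
  invisible(x)
}

#' @export
`[.feature_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- feature_matrix(out, modality = attr(x, "modality"))
  out
}

modality_of <- function(m) attr(m, "modality")

is_feature_matrix <- function(x) inherits(x, "feature_matrix")

#' Read a feature matrix from disk
#'
#' Supported formats: delimited text (`csv`, `tsv`) with a header row of
#' feature names and the cell identifier in the first column, and sparse
#' MatrixMarket coordinate files (`mtx`) with sidecar `<stem>_rows.txt`
#' (cell ids) and `<stem>_cols.txt` (feature names), one name per line.
#' MTX entries absent from the triplet list are zeros.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; default guessed from the
#'   file extension.
#' @param modality modality tag attached to the result.
#' @return a [feature_matrix].
#' @export
read_feature_matrix <- function(path, format = NULL,
                                modality = c("expression",
                                             "electrophysiology", "latent")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("csv", "tsv", "mtx"))
      stop("cannot guess format from extension: ", path)
  }
  format <- match.arg(format, c("csv", "tsv", "mtx"))
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    rows_file <- paste0(stem, "_rows.txt")
    cols_file <- paste0(stem, "_cols.txt")
    if (!file.exists(rows_file) || !file.exists(cols_file))
      stop("mtx sidecar files not found: ", rows_file, ", ", cols_file)
    m <- as.matrix(Matrix::readMM(path))
    cell_ids <- readLines(rows_file)
    feature_names <- readLines(cols_file)
    return(feature_matrix(m, cell_ids, feature_names, modality))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("malformed header: need id column plus features")
  if (nrow(df) == 0) stop("no cells in ", path)
  ids <- df[[1]]
  vals <- vapply(df[-1], function(col) suppressWarnings(as.numeric(col)),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, colnames(df)[-1]))
  bad <- is.finite(vals) != !is.na(vals)  # Inf/-Inf present in file
  if (any(bad)) vals[bad] <- NA_real_
  feature_matrix(vals, ids, colnames(df)[-1], modality)
}

#' Write a feature matrix to disk
#'
#' Inverse of [read_feature_matrix()] for the delimited formats; values are
#' written with full double precision so a write/read round trip is exact.
#'
#' @param m a [feature_matrix].
#' @param path output path.
#' @param format `"csv"` or `"tsv"`; default from extension.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, format = NULL) {
  stopifnot(is_feature_matrix(m))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("csv", "tsv"))
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("cell", colnames(m)), collapse = sep), con)
  body <- apply(format(m, digits = 17, trim = TRUE, scientific = TRUE), 1,
                paste, collapse = sep)
  writeLines(paste(rownames(m), body, sep = sep), con)
  invisible(path)
}

#' Read a two-column cell label file
#'
#' @param path TSV with columns `cell_id` and `label` (no header required;
#'   a header line `cell_id<TAB>label` is tolerated).
#' @return named character vector, names are cell ids.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) != 2) stop("label file must have two columns")
  if (identical(tolower(df[1, 1]), "cell_id")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Pair the two modality matrices into one dataset
#'
#' A `mm_dataset` holds the electrophysiology and expression views of the
#' same cells in the same order -- the one-to-one correspondence that a
#' Patch-seq experiment provides by construction.
#'
#' @param e electrophysiology [feature_matrix].
#' @param t expression [feature_matrix].
#' @param labels optional named character vector of per-cell labels
#'   (e.g. transcriptomic types).
#' @return an object of class `mm_dataset`.
#' @export
mm_dataset <- function(e, t, labels = NULL) {
  stopifnot(is_feature_matrix(e), is_feature_matrix(t))
  if (!identical(rownames(e), rownames(t)))
    stop("the two modalities must cover the same cells in the same order")
  if (!is.null(labels)) {
    labels <- labels[rownames(e)]
    names(labels) <- rownames(e)
  }
  structure(list(e = e, t = t, labels = labels), class = "mm_dataset")
}

#' @export
print.mm_dataset <- function(x, ...) {
  cat(sprintf("mm_dataset: %d cells; e: %d features, t: %d features%s\n",
              nrow(x$e), ncol(x$e), ncol(x$t),
              if (is.null(x$labels)) "" else
                sprintf("; %d labelled", sum(!is.na(x$labels)))))
  invisible(x)
}

#' Drop incomplete features and cells, and pair the two views
#'
#' Features whose missing fraction exceeds `max_missing_frac` are dropped
#' (per view), then any cell that still has a missing entry in either view
#' is dropped, and both views are restricted to the shared cells, in the
#' order of the electrophysiology view.
#'
#' @param e,t the two [feature_matrix] views; their cell id sets must
#'   intersect.
#' @param max_missing_frac features missing in more than this fraction of
#'   cells are removed before cells are filtered; default 0.2.
#' @param labels optional named label vector, carried through.
#' @return an [mm_dataset] with no missing values.
#' @export
filter_complete <- function(e, t, max_missing_frac = 0.2, labels = NULL) {
  stopifnot(is_feature_matrix(e), is_feature_matrix(t))
  shared <- intersect(rownames(e), rownames(t))
  if (length(shared) == 0) stop("no shared cell ids between the two views")
  e <- e[shared, , drop = FALSE]
  t <- t[shared, , drop = FALSE]
  drop_features <- function(m) {
    frac <- colMeans(is.na(m))
    m[, frac <= max_missing_frac, drop = FALSE]
  }
  e <- drop_features(e)
  t <- drop_features(t)
  keep <- !apply(is.na(e), 1, any) & !apply(is.na(t), 1, any)
  if (!any(keep)) stop("no complete cells remain after filtering")
  mm_dataset(e[keep, , drop = FALSE], t[keep, , drop = FALSE], labels)
}

#' Standardize each feature to mean zero, unit variance
#'
#' Columns are centred and scaled by their sample standard deviation.
#' Constant columns cannot be scaled; they are set to all-zero and a warning
#' names them.
#'
#' @param m a [feature_matrix] with no missing values and at least 2 cells.
#' @return the standardized [feature_matrix].
#' @export
standardize_features <- function(m) {
  stopifnot(is_feature_matrix(m), nrow(m) >= 2)
  if (anyNA(m)) stop("missing values present; run filter_complete first")
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  const <- sd < .Machine$double.eps^0.5
  sd[const] <- 1
  out <- sweep(sweep(unclass(m), 2, mu, "-"), 2, sd, "/")
  if (any(const)) {
    out[, const] <- 0
    warning("constant features set to zero: ",
            paste(colnames(m)[const], collapse = ", "))
  }
  feature_matrix(out, rownames(m), colnames(m), modality_of(m))
}

#' Log-transform expression values
#'
#' Each value x becomes log2(x + pseudocount).
#'
#' @param m a [feature_matrix] of non-negative values.
#' @param pseudocount added before taking logs; default 1.
#' @return the transformed [feature_matrix].
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(is_feature_matrix(m))
  if (any(m < 0, na.rm = TRUE)) stop("negative values cannot be log-transformed")
  feature_matrix(log2(unclass(m) + pseudocount), rownames(m), colnames(m),
                 modality_of(m))
}

#' Restrict an expression matrix to a gene panel
#'
#' @param m a [feature_matrix].
#' @param genes character vector of feature names to keep (e.g. a neuronal
#'   marker-gene panel); names absent from `m` are ignored with a message.
#' @return the restricted [feature_matrix].
#' @export
restrict_genes <- function(m, genes) {
  stopifnot(is_feature_matrix(m))
  keep <- colnames(m)[colnames(m) %in% genes]
  if (length(keep) < length(genes))
    message(length(genes) - length(keep), " panel genes not present; ignored")
  if (length(keep) == 0) stop("no panel genes present in the matrix")
  m[, keep, drop = FALSE]
}
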