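#' Labeled binary fingerprint dataset
#'
#' The central container of the package: a molecules-by-fingerprints binary
#' matrix together with a per-molecule class label (`active` / `inactive`).
#' Rows are molecules (named by unique molecule ids), columns are named
#' fingerprint bits with values 0 or 1.
#'
#' @param matrix numeric or integer matrix of 0/1 values with unique,
#'   non-empty row names (molecule ids) and column names (fingerprint names).
#' @param labels vector of class labels, one per row. Accepted tokens
#'   (case-insensitive): `1`, `active`, `anticancer` for the active class;
#'   `0`, `inactive`, `non-anticancer` for the inactive class.
#' @return An object of class `labeled_dataset`: a list with elements
#'   `matrix` (integer 0/1 matrix) and `labels` (factor with levels
#'   `active`, `inactive` in row order).
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 0), nrow = 3,
#'             dimnames = list(c("m1", "m2", "m3"), c("FP1", "FP2")))
#' ds <- labeled_dataset(m, c("active", "active", "inactive"))
#' n_active(ds)
#' @export
labeled_dataset <- function(matrix, labels) {
  if (!is.matrix(matrix)) stop("`matrix` must be a matrix")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
    stop("`matrix` must have row names (molecule ids) and column names (fingerprint names)")
  if (anyDuplicated(rownames(matrix)))
    stop("duplicate molecule ids: ",
         paste(unique(rownames(matrix)[duplicated(rownames(matrix))]), collapse = ", "))
  if (anyDuplicated(colnames(matrix)))
    stop("duplicate fingerprint names: ",
         paste(unique(colnames(matrix)[duplicated(colnames(matrix))]), collapse = ", "))
  bad <- which(!(matrix %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(matrix)) + 1
    j <- ((bad[1] - 1) %/% nrow(matrix)) + 1
    stop(sprintf("non-binary cell at molecule '%s', fingerprint '%s': %s",
                 rownames(matrix)[i], colnames(matrix)[j],
                 format(matrix[i, j])))
  }
  if (length(labels) != nrow(matrix))
    stop("`labels` must have one entry per matrix row")
  storage.mode(matrix) <- "integer"
  structure(list(matrix = matrix, labels = normalize_labels(labels)),
            class = "labeled_dataset")
}

#' Normalize class-label tokens
#'
#' Maps `1`/`active`/`anticancer` to `active` and `0`/`inactive`/
#' `non-anticancer` to `inactive`, case-insensitively.
#'
#' @param labels vector of label tokens.
#' @return Factor with levels `c("active", "inactive")`.
#' @export
normalize_labels <- function(labels) {
  tok <- tolower(trimws(as.character(labels)))
  out <- rep(NA_character_, length(tok))
  out[tok %in% c("1", "active", "anticancer")] <- "active"
  out[tok %in% c("0", "inactive", "non-anticancer", "nonanticancer")] <- "inactive"
  if (anyNA(out))
    stop("unrecognized label token(s): ",
         paste(unique(tok[is.na(out)]), collapse = ", "))
  factor(out, levels = c("active", "inactive"))
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d molecules x %d fingerprints (%d active, %d inactive)\n",
              nrow(x$matrix), ncol(x$matrix), n_active(x), n_inactive(x)))
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$matrix)

#' Class sizes of a labeled dataset
#'
#' @param ds a `labeled_dataset`.
#' @return Number of active (`n_active`) or inactive (`n_inactive`) molecules.
#' @export
n_active <- function(ds) sum(ds$labels == "active")

#' @rdname n_active
#' @export
n_inactive <- function(ds) sum(ds$labels == "inactive")

#' Subset the rows of a labeled dataset
#'
#' @param ds a `labeled_dataset`.
#' @param i row index (integer, logical, or molecule ids).
#' @return A `labeled_dataset` restricted to the selected molecules.
#' @export
subset_molecules <- function(ds, i) {
  if (is.character(i)) {
    miss <- setdiff(i, rownames(ds$matrix))
    if (length(miss))
      stop("unknown molecule id(s): ", paste(miss, collapse = ", "))
    i <- match(i, rownames(ds$matrix))
  }
  labeled_dataset(ds$matrix[i, , drop = FALSE], ds$labels[i])
}

#' Select or reorder fingerprint columns
#'
#' Restricts a dataset to a set of fingerprints, in the requested order.
#' Labels, molecule ids and row order are unchanged.
#'
#' @param ds a `labeled_dataset`.
#' @param names character vector of fingerprint names to keep, in order.
#' @return A `labeled_dataset` with columns `names`.
#' @export
subset_fingerprints <- function(ds, names) {
  stopifnot(inherits(ds, "labeled_dataset"))
  missing <- setdiff(names, colnames(ds$matrix))
  if (length(missing))
    stop("unknown fingerprint name(s): ", paste(missing, collapse = ", "))
  structure(list(matrix = ds$matrix[, names, drop = FALSE], labels = ds$labels),
            class = "labeled_dataset")
}

#' Read a labeled fingerprint table
#'
#' Reads a comma-delimited table with a header row: a `molecule_id` column
#' (first), a `label` column, and one 0/1 column per fingerprint. The format
#' round-trips bit-exactly with [write_fingerprint_table()].
#'
#' @param path path to a CSV file.
#' @param label_column name of the class-label column (default `"label"`).
#' @return A `labeled_dataset`.
#' @export
read_fingerprint_table <- function(path, label_column = "label") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("expected at least molecule_id, label and one fingerprint column")
  id_col <- colnames(df)[1]
  if (!label_column %in% colnames(df))
    stop("missing label column '", label_column, "'")
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids))
    stop("duplicate molecule ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  fp_cols <- setdiff(colnames(df), c(id_col, label_column))
  m <- as.matrix(df[, fp_cols, drop = FALSE])
  if (!is.numeric(m)) stop("fingerprint columns must be numeric 0/1")
  rownames(m) <- ids
  labeled_dataset(m, df[[label_column]])
}

#' Write a labeled fingerprint table
#'
#' @param ds a `labeled_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_table <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- data.frame(molecule_id = rownames(ds$matrix),
                   label = as.character(ds$labels),
                   ds$matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
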