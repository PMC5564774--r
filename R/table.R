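#' Descriptor table container
#'
#' An n x p matrix of named descriptor values with compound ids and an
#' optional toxicity target log(IGC50^-1) in log10 units of (mmol/L)^-1.
#'
#' @param values numeric matrix (n x p) with column names, or a data.frame of
#'   numeric columns.
#' @param compound_id character vector of unique ids (length n).
#' @param target optional numeric target vector (length n).
#' @return object of class `descriptor_table` with fields `ids`, `values`,
#'   `target` (possibly `NULL`).
#' @export
descriptor_table <- function(values, compound_id, target = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  stopifnot(is.matrix(values), is.numeric(values))
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("descriptor table needs n >= 1 rows and p >= 1 columns", call. = FALSE)
  }
  if (is.null(colnames(values)) || any(!nzchar(colnames(values)))) {
    stop("descriptor columns must be named", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate descriptor names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  compound_id <- as.character(compound_id)
  if (length(compound_id) != nrow(values)) stop("compound_id length mismatch", call. = FALSE)
  if (anyDuplicated(compound_id)) {
    stop("duplicate compound id: ",
         paste(unique(compound_id[duplicated(compound_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite descriptor value at row %s, column %s",
                 compound_id[bad[1L]], colnames(values)[bad[2L]]), call. = FALSE)
  }
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (length(target) != nrow(values)) stop("target length mismatch", call. = FALSE)
    if (!all(is.finite(target))) stop("non-finite target value", call. = FALSE)
  }
  rownames(values) <- compound_id
  structure(list(ids = compound_id, values = values, target = target),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf("<descriptor_table: %d compounds x %d descriptors%s>\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$target)) "" else ", with target"))
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Subset a descriptor table by rows and/or descriptor columns
#' @param table a [descriptor_table()].
#' @param rows integer or logical row index (default all).
#' @param features character, integer or logical column selector (default all).
#' @return a [descriptor_table()].
#' @export
subset_table <- function(table, rows = NULL, features = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(rows)) rows <- seq_len(nrow(table$values))
  v <- table$values[rows, , drop = FALSE]
  if (!is.null(features)) {
    if (is.character(features)) {
      missing <- setdiff(features, colnames(v))
      if (length(missing) > 0L) {
        stop("unknown descriptor column(s): ", paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    v <- v[, features, drop = FALSE]
  }
  descriptor_table(v, compound_id = table$ids[rows],
                   target = if (!is.null(table$target)) table$target[rows])
}

#' Read a descriptor table from CSV
#'
#' Expects a header with a `compound_id` column, numeric descriptor columns
#' with '.' decimal separator, and (optionally) the target column.
#'
#' @param path CSV file path.
#' @param target_col name of the target column (default `"logIGC50inv"`).
#' @param require_target error if the target column is absent?
#' @return a [descriptor_table()].
#' @export
read_descriptor_table <- function(path, target_col = "logIGC50inv",
                                  require_target = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"compound_id" %in% names(df)) stop("missing 'compound_id' column in ", path, call. = FALSE)
  ids <- df[["compound_id"]]
  if (anyDuplicated(ids)) {
    stop("duplicate compound id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  value_cols <- setdiff(names(df), "compound_id")
  if (length(value_cols) == 0L) stop("no descriptor columns in ", path, call. = FALSE)
  num <- matrix(NA_real_, nrow(df), length(value_cols),
                dimnames = list(NULL, value_cols))
  for (cn in value_cols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric cell at row %s, column %s (value %s)",
                   ids[bad[1L]], cn, sQuote(df[[cn]][bad[1L]])), call. = FALSE)
    }
    num[, cn] <- v
  }
  target <- NULL
  if (target_col %in% value_cols) {
    target <- num[, target_col]
    num <- num[, setdiff(value_cols, target_col), drop = FALSE]
  } else if (require_target) {
    stop("required target column ", sQuote(target_col), " not found in ", path, call. = FALSE)
  }
  descriptor_table(num, compound_id = ids, target = target)
}

#' Write a descriptor table to CSV
#'
#' Emits `compound_id,<descriptors...>[,target]` with '.' decimals, UTF-8.
#' @param table a [descriptor_table()].
#' @param path output path.
#' @param target_col name used for the target column when present.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, target_col = "logIGC50inv") {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(compound_id = table$ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$target)) df[[target_col]] <- table$target
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
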