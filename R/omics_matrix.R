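#' Construct an omics matrix
#'
#' An `omics_matrix` is the package's container for an individuals x features
#' real-valued matrix of either SNP genotype dosages or gene transcript
#' levels, with unique row (individual) and column (feature) identifiers.
#'
#' @param values Numeric matrix, individuals in rows, features in columns.
#'   Must carry unique rownames and colnames (supplied here or already set).
#' @param kind Either `"genotype"` or `"transcript"`. Genotype dosages must
#'   lie in `[0, 2]` (the usual 0/1/2 or continuous-dosage convention) or be
#'   `NA`.
#' @param row_ids,col_ids Optional character vectors overriding the dimnames
#'   of `values`.
#'
#' @return An object of class `omics_matrix`: the numeric matrix with a
#'   `kind` attribute.
#' @export
omics_matrix <- function(values, kind = c("genotype", "transcript"),
                         row_ids = NULL, col_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(row_ids)) rownames(values) <- as.character(row_ids)
  if (!is.null(col_ids)) colnames(values) <- as.character(col_ids)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("id_", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate individual identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (kind == "genotype") {
    rng <- range(values, na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
      stop("genotype dosages must lie in [0, 2]; observed range [",
           signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  structure(values, kind = kind, class = c("omics_matrix", "matrix", "array"))
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d individuals x %d features\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  if (anyNA(x)) cat(sprintf("  missing entries: %d\n", sum(is.na(x))))
  invisible(x)
}

#' @export
`[.omics_matrix` <- function(x, i, j, ..., drop = FALSE) {
  kind <- attr(x, "kind")
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, kind = kind,
                     class = c("omics_matrix", "matrix", "array"))
  out
}

is_omics_matrix <- function(x) inherits(x, "omics_matrix")

#' Read a delimited individuals x features matrix
#'
#' Reads a TSV/CSV file with one header row of feature identifiers and a
#' first column of individual identifiers, as written by [write_matrix()].
#' CRLF and LF line endings parse identically.
#'
#' @param path File path.
#' @param kind Matrix kind passed to [omics_matrix()].
#' @return An [omics_matrix()].
#' @export
read_matrix <- function(path, kind = c("genotype", "transcript")) {
  kind <- match.arg(kind)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  if (ncol(dt) < 2) stop("expected an ID column plus at least one feature: ", path)
  ids <- as.character(dt[[1]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicated individual ID(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  }
  vals <- dt[, -1, drop = FALSE]
  nonnum <- !vapply(vals, is.numeric, logical(1))
  if (any(nonnum)) {
    # locate the first offending cell for the error message
    col <- which(nonnum)[1]
    suppressWarnings(conv <- as.numeric(vals[[col]]))
    bad <- which(is.na(conv) & !is.na(vals[[col]]) & vals[[col]] != "NA")[1]
    stop("non-numeric value in ", path, ", column '", names(vals)[col],
         "', data line ", if (is.na(bad)) "?" else bad)
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  omics_matrix(m, kind = kind)
}

#' Write an individuals x features matrix to TSV
#'
#' Values are written with 15 significant digits so that a write-then-read
#' round trip is lossless well beyond the 12 digits the package guarantees.
#'
#' @param x Matrix (plain or [omics_matrix()]).
#' @param path Output file path.
#' @export
write_matrix <- function(x, path) {
  m <- as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a PLINK .raw-style dosage export
#'
#' Convenience reader for the tab/space-separated additive dosage format with
#' leading FID/IID/PAT/MAT/SEX/PHENOTYPE columns; IID becomes the individual
#' identifier.
#'
#' @param path File path.
#' @return An [omics_matrix()] of kind `"genotype"`.
#' @export
read_plink_raw <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(dt))
  if (!"IID" %in% meta) stop("no IID column: not a PLINK .raw export?")
  ids <- as.character(dt[["IID"]])
  m <- as.matrix(dt[, setdiff(names(dt), meta), drop = FALSE])
  rownames(m) <- ids
  omics_matrix(m, kind = "genotype")
}

#' Write a relationship kernel to TSV
#'
#' Individual IDs appear both as the header row and the first column; values
#' carry 12 significant digits, so the file round-trips bit-exactly at that
#' precision through [read_kernel()].
#'
#' @param kernel A [relationship_kernel].
#' @param path Output path.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "relationship_kernel"))
  m <- kernel$values
  df <- data.frame(id = rownames(m),
                   apply(m, 2, function(col) sprintf("%.12g", col)),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(m))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a relationship kernel written by [write_kernel()]
#'
#' @param path File path.
#' @param component Kernel component label (`"g"`, `"t"`, `"tc"` or `"gt"`).
#' @param n_features Number of features used to build the kernel, if known.
#' @return A [relationship_kernel].
#' @export
read_kernel <- function(path, component, n_features = NA_integer_) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  if (!identical(colnames(m), ids))
    stop("kernel file header does not match its ID column: ", path)
  # symmetrize away formatting round-off
  m <- (m + t(m)) / 2
  relationship_kernel(m, component = component, n_features = n_features)
}
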