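# Plain-text readers/writers with strict schema validation.

.read_delim_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(utils::head(ids[duplicated(ids)], 3), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix from TSV/CSV
#'
#' First column = CpG id, remaining columns = samples; the delimiter is
#' taken from the file extension (`.csv` comma, otherwise tab). Values
#' must be finite and in [0,1]; violations are reported with the
#' offending CpG and sample.
#'
#' @param path File path.
#' @return CpG x sample numeric matrix.
#' @export
load_beta_matrix <- function(path) {
  m <- .read_delim_matrix(path)
  bad <- which(!is.finite(m) | m < 0 | m > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid beta value ", m[bad[1, 1], bad[1, 2]], " at CpG '",
         rownames(m)[bad[1, 1]], "', sample '", colnames(m)[bad[1, 2]],
         "' in ", path)
  m
}

#' Read a cell-type reference matrix from TSV/CSV
#'
#' First column = marker CpG id, remaining columns = cell types. Requires
#' at least two cell types with pairwise distinct profiles and values in
#' [0,1].
#'
#' @param path File path.
#' @return Marker CpG x cell type numeric matrix.
#' @export
load_reference <- function(path) {
  m <- load_beta_matrix(path)
  if (ncol(m) < 2) stop("reference must contain at least 2 cell types")
  for (i in seq_len(ncol(m) - 1))
    for (j in seq((i + 1), ncol(m)))
      if (all(m[, i] == m[, j]))
        stop("cell types '", colnames(m)[i], "' and '", colnames(m)[j],
             "' have identical profiles")
  m
}

#' Write a CpG x sample matrix as delimited text
#'
#' @param m Numeric matrix with row names.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @param id_column Name of the leading id column.
#' @export
write_beta_matrix <- function(m, path, id_column = "cpg_id") {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
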