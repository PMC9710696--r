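# Tab-separated on-disk formats shared by the CLI: feature matrices,
# truth/coverage tables and bin assignments. All files have headers.

#' Write / read a feature matrix
#'
#' Tab-separated with header: `sequence_id`, then one column per feature
#' dimension. Style, k-mer and coverage-augmented tables share this format,
#' so binning is feature-agnostic.
#'
#' @param features Numeric matrix with row names.
#' @param path Output path.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  dt <- data.table::data.table(sequence_id = rownames(features))
  vals <- data.table::as.data.table(features)
  data.table::setnames(vals, paste0("v", seq_len(ncol(features)) - 1L))
  data.table::fwrite(cbind(dt, vals), path, sep = "\t")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!"sequence_id" %in% names(dt)) {
    stop("feature table has no sequence_id column: ", path)
  }
  m <- as.matrix(dt[, setdiff(names(dt), "sequence_id"), drop = FALSE])
  rownames(m) <- dt$sequence_id
  m
}

#' Read a two-column tab-separated table into a named vector
#'
#' Used for truth tables (sequence_id, label) and coverage tables
#' (sequence_id, coverage).
#'
#' @param path Input path.
#' @param value_name Expected name of the value column; the second column is
#'   used if the name is absent.
#' @export
read_id_table <- function(path, value_name = "label") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 2L) stop("expected two columns in ", path)
  col <- if (value_name %in% names(dt)) value_name else names(dt)[2L]
  stats::setNames(dt[[col]], dt[[1L]])
}

#' Write a bin assignment
#'
#' @param assignment Named integer vector from [agglomerative_bin()].
#' @param path Output path.
#' @export
write_assignment <- function(assignment, path) {
  data.table::fwrite(
    data.table::data.table(sequence_id = names(assignment),
                           bin_index = as.integer(assignment)),
    path, sep = "\t")
  invisible(path)
}
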