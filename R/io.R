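# Table I/O shared by all pipeline stages: TSV (text, 12+ significant
# digits) or Feather (binary, exact) with an optional JSON sidecar
# carrying labels, time step and seeds.

#' Write a numeric matrix to disk
#'
#' @param path output path. Extension `.feather` selects the binary
#'   container (exact round-trip, requires the `arrow` package); anything
#'   else is written as TSV with a header row of column labels (round-trips
#'   to at least 12 significant digits).
#' @param matrix numeric matrix.
#' @param labels column labels (default: existing colnames or `V1..Vn`).
#' @param sidecar optional named list of metadata written to
#'   `<path>.json` (seeds, time step, provenance).
#' @return `path`, invisibly.
#' @export
write_table <- function(path, matrix, labels = NULL, sidecar = NULL) {
  matrix <- as.matrix(matrix)
  labels <- labels %||% colnames(matrix) %||%
    paste0("V", seq_len(ncol(matrix)))
  if (length(labels) != ncol(matrix)) {
    stop_rptraj("label count does not match column count",
                "rptraj_dim_mismatch")
  }
  colnames(matrix) <- labels
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_rptraj("the 'arrow' package is required for feather output",
                  "rptraj_missing_dependency")
    }
    arrow::write_feather(as.data.frame(matrix), path)
  } else {
    data.table::fwrite(as.data.table.matrix_safe(matrix), path, sep = "\t")
  }
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

as.data.table.matrix_safe <- function(m) {
  if (nrow(m) == 0L) {
    out <- data.table::as.data.table(
      stats::setNames(rep(list(numeric(0)), ncol(m)), colnames(m))
    )
  } else {
    out <- data.table::as.data.table(m)
  }
  out
}

#' Read a numeric matrix written by [write_table()]
#'
#' @param path file path (TSV or `.feather`).
#' @return numeric matrix with column names; the sidecar, when present, is
#'   attached as attribute `"sidecar"`.
#' @export
read_table <- function(path) {
  if (grepl("\\.feather$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop_rptraj("the 'arrow' package is required for feather input",
                  "rptraj_missing_dependency")
    }
    df <- as.data.frame(arrow::read_feather(path))
  } else {
    df <- data.table::fread(path, sep = "\t", header = TRUE,
                            data.table = FALSE)
  }
  m <- as.matrix(df)
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    attr(m, "sidecar") <- jsonlite::read_json(sidecar_path,
                                              simplifyVector = TRUE)
  }
  m
}
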