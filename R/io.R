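#' Read a UMI count matrix and its cell metadata
#'
#' Reads either a MatrixMarket sparse matrix with `features.tsv` /
#' `barcodes.tsv` sidecar files (the 10x-style layout) or a dense CSV/TSV
#' with genes in rows, together with a tab-separated metadata table mapping
#' every cell to a subject and every subject to a group.
#'
#' @param path path to the matrix file (`.mtx` or `.csv`/`.tsv`)
#' @param format `"mtx"` or `"csv"`
#' @param metadata_path tab-separated file with header columns
#'   `cell_id`, `subject_id`, `group`
#' @param features_path,barcodes_path sidecar paths for `"mtx"`; default to
#'   `features.tsv` and `barcodes.tsv` next to the matrix file
#' @return a [count_matrix]
#' @export
read_counts <- function(path, format = c("mtx", "csv"), metadata_path,
                        features_path = NULL, barcodes_path = NULL) {
  format <- match.arg(format)
  for (f in c(path, metadata_path))
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)

  if (format == "mtx") {
    if (is.null(features_path))
      features_path <- file.path(dirname(path), "features.tsv")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    for (f in c(features_path, barcodes_path))
      if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
    m <- Matrix::readMM(path)
    genes <- read.delim(features_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(barcodes_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m) || length(cells) != ncol(m))
      stop("sidecar files do not match the matrix dimensions", call. = FALSE)
    dimnames(m) <- list(genes, cells)
  } else {
    sep <- if (grepl("\\.tsv$", path)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE)
    m <- as.matrix(df)
  }

  md <- read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "subject_id", "group")
  if (!all(need %in% names(md)))
    stop("metadata must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(md$cell_id))
    stop("duplicated cell ids in metadata", call. = FALSE)

  count_matrix(m,
               subject_of_cell = stats::setNames(md$subject_id, md$cell_id),
               group_of_subject = stats::setNames(md$group, md$subject_id))
}

#' Write a count matrix and metadata to disk
#'
#' Inverse of [read_counts()]: writes the counts as MatrixMarket (+ sidecar
#' `features.tsv`/`barcodes.tsv`) or dense CSV, and the cell metadata as a
#' TSV with columns `cell_id`, `subject_id`, `group`. The round trip through
#' [read_counts()] reproduces the counts exactly.
#'
#' @param cm a [count_matrix]
#' @param path output matrix path
#' @param format `"mtx"` or `"csv"`
#' @param metadata_path output metadata path (default: `metadata.tsv` next
#'   to the matrix file)
#' @return `path`, invisibly
#' @export
write_counts <- function(cm, path, format = c("mtx", "csv"),
                         metadata_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  if (is.null(metadata_path))
    metadata_path <- file.path(dirname(path), "metadata.tsv")

  if (format == "mtx") {
    Matrix::writeMM(cm$counts, path)
    writeLines(rownames(cm$counts), file.path(dirname(path), "features.tsv"))
    writeLines(colnames(cm$counts), file.path(dirname(path), "barcodes.tsv"))
  } else {
    df <- as.data.frame(as.matrix(cm$counts), check.names = FALSE)
    utils::write.csv(df, path, quote = FALSE)
  }

  md <- data.frame(cell_id = colnames(cm$counts),
                   subject_id = unname(cm$subject),
                   group = unname(cm$group[cm$subject]))
  write.table(md, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
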