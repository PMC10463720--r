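#' UMI count matrix with subject and group structure
#'
#' Container for a genes x cells matrix of UMI counts together with the two
#' maps a multi-subject differential-expression analysis needs: cell ->
#' subject and subject -> group. Counts are stored as a sparse
#' [Matrix::dgCMatrix].
#'
#' @param counts non-negative integer matrix (base or `Matrix` sparse),
#'   genes in rows, cells in columns. Row and column names are used as gene
#'   and cell identifiers when `gene_ids`/`cell_ids` are not supplied.
#' @param subject_of_cell character vector, one subject id per cell (in
#'   column order, or named by cell id).
#' @param group_of_subject group label per subject, named by subject id.
#'   Must be codable as binary: values in `{0, 1}` are kept as-is, any other
#'   two-level coding is mapped to 0/1 by sorted order.
#' @param gene_ids,cell_ids optional identifier vectors overriding dimnames.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (dgCMatrix), `subject` (character per cell, named by cell id) and
#'   `group` (integer 0/1 per subject, named by subject id).
#' @export
count_matrix <- function(counts, subject_of_cell, group_of_subject,
                         gene_ids = NULL, cell_ids = NULL) {
  counts <- Matrix::drop0(
    methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix"))
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(cell_ids)) colnames(counts) <- cell_ids
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicated cell ids", call. = FALSE)
  x <- counts@x
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers with no missing entries",
         call. = FALSE)

  subject <- as.character(subject_of_cell)
  if (!is.null(names(subject_of_cell))) {
    miss <- setdiff(colnames(counts), names(subject_of_cell))
    if (length(miss))
      stop("cells present in counts but absent from metadata: ",
           paste(head(miss, 5), collapse = ", "), call. = FALSE)
    subject <- as.character(subject_of_cell[colnames(counts)])
  } else if (length(subject) != ncol(counts)) {
    stop("subject_of_cell must have one entry per cell", call. = FALSE)
  }
  names(subject) <- colnames(counts)

  group <- encode_group(group_of_subject)
  miss <- setdiff(unique(subject), names(group))
  if (length(miss))
    stop("subjects with no group label: ", paste(miss, collapse = ", "),
         call. = FALSE)
  group <- group[intersect(names(group), unique(subject))]

  structure(list(counts = counts, subject = subject, group = group),
            class = "count_matrix")
}

# Map an arbitrary two-level group coding to integer 0/1.
encode_group <- function(g) {
  if (is.null(names(g))) stop("group_of_subject must be named by subject id",
                              call. = FALSE)
  if (anyDuplicated(names(g))) {
    # one row per cell is allowed as long as the coding is consistent
    tab <- unique(data.frame(s = names(g), g = as.character(g)))
    if (anyDuplicated(tab$s))
      stop("a subject is mapped to more than one group", call. = FALSE)
    g <- stats::setNames(tab$g, tab$s)
  }
  vals <- sort(unique(as.character(g)))
  if (length(vals) > 2)
    stop("group column is not binary-codable (", length(vals), " levels)",
         call. = FALSE)
  if (all(vals %in% c("0", "1"))) {
    out <- as.integer(as.character(g))
  } else {
    out <- as.integer(as.character(g) == vals[length(vals)])
  }
  stats::setNames(out, names(g))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %d subjects (%d | %d)\n",
              nrow(x$counts), ncol(x$counts), length(x$group),
              sum(x$group == 0), sum(x$group == 1)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Per-cell sequencing depths
#'
#' Total UMI count of each cell (the depth offset `S_ij` of the model),
#' computed as the column sums of the count matrix.
#'
#' @param cm a [count_matrix]
#' @return named numeric vector, one depth per cell.
#' @export
cell_depths <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  Matrix::colSums(cm$counts)
}

#' Number of cells per subject
#'
#' @param cm a [count_matrix]
#' @return named integer vector, cells per subject.
#' @export
cells_per_subject <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- table(factor(cm$subject, levels = names(cm$group)))
  stats::setNames(as.integer(tab), names(cm$group))
}

#' Remove genes expressed in too few cells
#'
#' Drops every gene whose fraction of cells with a nonzero count is strictly
#' below `min_cell_fraction` (default 5% of cells); genes expressed in
#' exactly the threshold fraction are retained. The cell set is unchanged.
#'
#' @param cm a [count_matrix]
#' @param min_cell_fraction minimum fraction of cells with nonzero count
#' @return the filtered [count_matrix]
#' @export
filter_genes <- function(cm, min_cell_fraction = 0.05) {
  stopifnot(inherits(cm, "count_matrix"),
            min_cell_fraction >= 0, min_cell_fraction <= 1)
  frac <- Matrix::rowSums(cm$counts > 0) / ncol(cm$counts)
  keep <- frac >= min_cell_fraction
  if (!any(keep))
    stop("all genes removed by the expression filter", call. = FALSE)
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}

#' Remove subjects with too few cells
#'
#' Drops all cells of subjects contributing fewer than `min_cells` cells
#' (default 5); subjects with exactly `min_cells` cells are retained. Errors
#' if fewer than two subjects per group remain, since the subject-level
#' mixed model is then unidentifiable.
#'
#' @param cm a [count_matrix]
#' @param min_cells minimum number of cells per retained subject
#' @return the filtered [count_matrix]
#' @export
filter_subjects <- function(cm, min_cells = 5) {
  stopifnot(inherits(cm, "count_matrix"), min_cells >= 1)
  m <- cells_per_subject(cm)
  keep_subj <- names(m)[m >= min_cells]
  keep_cell <- cm$subject %in% keep_subj
  grp <- cm$group[keep_subj]
  if (sum(grp == 0) < 2 || sum(grp == 1) < 2)
    stop("fewer than 2 subjects per group remain after filtering; ",
         "the mixed model is unidentifiable", call. = FALSE)
  cm$counts <- cm$counts[, keep_cell, drop = FALSE]
  cm$subject <- cm$subject[keep_cell]
  cm$group <- grp
  cm
}

#' Median number of cells per subject
#'
#' Dataset-eligibility diagnostic: the median of the per-subject cell
#' counts. For an even number of subjects the mean of the two middle values
#' is returned.
#'
#' @param cm a [count_matrix]
#' @return a single number
#' @export
median_cells_per_subject <- function(cm) {
  stats::median(as.numeric(cells_per_subject(cm)))
}

#' Log-normalize UMI counts
#'
#' Library-size normalization in the droplet-data convention:
#' `log(1 + count / depth * scale_factor)`, so a zero count maps to exactly
#' zero and within-cell rank order is preserved.
#'
#' @param cm a [count_matrix]
#' @param scale_factor the depth rescaling constant (default `1e4`)
#' @param depths optional per-cell depths to use instead of the column sums
#'   of `cm` (e.g. depths computed before gene filtering)
#' @return an object of class `normalized_matrix`: list with `values` (a
#'   dgCMatrix the same shape as the counts) and `scale_factor`.
#' @export
log_normalize <- function(cm, scale_factor = 1e4, depths = NULL) {
  stopifnot(inherits(cm, "count_matrix"), scale_factor > 0)
  if (is.null(depths)) depths <- cell_depths(cm)
  if (any(depths <= 0))
    stop("zero-depth cell(s) present; filter cells before normalizing",
         call. = FALSE)
  v <- cm$counts
  ncol_nnz <- diff(v@p)
  v@x <- log1p(v@x / rep.int(depths, ncol_nnz) * scale_factor)
  structure(list(values = v, scale_factor = scale_factor),
            class = "normalized_matrix")
}
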