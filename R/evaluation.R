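#' Permutation-based empirical type I error
#'
#' Randomly reassigns the subject-level group labels (preserving the group
#' sizes; cells always travel with their subject), reruns the full analysis
#' on each permuted dataset, and reports for every gene the fraction of
#' permutations with p-value below `alpha`. Under the no-signal hypothesis
#' this fraction estimates the per-gene type I error at nominal level
#' `alpha`. Missing p-values (non-converged fits) count as non-significant.
#'
#' @param cm a [count_matrix]
#' @param n_perm number of label permutations
#' @param alpha nominal significance level
#' @param seed RNG seed for the permutation draws
#' @param config an [idesc_config] passed to [run_idesc()]
#' @param depths optional known per-cell depths forwarded to [run_idesc()]
#' @param de_fun analysis to run on each permuted dataset: a function taking
#'   a [count_matrix] and returning a data frame with columns `gene_id` and
#'   `p_value`. Defaults to the full pipeline. Injectable for calibration
#'   checks of other procedures.
#' @return `data.frame` (class `perm_type1`) with columns `gene_id` and
#'   `rate`; the per-permutation p-value matrix and permuted label matrix
#'   are attached as attributes `p_matrix` and `perms`.
#' @export
permutation_type1 <- function(cm, n_perm = 500, alpha = 0.05, seed = 1,
                              config = idesc_config(), depths = NULL,
                              de_fun = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (is.null(de_fun)) {
    de_fun <- function(x) {
      tbl <- run_idesc(x, config, depths = depths)
      data.frame(gene_id = tbl$gene_id, p_value = tbl$p_value)
    }
  }
  labels <- cm$group
  n_subj <- length(labels)
  perms <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(r) sample(unname(labels)),
           integer(n_subj))
  })
  rownames(perms) <- names(labels)

  p_list <- vector("list", n_perm)
  gene_ids <- NULL
  for (r in seq_len(n_perm)) {
    cm_r <- cm
    cm_r$group <- stats::setNames(perms[, r], names(labels))
    res <- de_fun(cm_r)
    if (is.null(gene_ids)) gene_ids <- res$gene_id
    p_list[[r]] <- res$p_value[match(gene_ids, res$gene_id)]
  }
  pmat <- do.call(cbind, p_list)
  rownames(pmat) <- gene_ids
  rate <- rowMeans(!is.na(pmat) & pmat < alpha)

  out <- data.frame(gene_id = gene_ids, rate = unname(rate))
  attr(out, "p_matrix") <- pmat
  attr(out, "perms") <- perms
  class(out) <- c("perm_type1", "data.frame")
  out
}

#' Sensitivity and specificity at a p-value threshold
#'
#' Missing p-values are treated as 1 (never significant), a conservative
#' convention.
#'
#' @param p_values per-gene p-values
#' @param truth per-gene logical ground-truth DE flags
#' @param alpha p-value threshold
#' @return list with `sensitivity` (`NA` when there are no true DE genes)
#'   and `specificity`.
#' @export
sens_spec <- function(p_values, truth, alpha = 0.05) {
  stopifnot(length(p_values) == length(truth))
  truth <- as.logical(truth)
  p <- ifelse(is.na(p_values), 1, p_values)
  sig <- p < alpha
  sensitivity <- if (!any(truth)) NA_real_ else mean(sig[truth])
  specificity <- if (!any(!truth)) NA_real_ else mean(!sig[!truth])
  list(sensitivity = sensitivity, specificity = specificity)
}

#' Area under the ROC curve for gene-level p-values
#'
#' Rank-statistic AUC with smaller p-values ranking as more likely DE; ties
#' are averaged (the Mann-Whitney convention). Missing p-values count as 1.
#'
#' @param p_values per-gene p-values
#' @param truth per-gene logical DE flags (both classes must be present)
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(p_values, truth) {
  stopifnot(length(p_values) == length(truth))
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  p <- ifelse(is.na(p_values), 1, p_values)
  r <- rank(-p)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Significance of the overlap of two gene sets
#'
#' One-sided (enrichment) Fisher's exact test: the hypergeometric upper tail
#' of the observed intersection size given the two set sizes and the
#' universe.
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`
#' @param universe the background gene set
#' @return the enrichment p-value.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  a <- unique(set_a)
  b <- unique(set_b)
  if (!all(a %in% universe) || !all(b %in% universe))
    stop("both sets must be subsets of the universe", call. = FALSE)
  k <- length(intersect(a, b))
  phyper(k - 1, length(a), length(universe) - length(a), length(b),
         lower.tail = FALSE)
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both sets are empty.
#'
#' @param set_a,set_b character vectors of gene ids
#' @return the Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  u <- union(a, b)
  if (length(u) == 0) return(0)
  length(intersect(a, b)) / length(u)
}

#' Per-cell effect coefficients
#'
#' For every cell, the dot product of its log-normalized expression over the
#' chosen DE genes with the estimated group effects of those genes, scaled
#' so that the maximum absolute value over cells is 1. Summarizes how
#' strongly each individual cell expresses the group-level fold-change
#' signature, and visualizes within- and between-subject variation.
#'
#' @param nm a `normalized_matrix`
#' @param tbl results table from [run_idesc()]
#' @param de_genes gene ids to use; must be converged rows of `tbl`
#' @return named numeric vector, one coefficient per cell, in `[-1, 1]`.
#' @export
effect_coefficients <- function(nm, tbl, de_genes) {
  stopifnot(inherits(nm, "normalized_matrix"))
  if (length(de_genes) == 0) stop("de_genes must be non-empty", call. = FALSE)
  idx <- match(de_genes, tbl$gene_id)
  if (anyNA(idx)) stop("de_genes must appear in the results table",
                       call. = FALSE)
  if (!all(tbl$converged[idx]))
    stop("all de_genes must have converged fits", call. = FALSE)
  if (!all(de_genes %in% rownames(nm$values)))
    stop("de_genes missing from the normalized matrix", call. = FALSE)
  b <- tbl$beta[idx]
  v <- as.numeric(Matrix::crossprod(nm$values[de_genes, , drop = FALSE], b))
  m <- max(abs(v))
  if (m > 0) v <- v / m
  stats::setNames(v, colnames(nm$values))
}
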