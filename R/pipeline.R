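#' Analysis configuration
#'
#' All tunable options of the end-to-end differential-expression pipeline,
#' with the defaults used throughout the package.
#'
#' @param min_cell_fraction gene filter: minimum fraction of cells with a
#'   nonzero count (default 0.05)
#' @param min_cells_per_subject subject filter: minimum cells per subject
#'   (default 5)
#' @param filter_order `"genes_first"` (default) or `"subjects_first"`
#' @param depths_after_gene_filter compute the depth offsets on the retained
#'   gene set (default) or on the pre-filter gene set
#' @param scale_factor log-normalization scale factor
#' @param span,loess_degree,clip_bounds dropout-curve controls, see
#'   [fit_dropout_curve()]
#' @param expression_axis dropout-curve x-axis convention, see
#'   [gene_expression_summary()]
#' @param integrator,gh_points,max_restarts per-gene fitting controls, see
#'   [fit_options()]
#' @param seed master seed; expanded deterministically into per-gene seeds
#' @param threads per-gene parallelism (results are identical to serial)
#' @return a list of class `idesc_config`
#' @export
idesc_config <- function(min_cell_fraction = 0.05, min_cells_per_subject = 5,
                         filter_order = c("genes_first", "subjects_first"),
                         depths_after_gene_filter = TRUE,
                         scale_factor = 1e4, span = 0.75, loess_degree = 2,
                         clip_bounds = c(1e-4, 1 - 1e-4),
                         expression_axis = c("log_mean", "mean"),
                         integrator = c("laplace", "aghq"), gh_points = 9,
                         max_restarts = 3, seed = 1, threads = 1) {
  structure(list(min_cell_fraction = min_cell_fraction,
                 min_cells_per_subject = min_cells_per_subject,
                 filter_order = match.arg(filter_order),
                 depths_after_gene_filter = depths_after_gene_filter,
                 scale_factor = scale_factor, span = span,
                 loess_degree = loess_degree, clip_bounds = clip_bounds,
                 expression_axis = match.arg(expression_axis),
                 integrator = match.arg(integrator), gh_points = gh_points,
                 max_restarts = max_restarts, seed = seed, threads = threads),
            class = "idesc_config")
}

.result_columns <- c("gene_id", "beta", "fold_change", "se_beta", "wald_z",
                     "p_value", "sigma2", "tau2", "theta", "d", "pi0",
                     "converged", "n_cells_expressing", "status")

#' Run the full differential-expression analysis
#'
#' Orchestrates the per-gene analysis over a whole matrix: gene and subject
#' filters, depth computation, log-normalization, pooled dropout-curve fit,
#' then one zero-inflated NB mixed-model fit and Wald test per gene.
#' Deterministic given `config$seed`; with `config$threads > 1` genes are
#' fitted in parallel with results identical to the serial run.
#'
#' @param cm a [count_matrix]
#' @param config an [idesc_config]
#' @param depths optional named per-cell sequencing depths to use as the
#'   model offsets instead of the column sums of `cm`. Intended for data
#'   where the matrix covers only a panel of genes (e.g. simulated
#'   datasets, whose generating depths are the cells' transcriptome-wide
#'   totals).
#' @return a `data.frame` (class `idesc_results`) with one row per tested
#'   gene and columns `gene_id, beta, fold_change, se_beta, wald_z, p_value,
#'   sigma2, tau2, theta, d, pi0, converged, n_cells_expressing, status`.
#'   Genes whose fit failed are retained with `status` describing the
#'   failure. The fitted dropout curve and the configuration are attached as
#'   attributes `curve` and `config`.
#' @export
run_idesc <- function(cm, config = idesc_config(), depths = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.null(depths) && is.null(names(depths)))
    stop("external depths must be named by cell id", call. = FALSE)
  depths_full <- cell_depths(cm)
  if (config$filter_order == "genes_first") {
    cm <- filter_genes(cm, config$min_cell_fraction)
    cm <- filter_subjects(cm, config$min_cells_per_subject)
  } else {
    cm <- filter_subjects(cm, config$min_cells_per_subject)
    cm <- filter_genes(cm, config$min_cell_fraction)
  }
  if (nrow(cm$counts) == 0)
    stop("no genes left after filtering", call. = FALSE)

  if (is.null(depths)) {
    depths <- if (config$depths_after_gene_filter) cell_depths(cm) else
      depths_full[colnames(cm$counts)]
  } else {
    miss <- setdiff(colnames(cm$counts), names(depths))
    if (length(miss))
      stop("external depths missing for some cells", call. = FALSE)
    depths <- depths[colnames(cm$counts)]
  }
  if (any(depths <= 0))
    stop("zero-depth cells after filtering", call. = FALSE)

  nm <- log_normalize(cm, config$scale_factor, depths = depths)
  zp <- gene_zero_proportion(cm)
  xs <- gene_expression_summary(nm, axis = config$expression_axis)
  curve <- fit_dropout_curve(xs, zp, span = config$span,
                             degree = config$loess_degree,
                             clip_bounds = config$clip_bounds)
  pi0 <- predict_pi0(curve, xs)

  genes <- rownames(cm$counts)
  counts <- cm$counts
  subject <- cm$subject
  group <- cm$group
  n_expr <- Matrix::rowSums(counts > 0)

  fit_one <- function(k) {
    yk <- as.numeric(counts[k, ])
    opt <- fit_options(integrator = config$integrator,
                       gh_points = config$gh_points,
                       max_restarts = config$max_restarts,
                       seed = derive_seed(config$seed, k))
    fit <- tryCatch(fit_gene(yk, depths, subject, group, pi0[k], opt),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(data.frame(gene_id = genes[k], beta = NA_real_,
                        fold_change = NA_real_, se_beta = NA_real_,
                        wald_z = NA_real_, p_value = NA_real_,
                        sigma2 = NA_real_, tau2 = NA_real_, theta = NA_real_,
                        d = NA_real_, pi0 = pi0[[k]], converged = FALSE,
                        n_cells_expressing = n_expr[[k]],
                        status = paste0("error: ", conditionMessage(fit))))
    }
    p <- fit$params
    data.frame(gene_id = genes[k],
               beta = if (is.null(p)) NA_real_ else p$beta,
               fold_change = if (is.null(p)) NA_real_ else exp(p$beta),
               se_beta = fit$se_beta, wald_z = fit$wald_z,
               p_value = fit$p_value,
               sigma2 = if (is.null(p)) NA_real_ else p$sigma2,
               tau2 = if (is.null(p)) NA_real_ else p$tau2,
               theta = if (is.null(p)) NA_real_ else p$theta,
               d = if (is.null(p)) NA_real_ else p$d,
               pi0 = pi0[[k]], converged = fit$converged,
               n_cells_expressing = n_expr[[k]],
               status = if (fit$converged) "ok" else "non_converged")
  }

  idx <- seq_along(genes)
  rows <- if (config$threads > 1) {
    parallel::mclapply(idx, fit_one, mc.cores = config$threads,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, fit_one)
  }
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  attr(tbl, "curve") <- curve
  attr(tbl, "config") <- config
  class(tbl) <- c("idesc_results", "data.frame")
  tbl
}

#' Call differentially expressed genes from a results table
#'
#' Genes with (optionally BH-adjusted) p-value below `alpha`. Non-converged
#' genes are never called.
#'
#' @param tbl results table from [run_idesc()]
#' @param alpha significance threshold
#' @param adjust `"none"` (default, matching the raw-p thresholds used
#'   throughout) or `"bh"` for Benjamini-Hochberg
#' @return character vector of gene ids.
#' @export
call_de <- function(tbl, alpha = 0.05, adjust = c("none", "bh")) {
  adjust <- match.arg(adjust)
  stopifnot(nrow(tbl) > 0)
  p <- tbl$p_value
  if (adjust == "bh") p <- p.adjust(p, method = "BH")
  sel <- !is.na(p) & p < alpha & tbl$converged
  tbl$gene_id[sel]
}

#' Write a results table to TSV
#'
#' Fixed column order, full-precision numeric formatting; the file
#' round-trips losslessly through [read_results()].
#'
#' @param tbl results table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results <- function(tbl, path) {
  out <- as.data.frame(tbl)[, .result_columns]
  for (cl in names(out)) {
    if (is.numeric(out[[cl]]) && !is.integer(out[[cl]]))
      out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path TSV path
#' @return a `data.frame` of class `idesc_results`.
#' @export
read_results <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(.result_columns %in% names(tbl)))
    stop("not a results table: missing columns", call. = FALSE)
  for (cl in setdiff(.result_columns,
                     c("gene_id", "converged", "status",
                       "n_cells_expressing")))
    tbl[[cl]] <- as.numeric(tbl[[cl]])
  tbl$converged <- as.logical(tbl$converged)
  class(tbl) <- c("idesc_results", "data.frame")
  tbl
}
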