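#' Per-gene proportion of zero counts
#'
#' @param cm a [count_matrix]
#' @return named vector of zero proportions in `[0, 1]`, one per gene.
#' @export
gene_zero_proportion <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"), ncol(cm$counts) >= 1)
  1 - Matrix::rowSums(cm$counts > 0) / ncol(cm$counts)
}

#' Gene-level expression summary for the dropout curve
#'
#' The x-axis of the pooled dropout curve: the log of the gene-level mean
#' log-normalized value across all cells (`axis = "log_mean"`, the default).
#' `axis = "mean"` returns the mean itself without the outer log; the two
#' conventions differ only by a monotone transform of the axis and are both
#' exposed because figure-style displays often label the raw mean.
#'
#' @param nm a `normalized_matrix` from [log_normalize()]
#' @param axis `"log_mean"` or `"mean"`
#' @return named vector, one summary per gene.
#' @export
gene_expression_summary <- function(nm, axis = c("log_mean", "mean")) {
  stopifnot(inherits(nm, "normalized_matrix"))
  axis <- match.arg(axis)
  mu <- Matrix::rowMeans(nm$values)
  if (any(mu <= 0))
    stop("gene(s) with zero mean normalized expression; ",
         "apply filter_genes() first", call. = FALSE)
  if (axis == "log_mean") log(mu) else mu
}

#' Fit the pooled dropout curve
#'
#' Local polynomial (LOESS) regression of per-gene zero proportions on the
#' gene-level expression summary. The curve pools information across genes
#' and supplies the baseline dropout rate `pi0` of every gene entering the
#' zero-inflated mixed model. Fitted values are clipped into `clip_bounds`
#' so that `logit(pi0)` is always finite.
#'
#' @param x gene-level expression summaries (see [gene_expression_summary()])
#' @param y per-gene zero proportions in `[0, 1]`
#' @param span LOESS span (fraction of points in each local fit)
#' @param degree local polynomial degree
#' @param clip_bounds length-2 numeric, clipping interval strictly inside
#'   `(0, 1)`
#' @return object of class `dropout_curve`
#' @export
fit_dropout_curve <- function(x, y, span = 0.75, degree = 2,
                              clip_bounds = c(1e-4, 1 - 1e-4)) {
  stopifnot(length(x) == length(y), all(is.finite(x)))
  if (length(x) < 10)
    stop("need at least 10 genes to fit the dropout curve", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("zero proportions must lie in [0, 1]",
                               call. = FALSE)
  stopifnot(length(clip_bounds) == 2, clip_bounds[1] > 0,
            clip_bounds[2] < 1, clip_bounds[1] < clip_bounds[2])
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  fit <- stats::loess(y ~ x, data = df, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  structure(list(fit = fit, x_range = range(df$x), clip_bounds = clip_bounds,
                 span = span, degree = degree, x = df$x, y = df$y),
            class = "dropout_curve")
}

#' Baseline dropout rates from a fitted curve
#'
#' Smoothed, clipped prediction of the baseline dropout rate at the given
#' expression summaries. Queries outside the training range are clamped to
#' the range endpoints (local regression is not extrapolated).
#'
#' @param curve a `dropout_curve` from [fit_dropout_curve()]
#' @param x_query expression summaries at which to predict
#' @return vector of dropout rates, strictly inside the curve's clip bounds.
#' @export
predict_pi0 <- function(curve, x_query) {
  stopifnot(inherits(curve, "dropout_curve"))
  xq <- clamp(as.numeric(x_query), curve$x_range[1], curve$x_range[2])
  p <- predict(curve$fit, newdata = data.frame(x = xq))
  p <- clamp(p, curve$clip_bounds[1], curve$clip_bounds[2])
  names(p) <- names(x_query)
  p
}

#' @export
print.dropout_curve <- function(x, ...) {
  cat(sprintf(
    "dropout_curve: %d genes, span %.2f, degree %d, x range [%.3g, %.3g]\n",
    length(x$x), x$span, x$degree, x$x_range[1], x$x_range[2]))
  invisible(x)
}

#' Subject-level dropout curves
#'
#' Diagnostic companion of [fit_dropout_curve()]: one curve per subject,
#' fitted on that subject's cells only, to visualize between-subject
#' heterogeneity of the dropout-expression relationship. These curves are
#' not used in the test statistic.
#'
#' @param cm a [count_matrix]
#' @param nm matching `normalized_matrix`
#' @param span,degree,clip_bounds as in [fit_dropout_curve()]
#' @param min_genes minimum number of expressed genes for a subject to be
#'   fitted; subjects below it are skipped with a warning
#' @param axis expression-summary convention, see [gene_expression_summary()]
#' @return named list of `dropout_curve` objects, one per fitted subject.
#' @export
subject_level_curves <- function(cm, nm, span = 0.75, degree = 2,
                                 clip_bounds = c(1e-4, 1 - 1e-4),
                                 min_genes = 10,
                                 axis = c("log_mean", "mean")) {
  stopifnot(inherits(cm, "count_matrix"), inherits(nm, "normalized_matrix"))
  axis <- match.arg(axis)
  out <- list()
  for (s in names(cm$group)) {
    cells <- which(cm$subject == s)
    vals <- nm$values[, cells, drop = FALSE]
    mu <- Matrix::rowMeans(vals)
    keep <- mu > 0
    if (sum(keep) < min_genes) {
      warning("subject ", s, " has fewer than ", min_genes,
              " expressed genes; skipped", call. = FALSE)
      next
    }
    x <- if (axis == "log_mean") log(mu[keep]) else mu[keep]
    y <- Matrix::rowSums(cm$counts[keep, cells, drop = FALSE] == 0) /
      length(cells)
    out[[s]] <- fit_dropout_curve(x, y, span = span, degree = degree,
                                  clip_bounds = clip_bounds)
  }
  out
}
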