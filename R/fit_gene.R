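# Per-gene maximum-likelihood fitting of the zero-inflated NB mixed model.
#
# The 6-dimensional parameter (alpha, beta, log sigma^2, theta, log tau^2,
# log d) is maximized by L-BFGS-B on the Laplace-approximate marginal
# likelihood; the per-subject random-effect modes are warm-started across
# objective evaluations. Standard errors come from the observed information
# (central-difference Hessian) at the optimum, with boundary-stuck or
# information-free coordinates dropped before inversion.

#' Numerical options for [fit_gene()]
#'
#' @param integrator `"laplace"` (default) or `"aghq"`
#' @param gh_points quadrature nodes per dimension when `integrator="aghq"`
#' @param max_restarts maximum jittered restarts after a failed fit
#' @param factr,pgtol L-BFGS-B convergence controls (relative objective
#'   change and projected-gradient infinity norm)
#' @param maxit maximum L-BFGS-B iterations
#' @param seed seed for the restart jitter
#' @return a list of class `fit_options`
#' @export
fit_options <- function(integrator = c("laplace", "aghq"), gh_points = 9,
                        max_restarts = 3, factr = 1e7, pgtol = 1e-5,
                        maxit = 300, seed = 1) {
  integrator <- match.arg(integrator)
  structure(list(integrator = integrator, gh_points = gh_points,
                 max_restarts = max_restarts, factr = factr, pgtol = pgtol,
                 maxit = maxit, seed = seed),
            class = "fit_options")
}

# bounds on (alpha, beta, log sigma^2, theta, log tau^2, log d)
.par_lower <- c(-30, -10, log(1e-8), -15, log(1e-8), log(1e-4))
.par_upper <- c(10, 10, log(1e3), 15, log(1e3), log(1e6))

#' Fit the zero-inflated NB mixed model to one gene
#'
#' Maximizes the marginal likelihood of the two-component model (dropout +
#' negative binomial count, subject random intercepts in both components,
#' log depth offset in the NB mean) and tests the group effect with a Wald
#' statistic. The baseline dropout rate `pi0` is plugged in as known, as
#' produced by the pooled dropout curve.
#'
#' @param y per-cell counts of the gene
#' @param depths per-cell sequencing depths
#' @param subject per-cell subject ids
#' @param group named map subject -> group (0/1)
#' @param pi0 the gene's baseline dropout rate in `(0, 1)`
#' @param options a [fit_options] list
#' @return object of class `gene_fit`: list with `params`
#'   ([gene_model_params] at the optimum), `se_beta`, `wald_z`, `p_value`,
#'   `loglik`, `converged`, `boundary` (named logical for the two variance
#'   components), `n_subjects`, `n_cells`, `messages`.
#' @export
fit_gene <- function(y, depths, subject, group, pi0,
                     options = fit_options()) {
  stopifnot(pi0 > 0, pi0 < 1)
  if (all(y == 0))
    stop("gene has no nonzero counts; cannot be fitted", call. = FALSE)
  blocks <- gene_blocks(y, depths, subject, group)
  X <- blocks$X
  if (length(unique(X)) < 2)
    stop("both groups must be represented", call. = FALSE)
  q0 <- qlogis(pi0)
  gh <- gauss_hermite(options$gh_points)
  method <- if (options$integrator == "laplace") 0L else 1L
  n_subj <- length(X)

  # moment-style initial values: group rates on the depth-offset scale
  S <- exp(blocks$logS)
  in0 <- X[findInterval(seq_along(blocks$y) - 0.5, blocks$subj_ptr)] == 0
  r0 <- (sum(blocks$y[in0]) + 0.5) / sum(S[in0])
  r1 <- (sum(blocks$y[!in0]) + 0.5) / sum(S[!in0])
  par0 <- c(log(r0), clamp(log(r1 / r0), -3, 3), log(0.1), 0, log(0.1), 0)
  par0 <- clamp(par0, .par_lower + 1e-6, .par_upper - 1e-6)

  env <- new.env(parent = emptyenv())
  negll <- function(par) {
    res <- cpp_marginal_loglik(par, blocks$y, blocks$logS, blocks$lgy1,
                               blocks$uyidx, blocks$uy, blocks$subj_ptr,
                               X, q0, env$modes, method,
                               gh$nodes, gh$weights)
    if (!res$ok || !is.finite(res$ll)) return(1e10)
    env$modes <- res$modes
    -res$ll
  }

  messages <- character(0)
  best <- NULL
  for (attempt in 0:options$max_restarts) {
    start <- if (attempt == 0) par0 else
      with_local_seed(derive_seed(options$seed, attempt),
                      clamp(par0 + rnorm(6, 0, 0.5),
                            .par_lower + 1e-6, .par_upper - 1e-6))
    env$modes <- matrix(0, n_subj, 2)
    opt <- tryCatch(
      optim(start, negll, method = "L-BFGS-B",
            lower = .par_lower, upper = .par_upper,
            control = list(factr = options$factr, pgtol = options$pgtol,
                           maxit = options$maxit)),
      error = function(e) NULL)
    if (is.null(opt)) {
      messages <- c(messages, sprintf("attempt %d: optimizer error", attempt))
      next
    }
    if (opt$value >= 1e10) {
      messages <- c(messages,
                    sprintf("attempt %d: non-finite likelihood", attempt))
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) break
    messages <- c(messages, sprintf("attempt %d: optim code %d (%s)",
                                    attempt, opt$convergence, opt$message))
  }

  ests <- function(par) {
    gene_model_params(alpha = par[1], beta = par[2], sigma2 = exp(par[3]),
                      theta = par[4], tau2 = exp(par[5]), d = exp(par[6]),
                      pi0 = pi0)
  }

  if (is.null(best)) {
    return(structure(list(params = NULL, se_beta = NA_real_,
                          wald_z = NA_real_, p_value = NA_real_,
                          loglik = NA_real_, converged = FALSE,
                          boundary = c(sigma2 = NA, tau2 = NA),
                          n_subjects = n_subj, n_cells = length(blocks$y),
                          messages = c(messages, "all attempts failed")),
                     class = "gene_fit"))
  }

  par_hat <- best$par
  boundary <- c(sigma2 = par_hat[3] <= .par_lower[3] + 1e-6,
                tau2 = par_hat[5] <= .par_lower[5] + 1e-6)
  if (any(boundary))
    messages <- c(messages, paste0("variance at lower boundary: ",
                                   paste(names(boundary)[boundary],
                                         collapse = ", ")))

  # observed information on the free coordinates
  at_bound <- par_hat <= .par_lower + 1e-6 | par_hat >= .par_upper - 1e-6
  free <- which(!at_bound | seq_along(par_hat) %in% c(1, 2))
  # warm up the random-effect mode cache at the optimum so every
  # finite-difference evaluation starts from converged modes
  env$modes <- matrix(0, n_subj, 2)
  negll(par_hat)
  negll(par_hat)
  fn_free <- function(p) {
    full <- par_hat
    full[free] <- p
    negll(full)
  }
  H <- tryCatch(num_hessian(fn_free, par_hat[free]), error = function(e) NULL)
  se_beta <- NA_real_
  if (!is.null(H) && all(is.finite(H))) {
    # Flat directions (e.g. a saturated zero-observation deviation or a
    # drifting dropout variance) make the full information singular; drop
    # the least-informative non-beta coordinates until it inverts cleanly.
    keep <- diag(H) > 1e-8
    keep[free == 2] <- TRUE
    repeat {
      Hk <- H[keep, keep, drop = FALSE]
      V <- tryCatch(chol2inv(chol(Hk)), error = function(e) NULL)
      bidx <- which(free[keep] == 2)
      if (!is.null(V) && V[bidx, bidx] > 0) {
        se_beta <- sqrt(V[bidx, bidx])
        break
      }
      droppable <- which(keep & free != 2)
      if (length(droppable) == 0) break
      keep[droppable[which.min(diag(H)[droppable])]] <- FALSE
    }
  }
  if (!is.finite(se_beta))
    messages <- c(messages, "standard error unavailable (singular information)")

  converged <- best$convergence == 0 && is.finite(se_beta)
  wald_z <- if (is.finite(se_beta)) par_hat[2] / se_beta else NA_real_
  p_value <- if (is.finite(se_beta)) 2 * pnorm(-abs(wald_z)) else NA_real_

  structure(list(params = ests(par_hat), se_beta = se_beta, wald_z = wald_z,
                 p_value = p_value, loglik = -best$value,
                 converged = converged, boundary = boundary,
                 n_subjects = n_subj, n_cells = length(blocks$y),
                 messages = messages),
            class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  if (is.null(x$params)) {
    cat("gene_fit: failed (", paste(x$messages, collapse = "; "), ")\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("gene_fit: beta = %.4f (se %.4f), z = %.3f, p = %.3g\n",
                     "  alpha %.3f, sigma2 %.4g, theta %.3f, tau2 %.4g, ",
                     "d %.3g, pi0 %.3f\n  %d subjects, %d cells, %s\n"),
              x$params$beta, x$se_beta, x$wald_z, x$p_value, x$params$alpha,
              x$params$sigma2, x$params$theta, x$params$tau2, x$params$d,
              x$params$pi0, x$n_subjects, x$n_cells,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Wald test of the group effect
#'
#' `z = beta / se(beta)` referred to a standard normal; two-sided p-value.
#'
#' @param fit a `gene_fit` from [fit_gene()]
#' @return list with elements `z` and `p` (both `NA`, with a `reason`
#'   attribute, when the standard error is unavailable).
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "gene_fit"))
  if (is.null(fit$params) || !is.finite(fit$se_beta) || fit$se_beta <= 0) {
    out <- list(z = NA_real_, p = NA_real_)
    attr(out, "reason") <- "standard error missing or non-positive"
    return(out)
  }
  z <- fit$params$beta / fit$se_beta
  list(z = z, p = 2 * pnorm(-abs(z)))
}
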