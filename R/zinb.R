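#' Negative binomial log-pmf (mean/dispersion parameterization)
#'
#' Log probability of `y` under a negative binomial with mean `mu` and
#' dispersion `d`, i.e. variance `mu + mu^2/d` (the "nbinom2" convention:
#' larger `d` means less overdispersion; `d -> Inf` recovers the Poisson).
#'
#' @param y non-negative integer count(s)
#' @param mu positive mean(s)
#' @param d positive dispersion
#' @return log probability, vectorized over `y`/`mu`.
#' @export
nb_log_pmf <- function(y, mu, d) {
  if (any(y < 0) || any(y != round(y)))
    stop("y must be a non-negative integer", call. = FALSE)
  stopifnot(all(mu > 0), all(d > 0))
  dnbinom(y, size = d, mu = mu, log = TRUE)
}

#' Cell-level log-likelihood of the zero-inflated NB mixture
#'
#' One observation's contribution to the model likelihood. A zero count can
#' arise from dropout (probability `pi_zero_branch`, which includes the
#' zero-observation deviation `theta` on the logit scale) or from the count
#' distribution; a positive count rules dropout out, with the dropout
#' probability evaluated without `theta` (`pi_pos_branch`).
#'
#' @param y observed count(s)
#' @param S cell depth(s)
#' @param lambda relative expression rate (positive)
#' @param pi_zero_branch dropout probability applying at an observed zero
#' @param pi_pos_branch dropout probability applying at a positive count
#' @param d dispersion
#' @return log-likelihood, vectorized over cells.
#' @export
zinb_cell_loglik <- function(y, S, lambda, pi_zero_branch, pi_pos_branch, d) {
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  stopifnot(all(pi_zero_branch > 0), all(pi_zero_branch < 1),
            all(pi_pos_branch > 0), all(pi_pos_branch < 1), all(d > 0))
  n <- length(y)
  mu <- rep(S * lambda, length.out = n)
  p0 <- rep(pi_zero_branch, length.out = n)
  pp <- rep(pi_pos_branch, length.out = n)
  out <- numeric(n)
  z <- y == 0
  if (any(z)) {
    nb0 <- dnbinom(0, size = d, mu = mu[z])
    out[z] <- log(p0[z] + (1 - p0[z]) * nb0)
  }
  if (any(!z)) {
    out[!z] <- log1p(-pp[!z]) + nb_log_pmf(y[!z], mu[!z], d)
  }
  out
}

#' Model parameters for one gene
#'
#' @param alpha intercept of the log relative-expression rate
#' @param beta group effect (log fold change, group 2 vs group 1)
#' @param sigma2 variance of the subject random intercept in the count
#'   component (`>= 0`)
#' @param theta logit-scale deviation of the dropout rate at an observed zero
#' @param tau2 variance of the subject random intercept in the dropout
#'   component (`>= 0`)
#' @param d NB dispersion (`> 0`), variance `mu + mu^2/d`
#' @param pi0 baseline dropout rate in `(0, 1)` (plugged in from the pooled
#'   dropout curve, treated as known)
#' @return object of class `gene_model_params`
#' @export
gene_model_params <- function(alpha, beta, sigma2 = 0, theta = 0, tau2 = 0,
                              d = 1, pi0 = 0.5) {
  stopifnot(sigma2 >= 0, tau2 >= 0, d > 0, pi0 > 0, pi0 < 1)
  structure(list(alpha = alpha, beta = beta, sigma2 = sigma2, theta = theta,
                 tau2 = tau2, d = d, pi0 = pi0),
            class = "gene_model_params")
}

# Internal: reorder one gene's cells by subject and precompute the static
# tables the C++ likelihood needs.
gene_blocks <- function(y, depths, subject, group) {
  stopifnot(length(y) == length(depths), length(y) == length(subject))
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(depths <= 0)) stop("all cell depths must be positive", call. = FALSE)
  subj_levels <- names(group)
  if (is.null(subj_levels)) {
    subj_levels <- unique(subject)
    names(group) <- subj_levels
  }
  f <- factor(subject, levels = subj_levels)
  if (anyNA(f)) stop("cells mapped to unknown subjects", call. = FALSE)
  ord <- order(as.integer(f))
  y <- as.integer(y[ord])
  logS <- log(as.numeric(depths[ord]))
  sizes <- tabulate(f, nbins = length(subj_levels))
  keep <- sizes > 0
  subj_levels <- subj_levels[keep]
  sizes <- sizes[keep]
  uy <- sort(unique(y[y > 0]))
  uyidx <- integer(length(y))
  pos <- y > 0
  uyidx[pos] <- match(y[pos], uy) - 1L
  list(y = y, logS = logS,
       lgy1 = lgamma(y + 1),
       uy = as.numeric(uy), uyidx = uyidx,
       subj_ptr = as.integer(c(0, cumsum(sizes))),
       X = as.numeric(group[subj_levels]),
       subjects = subj_levels)
}

par_from_params <- function(params) {
  c(params$alpha, params$beta, log(max(params$sigma2, 1e-300)), params$theta,
    log(max(params$tau2, 1e-300)), log(params$d))
}

#' Subject-level integrated log-likelihood
#'
#' Log-likelihood of one subject's cells with the pair of subject random
#' intercepts integrated out: a joint 2-D Laplace approximation (default),
#' adaptive Gauss-Hermite quadrature, or plain Monte Carlo (for validation).
#' With `sigma2 = tau2 = 0` all three reduce to the fixed-effect
#' log-likelihood.
#'
#' @param params a [gene_model_params]
#' @param y,depths the subject's counts and cell depths
#' @param x_i subject's group indicator (0/1)
#' @param method `"laplace"`, `"aghq"` or `"mc"`
#' @param gh_points quadrature nodes per dimension for `"aghq"`
#' @param n_mc Monte Carlo sample size for `"mc"`
#' @param seed RNG seed for `"mc"`
#' @return the integrated log-likelihood (a single number).
#' @export
subject_integrated_loglik <- function(params, y, depths, x_i = 0,
                                      method = c("laplace", "aghq", "mc"),
                                      gh_points = 15, n_mc = 1e5, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(params, "gene_model_params"), length(y) >= 1)
  if (method == "mc") {
    sg <- sqrt(params$sigma2); tu <- sqrt(params$tau2)
    q0 <- qlogis(params$pi0)
    lls <- with_local_seed(seed, {
      u <- rnorm(n_mc); v <- rnorm(n_mc)
      vapply(seq_len(n_mc), function(r) {
        lam <- exp(params$alpha + params$beta * x_i + sg * u[r])
        sum(zinb_cell_loglik(y, depths, lam,
                             plogis(q0 + params$theta + tu * v[r]),
                             plogis(q0 + tu * v[r]), params$d))
      }, numeric(1))
    })
    mx <- max(lls)
    return(mx + log(mean(exp(lls - mx))))
  }
  blocks <- gene_blocks(y, depths, rep("s1", length(y)),
                        stats::setNames(x_i, "s1"))
  gh <- gauss_hermite(gh_points)
  res <- cpp_marginal_loglik(par_from_params(params), blocks$y, blocks$logS,
                             blocks$lgy1, blocks$uyidx, blocks$uy,
                             blocks$subj_ptr, blocks$X, qlogis(params$pi0),
                             matrix(0, 1, 2),
                             if (method == "laplace") 0L else 1L,
                             gh$nodes, gh$weights)
  if (!res$ok) stop("random-effect integration failed at this parameter ",
                    "point", call. = FALSE)
  res$ll
}

#' Marginal log-likelihood of one gene
#'
#' Sum of [subject_integrated_loglik()] over the subjects of a gene.
#'
#' @param params a [gene_model_params]
#' @param y,depths,subject per-cell counts, depths and subject ids
#' @param group named group map (subject -> 0/1)
#' @param method integration method, see [subject_integrated_loglik()]
#' @param gh_points quadrature nodes per dimension for `"aghq"`
#' @return the marginal log-likelihood (a single number).
#' @export
marginal_loglik <- function(params, y, depths, subject, group,
                            method = c("laplace", "aghq"), gh_points = 15) {
  method <- match.arg(method)
  stopifnot(inherits(params, "gene_model_params"))
  blocks <- gene_blocks(y, depths, subject, group)
  gh <- gauss_hermite(gh_points)
  res <- cpp_marginal_loglik(par_from_params(params), blocks$y, blocks$logS,
                             blocks$lgy1, blocks$uyidx, blocks$uy,
                             blocks$subj_ptr, blocks$X, qlogis(params$pi0),
                             matrix(0, length(blocks$X), 2),
                             if (method == "laplace") 0L else 1L,
                             gh$nodes, gh$weights)
  if (!res$ok) stop("random-effect integration failed at this parameter ",
                    "point", call. = FALSE)
  res$ll
}
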