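# Fixtures and independent oracles shared across the test files. Everything
# is generated in code; no data files are read.

# A small hand-controllable count matrix: K genes x (n_subj * m) cells with
# Poisson-ish counts, at least two subjects per group.
toy_cm <- function(K = 12, n_subj = 6, m = 10, seed = 1, rate = 5) {
  withr::local_seed(seed)
  N <- n_subj * m
  counts <- matrix(rpois(K * N, rate), K, N)
  subj <- rep(sprintf("s%02d", seq_len(n_subj)), each = m)
  cells <- sprintf("c%03d", seq_len(N))
  group <- stats::setNames(rep(c(0L, 1L), each = n_subj / 2),
                           sprintf("s%02d", seq_len(n_subj)))
  count_matrix(counts, gene_ids = sprintf("g%02d", seq_len(K)),
               cell_ids = cells,
               subject_of_cell = stats::setNames(subj, cells),
               group_of_subject = group)
}

# Brute-force 2-D trapezoid integration of the subject marginal likelihood
# on a +-width SD grid, built on the exported cell-level log-likelihood --
# independent of the compiled Laplace/AGHQ path.
quad_subject_loglik <- function(params, y, S, x_i, ngrid = 401, width = 8) {
  sg <- sqrt(params$sigma2)
  tu <- sqrt(params$tau2)
  q0 <- stats::qlogis(params$pi0)
  u <- seq(-width, width, length.out = ngrid)
  v <- seq(-width, width, length.out = ngrid)
  du <- u[2] - u[1]
  dv <- v[2] - v[1]
  M <- outer(u, v, Vectorize(function(uu, vv) {
    lam <- exp(params$alpha + params$beta * x_i + sg * uu)
    sum(zinb_cell_loglik(y, S, lam,
                         stats::plogis(q0 + params$theta + tu * vv),
                         stats::plogis(q0 + tu * vv), params$d)) +
      stats::dnorm(uu, log = TRUE) + stats::dnorm(vv, log = TRUE)
  }))
  mx <- max(M)
  mx + log(sum(exp(M - mx)) * du * dv)
}

# Simulate a small model-generated gene and fit it; shared by several tests.
quick_fit <- function(beta = 0, n_subjects = 6, m = 20, seed = 1,
                      pi0 = 0.3, sigma2 = 0.1, tau2 = 0.1, d = 1,
                      alpha = log(2e-3)) {
  params <- gene_model_params(alpha = alpha, beta = beta, sigma2 = sigma2,
                              tau2 = tau2, d = d, pi0 = pi0)
  g <- simulate_zinb_gene(n_subjects, m, params, seed = seed)
  fit_gene(g$y, g$depths, g$subject, g$group, pi0 = pi0)
}
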