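#' Simulation configuration
#'
#' Settings of the multi-subject UMI simulation used for type-I-error and
#' power studies. The defaults are the study conditions used throughout:
#' dispersion `d = 1`, logit-scale dropout variance `sigma2_pi = 2000`,
#' 150 DE genes and 300 non-DE genes, 30 subjects split 15/15.
#'
#' @param n_subjects number of base subjects drawn from the reference
#' @param m simulated cells per subject-sample (study grid: 20, 50, 100)
#' @param beta log fold change of the DE genes (grid: +-0.1 ... +-0.7)
#' @param delta capture-efficiency knob scaling the baseline dropout logit
#'   (grid: 0.5, 1, 1.5). With reference dropout rates mostly above 1/2,
#'   delta = 0.5 is the high-capture setting (fewest zeros) and delta = 1.5
#'   the low-capture setting (most zeros)
#' @param sigma2_pi variance of the cell-level dropout logit
#' @param d NB dispersion used for all simulated genes
#' @param n_de,n_null number of ground-truth DE and non-DE genes
#' @param paired if `TRUE`, every base subject contributes one sample to
#'   *each* group (sharing its dropout and expression parameters), giving
#'   `2 * n_subjects` analyzed subjects; if `FALSE` (default) the base
#'   subjects are split evenly between the two groups
#' @param seed RNG seed; fixes the dataset bit-for-bit
#' @return a list of class `simulation_config`
#' @export
simulation_config <- function(n_subjects = 30, m = 50, beta = 0.4, delta = 1,
                              sigma2_pi = 2000, d = 1, n_de = 150,
                              n_null = 300, paired = FALSE, seed = 1) {
  stopifnot(n_subjects >= 2, m >= 1, delta > 0, sigma2_pi >= 0, d > 0,
            n_de >= 0, n_null >= 1)
  if (!paired && n_subjects %% 2 != 0)
    stop("unpaired designs need an even number of subjects", call. = FALSE)
  structure(list(n_subjects = n_subjects, m = m, beta = beta, delta = delta,
                 sigma2_pi = sigma2_pi, d = d, n_de = n_de, n_null = n_null,
                 paired = paired, seed = seed),
            class = "simulation_config")
}

#' Synthetic reference parameters
#'
#' Generates a reference-parameter set of the same shape as
#' [estimate_reference_params()] output without requiring any real dataset:
#' per-gene, per-subject relative expression rates drawn log-normally with
#' subject-level jitter, per-gene dispersions around 1, subject-specific
#' dropout rates following a decreasing logistic trend in log expression
#' (the S-shaped dropout-vs-expression relationship of droplet data), and
#' per-subject sequencing-depth pools. The defaults guarantee at least 450
#' genes satisfying the moderate-to-high expression selection rule
#' `lambda_ik >= 1/S_ij` for all cells and subjects.
#'
#' @param K number of genes (>= 450)
#' @param n_subjects number of subjects (>= 30)
#' @param seed RNG seed (bit-reproducible output)
#' @param depth_pool_size depths per subject pool
#' @param depth_meanlog,depth_sdlog log-normal depth distribution
#' @param lambda_meanlog,lambda_sdlog gene-level log-normal distribution of
#'   relative expression
#' @param subject_lambda_sd log-scale sd of the subject-level expression
#'   jitter
#' @param dropout_intercept,dropout_slope,dropout_subject_sd logit-linear
#'   dependence of the dropout rate on centred log expression (slope < 0)
#'   plus subject-level logit jitter
#' @param d_meanlog,d_sdlog log-normal distribution of per-gene dispersion
#' @return object of class `reference_params`: list with `gene_ids`,
#'   `subjects`, `pi_hat` (K x n), `lambda_hat` (K x n), `d_hat` (K) and
#'   `depth_pools` (named list).
#' @export
make_synthetic_reference <- function(K = 600, n_subjects = 30, seed = 1,
                                     depth_pool_size = 200,
                                     depth_meanlog = log(5000),
                                     depth_sdlog = 0.3,
                                     lambda_meanlog = log(3e-3),
                                     lambda_sdlog = 1,
                                     subject_lambda_sd = 0.15,
                                     dropout_intercept = 1,
                                     dropout_slope = -1,
                                     dropout_subject_sd = 0.3,
                                     d_meanlog = 0, d_sdlog = 0.3) {
  stopifnot(K >= 450, n_subjects >= 30, dropout_slope < 0)
  with_local_seed(seed, {
    subjects <- sprintf("S%02d", seq_len(n_subjects))
    shift <- rnorm(n_subjects, 0, 0.2)
    depth_pools <- lapply(seq_len(n_subjects), function(i) {
      pmax(round(rlnorm(depth_pool_size, depth_meanlog + shift[i],
                        depth_sdlog)), 1000)
    })
    names(depth_pools) <- subjects

    lambda_k <- rlnorm(K, lambda_meanlog, lambda_sdlog)
    lambda_hat <- lambda_k *
      exp(matrix(rnorm(K * n_subjects, 0, subject_lambda_sd), K, n_subjects))
    d_hat <- rlnorm(K, d_meanlog, d_sdlog)
    logit_pi <- dropout_intercept +
      dropout_slope * (log(lambda_hat) - lambda_meanlog) +
      matrix(rnorm(K * n_subjects, 0, dropout_subject_sd), K, n_subjects)
    pi_hat <- clamp(plogis(logit_pi), 1e-3, 1 - 1e-3)

    gene_ids <- sprintf("gene%04d", seq_len(K))
    dimnames(lambda_hat) <- dimnames(pi_hat) <- list(gene_ids, subjects)
    names(d_hat) <- gene_ids
    ref <- structure(list(gene_ids = gene_ids, subjects = subjects,
                          pi_hat = pi_hat, lambda_hat = lambda_hat,
                          d_hat = d_hat, depth_pools = depth_pools),
                     class = "reference_params")
    if (length(eligible_genes(ref)) < 450)
      stop("fewer than 450 genes satisfy the expression selection rule; ",
           "increase K or the expression level", call. = FALSE)
    ref
  })
}

# Genes passing the moderate-to-high expression rule: lambda_ik >= 1/S_ij
# for every cell of every subject, evaluated against the depth pools.
eligible_genes <- function(ref) {
  thr <- vapply(ref$depth_pools, function(p) 1 / min(p), numeric(1))
  ok <- rowSums(sweep(ref$lambda_hat, 2, thr, `>=`)) == ncol(ref$lambda_hat)
  ref$gene_ids[ok]
}

#' Estimate reference parameters from a real dataset
#'
#' Per-gene maximum-likelihood fit of a fixed-effect zero-inflated NB model
#' with subject-specific dropout rate and relative expression and a shared
#' per-gene dispersion:
#' `Y_ij ~ pi_i I(Y=0) + (1 - pi_i) NB(S_ij lambda_i, d)`.
#' The estimates (plus the per-subject depth pools) parameterize the
#' simulator so that simulated data mimic the source dataset.
#'
#' @param cm a preprocessed [count_matrix]
#' @param clip clipping interval for the dropout-rate estimates
#' @param d_interval search interval for `log d`
#' @param depths optional named per-cell depths overriding the column sums
#'   (for matrices covering only a gene panel)
#' @return a `reference_params` object; genes whose fit fails are excluded
#'   with a warning.
#' @export
estimate_reference_params <- function(cm, clip = c(1e-4, 1 - 1e-4),
                                      d_interval = c(log(0.05), log(50)),
                                      depths = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(depths)) depths <- cell_depths(cm)
  else depths <- depths[colnames(cm$counts)]
  if (any(!is.finite(depths) | depths <= 0))
    stop("invalid cell depths", call. = FALSE)
  subjects <- names(cm$group)
  genes <- rownames(cm$counts)
  K <- length(genes)
  n <- length(subjects)
  cells_of <- lapply(subjects, function(s) which(cm$subject == s))

  lam_bounds <- c(-30, 5)
  fit_subject <- function(y, S, ld) {
    d <- exp(ld)
    nll <- function(p) {
      pi <- plogis(p[1]); lam <- exp(p[2]); mu <- S * lam
      ll <- sum(ifelse(y == 0,
                       log(pi + (1 - pi) * dnbinom(0, size = d, mu = mu)),
                       log1p(-pi) + dnbinom(y, size = d, mu = mu, log = TRUE)))
      if (!is.finite(ll)) 1e10 else -ll
    }
    init <- c(qlogis(clamp(mean(y == 0), 0.02, 0.98)),
              log((sum(y) + 0.5) / sum(S)))
    optim(init, nll, method = "L-BFGS-B",
          lower = c(qlogis(clip[1]), lam_bounds[1]),
          upper = c(qlogis(clip[2]), lam_bounds[2]))
  }

  pi_hat <- matrix(NA_real_, K, n, dimnames = list(genes, subjects))
  lambda_hat <- matrix(NA_real_, K, n, dimnames = list(genes, subjects))
  d_hat <- stats::setNames(rep(NA_real_, K), genes)
  ok <- rep(TRUE, K)

  for (k in seq_len(K)) {
    yk <- as.numeric(cm$counts[k, ])
    res <- tryCatch({
      prof <- function(ld) {
        sum(vapply(seq_len(n), function(i) {
          idx <- cells_of[[i]]
          fit_subject(yk[idx], depths[idx], ld)$value
        }, numeric(1)))
      }
      opt_d <- optimize(prof, interval = d_interval)
      ld <- opt_d$minimum
      fits <- lapply(seq_len(n), function(i) {
        idx <- cells_of[[i]]
        fit_subject(yk[idx], depths[idx], ld)
      })
      list(ld = ld,
           pi = vapply(fits, function(f) clamp(plogis(f$par[1]),
                                               clip[1], clip[2]),
                       numeric(1)),
           lam = vapply(fits, function(f) exp(f$par[2]), numeric(1)),
           conv = all(vapply(fits, function(f) f$convergence == 0,
                             logical(1))))
    }, error = function(e) NULL)
    if (is.null(res) || !res$conv) {
      ok[k] <- FALSE
      next
    }
    d_hat[k] <- exp(res$ld)
    pi_hat[k, ] <- res$pi
    lambda_hat[k, ] <- res$lam
  }
  if (!all(ok))
    warning(sum(!ok), " gene(s) excluded from the reference ",
            "(non-convergent fixed-effect fit)", call. = FALSE)

  depth_pools <- lapply(cells_of, function(idx) as.numeric(depths[idx]))
  names(depth_pools) <- subjects
  structure(list(gene_ids = genes[ok], subjects = subjects,
                 pi_hat = pi_hat[ok, , drop = FALSE],
                 lambda_hat = lambda_hat[ok, , drop = FALSE],
                 d_hat = d_hat[ok], depth_pools = depth_pools),
            class = "reference_params")
}

#' Simulate a multi-subject UMI dataset with ground truth
#'
#' Draws a dataset from the reference-driven generative process: base
#' subjects are sampled from the reference; each subject-sample receives `m`
#' sequencing depths drawn without replacement from that subject's depth
#' pool (with replacement, with a warning, if the pool is too small); counts
#' follow `Y ~ pi I(Y=0) + (1 - pi) NB(S * lambda_hat * exp(beta * I(group
#' 2)), d)` where the cell-level dropout logit is drawn as `N(delta *
#' logit(pi_hat), sigma2_pi)`. DE genes receive the `exp(beta)` mean shift in
#' group 2 only. Per-gene RNG substreams make the dataset reproducible
#' bit-for-bit and ensure that changing `beta` alters counts only for DE
#' genes in group 2.
#'
#' @param ref a `reference_params` object
#' @param cfg a [simulation_config]
#' @return object of class `simulated_dataset`: list with `cm` (a
#'   [count_matrix]), `truth` (`data.frame` with `gene_id`, `is_de`,
#'   `beta_true`) and `config`.
#' @export
simulate_dataset <- function(ref, cfg = simulation_config()) {
  stopifnot(inherits(ref, "reference_params"),
            inherits(cfg, "simulation_config"))
  elig <- eligible_genes(ref)
  n_genes <- cfg$n_de + cfg$n_null
  if (length(elig) < n_genes)
    stop("only ", length(elig), " eligible genes in the reference; ",
         n_genes, " requested", call. = FALSE)
  if (cfg$n_subjects > length(ref$subjects))
    stop("reference has fewer subjects than requested", call. = FALSE)

  design <- with_local_seed(derive_seed(cfg$seed, 0L), {
    genes <- sort(sample(elig, n_genes))
    de_genes <- sample(genes, cfg$n_de)
    base <- sample(ref$subjects, cfg$n_subjects)
    if (cfg$paired) {
      samples <- c(paste0(base, "_g1"), paste0(base, "_g2"))
      base_of <- c(base, base)
      grp <- rep(c(0L, 1L), each = cfg$n_subjects)
    } else {
      samples <- base
      base_of <- base
      grp <- rep(c(0L, 1L), each = cfg$n_subjects / 2)
    }
    depths <- lapply(seq_along(samples), function(s) {
      pool <- ref$depth_pools[[base_of[s]]]
      if (cfg$m > length(pool)) {
        warning("depth pool of subject ", base_of[s], " smaller than m; ",
                "sampling with replacement", call. = FALSE)
        sample(pool, cfg$m, replace = TRUE)
      } else {
        sample(pool, cfg$m, replace = FALSE)
      }
    })
    list(genes = genes, de_genes = de_genes, samples = samples,
         base_of = base_of, grp = grp, depths = depths)
  })

  n_samp <- length(design$samples)
  N <- n_samp * cfg$m
  S <- unlist(design$depths)
  cell_sample <- rep(seq_len(n_samp), each = cfg$m)
  cell_ids <- sprintf("%s_c%03d", design$samples[cell_sample],
                      rep(seq_len(cfg$m), times = n_samp))
  x_cell <- design$grp[cell_sample]
  base_cell <- design$base_of[cell_sample]

  is_de <- design$genes %in% design$de_genes
  counts <- matrix(0L, n_genes, N)
  sd_pi <- sqrt(cfg$sigma2_pi)
  for (g in seq_len(n_genes)) {
    gene <- design$genes[g]
    lam <- ref$lambda_hat[gene, base_cell]
    piL <- qlogis(ref$pi_hat[gene, base_cell])
    b <- if (is_de[g]) cfg$beta else 0
    # separate RNG substreams: dropout draws, group-1 counts, group-2
    # counts. beta enters only the group-2 stream, so changing it leaves
    # all other draws untouched.
    drop <- with_local_seed(derive_seed(cfg$seed, 3L * g - 2L), {
      z <- rnorm(N, cfg$delta * piL, sd_pi)
      rbinom(N, 1L, plogis(z))
    })
    mu <- S * lam * exp(b * x_cell)
    y <- integer(N)
    g1 <- x_cell == 0
    y[g1] <- with_local_seed(derive_seed(cfg$seed, 3L * g - 1L),
                             rnbinom(sum(g1), size = cfg$d, mu = mu[g1]))
    y[!g1] <- with_local_seed(derive_seed(cfg$seed, 3L * g),
                              rnbinom(sum(!g1), size = cfg$d, mu = mu[!g1]))
    counts[g, ] <- ifelse(drop == 1L, 0L, y)
  }

  cm <- count_matrix(counts, gene_ids = design$genes, cell_ids = cell_ids,
                     subject_of_cell = stats::setNames(
                       design$samples[cell_sample], cell_ids),
                     group_of_subject = stats::setNames(design$grp,
                                                        design$samples))
  truth <- data.frame(gene_id = design$genes, is_de = is_de,
                      beta_true = ifelse(is_de, cfg$beta, 0))
  # The generating depths are the cells' transcriptome-wide totals, of
  # which the simulated gene panel is only a small subset; analyses of the
  # simulated data should use these as the depth offsets.
  structure(list(cm = cm, truth = truth,
                 depths = stats::setNames(S, cell_ids), config = cfg),
            class = "simulated_dataset")
}

#' Simulate one gene directly from the mixed model
#'
#' Generative counterpart of [fit_gene()] with `theta = 0` (the
#' zero-observation deviation makes the two-branch likelihood a quasi-model,
#' so only the `theta = 0` member is a proper generative distribution):
#' subject random intercepts in both components, NB counts with depth
#' offset. Used for parameter-recovery and calibration studies.
#'
#' @param n_subjects number of subjects (split evenly between groups)
#' @param m cells per subject
#' @param params a [gene_model_params] (its `theta` must be 0)
#' @param depth_meanlog,depth_sdlog log-normal depth distribution
#' @param seed RNG seed
#' @return list with `y`, `depths`, `subject`, `group`.
#' @export
simulate_zinb_gene <- function(n_subjects, m, params,
                               depth_meanlog = log(5000), depth_sdlog = 0.3,
                               seed = 1) {
  stopifnot(inherits(params, "gene_model_params"), n_subjects %% 2 == 0)
  if (params$theta != 0)
    stop("only theta = 0 defines a proper generative model", call. = FALSE)
  with_local_seed(seed, {
    subjects <- sprintf("S%02d", seq_len(n_subjects))
    group <- stats::setNames(rep(c(0L, 1L), each = n_subjects / 2), subjects)
    gamma_i <- rnorm(n_subjects, 0, sqrt(params$sigma2))
    eta_i <- rnorm(n_subjects, 0, sqrt(params$tau2))
    N <- n_subjects * m
    subj_cell <- rep(seq_len(n_subjects), each = m)
    depths <- pmax(round(rlnorm(N, depth_meanlog, depth_sdlog)), 100)
    lam <- exp(params$alpha + params$beta * group[subj_cell] +
                 gamma_i[subj_cell])
    pi <- plogis(qlogis(params$pi0) + eta_i[subj_cell])
    drop <- rbinom(N, 1L, pi)
    y <- ifelse(drop == 1L, 0L, rnbinom(N, size = params$d, mu = depths * lam))
    list(y = y, depths = depths, subject = subjects[subj_cell], group = group)
  })
}
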