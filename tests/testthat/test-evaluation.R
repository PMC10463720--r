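test_that("sensitivity and specificity match hand counts", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  p <- c(0.01, 0.2, NA, 0.03, 0.6, 0.9)
  ss <- sens_spec(p, truth, alpha = 0.05)
  expect_equal(ss$sensitivity, 1 / 3)   # only the 0.01 among true DE
  expect_equal(ss$specificity, 2 / 3)   # 0.03 is a false positive
  # all significant: sensitivity 1, specificity 0
  ss2 <- sens_spec(rep(0, 6), truth, alpha = 0.05)
  expect_equal(ss2$sensitivity, 1)
  expect_equal(ss2$specificity, 0)
  # no true DE genes: sensitivity undefined
  expect_true(is.na(sens_spec(p, rep(FALSE, 6), 0.05)$sensitivity))
})

test_that("AUC oracle cases and invariances", {
  truth <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(roc_auc(c(0.01, 0.02, 0.03, 0.04, 0.5, 0.6, 0.7, 0.8), truth),
               1)
  expect_equal(roc_auc(c(0.5, 0.6, 0.7, 0.8, 0.01, 0.02, 0.03, 0.04), truth),
               0)
  # invariant under strictly monotone transforms of p
  withr::local_seed(8)
  p <- runif(8)
  expect_equal(roc_auc(p, truth), roc_auc(plogis(5 * qlogis(p)), truth))
  # random labels give AUC ~ 0.5 on average
  aucs <- vapply(1:200, function(s) {
    withr::local_seed(s)
    roc_auc(runif(20), sample(rep(c(TRUE, FALSE), 10)))
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
  expect_error(roc_auc(p, rep(TRUE, 8)), "both classes")
})

test_that("Fisher overlap matches brute-force hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:20)
  a <- universe[1:5]
  b <- universe[c(1:4, 10)]
  # P(overlap >= 4) by enumeration over the hypergeometric pmf
  pmf <- function(k) choose(5, k) * choose(15, 5 - k) / choose(20, 5)
  expect_equal(fisher_overlap(a, b, universe), sum(vapply(4:5, pmf,
                                                          numeric(1))),
               tolerance = 1e-12)
  # symmetry
  expect_equal(fisher_overlap(a, b, universe), fisher_overlap(b, a, universe))
  # matches fisher.test's one-sided alternative
  ft <- stats::fisher.test(matrix(c(4, 1, 1, 14), 2, 2),
                           alternative = "greater")
  expect_equal(fisher_overlap(a, b, universe), ft$p.value, tolerance = 1e-9)
  # degenerate: forced overlap is never significant
  expect_equal(fisher_overlap(universe, universe, universe), 1)
  # disjoint sets sit on the anti-enrichment side
  expect_gte(fisher_overlap(universe[1:5], universe[6:10], universe), 0.5)
  expect_error(fisher_overlap(a, b, character(0)), "empty universe")
  expect_error(fisher_overlap(c(a, "zz"), b, universe), "subsets")
})

test_that("Jaccard index: identities and the published worked example", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a", "b"), c("c", "d")), 0)
  expect_equal(jaccard(character(0), character(0)), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "a", "a")), 1)  # dedup
  # two DE lists of 5577 and 1124 genes sharing 808
  A <- sprintf("g%04d", 1:5577)
  B <- sprintf("g%04d", c(1:808, 6001:6316 + 1))
  expect_identical(length(B), 1124L)
  expect_equal(jaccard(A, B), 808 / 5893)
  expect_equal(round(jaccard(A, B), 3), 0.137)
  # symmetry
  expect_equal(jaccard(A, B), jaccard(B, A))
})

test_that("effect coefficients are scaled dot products", {
  # 2 genes x 3 cells with hand-computable values
  vals <- Matrix::Matrix(rbind(g1 = c(1, 2, 0), g2 = c(0.5, 0, 1)),
                         sparse = TRUE)
  nm <- structure(list(values = methods::as(vals, "generalMatrix"),
                       scale_factor = 1e4),
                  class = "normalized_matrix")
  colnames(nm$values) <- c("c1", "c2", "c3")
  tbl <- data.frame(gene_id = c("g1", "g2"), beta = c(0.5, -1),
                    converged = TRUE)
  ec <- effect_coefficients(nm, tbl, c("g1", "g2"))
  raw <- c(1 * 0.5 + 0.5 * -1, 2 * 0.5, 1 * -1)
  expect_equal(unname(ec), raw / max(abs(raw)))
  expect_equal(max(abs(ec)), 1)
  # single positive gene: cell ranking equals expression ranking
  ec1 <- effect_coefficients(nm, tbl[1, , drop = FALSE], "g1")
  expect_identical(order(ec1), order(as.numeric(nm$values["g1", ])))
  expect_error(effect_coefficients(nm, tbl, character(0)), "non-empty")
  tbl$converged[2] <- FALSE
  expect_error(effect_coefficients(nm, tbl, c("g1", "g2")), "converged")
})

test_that("permutation harness: injected dummy analyses behave as specified", {
  cm <- toy_cm(K = 15, n_subj = 6, m = 8, seed = 91)
  genes <- rownames(cm$counts)
  # a method that never rejects has rate 0 everywhere
  never <- function(x) data.frame(gene_id = genes, p_value = rep(1, 15))
  pt0 <- permutation_type1(cm, n_perm = 20, alpha = 0.05, seed = 1,
                           de_fun = never)
  expect_true(all(pt0$rate == 0))
  # uniform p-values land in the binomial band around alpha
  k <- 0
  unif <- function(x) {
    k <<- k + 1
    withr::local_seed(1000 + k)
    data.frame(gene_id = genes, p_value = runif(15))
  }
  pt1 <- permutation_type1(cm, n_perm = 400, alpha = 0.05, seed = 2,
                           de_fun = unif)
  band <- qbinom(c(0.005, 0.995), 400, 0.05) / 400
  expect_gte(median(pt1$rate), band[1])
  expect_lte(median(pt1$rate), band[2])
  # permutations preserve group sizes
  perms <- attr(pt1, "perms")
  expect_true(all(colSums(perms) == sum(cm$group)))
})

test_that("each permutation replicate is exactly a relabeled rerun", {
  ref <- make_synthetic_reference(seed = 101)
  cfg <- simulation_config(n_subjects = 6, m = 15, beta = 0, n_de = 0,
                           n_null = 12, seed = 92)
  sim <- simulate_dataset(ref, cfg)
  config <- idesc_config(seed = 3)
  pt <- permutation_type1(sim$cm, n_perm = 3, alpha = 0.05, seed = 4,
                          config = config, depths = sim$depths)
  perms <- attr(pt, "perms")
  pmat <- attr(pt, "p_matrix")
  # replaying one permuted labeling by hand reproduces its p-values exactly
  cm_r <- sim$cm
  cm_r$group <- stats::setNames(perms[, 2], rownames(perms))
  direct <- run_idesc(cm_r, config, depths = sim$depths)
  expect_identical(unname(pmat[, 2]), direct$p_value)
  # so a permutation equal to the original labels reproduces the base run
  base <- run_idesc(sim$cm, config, depths = sim$depths)
  cm_id <- sim$cm
  cm_id$group <- stats::setNames(unname(sim$cm$group), names(sim$cm$group))
  expect_identical(run_idesc(cm_id, config, depths = sim$depths)$p_value,
                   base$p_value)
})
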