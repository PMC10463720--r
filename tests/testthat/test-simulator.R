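test_that("synthetic references are reproducible and well-formed", {
  r1 <- make_synthetic_reference(seed = 5)
  r2 <- make_synthetic_reference(seed = 5)
  expect_identical(r1, r2)
  expect_true(all(r1$pi_hat > 0 & r1$pi_hat < 1))
  expect_true(all(r1$lambda_hat > 0))
  expect_true(all(r1$d_hat > 0))
  # dropout decreases with expression across genes
  expect_lt(cor(log(rowMeans(r1$lambda_hat)), rowMeans(r1$pi_hat),
                method = "spearman"), -0.5)
  # the moderate-to-high expression rule leaves enough genes at defaults
  expect_gte(length(idesc:::eligible_genes(r1)), 450)
})

test_that("the default simulation contract holds: 150 DE / 300 non-DE, 30 subjects", {
  ref <- make_synthetic_reference(seed = 6)
  sim <- simulate_dataset(ref, simulation_config(seed = 60))
  expect_identical(sum(sim$truth$is_de), 150L)
  expect_identical(sum(!sim$truth$is_de), 300L)
  expect_identical(nrow(sim$cm$counts), 450L)
  expect_identical(length(sim$cm$group), 30L)
  expect_identical(as.vector(table(sim$cm$group)), c(15L, 15L))
  expect_true(all(sim$truth$beta_true[!sim$truth$is_de] == 0))
  expect_true(all(cells_per_subject(sim$cm) == 50))
  expect_identical(median_cells_per_subject(sim$cm), 50)
})

test_that("simulation is seed-deterministic and beta-localized", {
  ref <- make_synthetic_reference(seed = 6)
  cfg <- simulation_config(n_subjects = 8, m = 10, beta = 0.5, n_de = 5,
                           n_null = 10, seed = 61)
  s1 <- simulate_dataset(ref, cfg)
  s2 <- simulate_dataset(ref, cfg)
  expect_identical(as.matrix(s1$cm$counts), as.matrix(s2$cm$counts))
  # changing beta only touches DE genes in group-2 cells
  cfg3 <- cfg; cfg3$beta <- 1.2
  s3 <- simulate_dataset(ref, cfg3)
  de <- s1$truth$gene_id[s1$truth$is_de]
  g2_cells <- names(s1$cm$subject)[s1$cm$group[s1$cm$subject] == 1]
  m1 <- as.matrix(s1$cm$counts); m3 <- as.matrix(s3$cm$counts)
  null_genes <- setdiff(rownames(m1), de)
  expect_identical(m1[null_genes, ], m3[null_genes, ])
  g1_cells <- setdiff(colnames(m1), g2_cells)
  expect_identical(m1[de, g1_cells], m3[de, g1_cells])
  expect_false(identical(m1[de, g2_cells], m3[de, g2_cells]))
})

test_that("capture efficiency controls the zero fraction monotonically", {
  ref <- make_synthetic_reference(seed = 6)
  zf <- vapply(c(0.5, 1, 1.5), function(delta) {
    cfg <- simulation_config(n_subjects = 10, m = 20, beta = 0, n_de = 0,
                             n_null = 60, delta = delta, seed = 62)
    mean(as.matrix(simulate_dataset(ref, cfg)$cm$counts) == 0)
  }, numeric(1))
  # delta scales the dropout logit; with reference dropout rates mostly
  # above 1/2, larger delta means lower capture efficiency and more zeros
  expect_true(all(diff(zf) > 0))
})

test_that("the e^beta mean shift is present in DE genes", {
  ref <- make_synthetic_reference(seed = 6)
  cfg <- simulation_config(n_subjects = 30, m = 50, beta = 0.4, n_de = 30,
                           n_null = 30, seed = 63)
  sim <- simulate_dataset(ref, cfg)
  m <- as.matrix(sim$cm$counts)
  S <- sim$depths
  grp <- sim$cm$group[sim$cm$subject]
  # depth-normalized nonzero-branch means; dropout is group-independent
  ratio <- vapply(seq_len(nrow(m)), function(k) {
    y <- m[k, ]
    mean(y[grp == 1] / S[grp == 1]) / mean(y[grp == 0] / S[grp == 0])
  }, numeric(1))
  de <- sim$truth$is_de
  expect_equal(median(log(ratio[de])), 0.4, tolerance = 0.35)
  expect_equal(median(log(ratio[!de])), 0, tolerance = 0.12)
  expect_gt(median(log(ratio[de])) - median(log(ratio[!de])), 0.2)
})

test_that("paired designs give every base subject one sample per group", {
  ref <- make_synthetic_reference(seed = 6)
  cfg <- simulation_config(n_subjects = 5, m = 8, beta = 0, n_de = 0,
                           n_null = 10, paired = TRUE, seed = 64)
  sim <- simulate_dataset(ref, cfg)
  expect_identical(length(sim$cm$group), 10L)
  expect_identical(as.vector(table(sim$cm$group)), c(5L, 5L))
  base <- sub("_g[12]$", "", names(sim$cm$group))
  expect_true(all(table(base) == 2))
})

test_that("depth pools too small for m fall back to replacement with warning", {
  ref <- make_synthetic_reference(seed = 6, depth_pool_size = 30)
  cfg <- simulation_config(n_subjects = 4, m = 40, beta = 0, n_de = 0,
                           n_null = 5, seed = 65)
  w <- capture_warnings(sim <- simulate_dataset(ref, cfg))
  expect_true(any(grepl("with replacement", w)))
  expect_true(all(cells_per_subject(sim$cm) == 40))
})

test_that("reference estimation recovers known fixed-effect parameters", {
  # single subject, many cells, known (pi, lambda, d)
  withr::local_seed(71)
  n <- 2000
  S <- pmax(round(rlnorm(n, log(4000), 0.3)), 500)
  drop <- rbinom(n, 1, 0.3)
  y <- ifelse(drop == 1, 0L, rnbinom(n, size = 1, mu = S * 0.01))
  counts <- matrix(y, 1, n, dimnames = list("g1", sprintf("c%04d", 1:n)))
  counts <- rbind(counts, g2 = rpois(n, 2) + 1L)  # keeps depths positive
  cm <- count_matrix(counts, subject_of_cell = rep("s1", n),
                     group_of_subject = c(s1 = 0))
  # the 2-gene panel's column sums are not the generating depths; supply
  # the true totals explicitly
  ref <- estimate_reference_params(
    cm, depths = stats::setNames(S, colnames(cm$counts)))
  expect_equal(unname(ref$pi_hat["g1", 1]), 0.3, tolerance = 0.1)
  expect_equal(unname(ref$d_hat["g1"]), 1, tolerance = 0.35)
  expect_equal(unname(ref$lambda_hat["g1", 1]), 0.01, tolerance = 0.1)
})

test_that("reference estimation respects its boundary and offset contracts", {
  withr::local_seed(72)
  n <- 300
  S <- rep(4000, n)
  y1 <- rnbinom(n, size = 2, mu = S * 0.005) + 1L  # no zeros at all
  y2 <- ifelse(rbinom(n, 1, 0.4) == 1, 0L, rnbinom(n, size = 1, mu = S * 0.004))
  cm <- count_matrix(rbind(g1 = y1, g2 = y2),
                     subject_of_cell = rep("s1", n),
                     group_of_subject = c(s1 = 0))
  ref <- estimate_reference_params(cm)
  # a subject with no zeros sits at the lower clip bound
  expect_equal(unname(ref$pi_hat["g1", 1]), 1e-4)
  # doubling all depths halves the estimated rates (offset contract)
  ref2 <- estimate_reference_params(cm, depths = 2 * cell_depths(cm))
  expect_equal(ref2$lambda_hat, ref$lambda_hat / 2, tolerance = 1e-3)
})
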