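test_that("count_matrix validates its invariants", {
  counts <- matrix(0:5, 3, 2)
  expect_error(count_matrix(counts, gene_ids = c("a", "a", "b"),
                            cell_ids = c("c1", "c2"),
                            subject_of_cell = c(c1 = "s1", c2 = "s2"),
                            group_of_subject = c(s1 = 0, s2 = 1)),
               "duplicated gene")
  expect_error(count_matrix(matrix(c(0, -1, 2, 3), 2, 2),
                            subject_of_cell = c("s1", "s2"),
                            group_of_subject = c(s1 = 0, s2 = 1)),
               "non-negative integers")
  expect_error(count_matrix(matrix(c(0.5, 1, 2, 3), 2, 2),
                            subject_of_cell = c("s1", "s2"),
                            group_of_subject = c(s1 = 0, s2 = 1)),
               "non-negative integers")
  # cells missing from metadata
  expect_error(count_matrix(counts, gene_ids = letters[1:3],
                            cell_ids = c("c1", "c2"),
                            subject_of_cell = c(c1 = "s1"),
                            group_of_subject = c(s1 = 0)),
               "absent from metadata")
  # three group levels are not binary-codable
  expect_error(count_matrix(matrix(1:9, 3, 3),
                            subject_of_cell = c("s1", "s2", "s3"),
                            group_of_subject = c(s1 = "a", s2 = "b",
                                                 s3 = "c")),
               "not binary-codable")
  # non-0/1 two-level coding is mapped by sorted order
  cm <- count_matrix(counts,
                     subject_of_cell = c("s1", "s2"),
                     group_of_subject = c(s1 = "case", s2 = "ctrl"))
  expect_identical(unname(cm$group), c(0L, 1L))
})

test_that("gene filter keeps exactly the genes at or above the threshold", {
  # 10 genes expressed in 0..9 of 100 cells; threshold 0.05 keeps >= 5
  counts <- matrix(0L, 10, 100)
  for (k in 1:10) if (k > 1) counts[k, seq_len(k - 1)] <- 1L
  cm <- count_matrix(counts,
                     subject_of_cell = rep(c("s1", "s2", "s3", "s4"), 25),
                     group_of_subject = c(s1 = 0, s2 = 0, s3 = 1, s4 = 1))
  kept <- filter_genes(cm, 0.05)
  frac <- Matrix::rowSums(cm$counts > 0) / 100
  expect_identical(rownames(kept$counts), rownames(cm$counts)[frac >= 0.05])
  # gene in 4/100 removed, gene in exactly 5/100 retained
  expect_false("gene0005" %in% rownames(kept$counts))  # 4 nonzero cells
  expect_true("gene0006" %in% rownames(kept$counts))   # 5 nonzero cells
  expect_identical(ncol(kept$counts), 100L)
  expect_error(filter_genes(cm, 1), "all genes removed")
})

test_that("subject filter boundary and brute-force recount", {
  withr::local_seed(7)
  counts <- matrix(rpois(8 * 31, 3), 8, 31)
  subj <- rep(c("a", "b", "c", "d", "e", "f"), c(4, 5, 6, 7, 8, 1))
  cm <- count_matrix(counts, subject_of_cell = subj,
                     group_of_subject = c(a = 0, b = 0, c = 0, d = 1, e = 1,
                                          f = 1))
  out <- filter_subjects(cm, min_cells = 5)
  # 'a' (4 cells) and 'f' (1 cell) dropped; 'b' with exactly 5 cells kept
  expect_identical(sort(names(out$group)), c("b", "c", "d", "e"))
  expect_identical(sum(cells_per_subject(out)),
                   as.integer(sum(table(subj)[table(subj) >= 5])))
  expect_error(filter_subjects(cm, min_cells = 7),
               "fewer than 2 subjects per group")
})

test_that("filters are idempotent and commute", {
  withr::local_seed(3)
  counts <- matrix(rbinom(20 * 40, 4, 0.15), 20, 40)
  counts[, 1:3] <- pmax(counts[, 1:3], 1)  # keep depths positive
  subj <- rep(sprintf("s%d", 1:6), c(3, 5, 9, 9, 7, 7))
  cm <- count_matrix(counts, subject_of_cell = subj,
                     group_of_subject = stats::setNames(
                       c(0, 0, 0, 1, 1, 1), sprintf("s%d", 1:6)))
  a <- filter_subjects(filter_genes(cm, 0.1), 5)
  b <- filter_genes(filter_subjects(cm, 5), 0.1)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  expect_identical(a$group, b$group)
  expect_identical(as.matrix(filter_genes(a, 0.1)$counts), as.matrix(a$counts))
  expect_identical(as.matrix(filter_subjects(a, 5)$counts), as.matrix(a$counts))
})

test_that("median cells per subject follows the even-length convention", {
  mk <- function(sizes) {
    n <- sum(sizes)
    subj <- rep(sprintf("s%d", seq_along(sizes)), sizes)
    grp <- stats::setNames(rep_len(c(0, 1), length(sizes)),
                           sprintf("s%d", seq_along(sizes)))
    count_matrix(matrix(1L, 2, n), subject_of_cell = subj,
                 group_of_subject = grp)
  }
  expect_equal(median_cells_per_subject(mk(c(10, 20, 30))), 20)
  expect_equal(median_cells_per_subject(mk(c(10, 20))), 15)
})

test_that("log-normalization matches its closed form and preserves ranks", {
  cm <- toy_cm(K = 8, n_subj = 4, m = 6, seed = 5)
  nm <- log_normalize(cm, scale_factor = 1e4)
  S <- cell_depths(cm)
  dense <- as.matrix(cm$counts)
  expected <- log1p(sweep(dense, 2, S, "/") * 1e4)
  expect_equal(as.matrix(nm$values), expected, tolerance = 1e-12)
  # zero iff zero
  expect_identical(as.matrix(nm$values) == 0, dense == 0)
  # count equal to the cell depth maps to log(scale_factor + 1)
  one <- count_matrix(matrix(c(3L, 2L), 1, 2),
                      subject_of_cell = c("s1", "s2"),
                      group_of_subject = c(s1 = 0, s2 = 1))
  expect_equal(log_normalize(one)$values[1, 1], log(10001))
  # within-cell rank order preserved
  for (j in seq_len(ncol(dense)))
    expect_identical(order(dense[, j]), order(as.matrix(nm$values)[, j]))
  # zero-depth cell rejected
  z <- count_matrix(matrix(c(1L, 0L), 1, 2),
                    subject_of_cell = c("s1", "s2"),
                    group_of_subject = c(s1 = 0, s2 = 1))
  expect_error(log_normalize(z), "filter")
})
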