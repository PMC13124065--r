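test_that("cell-mean matrix centers by the grand mean (hand fixture)", {
  rows <- expand.grid(subject = 1:2, group = c("A", "B"),
                      condition = c("c1", "c2"), stringsAsFactors = FALSE)
  rows$subject <- paste(rows$group, rows$subject, sep = "_")
  vals <- c("A/c1" = 1, "B/c1" = 3, "A/c2" = 5, "B/c2" = 7)
  x <- matrix(vals[paste(rows$group, rows$condition, sep = "/")], ncol = 1)
  block <- data_block(x, rows$subject, rows$group, rows$condition, "e1")
  design <- study_design(rows[, c("subject", "group", "condition")])
  cm <- condition_mean_matrix(block, design)
  expect_equal(cm$grand_mean[["e1"]], 4)
  # design_cells order is group-major: A/c1, A/c2, B/c1, B/c2
  expect_equal(as.vector(cm$M), c(-3, 1, -1, 3))
  # identical subjects in every cell -> centered matrix all zero
  block0 <- data_block(matrix(2, nrow(rows), 3), rows$subject, rows$group,
                       rows$condition, paste0("e", 1:3))
  expect_true(all(condition_mean_matrix(block0, design)$M == 0))
  # an empty cell is a design error naming the cell
  bad <- block
  bad$group[bad$group == "B" & bad$condition == "c2"] <- "A"
  expect_error(condition_mean_matrix(
    data_block(x, paste0(seq_len(nrow(rows))), bad$group, bad$condition, "e1"),
    design), "B/c2")
})

test_that("a 4x3 design yields 12 cells and 11 latent variables", {
  nb <- noise_block(n_groups = 4, n_conditions = 3, n_subj = 4, n_elem = 15)
  cm <- condition_mean_matrix(nb$block, nb$design)
  expect_equal(nrow(cm$M), 12)
  fit <- pls_svd(cm$M)
  expect_length(fit$s, 11)
})

test_that("the SVD decomposition obeys its algebraic identities", {
  set.seed(20)
  M <- matrix(rnorm(8 * 30), 8, 30)
  M <- sweep(M, 2, colMeans(M))
  fit <- pls_svd(M)
  expect_lt(max(abs(crossprod(fit$u) - diag(ncol(fit$u)))), 1e-10)
  expect_lt(max(abs(crossprod(fit$v) - diag(ncol(fit$v)))), 1e-10)
  expect_equal(sum(fit$s^2), sum(M^2), tolerance = 1e-10)
  expect_equal(sum(fit$cov_explained), 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$u %*% diag(fit$s) %*% t(fit$v) - M)), 1e-8)
  # rank-1 recovery up to the sign convention
  u <- c(2, -1, 1) / sqrt(6); v <- c(1, 2, 2, 0) / 3
  M1 <- 5 * outer(u, v)
  f1 <- pls_svd(M1)
  expect_equal(f1$s[1], 5, tolerance = 1e-10)
  expect_equal(abs(f1$v[, 1]), abs(v), tolerance = 1e-10)
  expect_gt(f1$v[which.max(abs(f1$v[, 1])), 1], 0)   # sign convention pinned
  expect_error(pls_svd(matrix(0, 3, 4)), "all-zero")
})

test_that("brain scores reconstruct cell entries and vanish on zero rows", {
  nb <- noise_block(n_groups = 2, n_conditions = 2, n_subj = 4, n_elem = 6,
                    seed = 21)
  cm <- condition_mean_matrix(nb$block, nb$design)
  fit <- pls_svd(cm$M)
  model <- c(fit, list(grand_mean = cm$grand_mean, cells = cm$cells,
                       elements = nb$block$elements))
  # a synthetic block whose rows equal their cell means
  cellkey <- paste(cm$cells$group, cm$cells$condition, sep = "/")
  rowkey <- paste(nb$block$group, nb$block$condition, sep = "/")
  xb <- cm$cell_means[match(rowkey, cellkey), ]
  bl2 <- data_block(xb, nb$block$subject, nb$block$group, nb$block$condition,
                    nb$block$elements)
  sc <- brain_scores(bl2, model)
  us <- fit$u %*% diag(fit$s)
  expect_equal(sc$cell_scores, us, ignore_attr = TRUE, tolerance = 1e-10)
  # a row equal to the grand mean projects to zero
  bz <- data_block(rbind(model$grand_mean), "z", nb$block$group[1],
                   nb$block$condition[1], nb$block$elements)
  expect_true(all(abs(brain_scores(bz, model)$scores) < 1e-12))
  # element mismatch is a schema error
  bm <- data_block(xb[, 1:3], nb$block$subject, nb$block$group,
                   nb$block$condition, nb$block$elements[1:3])
  expect_error(brain_scores(bm, model), "element set")
})

test_that("permutation p-values are seeded, floored, and sensitive", {
  pb <- planted_block(effect = 3, n_subj = 5, seed = 22)
  p1 <- permutation_test(pb$block, pb$design, n_perm = 199, seed = 7)
  p2 <- permutation_test(pb$block, pb$design, n_perm = 199, seed = 7)
  expect_identical(p1, p2)
  expect_equal(p1[1], 1 / 200)               # add-one floor attained
  expect_error(permutation_test(pb$block, pb$design, n_perm = 10), ">= 100")
  # within-subject scheme runs and preserves group membership
  p3 <- permutation_test(pb$block, pb$design, n_perm = 100, seed = 7,
                         scheme = "within_subject")
  expect_true(all(p3 >= 0 & p3 <= 1))
})

test_that("bootstrap ratios flag planted elements and spare noise ones", {
  pb <- planted_block(effect = 3, n_subj = 6, n_elem = 30, n_hit = 5, seed = 23)
  bt <- bootstrap_test(pb$block, pb$design, n_boot = 300, seed = 9)
  bt2 <- bootstrap_test(pb$block, pb$design, n_boot = 300, seed = 9)
  expect_identical(bt$ratios, bt2$ratios)
  thr <- bsr_threshold()
  expect_equal(thr, qnorm(0.995))
  expect_true(all(abs(bt$ratios[1:5, 1]) > thr))
  # noise elements rarely exceed the 99% threshold
  expect_lt(mean(abs(bt$ratios[6:30, 1]) > thr), 0.25)
  expect_error(bootstrap_test(pb$block, pb$design, n_boot = 10), ">= 100")
})

test_that("the full model recovers a planted monotonic group contrast", {
  pb <- planted_block(effect = 2.5, n_subj = 6, seed = 24)
  fit <- mc_task_pls(pb$block, pb$design, n_perm = 200, n_boot = 200, seed = 3)
  expect_length(fit$s, 11)
  expect_lt(fit$perm_p[1], 0.05)
  cosine <- sum(fit$u[, 1] * pb$planted) /
    sqrt(sum(fit$u[, 1]^2) * sum(pb$planted^2))
  expect_gt(abs(cosine), 0.9)
  # group separation on LV1: extreme groups have disjoint score CIs
  ci <- group_score_ci(fit, 1)
  g1 <- ci[ci$group == "G1", ]; g4 <- ci[ci$group == "G4", ]
  expect_true(g1$hi < g4$lo || g4$hi < g1$lo)
  # planted two-group separation in subject scores
  sc1 <- fit$scores[pb$block$group == "G1", 1]
  sc4 <- fit$scores[pb$block$group == "G4", 1]
  d <- abs(mean(sc1) - mean(sc4)) / sqrt((var(sc1) + var(sc4)) / 2)
  expect_gt(d, 1)
})

test_that("missing elements are excluded pairwise and dropped when pervasive", {
  nb <- noise_block(n_subj = 5, n_elem = 10, seed = 25)
  nb$block$x[, 1] <- NA                       # fully missing element
  nb$block$x[2, 3] <- NA                      # sporadic missing value
  expect_message(fit <- mc_task_pls(nb$block, nb$design, n_perm = 100,
                                    n_boot = 0, seed = 1), "dropping")
  expect_equal(nrow(fit$v), 9)
  expect_false(anyNA(fit$v))
})

test_that("tidy tables round-trip into data blocks with segment averaging", {
  df <- data.frame(subject = rep(c("s1", "s2"), each = 4),
                   group = "A", condition = rep(c("c1", "c2"), each = 2),
                   segment = rep(1:2, 4),
                   element = "e1",
                   value = c(1, 3, 5, 7, 2, 4, 6, 8))
  b <- data_block_from_tidy(df)
  expect_equal(dim(b$x), c(4L, 1L))
  expect_equal(sort(as.vector(b$x)), c(2, 3, 6, 7))   # segment means
})
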