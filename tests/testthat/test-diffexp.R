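test_that("fold change is the ratio of linear group means and reciprocal under label swap", {
  em <- make_em(ck = cbind(c(100, 50), c(120, 50)),
                rs = cbind(c(220, 50), c(220, 50)))
  r <- fold_change(em)
  expect_equal(unname(r), c(220 / 110, 1))

  swapped <- expression_matrix(unclass(em),
                               ifelse(attr(em, "groups") == "CK", "RS", "CK"))
  expect_equal(unname(fold_change(swapped)), unname(1 / r))
})

test_that("the SAM d-statistic matches hand computation and is antisymmetric", {
  # CK log2 = (1,1,1), RS log2 = (3,3,3): pooled SE 0, d = 2 / s0
  em <- make_em(ck = matrix(2^c(1, 1, 1), nrow = 1),
                rs = matrix(2^c(3, 3, 3), nrow = 1))
  expect_equal(unname(sam_d_statistic(em, s0 = 0.1)), 20)

  em2 <- make_em(ck = matrix(c(4, 5, 6, 7, 8, 9), nrow = 2),
                 rs = matrix(c(9, 5, 11, 6, 13, 7), nrow = 2))
  d <- sam_d_statistic(em2, s0 = 0.05)
  swapped <- expression_matrix(unclass(em2),
                               ifelse(attr(em2, "groups") == "CK", "RS", "CK"))
  expect_equal(unname(sam_d_statistic(swapped, s0 = 0.05)), unname(-d))

  # equal group means give d = 0
  em3 <- make_em(ck = matrix(c(2, 4), nrow = 1), rs = matrix(c(4, 2), nrow = 1))
  expect_equal(unname(sam_d_statistic(em3, s0 = 0.2)), 0)

  expect_error(sam_d_statistic(make_em(matrix(1, 1), matrix(2, 1)), 0.1),
               "fold-change-only", class = "rslgn_input_error")
})

test_that("s0 estimation matches an independent grid search and handles degenerate input", {
  sim <- simulate_expression(simulation_config(n_genes = 500, seed = 3))
  em <- sim$matrix
  s0 <- estimate_s0(em)

  # independent brute-force search over the same percentile grid
  v <- log2(unclass(em))
  ck <- which(attr(em, "groups") == "CK"); rs <- which(attr(em, "groups") == "RS")
  n1 <- length(ck); n2 <- length(rs)
  s <- sapply(seq_len(nrow(v)), function(g) {
    x <- v[g, ck]; y <- v[g, rs]
    sqrt((1 / n1 + 1 / n2) *
           (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (n1 + n2 - 2))
  })
  num <- rowMeans(v[, rs]) - rowMeans(v[, ck])
  bins <- cut(rank(s, ties.method = "first"), breaks = 10, labels = FALSE)
  cvs <- sapply(unname(quantile(s, seq(0, 0.95, 0.05))), function(cand) {
    d <- num / (s + cand)
    spread <- sapply(1:10, function(b) mad(d[bins == b]))
    sd(spread) / mean(spread)
  })
  expect_equal(s0, unname(quantile(s, seq(0, 0.95, 0.05)))[which.min(cvs)])

  noiseless <- simulate_expression(simulation_config(n_genes = 50, seed = 2,
                                                     noise_sd_log2 = 0))$matrix
  expect_warning(s0z <- estimate_s0(noiseless), "s0 set to 0")
  expect_equal(s0z, 0)
})

test_that("q-values match the exhaustive loop-based oracle on a 3v3 design", {
  sim <- simulate_expression(simulation_config(n_genes = 40, n_per_group = 3,
                                               seed = 8))
  em <- sim$matrix
  s0 <- estimate_s0(em)
  q <- permutation_q_values(em, screen_params(n_permutations = 1000), s0 = s0)
  expect_true(attr(q, "exhaustive"))
  expect_equal(attr(q, "n_permutations_used"), 20)
  expect_equal(as.numeric(q), as.numeric(oracle_exhaustive_q(em, s0)),
               tolerance = 1e-12)
})

test_that("sampled and exhaustive permutation modes agree when all assignments fit", {
  em <- simulate_expression(simulation_config(n_genes = 30, n_per_group = 3,
                                              seed = 14))$matrix
  pe <- permutation_q_values(em, screen_params(n_permutations = 20), method = "exhaustive")
  ps <- permutation_q_values(em, screen_params(n_permutations = 20), method = "sampled")
  expect_equal(as.numeric(pe), as.numeric(ps))
})

test_that("q-values are in [0,1], monotone in |d|, and smallest for the largest |d|", {
  em <- simulate_expression(simulation_config(n_genes = 200, seed = 10))$matrix
  q <- permutation_q_values(em, screen_params())
  d <- attr(q, "d_stat")
  expect_true(all(q >= 0 & q <= 1))
  ord <- order(abs(d), decreasing = TRUE)
  expect_true(all(diff(q[ord]) >= -1e-15))
  expect_equal(unname(q[which.max(abs(d))]), min(q))
})

test_that("screen calls apply both gates inclusively at the printed boundaries", {
  p <- screen_params()
  r <- c(a = 1.99, b = 2.0, c = 3.0, d = 0.5, e = 0.51, f = 1.0)
  q <- c(a = 0, b = 0, c = 0.051, d = 0, e = 0, f = 0)
  deg <- screen_degs(r, q, p)
  calls <- setNames(deg$call, deg$gene_id)
  expect_identical(unname(calls[c("a", "b", "c", "d", "e", "f")]),
                   c("unchanged", "up", "unchanged", "down", "unchanged", "unchanged"))
  # q exactly at the gate passes
  deg2 <- screen_degs(c(g = 3), c(g = 0.05), p)
  expect_identical(deg2$call, "up")
  expect_error(screen_degs(r, q[-1], p), "differ", class = "rslgn_input_error")
})

test_that("shrinking q_max or widening fold bounds never yields more calls", {
  em <- simulate_expression(simulation_config(n_genes = 300, seed = 15))$matrix
  r <- fold_change(em)
  q <- permutation_q_values(em, screen_params())
  n_calls <- function(p) sum(screen_degs(r, q, p)$call != "unchanged")
  base <- n_calls(screen_params())
  expect_lte(n_calls(screen_params(q_max = 0.01)), base)
  expect_lte(n_calls(screen_params(fc_up = 3, fc_down = 0.3)), base)
})

test_that("label swap maps up-calls to down-calls when bounds are reciprocal", {
  em <- simulate_expression(simulation_config(n_genes = 200, seed = 16))$matrix
  p <- screen_params(fc_up = 2, fc_down = 0.5)
  deg <- screen_degs(fold_change(em), permutation_q_values(em, p), p)
  swapped <- expression_matrix(unclass(em),
                               ifelse(attr(em, "groups") == "CK", "RS", "CK"))
  deg_sw <- screen_degs(fold_change(swapped), permutation_q_values(swapped, p), p)
  expect_identical(deg_sw$call[deg$call == "up"],
                   rep("down", sum(deg$call == "up")))
  expect_identical(deg_sw$call[deg$call == "down"],
                   rep("up", sum(deg$call == "down")))
})

test_that("hierarchical clustering merges forced structure first and matches a naive UPGMA", {
  # A and B identical, C anti-correlated: first merge is {A, B} at height 0
  prof <- rbind(A = c(1, 2, 3, 4), B = c(1, 2, 3, 4), C = c(4, 3, 2, 1))
  v <- 2^prof
  colnames(v) <- c("CK_1", "CK_2", "RS_1", "RS_2")
  em <- expression_matrix(v, c("CK", "CK", "RS", "RS"))
  hc <- hierarchical_cluster(em, "genes")
  expect_equal(hc$height[1], 0)
  first <- rownames(v)[-hc$merge[1, ]]
  expect_setequal(first, c("A", "B"))

  em12 <- simulate_expression(simulation_config(n_genes = 12, seed = 17,
                                                pathway_size_range = c(2, 5)))$matrix
  hc12 <- hierarchical_cluster(em12, "genes")
  cc <- cor(t(log2(unclass(em12))))
  expect_equal(sort(hc12$height), oracle_upgma_heights(as.dist(1 - cc)),
               tolerance = 1e-12)

  flat <- em12
  flat[1, ] <- 100   # zero-variance profile
  expect_warning(hierarchical_cluster(flat, "genes"), "zero-variance")
})
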