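test_that("single-cluster fit halves the VAF into a cell fraction", {
  sh <- clone_tree(0L)                           # A -> B
  fit <- fit_clone_frequencies(sh, "B", matrix(0.25, 1, 4))
  expect_equal(unname(fit$freqs["B", ]), rep(0.5, 4), tolerance = 1e-8)
  expect_equal(unname(fit$freqs["A", ]), rep(0.5, 4), tolerance = 1e-8)
  expect_lt(fit$objective, 1e-12)
})

test_that("chain fit solves the subtree-sum system exactly", {
  sh <- clone_tree(c(0L, 1L))                    # A -> B -> C
  fit <- fit_clone_frequencies(sh, c("B", "C"),
                               matrix(c(0.4, 0.1), 2, 3))
  expect_equal(unname(fit$freqs["C", ]), rep(0.2, 3), tolerance = 1e-6)
  expect_equal(unname(fit$freqs["B", ]), rep(0.6, 3), tolerance = 1e-6)
  expect_equal(unname(fit$freqs["A", ]), rep(0.2, 3), tolerance = 1e-6)
  expect_lt(fit$objective, 1e-10)
})

test_that("frequencies form a simplex and infeasible assignments fail", {
  set.seed(89)
  sh <- clone_tree(c(0L, 1L, 1L))
  vafs <- matrix(stats::runif(9, 0, 0.5), 3, 3)
  fit <- fit_clone_frequencies(sh, c("B", "C", "D"), vafs)
  expect_true(all(fit$freqs >= -1e-10))
  expect_equal(unname(colSums(fit$freqs)), rep(1, 3), tolerance = 1e-8)
  expect_error(fit_clone_frequencies(clone_tree(0L), c("B", "C"),
                                     matrix(0.1, 2, 2)), "infeasible")
  expect_error(fit_clone_frequencies(clone_tree(c(0L, 1L)), c("B", "B"),
                                     matrix(0.1, 2, 2)), "distinct")
})

test_that("unassigned nodes are contracted before fitting", {
  sh <- clone_tree(c(0L, 1L, 2L))                # A -> B -> C -> D
  fit <- fit_clone_frequencies(sh, c("B", "D"), matrix(c(0.4, 0.1), 2, 2))
  expect_equal(fit$tree$n_nodes, 2)              # C contracted away
  expect_lt(fit$objective, 1e-10)
})

test_that("well-separated VAF profiles cluster perfectly", {
  set.seed(97)
  centers <- rbind(rep(0.45, 4), rep(0.1, 4))
  vafs <- rbind(centers[rep(1, 30), ] + stats::rnorm(120, 0, 0.02),
                centers[rep(2, 30), ] + stats::rnorm(120, 0, 0.02))
  cl <- cluster_vafs(pmax(vafs, 0), k = 2, seed = 1)
  expect_equal(cl$k, 2)
  expect_length(unique(cl$assignment[1:30]), 1)
  expect_length(unique(cl$assignment[31:60]), 1)
  expect_false(cl$assignment[1] == cl$assignment[31])

  one <- cluster_vafs(vafs, k = 1, seed = 1)
  expect_equal(as.numeric(one$centers), colMeans(vafs))
})

test_that("three-cluster recovery succeeds in at least 90% of seeds", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    truth_lab <- rep(1:3, each = 25)
    centers <- rbind(c(0.5, 0.5, 0.5), c(0.3, 0.05, 0.3), c(0.05, 0.25, 0.02))
    vafs <- pmax(centers[truth_lab, ] +
                   matrix(stats::rnorm(225, 0, 0.02), 75, 3), 0)
    cl <- cluster_vafs(vafs, k = 3, seed = seed)
    perfect <- all(vapply(1:3, function(g)
      length(unique(cl$assignment[truth_lab == g])) == 1, logical(1))) &&
      length(unique(cl$assignment[!duplicated(truth_lab)])) == 3
    hits <- hits + perfect
  }
  expect_gte(hits, 9)
})

test_that("noiseless truth compositions are refit exactly", {
  cfg <- sim_config(n_patients = 1, n_mutations = 60, seed = 13)
  truth <- simulate_truth(cfg)
  pt <- truth$patients[[1]]
  vafs <- pt$true_vaf
  k_true <- length(unique(pt$mutations$clone))
  fit <- select_best_fit(vafs, max_nodes = 4, k_range = k_true, seed = 2)
  expect_lt(fit$objective, 1e-10)
  # fitted frequencies match the generating simplexes after name matching
  rmse <- clonalspread:::clone_frequency_rmse(
    fit, rownames(vafs), pt$mutations, pt$freqs)
  expect_lt(rmse, 1e-5)
})

test_that("model scoring prefers the generating clone count and shape", {
  cfg <- sim_config(n_patients = 1, n_clones = 3, n_mutations = 90,
                    scenario = "early_divergence", seed = 29)
  truth <- simulate_truth(cfg)
  pt <- truth$patients[[1]]
  fit <- select_best_fit(pt$true_vaf, max_nodes = 5, seed = 3)
  expect_equal(fit$tree$n_nodes, 3)   # 3-node truth beats richer shapes

  # single truncal cluster: everything at VAF ~0.4 everywhere -> chain A-B
  mono <- matrix(0.4, 40, 9) + stats::rnorm(360, 0, 0.005)
  fit2 <- select_best_fit(pmax(mono, 0), max_nodes = 5, seed = 4)
  expect_equal(fit2$tree$n_nodes, 1)

  fit3 <- select_best_fit(pt$true_vaf, max_nodes = 5, seed = 3)
  expect_equal(fit$score, fit3$score)  # deterministic under fixed seed
  expect_equal(fit$tree$canonical, fit3$tree$canonical)
})

test_that("ancestral clones are detected as direct children of the root", {
  sh <- clone_tree(c(0L, 1L))                    # A -> B -> C
  fit <- fit_clone_frequencies(sh, c("B", "C"),
                               cbind(s1 = c(0.4, 0.02), s2 = c(0.25, 0.25)))
  sites <- c(s1 = "omentum", s2 = "ovary")
  # s1: freq(B) ~ 0.76 -> flagged; B is A's direct child
  rep <- detect_ancestral_clones(fit, sites, threshold = 0.05)
  expect_true(rep$per_sample$ancestral_present[1])
  expect_equal(rep$peritoneal_with_ancestral, "s1")
  # a sample whose mass sits only on grandchildren is not flagged
  fit$freqs["B", "s2"] <- 0
  fit$freqs["C", "s2"] <- 0.5
  rep2 <- detect_ancestral_clones(fit, sites, threshold = 0.05)
  expect_false(rep2$per_sample$ancestral_present[2])
})
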