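test_that("substitution models are valid reversible rate matrices", {
  for (nm in c("JC69", "K80", "HKY85")) {
    m <- substitution_model(nm, kappa = 3, pi = c(0.4, 0.1, 0.2, 0.3))
    expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sum(m$pi), 1)
    expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)  # unit rate
    P <- transition_prob(m, 0.37)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(all(P >= 0))
    # detailed balance: diag(pi) P is symmetric for reversible models
    flux <- diag(m$pi) %*% P
    expect_equal(flux, t(flux), tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_error(substitution_model("K80", kappa = -1), "kappa")
  expect_error(transition_prob(substitution_model("JC69"), -0.1), "negative")
})

test_that("two-taxon JC69 likelihood matches the closed form", {
  aln <- as_pseudoalignment(matrix(c("A", "A"), 2, 1,
                                   dimnames = list(c("t1", "t2"), NULL)))
  m <- substitution_model("JC69")
  tr0 <- ape::read.tree(text = "(t1:0,t2:0);")
  expect_equal(tree_loglik(tr0, aln, m), log(0.25), tolerance = 1e-12)
  for (t_total in c(0.05, 0.3, 1.2)) {
    tr <- ape::read.tree(text = sprintf("(t1:%f,t2:%f);", t_total / 2,
                                        t_total / 2))
    closed <- log(0.25 * (0.25 + 0.75 * exp(-4 * t_total / 3)))
    expect_equal(tree_loglik(tr, aln, m), closed, tolerance = 1e-10)
  }
})

test_that("pruning equals exhaustive internal-state enumeration", {
  set.seed(53)
  for (ntax in c(4, 5)) {
    for (rep in 1:3) {
      tree <- ape::rtree(ntax, rooted = FALSE)
      tree$edge.length <- stats::runif(nrow(tree$edge), 0.02, 0.8)
      model <- substitution_model(sample(c("JC69", "K80", "HKY85"), 1),
                                  kappa = stats::runif(1, 0.5, 8),
                                  pi = c(0.3, 0.2, 0.25, 0.25))
      chars <- sim_chars_under_model(tree, 20, model)
      aln <- as_pseudoalignment(chars)
      expect_equal(tree_loglik(tree, aln, model),
                   oracle_loglik_enum(tree, chars, model),
                   tolerance = 1e-9)
    }
  }
})

test_that("likelihood is invariant under re-rooting", {
  set.seed(59)
  tree <- ape::rtree(6, rooted = FALSE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.5)
  model <- substitution_model("HKY85", kappa = 4, pi = c(0.35, 0.15, 0.2, 0.3))
  chars <- sim_chars_under_model(tree, 30, model)
  aln <- as_pseudoalignment(chars)
  base <- tree_loglik(tree, aln, model)
  for (og in tree$tip.label[1:3]) {
    rerooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_loglik(rerooted, aln, model), base, tolerance = 1e-8)
  }
})

test_that("branch-length optimization increases likelihood monotonically", {
  set.seed(61)
  model <- substitution_model("JC69")
  tree <- ape::rtree(6, rooted = FALSE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.05, 0.3)
  aln <- as_pseudoalignment(sim_chars_under_model(tree, 100, model))
  start <- tree
  start$edge.length <- rep(0.5, nrow(tree$edge))
  before <- tree_loglik(start, aln, model)
  fit <- optimize_branch_lengths(start, aln, model)
  expect_gt(fit$logLik, before)
  expect_true(all(fit$tree$edge.length >= 0))
})

test_that("BIC model selection identifies the generating model", {
  set.seed(67)
  tree <- ape::rtree(6, rooted = FALSE)
  tree$edge.length <- stats::runif(nrow(tree$edge), 0.1, 0.4)

  # JC69 data: the extra kappa of K80 cannot pay its BIC penalty
  aln_jc <- as_pseudoalignment(
    sim_chars_under_model(tree, 500, substitution_model("JC69")))
  sel_jc <- select_model(aln_jc, c("JC69", "K80"))
  expect_equal(sel_jc$model$name, "JC69")
  expect_equal(sel_jc$table$model[which.min(sel_jc$table$BIC)], "JC69")

  # strongly transition-biased data selects K80
  aln_k80 <- as_pseudoalignment(
    sim_chars_under_model(tree, 2000, substitution_model("K80", kappa = 8)))
  sel_k80 <- select_model(aln_k80, c("JC69", "K80"))
  expect_equal(sel_k80$model$name, "K80")
  expect_gt(sel_k80$model$kappa, 3)

  expect_error(select_model(aln_jc, character(0)), "empty")
})
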