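# Independent oracles: exhaustive-state likelihood, brute-force rooted
# shape generation, brute-force set intersection.

# likelihood by exhaustive enumeration of internal-node states (only
# feasible for <= 5 taxa); shares nothing with the pruning recursion
oracle_loglik_enum <- function(tree, chars, model) {
  tr <- stats::reorder(ape::unroot(tree), "postorder")
  nt <- length(tr$tip.label)
  nn <- tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  nuc <- c("A", "C", "G", "T")
  P_edge <- lapply(seq_len(nrow(tr$edge)), function(k)
    transition_prob(model, tr$edge.length[k]))
  states_grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
  total <- 0
  for (col in seq_len(ncol(chars))) {
    tip_state <- match(chars[tr$tip.label, col], nuc)
    col_lik <- 0
    for (g in seq_len(nrow(states_grid))) {
      st <- c(tip_state, rep(NA, nn))
      st[(nt + 1):(nt + nn)] <- states_grid[g, ]
      p <- model$pi[st[root]]
      for (k in seq_len(nrow(tr$edge))) {
        p <- p * P_edge[[k]][st[tr$edge[k, 1]], st[tr$edge[k, 2]]]
      }
      col_lik <- col_lik + p
    }
    total <- total + log(col_lik)
  }
  unname(total)
}

# rooted unlabeled trees with n nodes via parent vectors p[i] < i,
# deduplicated by a recursively sorted canonical form
oracle_rooted_shape_count <- function(n) {
  if (n == 1) return(1L)
  canon <- function(parent) {
    children <- lapply(seq_along(parent), function(v)
      which(parent == v))
    build <- function(v) {
      kids <- children[[v]]
      if (length(kids) == 0) return("()")
      paste0("(", paste(sort(vapply(kids, build, character(1))),
                        collapse = ""), ")")
    }
    build(1)
  }
  grids <- expand.grid(lapply(2:n, function(i) seq_len(i - 1)))
  length(unique(apply(grids, 1, function(row) canon(c(0L, as.integer(row))))))
}

# per-key membership tally across call sets
oracle_consensus_keys <- function(key_sets, min_callers) {
  tab <- table(unlist(lapply(key_sets, unique)))
  sort(names(tab)[tab >= min_callers])
}

# all unrooted topologies on a taxon set (4 -> 3, 5 -> 15)
all_unrooted_topologies <- function(taxa) {
  trees <- phangorn::allTrees(length(taxa), rooted = FALSE,
                              tip.label = taxa)
  lapply(trees, function(t) {
    t$edge.length <- rep(0.1, nrow(t$edge))
    t
  })
}
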