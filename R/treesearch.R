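# Maximum-likelihood tree search: random starts, NNI hill climbing with
# branch-length re-optimization, and nonparametric bootstrap replicates.

#' Canonical Newick string of a topology
#'
#' Branch lengths are dropped; the tree is (re-)rooted on the
#' lexicographically smallest taxon and children are sorted by their
#' subtree strings, so two trees share a canonical string iff they have the
#' same unrooted topology. Used for deterministic tie-breaking and
#' equality checks.
#'
#' @param tree `phylo`
#' @return character scalar
#' @export
canonical_newick <- function(tree) {
  tree <- ape::unroot(tree)
  ref <- sort(tree$tip.label)[1]
  ntip <- length(tree$tip.label)
  adj <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]
    b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  build <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (length(kids) == 0) return(tree$tip.label[node])
    parts <- sort(vapply(kids, build, character(1), parent = node))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root_tip <- which(tree$tip.label == ref)
  paste0("(", ref, ",", build(adj[[root_tip]][1], root_tip), ");")
}

random_topology <- function(taxa, bl = 0.1) {
  tr <- ape::rtree(length(taxa), rooted = FALSE, br = NULL)
  tr$tip.label <- sample(taxa)
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

nni_neighbors <- function(tree) {
  nb <- phangorn::nni(tree)
  lapply(nb, function(t) {
    if (is.null(t$edge.length)) t$edge.length <- rep(0.1, nrow(t$edge))
    t$edge.length[t$edge.length < 1e-9] <- 1e-9
    t
  })
}

# per-edge canonical child-side split keys ("" for trivial edges)
edge_splits <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  tips <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- tr$tip.label[i]
  e <- tr$edge
  keys <- character(nrow(e))
  for (k in seq_len(nrow(e))) {
    tips[[e[k, 1]]] <- c(tips[[e[k, 1]]], tips[[e[k, 2]]])
  }
  for (k in seq_len(nrow(e))) {
    side <- tips[[e[k, 2]]]
    keys[k] <- if (length(side) < 2 || length(side) > ntip - 2) "" else
      split_key(side, tr$tip.label)
  }
  list(tree = tr, keys = keys)
}

#' Heuristic maximum-likelihood tree search
#'
#' Each of `n_starts` searches begins from an independent random unrooted
#' topology, optimizes branch lengths, then hill-climbs over
#' nearest-neighbor-interchange rearrangements (the best improving
#' neighbor is accepted and branch lengths re-optimized) until no neighbor
#' improves the likelihood. The best tree across starts is returned;
#' likelihood ties are broken by the lexicographically smallest canonical
#' Newick string. Deterministic given `seed`.
#'
#' @param aln `pseudo_alignment` (>= 4 taxa for a meaningful search; with
#'   fewer taxa the unique unrooted topology is returned directly)
#' @param model [substitution_model]
#' @param n_starts number of random starting topologies
#' @param seed integer seed, or `NULL` to continue the current RNG stream
#' @return `phylo` with attributes `logLik` and `n_starts`
#' @export
search_ml_tree <- function(aln, model, n_starts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taxa <- aln$taxa
  pd <- pruning_data(aln)
  if (length(taxa) < 4) {
    fit <- optimize_bl_pruned(star_tree(taxa), pd, model)
    tr <- fit$tree
    attr(tr, "logLik") <- fit$logLik
    return(tr)
  }
  best <- NULL
  best_ll <- -Inf
  best_canon <- ""
  climb <- function(tr) {
    fit <- optimize_bl_pruned(tr, pd, model, max_sweeps = 2)
    tr <- fit$tree
    cur <- fit$logLik
    for (round in 1:40) {
      # evaluate each NNI neighbor with its central (rearranged) branch
      # re-optimized — the fixed-length surface alone is too myopic on
      # plateau-rich SNV alignments — then re-optimize all lengths after
      # accepting; stop when neither step improves
      moved <- FALSE
      repeat {
        cur_keys <- edge_splits(tr)$keys
        nbs <- nni_neighbors(tr)
        best_nb <- NULL
        best_nb_ll <- cur
        for (nb in nbs) {
          es <- edge_splits(nb)
          nb <- es$tree
          for (k in which(!(es$keys %in% cur_keys) & es$keys != "")) {
            opt <- stats::optimize(function(b) {
              l2 <- nb$edge.length
              l2[k] <- b
              loglik_pruned_cpp(nb$edge, l2, pd$tipL[nb$tip.label],
                                length(nb$tip.label), nb$Nnode,
                                model$right, model$eval, model$left,
                                unname(model$pi), pd$w)
            }, interval = c(1e-9, 5), maximum = TRUE, tol = 2e-3)
            nb$edge.length[k] <- opt$maximum
          }
          ll <- loglik_pruned(nb, pd, model)
          if (ll > best_nb_ll + 1e-7) {
            best_nb <- nb
            best_nb_ll <- ll
          }
        }
        if (is.null(best_nb)) break
        tr <- best_nb
        cur <- best_nb_ll
        moved <- TRUE
      }
      fit <- optimize_bl_pruned(tr, pd, model, max_sweeps = 2)
      improved <- fit$logLik > cur + 0.01
      tr <- fit$tree
      cur <- fit$logLik
      if (!moved && !improved) break
    }
    list(tree = tr, logLik = cur)
  }
  # single-taxon SPR: prune each tip and score reattachment on every
  # backbone edge; catches whole-sample misplacements that NNI cannot fix
  # in one move
  reinsert_sweep <- function(tr, cur) {
    improved <- FALSE
    for (tip in tr$tip.label) {
      backbone <- ape::drop.tip(tr, tip)
      cand <- list()
      lls <- numeric(0)
      for (k in seq_len(nrow(backbone$edge))) {
        ct <- phytools::bind.tip(backbone, tip, edge.length = 0.05,
                                 where = backbone$edge[k, 2],
                                 position = backbone$edge.length[k] / 2)
        ct <- ape::unroot(ct)
        ct$edge.length[ct$edge.length < 1e-9] <- 1e-9
        cand[[length(cand) + 1]] <- ct
        lls[length(lls) + 1] <- loglik_pruned(ct, pd, model)
      }
      for (j in order(-lls)[seq_len(min(2, length(lls)))]) {
        if (lls[j] < cur - 5) break   # no reattachment close to current
        fit <- optimize_bl_pruned(cand[[j]], pd, model, max_sweeps = 1)
        if (fit$logLik > cur + 1e-6) {
          tr <- fit$tree
          cur <- fit$logLik
          improved <- TRUE
          break
        }
      }
    }
    list(tree = tr, logLik = cur, improved = improved)
  }
  for (s in seq_len(n_starts)) {
    res <- climb(random_topology(taxa))
    repeat {
      sw <- reinsert_sweep(res$tree, res$logLik)
      if (!sw$improved) break
      res <- climb(sw$tree)
    }
    tr <- res$tree
    cur <- res$logLik
    canon <- canonical_newick(tr)
    if (cur > best_ll + 1e-9 ||
        (abs(cur - best_ll) <= 1e-9 && canon < best_canon)) {
      best <- tr
      best_ll <- cur
      best_canon <- canon
    }
  }
  # polish branch lengths of the winner only
  fit <- optimize_bl_pruned(best, pd, model, max_sweeps = 5, opt_tol = 1e-6)
  best <- fit$tree
  attr(best, "logLik") <- fit$logLik
  attr(best, "n_starts") <- n_starts
  best
}

#' Nonparametric bootstrap replicate trees
#'
#' Each replicate resamples alignment columns with replacement to the
#' original length and runs [search_ml_tree] from a single random start.
#' Deterministic given `seed`.
#'
#' @param aln `pseudo_alignment`
#' @param model [substitution_model]
#' @param n_reps number of replicates
#' @param seed integer seed
#' @return list of `phylo` trees (class `multiPhylo`)
#' @export
bootstrap_trees <- function(aln, model, n_reps = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_reps)
  n <- ncol(aln$chars)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_aln <- as_pseudoalignment(aln$chars[, idx, drop = FALSE])
    out[[r]] <- search_ml_tree(rep_aln, model, n_starts = 1, seed = NULL)
  }
  class(out) <- "multiPhylo"
  out
}
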