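# The pruning (post-order message passing) likelihood engine and
# coordinate-wise branch-length optimization.

#' Precompute pruning data for an alignment
#'
#' Compresses the alignment to unique site patterns with weights and builds
#' per-taxon tip likelihood matrices (4 x patterns indicator columns;
#' characters outside A,C,G,T are treated as fully ambiguous).
#'
#' @param aln `pseudo_alignment`
#' @return list with `tipL` (named list of 4 x npat matrices), `w`
#'   (pattern weights), `n_columns`
#' @export
pruning_data <- function(aln) {
  x <- aln$chars
  pat_id <- apply(x, 2, paste, collapse = "\r")
  tab <- table(pat_id)
  first <- match(names(tab), pat_id)
  pat <- x[, first, drop = FALSE]
  w <- as.numeric(tab)
  tipL <- lapply(rownames(x), function(tx) {
    m <- matrix(0, 4, length(w), dimnames = list(NUC, NULL))
    for (b in NUC) m[b, pat[tx, ] == b] <- 1
    ambiguous <- !(pat[tx, ] %in% NUC)
    if (any(ambiguous)) m[, ambiguous] <- 1
    m
  })
  names(tipL) <- rownames(x)
  list(tipL = tipL, w = w, n_columns = ncol(x))
}

# Core pruning evaluation against precomputed pattern data (C++ kernel).
loglik_pruned <- function(tree, pd, model) {
  if (any(tree$edge.length < 0)) stop("negative branch length")
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  tipL <- pd$tipL[tr$tip.label]
  if (any(vapply(tipL, is.null, logical(1)))) {
    stop("taxon not in alignment: ",
         paste(setdiff(tr$tip.label, names(pd$tipL)), collapse = ", "))
  }
  loglik_pruned_cpp(tr$edge, tr$edge.length, tipL, ntip, tr$Nnode,
                    model$right, model$eval, model$left,
                    unname(model$pi), pd$w)
}

#' Log-likelihood of an alignment on a tree
#'
#' Post-order pruning over the tree: each column's likelihood is the sum
#' over internal-state assignments of the product of transition
#' probabilities, computed in time linear in the number of edges. Equal to
#' (and tested against) exhaustive enumeration over internal states.
#'
#' @param tree `phylo`; leaf set must equal the alignment taxa; branch
#'   lengths in expected substitutions/site, all >= 0
#' @param aln `pseudo_alignment`
#' @param model [substitution_model]
#' @return log-likelihood (sum over columns)
#' @export
tree_loglik <- function(tree, aln, model) {
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree leaf set must equal alignment taxa")
  }
  loglik_pruned(tree, pruning_data(aln), model)
}

# Coordinate-wise branch-length optimization: golden-section (via
# stats::optimize) per edge, swept until the lnL gain drops below `tol`.
optimize_bl_pruned <- function(tree, pd, model, tol = 1e-6, max_sweeps = 10,
                               max_bl = 5, opt_tol = 1e-4) {
  tr <- stats::reorder(tree, "postorder")
  tipL <- pd$tipL[tr$tip.label]
  ntip <- length(tr$tip.label)
  len <- tr$edge.length
  eval_len <- function(l) {
    loglik_pruned_cpp(tr$edge, l, tipL, ntip, tr$Nnode, model$right,
                      model$eval, model$left, unname(model$pi), pd$w)
  }
  cur <- eval_len(len)
  prev_sweep <- -Inf
  for (sweep in seq_len(max_sweeps)) {
    for (k in seq_along(len)) {
      opt <- stats::optimize(function(b) {
        l2 <- len
        l2[k] <- b
        eval_len(l2)
      }, interval = c(1e-9, max_bl), maximum = TRUE, tol = opt_tol)
      if (opt$objective > cur) {
        len[k] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev_sweep < tol) break
    prev_sweep <- cur
  }
  tr$edge.length <- len
  list(tree = tr, logLik = cur)
}

#' Optimize branch lengths by per-branch univariate search
#'
#' @param tree `phylo` with starting branch lengths
#' @param aln `pseudo_alignment`
#' @param model [substitution_model]
#' @param tol stop when a full sweep improves lnL by less than this
#' @param max_sweeps sweep cap
#' @return list with `tree` (updated lengths) and `logLik`
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_sweeps = 10) {
  optimize_bl_pruned(tree, pruning_data(aln), model, tol, max_sweeps)
}
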