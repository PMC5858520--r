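# Clone-frequency fitting from VAFs: mutation clustering, constrained
# least squares on a candidate shape, model search over shapes x
# assignments x cluster counts, ancestral-clone detection.

#' Cluster mutations by their across-sample VAF profiles
#'
#' k-means on the mutations-by-samples VAF matrix. Deterministic given
#' `seed`; empty clusters (possible in degenerate inputs) are dropped and
#' the assignment relabeled contiguously.
#'
#' @param vafs numeric matrix, mutations x samples, entries in \[0, 1\]
#' @param k number of clusters (<= number of distinct profiles)
#' @param seed integer seed
#' @return list: `assignment` (integer per mutation), `centers` (k' x
#'   samples mean-VAF matrix), `k` (clusters actually returned)
#' @export
cluster_vafs <- function(vafs, k, seed = 1) {
  vafs <- as.matrix(vafs)
  n_distinct <- nrow(unique(vafs))
  k_eff <- min(k, n_distinct)
  set.seed(seed)
  if (k_eff == 1) {
    centers <- matrix(colMeans(vafs), 1, ncol(vafs),
                      dimnames = list(NULL, colnames(vafs)))
    return(list(assignment = rep(1L, nrow(vafs)), centers = centers, k = 1L))
  }
  km <- stats::kmeans(vafs, centers = k_eff, nstart = 10, iter.max = 100)
  keep <- which(km$size > 0)
  relab <- match(km$cluster, keep)
  list(assignment = as.integer(relab),
       centers = km$centers[keep, , drop = FALSE],
       k = length(keep))
}

# remove unassigned nodes from a clone tree by contracting them into their
# parent; returns the reduced clone_tree plus the relabeled assignment
reduce_clone_tree <- function(ct, assigned_nodes) {
  keep <- c("A", assigned_nodes)
  parent <- ct$parent
  up <- function(lb) {
    p <- parent[[lb]]
    while (p != "" && !(p %in% keep)) p <- parent[[p]]
    p
  }
  new_parent <- stats::setNames(vapply(keep, up, character(1)), keep)
  # rebuild as parent vector in preorder of the kept nodes
  kept_nonroot <- setdiff(keep, "A")
  ord <- kept_nonroot[order(vapply(kept_nonroot, function(lb) {
    d <- 0
    p <- new_parent[[lb]]
    while (p != "") {
      d <- d + 1
      p <- new_parent[[p]]
    }
    d
  }, numeric(1)))]
  idx <- stats::setNames(seq_along(ord), ord)
  pv <- vapply(ord, function(lb) {
    p <- new_parent[[lb]]
    if (p == "A") 0L else idx[[p]]
  }, integer(1))
  list(tree = clone_tree(pv), old_labels = ord)
}

#' Fit per-sample clone frequencies on one tree shape
#'
#' Model: a mutation cluster assigned to clone node v has predicted VAF
#' `0.5 * p_v(s)` in sample s, where `p_v(s)` is the prevalence of v's
#' subtree (the summed frequency of v and all its descendants) — diploid
#' heterozygous mutations, no copy-number correction. Frequencies are fit
#' per sample by least squares under non-negativity and a unit-sum simplex
#' that includes the normal root A. Nodes with no assigned cluster are
#' contracted into their parent first (their mass is not identifiable and
#' can always be absorbed without changing any predicted VAF).
#'
#' @param shape a [clone_tree]
#' @param cluster_nodes character vector: node label for each cluster
#'   (cluster i -> `cluster_nodes[i]`), injective over non-root nodes
#' @param cluster_vafs clusters x samples matrix of mean VAFs
#' @return object of class `clone_fit`: `tree` (reduced [clone_tree]),
#'   `cluster_nodes` (relabeled), `freqs` (nodes incl. A x samples),
#'   `objective` (sum of squared VAF residuals), `score` (`NA`, set by
#'   [select_best_fit])
#' @export
fit_clone_frequencies <- function(shape, cluster_nodes, cluster_vafs) {
  cluster_vafs <- as.matrix(cluster_vafs)
  k <- nrow(cluster_vafs)
  if (length(cluster_nodes) != k) {
    stop("need one node per cluster")
  }
  nonroot <- setdiff(shape$labels, "A")
  if (k > length(nonroot)) {
    stop("infeasible: more clusters (", k, ") than non-root nodes (",
         length(nonroot), ")")
  }
  if (anyDuplicated(cluster_nodes) || !all(cluster_nodes %in% nonroot)) {
    stop("cluster_nodes must be distinct non-root node labels")
  }
  red <- reduce_clone_tree(shape, cluster_nodes)
  ct <- red$tree
  relabel <- stats::setNames(setdiff(ct$labels, "A"), red$old_labels)
  cl_nodes <- unname(relabel[cluster_nodes])

  sub <- clone_subtree_matrix(ct)          # incl. A row/col
  nodes <- setdiff(ct$labels, "A")
  # design: predicted vaf of cluster i = 0.5 * sum_{u in subtree(node_i)} f_u
  M <- 0.5 * sub[cl_nodes, nodes, drop = FALSE]
  storage.mode(M) <- "double"
  ns <- ncol(cluster_vafs)
  freqs <- matrix(0, length(ct$labels), ns,
                  dimnames = list(ct$labels, colnames(cluster_vafs)))
  objective <- 0
  for (s in seq_len(ns)) {
    y <- cluster_vafs[, s]
    x <- solve_simplex_lsq(M, y)
    freqs[nodes, s] <- x
    freqs["A", s] <- max(0, 1 - sum(x))
    objective <- objective + sum((y - M %*% x)^2)
  }
  structure(list(tree = ct, cluster_nodes = cl_nodes, freqs = freqs,
                 objective = objective, score = NA_real_),
            class = "clone_fit")
}

# min ||y - M x||^2  s.t.  x >= 0, sum(x) <= 1   (M square full rank here)
solve_simplex_lsq <- function(M, y) {
  n <- ncol(M)
  x <- tryCatch(
    pracma::lsqlincon(M, y, A = matrix(1, 1, n), b = 1, lb = rep(0, n)),
    error = function(e) NULL
  )
  if (is.null(x) || anyNA(x)) x <- projected_gradient_lsq(M, y)
  x[x < 0] <- 0
  if (sum(x) > 1) x <- x / sum(x)
  x
}

# fallback solver: accelerated projected gradient onto {x >= 0, sum x <= 1}
projected_gradient_lsq <- function(M, y, iter = 5000) {
  n <- ncol(M)
  H <- crossprod(M)
  g0 <- crossprod(M, y)
  L <- max(eigen(H, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  x <- rep(1 / (n + 1), n)
  z <- x
  tk <- 1
  proj <- function(v) {
    v[v < 0] <- 0
    if (sum(v) > 1) {
      u <- sort(v, decreasing = TRUE)
      css <- cumsum(u)
      rho <- max(which(u - (css - 1) / seq_len(n) > 0))
      v <- pmax(v - (css[rho] - 1) / rho, 0)
    }
    v
  }
  for (i in seq_len(iter)) {
    xn <- proj(z - (H %*% z - g0) / L)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- xn + ((tk - 1) / tn) * (xn - x)
    if (max(abs(xn - x)) < 1e-12) {
      x <- xn
      break
    }
    x <- xn
    tk <- tn
  }
  as.numeric(x)
}

#' @export
print.clone_fit <- function(x, ...) {
  cat("clone_fit:", x$tree$n_nodes, "clones, objective",
      format(x$objective, digits = 4), "\n")
  invisible(x)
}

# distinct injective assignments of k clusters onto the non-root nodes of a
# shape, deduplicated over shape automorphisms via a labeled canonical form
assignments_for_shape <- function(shape, k) {
  nonroot <- setdiff(shape$labels, "A")
  if (k > length(nonroot)) return(list())
  perms <- permutations_of(nonroot, k)
  seen <- character(0)
  out <- list()
  for (p in perms) {
    sig <- labeled_canonical(shape, p)
    if (!(sig %in% seen)) {
      seen <- c(seen, sig)
      out[[length(out) + 1]] <- p
    }
  }
  out
}

permutations_of <- function(items, k) {
  if (k == 0) return(list(character(0)))
  out <- list()
  for (i in seq_along(items)) {
    for (rest in permutations_of(items[-i], k - 1)) {
      out[[length(out) + 1]] <- c(items[i], rest)
    }
  }
  out
}

# canonical string of a shape whose nodes carry cluster ids (0 = none)
labeled_canonical <- function(shape, cluster_nodes) {
  kids <- clone_children(shape)
  lab_of <- stats::setNames(rep(0L, length(shape$labels)), shape$labels)
  lab_of[cluster_nodes] <- seq_along(cluster_nodes)
  build <- function(node) {
    ks <- kids[[node]]
    inner <- if (length(ks) == 0) "" else
      paste(sort(vapply(ks, build, character(1))), collapse = "")
    paste0("(", lab_of[[node]], inner, ")")
  }
  build("A")
}

#' Search shapes, assignments and cluster counts for the best clone fit
#'
#' For each cluster count k in `k_range`, mutations are k-means-clustered
#' and every enumerated shape with exactly k clone nodes is fit under every
#' automorphism-distinct assignment of clusters to nodes (shapes with more
#' nodes than clusters reduce to these after contraction, so the scan is
#' complete). Fits are scored by
#' `mutation_objective + lambda * n_nodes * log(n_mutations * n_samples)`,
#' where `mutation_objective` sums squared VAF residuals over individual
#' mutations rather than cluster centers (a k-cluster fit on k nodes
#' reproduces the centers near-exactly, so a center-level score would
#' trivially favor a single clone); ties go to fewer nodes, then the
#' smaller canonical shape string.
#'
#' @param vafs mutations x samples VAF matrix
#' @param max_nodes largest clone count considered
#' @param k_range integer vector of cluster counts to scan (default
#'   `1:max_nodes`)
#' @param lambda penalty weight on the clone count
#' @param seed integer seed (clustering)
#' @return the best `clone_fit`, with `score` filled, plus attributes
#'   `assignment` (mutation -> cluster) and `k`
#' @export
select_best_fit <- function(vafs, max_nodes = 9, k_range = NULL, lambda = 0.05,
                            seed = 1) {
  vafs <- as.matrix(vafs)
  k_range <- k_range %||% seq_len(max_nodes)
  k_range <- k_range[k_range <= nrow(vafs) & k_range <= max_nodes]
  if (length(k_range) == 0) stop("empty k_range")
  shapes <- enumerate_clone_trees(max_nodes)
  shape_sizes <- vapply(shapes, `[[`, integer(1), "n_nodes")
  penalty_unit <- log(nrow(vafs) * ncol(vafs))

  best <- NULL
  for (k in k_range) {
    cl <- cluster_vafs(vafs, k, seed = seed)
    for (sh in shapes[shape_sizes == cl$k]) {
      for (asg in assignments_for_shape(sh, cl$k)) {
        fit <- fit_clone_frequencies(sh, asg, cl$centers)
        prev <- (clone_subtree_matrix(fit$tree) + 0) %*% fit$freqs
        pred <- 0.5 * prev[fit$cluster_nodes, , drop = FALSE]
        fit$mutation_objective <-
          sum((vafs - pred[cl$assignment, , drop = FALSE])^2)
        fit$score <- fit$mutation_objective + lambda * cl$k * penalty_unit
        if (is.null(best) ||
            fit$score < best$score - 1e-12 ||
            (abs(fit$score - best$score) <= 1e-12 &&
             (fit$tree$n_nodes < best$tree$n_nodes ||
              (fit$tree$n_nodes == best$tree$n_nodes &&
               fit$tree$canonical < best$tree$canonical)))) {
          attr(fit, "assignment") <- cl$assignment
          attr(fit, "k") <- cl$k
          best <- fit
        }
      }
    }
  }
  best
}

#' Detect ancestral clones in each sample
#'
#' An ancestral clone is a direct child of the normal root A. A sample is
#' flagged when any such clone has fitted frequency at or above
#' `threshold`; the summary lists which peritoneal (omentum/bowel) samples
#' carry ancestral clones.
#'
#' @param fit a `clone_fit`
#' @param site_labels named character vector sample -> site
#' @param threshold minimum clone frequency (cell fraction)
#' @return list: `per_sample` data.frame (`sample`, `site`,
#'   `ancestral_present`, `ancestral_frequency`),
#'   `peritoneal_with_ancestral` (sample names)
#' @export
detect_ancestral_clones <- function(fit, site_labels, threshold = 0.05) {
  a_children <- names(fit$tree$parent)[fit$tree$parent == "A"]
  samples <- colnames(fit$freqs)
  freq <- if (length(a_children) > 0) {
    apply(fit$freqs[a_children, , drop = FALSE], 2, max)
  } else rep(0, length(samples))
  per <- data.frame(
    sample = samples,
    site = unname(site_labels[samples]),
    ancestral_present = freq >= threshold,
    ancestral_frequency = unname(freq),
    stringsAsFactors = FALSE
  )
  peri <- per$sample[per$ancestral_present &
                       per$site %in% c("omentum", "bowel")]
  list(per_sample = per, peritoneal_with_ancestral = peri)
}
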