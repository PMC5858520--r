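# Rooted clone-tree shape enumeration. Clone "A" is the normal root with a
# single child (the founder clone); shapes are the non-isomorphic rooted
# unlabeled trees on the non-root nodes.

# All canonical shape strings for rooted trees with n nodes. A tree is
# "(" + sorted concatenation of child subtree strings + ")"; generation is
# canonical by construction (child multisets chosen non-decreasing).
rooted_shape_strings <- function(n, cache = new.env(parent = emptyenv())) {
  key <- as.character(n)
  if (!is.null(cache[[key]])) return(cache[[key]])
  if (n == 1) {
    cache[[key]] <- "()"
    return(cache[[key]])
  }
  out <- character(0)
  # choose multisets of subtrees with sizes summing to n-1
  partitions <- integer_partitions(n - 1)
  for (part in partitions) {
    # part: non-increasing sizes; enumerate multisets of trees per size
    per_size <- lapply(unique(part), function(s) {
      m <- sum(part == s)
      multiset_combos(rooted_shape_strings(s, cache), m)
    })
    combos <- Reduce(function(a, b) {
      unlist(lapply(a, function(x) lapply(b, function(y) c(x, y))),
             recursive = FALSE)
    }, per_size, accumulate = FALSE)
    for (kids in combos) {
      out <- c(out, paste0("(", paste(sort(kids), collapse = ""), ")"))
    }
  }
  cache[[key]] <- unique(out)
  cache[[key]]
}

# partitions of n into non-increasing positive parts
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq(min(n, max_part), 1)) {
    for (rest in integer_partitions(n - p, p)) {
      out[[length(out) + 1]] <- c(p, rest)
    }
  }
  out
}

# multisets (combinations with repetition) of size m from items
multiset_combos <- function(items, m) {
  if (m == 0) return(list(character(0)))
  out <- list()
  recurse <- function(start, chosen) {
    if (length(chosen) == m) {
      out[[length(out) + 1]] <<- chosen
      return()
    }
    for (i in start:length(items)) recurse(i, c(chosen, items[[i]]))
  }
  recurse(1, character(0))
  out
}

# parse a canonical shape string into a parent vector (node 1 = subtree
# root, preorder)
shape_to_parent <- function(s) {
  chars <- strsplit(s, "")[[1]]
  parent <- integer(0)
  stack <- integer(0)
  for (ch in chars) {
    if (ch == "(") {
      node <- length(parent) + 1L
      parent[node] <- if (length(stack) > 0) stack[length(stack)] else 0L
      stack <- c(stack, node)
    } else {
      stack <- stack[-length(stack)]
    }
  }
  parent
}

#' A clone tree object from a parent map
#'
#' Nodes are labeled `A` (normal root), `B`, `C`, ... in preorder; `A`'s
#' single child `B` is the founder clone.
#'
#' @param parent integer vector over the non-root nodes: parent of node i
#'   within the founder subtree (0 = attached to A)
#' @return object of class `clone_tree`: `labels`, `parent` (named
#'   character: node -> parent label, `A -> ""`), `n_nodes` (non-root
#'   count), `canonical` shape string
#' @export
clone_tree <- function(parent) {
  n <- length(parent)
  if (n < 1) stop("a clone tree needs at least one non-root node")
  labels <- if (n + 1 <= 26) LETTERS[seq_len(n + 1)] else
    c(LETTERS, paste0("A", LETTERS))[seq_len(n + 1)]
  pmap <- stats::setNames(rep("", n + 1), labels)
  for (i in seq_len(n)) {
    pmap[labels[i + 1]] <- labels[parent[i] + 1]
  }
  structure(list(labels = labels, parent = pmap, n_nodes = n,
                 canonical = canonical_shape(parent)),
            class = "clone_tree")
}

canonical_shape <- function(parent) {
  n <- length(parent)
  children <- lapply(0:n, function(p) which(parent == p))
  build <- function(node) {
    kids <- children[[node + 1]]
    if (length(kids) == 0) return("()")
    paste0("(", paste(sort(vapply(kids, build, character(1))),
                      collapse = ""), ")")
  }
  build(1)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("clone_tree:", x$n_nodes, "clone(s) under A;",
      paste(sprintf("%s->%s", names(x$parent)[-1], x$parent[-1]),
            collapse = " "), "\n")
  invisible(x)
}

#' Enumerate all clone-tree shapes up to a node budget
#'
#' Generates every non-isomorphic rooted tree shape with 1..`max_nodes`
#' clone nodes hanging below the normal root `A` (which has a single child,
#' the founder clone). Canonical-form generation guarantees completeness
#' without duplicates: counts by node number are 1, 1, 2, 4, 9, 20, 48,
#' 115, 286 for n = 1..9 (486 shapes in total at the default budget).
#'
#' @param max_nodes maximum number of non-root nodes (>= 1)
#' @return list of [clone_tree] objects
#' @export
enumerate_clone_trees <- function(max_nodes = 9) {
  if (max_nodes < 1) stop("max_nodes must be >= 1")
  cache <- new.env(parent = emptyenv())
  out <- list()
  for (n in seq_len(max_nodes)) {
    for (s in rooted_shape_strings(n, cache)) {
      out[[length(out) + 1]] <- clone_tree(shape_to_parent(s))
    }
  }
  out
}

# children lists and subtree membership for a clone_tree
clone_children <- function(ct) {
  lapply(stats::setNames(ct$labels, ct$labels), function(lb)
    names(ct$parent)[ct$parent == lb])
}

# logical matrix: desc[v, u] = u is in the subtree rooted at v
clone_subtree_matrix <- function(ct) {
  labs <- ct$labels
  m <- diag(length(labs)) == 1
  dimnames(m) <- list(labs, labs)
  for (u in labs[-1]) {
    anc <- ct$parent[[u]]
    while (anc != "") {
      m[anc, u] <- TRUE
      anc <- ct$parent[[anc]]
    }
  }
  m
}
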