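# Bipartition bookkeeping, majority-rule consensus, support mapping, and
# the early/late-divergence classifier.

# Canonical key of one bipartition: the side not containing the reference
# (lexicographically smallest) taxon, sorted and joined with "|".
split_key <- function(side, all_taxa) {
  ref <- sort(all_taxa)[1]
  if (ref %in% side) side <- setdiff(all_taxa, side)
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of a tree
#' @param tree `phylo`
#' @return character vector of canonical split keys
#' @export
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  tips <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- tr$tip.label[i]
  e <- tr$edge
  for (k in seq_len(nrow(e))) {
    tips[[e[k, 1]]] <- c(tips[[e[k, 1]]], tips[[e[k, 2]]])
  }
  internal_children <- unique(e[e[, 2] > ntip, 2])
  keys <- vapply(internal_children, function(nd) {
    side <- tips[[nd]]
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    split_key(side, tr$tip.label)
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bipartition frequencies across a set of trees
#' @param trees list of `phylo` on a common taxon set
#' @return named numeric vector: occurrence count per canonical split key
#' @export
count_splits <- function(trees) {
  tab <- table(unlist(lapply(trees, tree_splits)))
  out <- as.numeric(tab)
  names(out) <- names(tab)
  out
}

#' Majority-rule consensus tree
#'
#' Retains exactly the bipartitions present in strictly more than half of
#' the input trees; these are mutually compatible, so they assemble into a
#' single (possibly unresolved) tree whose internal node labels carry the
#' support, `100 * frequency`, rounded to 1 decimal.
#'
#' @param trees list of `phylo` trees on the same taxa
#' @return `phylo` with supports in `node.label`
#' @export
majority_rule_consensus <- function(trees) {
  if (length(trees) == 0) stop("no trees")
  taxa <- sort(trees[[1]]$tip.label)
  counts <- count_splits(trees)
  freq <- counts / length(trees)
  maj <- freq[freq > 0.5]
  clades <- lapply(names(maj), function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  supports <- round(100 * as.numeric(maj), 1)
  # sort clades large -> small; parent = smallest strictly containing clade
  ord <- order(-vapply(clades, length, integer(1)))
  clades <- clades[ord]
  supports <- supports[ord]
  nc <- length(clades)
  parent <- rep(0L, nc)             # 0 = root
  if (nc > 1) {
    for (i in seq_len(nc)) {
      for (j in seq_len(nc)) {
        if (i != j && length(clades[[j]]) > length(clades[[i]]) &&
            all(clades[[i]] %in% clades[[j]])) {
          if (parent[i] == 0L ||
              length(clades[[j]]) < length(clades[[parent[i]]])) {
            parent[i] <- j
          }
        }
      }
      overlap <- vapply(seq_len(nc), function(j) i != j &&
        any(clades[[i]] %in% clades[[j]]) &&
        !all(clades[[i]] %in% clades[[j]]) &&
        !all(clades[[j]] %in% clades[[i]]), logical(1))
      if (any(overlap)) stop("majority bipartitions conflict")
    }
  }
  # tip -> smallest containing clade (0 = root)
  tip_parent <- vapply(taxa, function(tx) {
    holders <- which(vapply(clades, function(cl) tx %in% cl, logical(1)))
    if (length(holders) == 0) return(0L)
    holders[which.min(vapply(holders, function(h) length(clades[[h]]),
                             integer(1)))]
  }, integer(1))
  build <- function(id) {
    kid_clades <- which(parent == id)
    kid_tips <- taxa[tip_parent == id]
    parts <- c(kid_tips,
               vapply(kid_clades, function(k)
                 paste0(build(k), format(supports[k], nsmall = 1)),
                 character(1)))
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(0L), ";"))
}

#' Map bootstrap support onto the best tree
#'
#' Annotates each internal edge of `best_tree` with the percentage of
#' `boot_trees` containing that bipartition (`node.label`, 1 decimal;
#' 0 when absent from every replicate).
#'
#' @param best_tree `phylo` (e.g. from [search_ml_tree])
#' @param boot_trees list of bootstrap trees (e.g. [bootstrap_trees])
#' @return `best_tree` with supports in `node.label`
#' @export
map_support_onto_best <- function(best_tree, boot_trees) {
  counts <- count_splits(boot_trees)
  n <- length(boot_trees)
  ntip <- length(best_tree$tip.label)
  tr <- stats::reorder(best_tree, "postorder")
  tips <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tips[[i]] <- tr$tip.label[i]
  e <- tr$edge
  for (k in seq_len(nrow(e))) {
    tips[[e[k, 1]]] <- c(tips[[e[k, 1]]], tips[[e[k, 2]]])
  }
  labs <- rep("", tr$Nnode)
  for (nd in (ntip + 1):(ntip + tr$Nnode)) {
    side <- tips[[nd]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- split_key(side, tr$tip.label)
    hits <- if (key %in% names(counts)) counts[[key]] else 0
    labs[nd - ntip] <- format(round(100 * hits / n, 1), nsmall = 1)
  }
  tr$node.label <- labs
  tr
}

#' Classify early vs late peritoneal divergence from a sample tree
#'
#' Roots the tree on the normal taxon, finds the smallest clade containing
#' all ovarian samples, and reports for each non-ovarian tumor sample
#' whether it attaches outside (ancestral to) that clade. The patient is
#' labelled peritoneal-early when at least one omentum/bowel sample is
#' ancestral and the ovarian clade's support meets `support_threshold`
#' (trees without support values count as fully supported).
#'
#' @param tree `phylo` containing the normal taxon (support values in
#'   `node.label` if available)
#' @param site_labels named character vector sample ->
#'   `"ovary"`/`"omentum"`/`"bowel"`
#' @param normal_label the normal taxon name
#' @param support_threshold minimum ovarian-clade support (percent)
#' @return list: `per_sample` data.frame (`sample`, `site`, `ancestral`),
#'   `ovarian_clade_support`, `peritoneal_early`
#' @export
classify_divergence <- function(tree, site_labels, normal_label = "normal",
                                support_threshold = 50) {
  if (!normal_label %in% tree$tip.label) stop("normal taxon not in tree")
  # supports are attached to bipartitions, which survive re-rooting even
  # though ape's node numbering does not
  support_of <- function(side) {
    if (is.null(tree$node.label)) return(NA_real_)
    ntip <- length(tree$tip.label)
    tr <- stats::reorder(tree, "postorder")
    tips <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) tips[[i]] <- tr$tip.label[i]
    for (k in seq_len(nrow(tr$edge))) {
      tips[[tr$edge[k, 1]]] <- c(tips[[tr$edge[k, 1]]], tips[[tr$edge[k, 2]]])
    }
    want <- split_key(side, tr$tip.label)
    for (nd in (ntip + 1):(ntip + tr$Nnode)) {
      if (split_key(tips[[nd]], tr$tip.label) == want) {
        return(suppressWarnings(as.numeric(tr$node.label[nd - ntip])))
      }
    }
    NA_real_
  }
  rt <- ape::root(ape::unroot(tree), outgroup = normal_label,
                  resolve.root = TRUE)
  ovarian <- names(site_labels)[site_labels == "ovary"]
  ovarian <- intersect(ovarian, rt$tip.label)
  if (length(ovarian) < 2) stop("need >= 2 ovarian samples in the tree")
  mrca <- ape::getMRCA(rt, ovarian)
  clade_tips <- ape::extract.clade(rt, mrca)$tip.label
  support <- support_of(clade_tips)
  eff_support <- if (is.na(support)) 100 else support
  others <- setdiff(names(site_labels), c(ovarian, normal_label))
  others <- intersect(others, rt$tip.label)
  per <- data.frame(
    sample = others,
    site = unname(site_labels[others]),
    ancestral = !(others %in% clade_tips),
    stringsAsFactors = FALSE
  )
  peritoneal <- per$site %in% c("omentum", "bowel")
  list(
    per_sample = per,
    ovarian_clade_support = support,
    peritoneal_early = any(per$ancestral[peritoneal]) &&
      eff_support >= support_threshold
  )
}
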