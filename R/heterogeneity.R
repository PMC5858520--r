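# Intratumor-heterogeneity quantification: the joint-coverage mutation
# matrix, shared/unique summaries, per-sample count statistics, and the
# heatmap-ready VAF matrix.

infer_site <- function(samples) {
  site <- rep(NA_character_, length(samples))
  site[grepl("^ov", samples, ignore.case = TRUE)] <- "ovary"
  site[grepl("^om", samples, ignore.case = TRUE)] <- "omentum"
  site[grepl("^bw|^bo", samples, ignore.case = TRUE)] <- "bowel"
  names(site) <- samples
  site
}

#' Build the samples-by-variants mutation matrix under joint coverage
#'
#' Collects one patient's per-sample consensus variants into
#' presence/VAF/covered grids and keeps only variant positions where the
#' coverage thresholds are met in EVERY tumor sample and in the normal —
#' without this joint constraint, a call private to one sample could be an
#' artifact of missing coverage elsewhere rather than genuine heterogeneity.
#'
#' @param per_sample_variants named list of variant tables (one per tumor
#'   sample of the patient)
#' @param depth_table long-format depth table covering all samples + normal
#' @param cfg [filter_config] supplying the depth thresholds
#' @param patient patient label
#' @param sites named character vector sample -> site
#'   (`"ovary"`/`"omentum"`/`"bowel"`); inferred from sample-name prefixes
#'   when `NULL`
#' @param normal_sample normal sample id in `depth_table`
#' @return object of class `mutation_matrix`: list with `patient`,
#'   `samples`, `sites`, `variants` (data.frame of keys), and
#'   variants-by-samples `presence`, `vaf`, `covered` matrices
#' @export
build_mutation_matrix <- function(per_sample_variants, depth_table, cfg,
                                  patient = "patient", sites = NULL,
                                  normal_sample = "normal") {
  samples <- names(per_sample_variants)
  if (length(samples) < 2) stop("need at least 2 samples to assess sharing")
  sites <- sites %||% infer_site(samples)

  all <- do.call(rbind, Map(function(v, s) {
    if (nrow(v) == 0) return(NULL)
    v$sample <- s
    v
  }, per_sample_variants, samples))
  if (is.null(all) || nrow(all) == 0) stop("no variants in any sample")
  uni <- all[!duplicated(variant_key(all)),
             c("chrom", "pos", "ref", "alt", "kind"), drop = FALSE]
  uni <- uni[order(uni$chrom, uni$pos, uni$ref, uni$alt), , drop = FALSE]
  uni$key <- variant_key(uni)
  rownames(uni) <- NULL
  nv <- nrow(uni)

  presence <- matrix(FALSE, nv, length(samples),
                     dimnames = list(uni$key, samples))
  vaf <- matrix(0, nv, length(samples), dimnames = dimnames(presence))
  covered <- matrix(FALSE, nv, length(samples), dimnames = dimnames(presence))
  pk <- position_key(uni)
  for (s in samples) {
    covered[, s] <- depth_lookup(depth_table, pk, s) >= cfg$min_tumor_depth
    vs <- per_sample_variants[[s]]
    idx <- match(variant_key(vs), uni$key)
    presence[idx, s] <- TRUE
    vaf[idx, s] <- ifelse(is.na(vs$vaf), 0, vs$vaf)
  }
  normal_ok <- depth_lookup(depth_table, pk, normal_sample) >=
    cfg$min_normal_depth

  keep <- normal_ok & apply(covered, 1, all)
  structure(list(
    patient = patient, samples = samples, sites = sites,
    variants = uni[keep, , drop = FALSE],
    presence = presence[keep, , drop = FALSE],
    vaf = vaf[keep, , drop = FALSE],
    covered = covered[keep, , drop = FALSE]
  ), class = "mutation_matrix")
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat("mutation_matrix:", x$patient, "-", nrow(x$variants),
      "fully covered variants x", length(x$samples), "samples\n")
  invisible(x)
}

#' Shared-mutation summary for a sample group
#'
#' `total` counts distinct variants present in at least one group member;
#' `shared` counts those present in every member; `percent` is
#' `100 * shared / total`, rounded half-up to 2 decimals.
#'
#' @param matrix a [build_mutation_matrix] result
#' @param group character vector of sample names (subset of
#'   `matrix$samples`), or a single site name (`"ovary"`, `"omentum"`,
#'   `"bowel"`, `"all"`)
#' @param label group label for the output row
#' @return one-row data.frame: `group`, `total`, `shared`, `percent`
#' @export
shared_fraction <- function(matrix, group, label = NULL) {
  if (length(group) == 1 && group %in% c("ovary", "omentum", "bowel", "all")) {
    label <- label %||% group
    group <- if (group == "all") matrix$samples else
      names(matrix$sites)[matrix$sites == group]
  }
  if (length(group) == 0) stop("empty sample group")
  if (!all(group %in% matrix$samples)) {
    stop("unknown samples: ",
         paste(setdiff(group, matrix$samples), collapse = ", "))
  }
  p <- matrix$presence[, group, drop = FALSE]
  total <- sum(rowSums(p) >= 1)
  shared <- sum(rowSums(p) == length(group))
  data.frame(group = label %||% paste(group, collapse = "+"),
             total = total, shared = shared,
             percent = if (total > 0) round_half_up(100 * shared / total, 2)
                       else NA_real_,
             stringsAsFactors = FALSE)
}

#' Region and all-region sharing table for one patient
#' @param matrix a [build_mutation_matrix] result
#' @return data.frame with one row per region plus `all`
#' @export
sharing_summary <- function(matrix) {
  groups <- intersect(c("ovary", "omentum", "bowel"), unique(matrix$sites))
  do.call(rbind, lapply(c(groups, "all"), function(g)
    shared_fraction(matrix, g)))
}

#' Per-sample variant counts with median and range
#'
#' @param x either a named list of variant tables or a named numeric vector
#'   of per-sample counts (e.g. a published count table fed back in)
#' @return list with `counts` (data.frame `sample`, `n`), `median`, `min`,
#'   `max`
#' @export
per_sample_counts <- function(x) {
  n <- if (is.numeric(x)) x else vapply(x, nrow, integer(1))
  if (length(n) == 0) stop("no samples")
  list(
    counts = data.frame(sample = names(n) %||% seq_along(n),
                        n = as.integer(n), stringsAsFactors = FALSE),
    median = stats::median(n), min = min(n), max = max(n)
  )
}

#' Export the heatmap-ordered VAF matrix
#'
#' Rows are variants, truncal-first: variants present in every sample sort
#' to the top (descending mean VAF), then the rest by number of carrying
#' samples and mean VAF. Columns are samples in ovary, omentum, bowel
#' order. Catalogued-somatic (COSMIC-style) variants are flagged when an
#' annotation table with a `cosmic` column is supplied. Absent calls render
#' as VAF 0.
#'
#' @param matrix a [build_mutation_matrix] result
#' @param annotations optional data.frame with variant keys plus `gene`
#'   and/or logical `cosmic` columns
#' @param path optional TSV output path
#' @return data.frame (variant metadata + ordered VAF columns), invisibly
#'   when `path` is given
#' @export
vaf_matrix_export <- function(matrix, annotations = NULL, path = NULL) {
  site_order <- c("ovary", "omentum", "bowel")
  cols <- unlist(lapply(site_order, function(st)
    names(matrix$sites)[matrix$sites == st]))
  cols <- c(cols, setdiff(matrix$samples, cols))
  v <- matrix$vaf[, cols, drop = FALSE]
  p <- matrix$presence[, cols, drop = FALSE]
  truncal <- rowSums(p) == ncol(p)
  ord <- order(-truncal, -rowSums(p), -rowMeans(v))
  out <- cbind(matrix$variants[ord, c("chrom", "pos", "ref", "alt", "key")],
               truncal = truncal[ord],
               as.data.frame(v[ord, , drop = FALSE]))
  if (!is.null(annotations)) {
    idx <- match(out$key, variant_key(annotations))
    if (!is.null(annotations$gene)) out$gene <- annotations$gene[idx]
    if (!is.null(annotations$cosmic)) {
      out$cosmic <- !is.na(idx) & isTRUE_vec(annotations$cosmic[idx])
    }
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

isTRUE_vec <- function(x) !is.na(x) & x
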