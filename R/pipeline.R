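# End-to-end orchestration: consensus -> heterogeneity -> sample phylogeny
# -> clonal inference, with per-stage artifacts and a manifest.

#' Pipeline configuration
#'
#' Two presets: `"desk"` (10 search starts, 50 bootstrap replicates, clone
#' trees up to 6 nodes) for routine runs and tests, and `"paper"` (100
#' starts, 200 replicates, up to 9 nodes) matching the full-scale study
#' settings. Individual fields can be overridden; unknown keys are
#' rejected.
#'
#' @param preset `"desk"` or `"paper"`
#' @param ... overrides for top-level fields (`filter`, `coverage_mode`,
#'   `n_starts`, `n_boot`, `model_candidates`, `max_nodes`, `k_range`,
#'   `lambda`, `ancestral_threshold`, `divergence_support`, `seed`)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(preset = c("desk", "paper"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    filter = filter_config(),
    coverage_mode = "all-samples",
    model_candidates = c("JC69", "K80", "HKY85"),
    n_starts = if (preset == "desk") 10L else 100L,
    n_boot = if (preset == "desk") 50L else 200L,
    max_nodes = if (preset == "desk") 6L else 9L,
    k_range = NULL,
    lambda = 0.01,
    ancestral_threshold = 0.05,
    divergence_support = 50,
    seed = 17L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown pipeline_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose top-level keys are [pipeline_config] fields
#'   (plus optional `preset`); `filter` may be a mapping of
#'   [filter_config] arguments
#' @return `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- y$preset %||% "desk"
  y$preset <- NULL
  if (!is.null(y$filter)) y$filter <- do.call(filter_config, y$filter)
  do.call(pipeline_config, c(list(preset = preset), y))
}

# restrict a mutation_matrix to a key subset
mm_subset <- function(m, keys) {
  keep <- m$variants$key %in% keys
  m$variants <- m$variants[keep, , drop = FALSE]
  m$presence <- m$presence[keep, , drop = FALSE]
  m$vaf <- m$vaf[keep, , drop = FALSE]
  m$covered <- m$covered[keep, , drop = FALSE]
  m
}

#' Graphviz DOT rendering of a clone fit
#' @param fit `clone_fit`
#' @param path output file
#' @export
write_clone_dot <- function(fit, path) {
  lines <- c("digraph clones {", "  node [shape=circle];")
  for (nd in names(fit$tree$parent)) {
    p <- fit$tree$parent[[nd]]
    if (p != "") lines <- c(lines, sprintf("  %s -> %s;", p, nd))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

# discover <sample>.<caller>.vcf files in a patient directory
discover_caller_vcfs <- function(pdir) {
  files <- list.files(pdir, pattern = "\\.vcf$")
  files <- setdiff(files, "normal.vcf")
  parts <- strsplit(sub("\\.vcf$", "", files), ".", fixed = TRUE)
  ok <- lengths(parts) == 2
  data.frame(
    file = file.path(pdir, files[ok]),
    sample = vapply(parts[ok], `[[`, character(1), 1),
    caller = vapply(parts[ok], `[[`, character(1), 2),
    stringsAsFactors = FALSE
  )
}

#' Run the analysis for one patient directory
#'
#' Expects the interchange layout the simulator emits:
#' `<sample>.<caller>.vcf`, `normal.vcf`, `depths.tsv`,
#' `annotations.tsv`, optional `population_sites.bed` /
#' `editing_sites.bed`.
#'
#' @param pdir patient directory
#' @param out_dir artifact directory (created); `NULL` for no file output
#' @param cfg [pipeline_config]
#' @return list with `consensus` (per-sample fully filtered variant
#'   tables), `somatic` (per-sample consensus after germline subtraction
#'   only), `ledgers`, `matrix`, `sharing`, `counts`, `tree`,
#'   `model_table`, `divergence`, `clone_fit`, `ancestral`
#' @export
run_patient_analysis <- function(pdir, out_dir = NULL, cfg = pipeline_config()) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  vfiles <- discover_caller_vcfs(pdir)
  if (nrow(vfiles) == 0) stop("no caller VCFs found in ", pdir)
  samples <- sort(unique(vfiles$sample))
  depth_table <- read_depth_table(file.path(pdir, "depths.tsv"))
  germline <- read_caller_vcf(file.path(pdir, "normal.vcf"), "normal")
  ann_path <- file.path(pdir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) {
    utils::read.table(ann_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  } else NULL
  pop_path <- file.path(pdir, "population_sites.bed")
  edit_path <- file.path(pdir, "editing_sites.bed")
  pop_sites <- if (file.exists(pop_path)) read_bed_sites(pop_path) else NULL
  edit_sites <- if (file.exists(edit_path)) read_bed_sites(edit_path) else NULL

  consensus <- list()
  somatic <- list()
  ledgers <- list()
  for (s in samples) {
    vf <- vfiles[vfiles$sample == s, , drop = FALSE]
    sets <- Map(read_caller_vcf, vf$file, vf$caller)
    names(sets) <- vf$caller
    indel_callers <- intersect(names(sets), c("mutect2", "haplotypecaller"))
    cons <- consensus_calls(
      sets,
      indel_sets = if (length(indel_callers) >= cfg$filter$min_indel_callers)
        sets[indel_callers] else list(),
      cfg = cfg$filter
    )
    tumor_req <- if (cfg$coverage_mode == "all-samples") samples else s
    casc <- apply_filter_cascade(
      cons, depth_table, cfg$filter, tumor_req, normal_vcf = germline,
      population_sites = pop_sites, editing_sites = edit_sites,
      mode = cfg$coverage_mode
    )
    somatic[[s]] <- apply_germline_filter(cons, germline)$variants
    consensus[[s]] <- casc$variants
    ledgers[[s]] <- casc$ledger
    if (!is.null(out_dir)) {
      utils::write.table(casc$variants,
                         file.path(out_dir, paste0(s, ".variants.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(casc$ledger,
                         file.path(out_dir, paste0(s, ".ledger.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  counts <- per_sample_counts(consensus)
  m <- build_mutation_matrix(consensus, depth_table, cfg$filter,
                             patient = basename(pdir))
  sharing <- sharing_summary(m)

  # phylogeny from synonymous + non-synonymous SNVs (drop unannotated)
  phylo_keys <- m$variants$key
  nonsyn_keys <- phylo_keys
  if (!is.null(annotations)) {
    akey <- variant_key(annotations)
    cls <- annotations$class[match(phylo_keys, akey)]
    phylo_keys <- phylo_keys[!is.na(cls)]
    nonsyn_keys <- m$variants$key[!is.na(cls) & cls != "synonymous"]
  }
  aln <- build_pseudoalignment(mm_subset(m, phylo_keys))
  set.seed(cfg$seed)
  sel <- select_model(aln, cfg$model_candidates)
  best <- search_ml_tree(aln, sel$model, n_starts = cfg$n_starts)
  if (cfg$n_boot > 0) {
    boots <- bootstrap_trees(aln, sel$model, n_reps = cfg$n_boot)
    best <- map_support_onto_best(best, boots)
  }
  divergence <- classify_divergence(best, m$sites, normal_label = "normal",
                                    support_threshold = cfg$divergence_support)

  mm_ns <- mm_subset(m, nonsyn_keys)
  fit <- NULL
  ancestral <- NULL
  if (nrow(mm_ns$vaf) >= 1) {
    fit <- select_best_fit(mm_ns$vaf, max_nodes = cfg$max_nodes,
                           k_range = cfg$k_range, lambda = cfg$lambda,
                           seed = cfg$seed)
    attr(fit, "mutation_keys") <- rownames(mm_ns$vaf)
    ancestral <- detect_ancestral_clones(fit, m$sites,
                                         threshold = cfg$ancestral_threshold)
  }

  if (!is.null(out_dir)) {
    utils::write.table(sharing, file.path(out_dir, "sharing.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    vaf_matrix_export(m, annotations, file.path(out_dir, "vaf_matrix.tsv"))
    ape::write.tree(best, file.path(out_dir, "sample_tree.nwk"))
    jsonlite::write_json(list(
      peritoneal_early = divergence$peritoneal_early,
      ovarian_clade_support = divergence$ovarian_clade_support,
      per_sample = divergence$per_sample
    ), file.path(out_dir, "divergence.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(fit)) {
      jsonlite::write_json(list(
        parent = as.list(fit$tree$parent),
        cluster_nodes = fit$cluster_nodes,
        objective = fit$objective,
        frequencies = as.data.frame(t(fit$freqs))
      ), file.path(out_dir, "clone_tree.json"), auto_unbox = TRUE,
        digits = NA)
      write_clone_dot(fit, file.path(out_dir, "clone_tree.dot"))
    }
  }

  list(consensus = consensus, somatic = somatic, ledgers = ledgers,
       matrix = m,
       sharing = sharing, counts = counts, tree = best,
       model_table = sel$table, divergence = divergence, clone_fit = fit,
       ancestral = ancestral)
}

#' Run the full pipeline over a cohort directory
#'
#' Processes each `patient*` subdirectory with [run_patient_analysis],
#' writes per-patient artifacts plus cohort-level per-sample-count and
#' sharing tables, and a manifest recording the package version, seed and
#' input digests. Reruns with the same inputs, configuration and seed are
#' byte-identical.
#'
#' @param input_dir cohort directory (one subdirectory per patient)
#' @param out_dir output directory
#' @param cfg [pipeline_config]
#' @return named list of per-patient results, invisibly
#' @export
run_pipeline <- function(input_dir, out_dir, cfg = pipeline_config()) {
  pdirs <- list.dirs(input_dir, recursive = FALSE)
  pdirs <- pdirs[vapply(pdirs, function(d)
    nrow(discover_caller_vcfs(d)) > 0, logical(1))]
  if (length(pdirs) == 0) stop("no patient directories under ", input_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  for (pd in pdirs) {
    pid <- basename(pd)
    results[[pid]] <- run_patient_analysis(pd, file.path(out_dir, pid), cfg)
  }

  count_tab <- do.call(rbind, lapply(names(results), function(pid) {
    cts <- results[[pid]]$counts$counts
    stats::setNames(as.data.frame(t(cts$n)), cts$sample)
  }))
  rownames(count_tab) <- names(results)
  utils::write.table(cbind(patient = rownames(count_tab), count_tab),
                     file.path(out_dir, "per_sample_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  share_tab <- do.call(rbind, lapply(names(results), function(pid) {
    cbind(patient = pid, results[[pid]]$sharing)
  }))
  utils::write.table(share_tab, file.path(out_dir, "region_sharing.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  inputs <- list.files(input_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = as.character(utils::packageVersion("clonalspread")),
    seed = cfg$seed,
    coverage_mode = cfg$coverage_mode,
    n_starts = cfg$n_starts, n_boot = cfg$n_boot,
    max_nodes = cfg$max_nodes,
    inputs = as.list(tools::md5sum(inputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
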